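# Synthetic county and HPSA data with the statistical structure the pipeline
# assumes: a Gaussian copula over the continuous measures (log-normal income
# and density, beta-scaled percents), rurality codes derived from noisy
# density percentiles, a persistent-poverty flag in the high-poverty tail,
# and per-region pcHPSA rates matching the reference regional shares.

.sim_measures <- c("pct_65plus", "lbw_rate", "median_hh_income",
                   "unemployment_rate", "pct_below_fpl",
                   "pct_65plus_deep_poverty", "pct_under18_deep_poverty",
                   "pct_no_hs", "pct_nonwhite_hispanic",
                   "pct_uninsured_lowincome", "pop_density")

# Beta shape parameters from a mean/sd on the proportion scale.
.beta_shapes <- function(m, s) {
  v <- s^2
  k <- m * (1 - m) / v - 1
  c(shape1 = m * k, shape2 = (1 - m) * k)
}

# Default correlation: a two-factor structure (a county "deprivation" factor
# and an age/density factor), positive semi-definite by construction.  The
# poverty and income loadings (0.95 / -0.93, implied pairwise -0.88) are set
# so that the poverty -> low-income conditional marker co-occurrence lands
# near the assumed 76%; weaker loadings lose too much tail dependence once
# marginals and quartile thresholds are applied.  Other implied pairs:
# poverty-education +0.64, poverty-deep-poverty +0.74,
# poverty-unemployment/uninsured +0.53, income-density +0.32,
# 65plus-density -0.30.
.default_correlation <- function() {
  v <- .sim_measures
  L <- matrix(0, nrow = length(v), ncol = 2L, dimnames = list(v, NULL))
  L["pct_below_fpl", 1] <- 0.95
  L["median_hh_income", 1] <- -0.93
  L["pct_65plus_deep_poverty", 1] <- 0.78
  L["pct_under18_deep_poverty", 1] <- 0.78
  L["pct_no_hs", 1] <- 0.67
  L["unemployment_rate", 1] <- 0.56
  L["pct_uninsured_lowincome", 1] <- 0.56
  L["pct_nonwhite_hispanic", 1] <- 0.44
  L["lbw_rate", 1] <- 0.44
  L["pop_density", 1] <- -0.34
  L["pct_65plus", 2] <- 0.55
  L["pop_density", 2] <- -0.55
  R <- tcrossprod(L) + diag(1 - rowSums(L^2))
  dimnames(R) <- list(v, v)
  R
}

# Regional shares of the 3,142 counties and regional pcHPSA-county rates,
# both taken from the reference regional summary.
.default_region_counts <- c(67, 83, 283, 736, 524, 503, 412, 291, 95, 148)
.default_pchpsa_rate <- c(0.925, 0.831, 0.788, 0.913, 0.845, 0.913, 0.869,
                          0.931, 1.000, 0.980)
# Mean extra designations per pcHPSA county, per region: larger in the
# regions where the multiple-pcHPSA marker dominates.
.default_hpsa_extra_mean <- c(3.0, 2.2, 1.0, 1.1, 1.1, 1.1, 0.8, 0.8, 3.4,
                              2.0)

#' Configuration for the synthetic county generator
#'
#' Defaults emulate the reference 2017 study conditions: 3,142 counties
#' distributed over the ten HHS Regions in the reference shares, correlated
#' poverty/income/education measures via a Gaussian copula, density-linked
#' rurality codes, per-region pcHPSA rates, and a 25% missing-at-random low
#' birth weight rate.
#'
#' @param n_counties Number of counties (default 3142).
#' @param seed Integer RNG seed; the generator is fully reproducible given
#'   the seed.
#' @param region_weights Length-10 non-negative shares of counties per HHS
#'   Region (normalized internally).
#' @param correlation Correlation matrix over the continuous measures (unit
#'   diagonal, symmetric positive semi-definite).
#' @param pchpsa_rate Length-10 per-region probability that a county is a
#'   pcHPSA county.
#' @param lbw_missing_rate Fraction of counties with a missing low birth
#'   weight rate (default 0.25).
#' @param planted Optional planted-structure spec: a list with elements
#'   `region`, `markers` (character names), `effect` in `[0, 1]`, applied by
#'   [plant_structure()] after generation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_counties = 3142L, seed = 1L,
                       region_weights = .default_region_counts,
                       correlation = .default_correlation(),
                       pchpsa_rate = .default_pchpsa_rate,
                       lbw_missing_rate = 0.25,
                       planted = NULL) {
  if (length(region_weights) != 10L || any(region_weights < 0)) {
    stop("region_weights must be 10 non-negative shares", call. = FALSE)
  }
  if (!isTRUE(all.equal(unname(diag(correlation)),
                        rep(1, nrow(correlation)))) ||
      !isTRUE(all.equal(correlation, t(correlation)))) {
    stop("correlation must be symmetric with unit diagonal", call. = FALSE)
  }
  off <- abs(correlation) > 1
  if (any(off)) {
    idx <- which(off, arr.ind = TRUE)[1L, ]
    stop("infeasible correlation for pair (",
         rownames(correlation)[idx[1L]], ", ",
         colnames(correlation)[idx[2L]], ")", call. = FALSE)
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    # identify the most negative-definite 2x2 principal minor for the message
    worst <- c(NA_character_, NA_character_); worst_det <- Inf
    v <- rownames(correlation)
    for (a in seq_along(v)) for (b in seq_len(a - 1L)) {
      d <- 1 - correlation[a, b]^2
      if (d < worst_det) { worst_det <- d; worst <- v[c(b, a)] }
    }
    stop("correlation matrix is not positive semi-definite (min eigenvalue ",
         format(min(ev)), "); tightest pair: (",
         paste(worst, collapse = ", "), ")", call. = FALSE)
  }
  if (length(pchpsa_rate) != 10L || any(pchpsa_rate < 0 | pchpsa_rate > 1)) {
    stop("pchpsa_rate must be 10 probabilities", call. = FALSE)
  }
  if (lbw_missing_rate < 0 || lbw_missing_rate >= 1) {
    stop("lbw_missing_rate must be in [0,1)", call. = FALSE)
  }
  out <- list(n_counties = as.integer(n_counties), seed = as.integer(seed),
              region_weights = region_weights / sum(region_weights),
              correlation = correlation, pchpsa_rate = pchpsa_rate,
              lbw_missing_rate = lbw_missing_rate, planted = planted)
  class(out) <- "sim_config"
  out
}

# Per-region shifts on the latent normal scale: poverty-linked measures run
# higher in Regions 4 and 6, density lower (rural/sparse) in 7, 8 and 10,
# older populations in 1 and 3, racial/ethnic diversity in 6 and 9.
.region_shift <- function() {
  s <- matrix(0, nrow = 10L, ncol = length(.sim_measures),
              dimnames = list(NULL, .sim_measures))
  s[c(4, 6), "pct_below_fpl"] <- 0.7
  s[c(4, 6), "median_hh_income"] <- -0.5
  s[c(4, 6), "pct_no_hs"] <- 0.5
  s[8, "pop_density"] <- -1.3
  s[7, "pop_density"] <- -0.7
  s[10, "pop_density"] <- -0.6
  s[2, "pop_density"] <- 0.8
  s[c(1, 3), "pct_65plus"] <- 0.5
  s[c(6, 9), "pct_nonwhite_hispanic"] <- 0.7
  s[c(9, 10), "unemployment_rate"] <- 0.4
  s
}

.apply_marginals <- function(u) {
  b <- function(m, s) .beta_shapes(m, s)
  data.frame(
    pct_65plus = 100 * stats::qbeta(u[, "pct_65plus"], b(0.18, 0.045)[1],
                                    b(0.18, 0.045)[2]),
    lbw_rate = stats::qlnorm(u[, "lbw_rate"], log(78), 0.25),
    median_hh_income = stats::qlnorm(u[, "median_hh_income"], log(50000), 0.28),
    unemployment_rate = 100 * stats::qbeta(u[, "unemployment_rate"],
                                           b(0.045, 0.016)[1],
                                           b(0.045, 0.016)[2]),
    pct_below_fpl = 100 * stats::qbeta(u[, "pct_below_fpl"],
                                       b(0.155, 0.062)[1], b(0.155, 0.062)[2]),
    pct_65plus_deep_poverty = 100 * stats::qbeta(
      u[, "pct_65plus_deep_poverty"], b(0.035, 0.018)[1], b(0.035, 0.018)[2]),
    pct_under18_deep_poverty = 100 * stats::qbeta(
      u[, "pct_under18_deep_poverty"], b(0.09, 0.045)[1], b(0.09, 0.045)[2]),
    pct_no_hs = 100 * stats::qbeta(u[, "pct_no_hs"], b(0.13, 0.06)[1],
                                   b(0.13, 0.06)[2]),
    pct_nonwhite_hispanic = 100 * stats::qbeta(
      u[, "pct_nonwhite_hispanic"], b(0.24, 0.17)[1], b(0.24, 0.17)[2]),
    pct_uninsured_lowincome = 100 * stats::qbeta(
      u[, "pct_uninsured_lowincome"], b(0.18, 0.06)[1], b(0.18, 0.06)[2]),
    pop_density = stats::qlnorm(u[, "pop_density"], log(45), 1.5)
  )
}

# Cumulative shares of rurality codes from the rural end, approximating the
# 2013 national code distributions.
.rucc_breaks <- c(0.135, 0.205, 0.343, 0.532, 0.561, 0.629, 0.742, 0.863, 1)
.rucc_codes  <- c(9L, 8L, 7L, 6L, 5L, 4L, 3L, 2L, 1L)
.uic_breaks <- c(0.07, 0.10, 0.24, 0.36, 0.42, 0.45, 0.58, 0.68, 0.70, 0.73,
                 0.88, 1)
.uic_codes  <- c(12L, 11L, 10L, 9L, 8L, 7L, 6L, 5L, 4L, 3L, 2L, 1L)

.code_from_band <- function(v, breaks, codes) {
  codes[findInterval(v, c(0, breaks), rightmost.closed = TRUE,
                     left.open = TRUE)]
}

#' Generate a synthetic county table and HPSA designation records
#'
#' Draws the continuous measures through a Gaussian copula with the
#' configured correlation (plus modest per-region mean shifts), derives
#' rurality codes from noisy density percentiles so rural and sparse markers
#' co-occur at roughly the reference conditional rate, flags a
#' persistent-poverty tail, assigns per-region pcHPSA status and designation
#' counts, and emits one designation record per (pcHPSA, county) pair —
#' including withdrawn / proposed-withdrawal / late-designation distractor
#' records that [filter_hpsas()] must remove.  Fully reproducible: the same
#' config yields byte-identical tables.
#'
#' @param config A [sim_config()].
#' @return A list with `counties` (county table in the [county_schema()]
#'   layout), `hpsas` (designation records), and `config`.
#' @export
simulate_counties <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_counties
  # region allocation: largest-remainder apportionment of the shares
  alloc <- floor(config$region_weights * n)
  rem <- n - sum(alloc)
  if (rem > 0) {
    frac <- config$region_weights * n - alloc
    alloc[order(-frac)[seq_len(rem)]] <- alloc[order(-frac)[seq_len(rem)]] + 1
  }
  region <- rep(1:10, times = alloc)

  # states and FIPS: counties spread over the region's states; county codes
  # are sequential odd numbers so they never collide with real counties
  state <- character(n)
  for (r in 1:10) {
    st <- .hhs_region_states[[as.character(r)]]
    state[region == r] <- rep_len(st, sum(region == r))
  }
  seq_in_state <- stats::ave(seq_len(n), state, FUN = seq_along)
  fips <- paste0(.state_fips_prefix[state],
                 formatC(2L * seq_in_state - 1L, width = 3, flag = "0"))

  # Gaussian copula with per-region latent shifts
  L <- MASS::mvrnorm(n, mu = rep(0, length(.sim_measures)),
                     Sigma = config$correlation)
  colnames(L) <- .sim_measures
  L <- L + .region_shift()[region, , drop = FALSE]
  u <- stats::pnorm(L)
  meas <- .apply_marginals(u)

  # rurality codes from a noisy copy of the density percentile
  # (rho = 0.85, see package vignette)
  d_pct <- rank(meas$pop_density, ties.method = "first") / (n + 1)
  rho_v <- 0.85
  v <- stats::pnorm(rho_v * stats::qnorm(d_pct) +
                      sqrt(1 - rho_v^2) * stats::rnorm(n))
  rho_w <- 0.95
  w <- stats::pnorm(rho_w * stats::qnorm(v) +
                      sqrt(1 - rho_w^2) * stats::rnorm(n))
  rucc <- .code_from_band(v, .rucc_breaks, .rucc_codes)
  uic <- .code_from_band(w, .uic_breaks, .uic_codes)

  # persistent poverty: noisy high-poverty tail, ~11-12% of counties
  p_rank <- rank(meas$pct_below_fpl, ties.method = "first") / (n + 1)
  pp_lat <- 0.8 * stats::qnorm(p_rank) + 0.6 * stats::rnorm(n)
  persistent <- stats::pnorm(pp_lat) > 0.885

  # pcHPSA status and designation counts
  rate <- config$pchpsa_rate[region]
  p_rec <- pmin(rate, 0.95)            # share of counties with >= 1 record
  has_rec <- stats::runif(n) < p_rec
  extra_mu <- .default_hpsa_extra_mean[region]
  hpsa_count <- integer(n)
  hpsa_count[has_rec] <- 1L + stats::rnbinom(sum(has_rec), size = 1.2,
                                             mu = extra_mu[has_rec])
  # zero-record counties may still be whole-county pcHPSAs in the AHRF
  p_whole0 <- ifelse(rate > p_rec, (rate - p_rec) / (1 - p_rec), 0)
  class0 <- ifelse(stats::runif(n) < p_whole0, "whole", "none")
  class1 <- sample(c("partial", "whole", "none"), n, replace = TRUE,
                   prob = c(0.7, 0.1, 0.2))
  ahrf_class <- ifelse(has_rec, class1, class0)

  lbw <- round(meas$lbw_rate, 1)
  lbw[stats::runif(n) < config$lbw_missing_rate] <- NA_real_

  counties <- data.frame(
    fips = fips, state = state, hhs_region = region,
    pct_65plus = round(meas$pct_65plus, 2),
    lbw_rate = lbw,
    median_hh_income = round(meas$median_hh_income),
    unemployment_rate = round(meas$unemployment_rate, 2),
    pct_below_fpl = round(meas$pct_below_fpl, 2),
    pct_65plus_deep_poverty = round(meas$pct_65plus_deep_poverty, 2),
    pct_under18_deep_poverty = round(meas$pct_under18_deep_poverty, 2),
    persistent_poverty = persistent,
    pct_no_hs = round(meas$pct_no_hs, 2),
    pct_nonwhite_hispanic = round(meas$pct_nonwhite_hispanic, 2),
    pct_uninsured_lowincome = round(meas$pct_uninsured_lowincome, 2),
    pop_density = pmax(round(meas$pop_density, 2), 0.01),
    rucc = rucc, uic = uic, ahrf_hpsa_class = ahrf_class,
    stringsAsFactors = FALSE
  )

  hpsas <- .simulate_hpsa_records(counties, hpsa_count)

  if (!is.null(config$planted)) {
    counties <- plant_structure(counties, config$planted$region,
                                config$planted$markers,
                                config$planted$effect)
  }
  list(counties = counties, hpsas = hpsas, config = config)
}

.simulate_hpsa_records <- function(counties, hpsa_count) {
  as_of <- as.Date("2017-07-01")
  fips_rep <- rep(counties$fips, times = hpsa_count)
  n_act <- length(fips_rep)
  # distractors the designation-date/status filter must drop: withdrawn,
  # proposed-for-withdrawal, and post-snapshot designations
  n_dis <- max(1L, round(0.10 * n_act))
  fips_dis <- sample(counties$fips, n_dis, replace = TRUE)
  kind <- sample(c("withdrawn", "proposed_withdrawal", "late"), n_dis,
                 replace = TRUE, prob = c(0.45, 0.25, 0.30))
  all_fips <- c(fips_rep, fips_dis)
  n_all <- length(all_fips)
  desig <- as_of - sample(30:6000, n_all, replace = TRUE)
  status <- c(rep("designated", n_act), ifelse(kind == "late", "designated",
                                               kind))
  late <- c(rep(FALSE, n_act), kind == "late")
  desig[late] <- as_of + sample(1:400, sum(late), replace = TRUE)
  status_date <- desig
  changed <- status != "designated"
  status_date[changed] <- desig[changed] +
    sample(30:1000, sum(changed), replace = TRUE)
  ord <- sample.int(n_all)   # shuffle so actives/distractors interleave
  data.frame(
    hpsa_id = sprintf("SYN-%06d", seq_len(n_all)),
    county_fips = all_fips[ord],
    hpsa_type = sample(c("geographic", "population", "facility"), n_all,
                       replace = TRUE, prob = c(0.5, 0.3, 0.2)),
    status = status[ord],
    designation_date = desig[ord],
    status_date = status_date[ord],
    stringsAsFactors = FALSE
  )
}

#' Plant a high-variance marker structure in one region
#'
#' Inflates the within-region spread of the source measures behind the named
#' quantile markers so those markers dominate the region's cross-county
#' variance: the extreme half of the region (by in-region rank) is spread
#' over a national quantile band far beyond the marker threshold (q85-q98
#' for high-direction markers, q02-q15 for low-direction), the rest over a
#' band around the national median, linearly interpolated by `effect`
#' (0 = unchanged, 1 = fully planted).  The push is rank-preserving, so
#' planted markers keep their correlation structure and the field stays
#' non-degenerate.  Other regions are untouched.
#'
#' @param counties County table.
#' @param region HHS Region 1-10 to plant in.
#' @param markers Character names of quantile markers (see [marker_rules()]).
#' @param effect Effect size in `[0, 1]`.
#' @return The modified county table.
#' @export
plant_structure <- function(counties, region, markers, effect) {
  stopifnot(effect >= 0, effect <= 1)
  region <- as.integer(region)
  if (is.na(region) || region < 1L || region > 10L) {
    stop("region must be 1..10", call. = FALSE)
  }
  rules <- marker_rules()
  rows <- counties$hhs_region == region
  if (!any(rows)) stop("no counties in region ", region, call. = FALSE)
  for (mk in markers) {
    r <- rules[rules$name == mk, ]
    if (nrow(r) != 1L || !r$rule_kind %in% c("quantile_high", "quantile_low")) {
      stop("plant_structure supports quantile markers only; got '", mk, "'",
           call. = FALSE)
    }
    f <- r$source_field
    x <- counties[[f]]
    sub <- x[rows]
    ok <- !is.na(sub)
    # in-region percentile, rank-preserving
    p <- rank(sub[ok], ties.method = "first") / (sum(ok) + 1)
    # target national quantile levels: the extreme half of the region is
    # spread over a band far beyond the marker threshold, the rest over a
    # band around the national median, keeping the field non-degenerate
    lev <- if (r$direction == "high") {
      ifelse(p > 0.5, 0.85 + 0.26 * (p - 0.5), 0.40 + 0.40 * p)
    } else {
      ifelse(p < 0.5, 0.02 + 0.26 * p, 0.40 + 0.40 * (p - 0.5))
    }
    target <- stats::quantile(x, probs = lev, na.rm = TRUE, names = FALSE)
    planted <- sub
    planted[ok] <- (1 - effect) * sub[ok] + effect * target
    counties[[f]][rows] <- planted
  }
  counties
}
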