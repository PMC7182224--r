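# Marker engine: the fifteen binary vulnerability markers.  Twelve are
# quantile rules against the national distribution (strict inequalities);
# three are pre-defined classifications (persistent poverty, rurality codes,
# pcHPSA-county status).

#' The default marker rule set
#'
#' Fifteen binary markers of medical, economic, and geographic vulnerability.
#' `quantile_high` rules set the marker when the county measure strictly
#' exceeds the national 75th percentile; `quantile_low` rules when it is
#' strictly below the national 25th percentile; `classification` rules use a
#' pre-defined scheme (persistent-poverty flag, rurality codes, pcHPSA-county
#' status).  Marker 15's quantile is taken over the per-county pcHPSA counts
#' (zeros included).
#'
#' @return A `data.frame` with columns `marker_id`, `name`, `label`,
#'   `rule_kind`, `source_field`, `quantile`, `direction`.
#' @seealso [score_markers()], [read_marker_rules()]
#' @export
marker_rules <- function() {
  rules <- data.frame(
    marker_id = 1:15,
    name = c("older_population", "low_birth_weight", "low_income",
             "unemployment", "poverty", "deep_poverty_65plus",
             "deep_poverty_under18", "persistent_poverty", "education",
             "race_ethnicity", "insurance", "sparse_population", "rurality",
             "pchpsa_county", "pchpsa_count"),
    label = c("Older population", "Low birth weight", "Low income",
              "Unemployment", "Poverty",
              "Deep poverty among adults 65 and older",
              "Deep poverty among children under 18", "Persistent poverty",
              "Education", "Race/ethnicity", "Insurance",
              "Sparse population", "Rurality", "pcHPSA county",
              "pcHPSA count"),
    rule_kind = c("quantile_high", "quantile_high", "quantile_low",
                  "quantile_high", "quantile_high", "quantile_high",
                  "quantile_high", "classification", "quantile_high",
                  "quantile_high", "quantile_high", "quantile_low",
                  "classification", "classification", "quantile_high"),
    source_field = c("pct_65plus", "lbw_rate", "median_hh_income",
                     "unemployment_rate", "pct_below_fpl",
                     "pct_65plus_deep_poverty", "pct_under18_deep_poverty",
                     "persistent_poverty", "pct_no_hs",
                     "pct_nonwhite_hispanic", "pct_uninsured_lowincome",
                     "pop_density", "rucc_uic", "hpsa_status", "hpsa_count"),
    quantile = c(0.75, 0.75, 0.25, 0.75, 0.75, 0.75, 0.75, NA, 0.75, 0.75,
                 0.75, 0.25, NA, NA, 0.75),
    stringsAsFactors = FALSE
  )
  rules$direction <- ifelse(rules$rule_kind == "quantile_low", "low",
                            ifelse(rules$rule_kind == "quantile_high",
                                   "high", NA))
  rules
}

.validate_rules <- function(rules) {
  if (!setequal(rules$marker_id, 1:15) || anyDuplicated(rules$marker_id)) {
    stop("rule set must define marker ids 1..15 exactly once", call. = FALSE)
  }
  q <- rules$quantile
  hi <- rules$rule_kind == "quantile_high"
  lo <- rules$rule_kind == "quantile_low"
  if (any(is.na(q[hi | lo])) || any(q[hi | lo] <= 0 | q[hi | lo] >= 1)) {
    stop("quantile rules need a quantile in (0,1)", call. = FALSE)
  }
  if (any(q[hi] < 0.5) || any(q[lo] > 0.5)) {
    stop("quantile inconsistent with rule_kind", call. = FALSE)
  }
  rules[order(rules$marker_id), , drop = FALSE]
}

#' Read a marker rule set from a CSV config file
#'
#' Supports sensitivity analyses: the file carries the columns of
#' [marker_rules()] (the `label` and `direction` columns may be omitted) and
#' must define marker ids 1-15 exactly once.  Classification rules
#' (`persistent_poverty`, `rurality`, `pchpsa_county`) keep their built-in
#' logic; only their presence is configurable.
#'
#' @param path Path to the rules CSV.
#' @return A validated rules `data.frame`.
#' @export
read_marker_rules <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("marker_id", "name", "rule_kind", "source_field", "quantile")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("rules file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"label" %in% names(raw)) raw$label <- raw$name
  raw$direction <- ifelse(raw$rule_kind == "quantile_low", "low",
                          ifelse(raw$rule_kind == "quantile_high",
                                 "high", NA))
  .validate_rules(raw)
}

#' Empirical quantile threshold over the national distribution
#'
#' Linear-interpolation quantile (the order-statistic position `1 + (n-1)q`
#' estimator, `stats::quantile` type 7) of the non-missing values.  This is
#' the threshold definition used by every quantile marker rule; any
#' consistent estimator choice can only move boundary ties.
#'
#' @param values Numeric vector; missing values are excluded.
#' @param q Quantile fraction in (0,1).
#' @return The threshold, a single number.
#' @export
quantile_threshold <- function(values, q) {
  if (length(q) != 1L || is.na(q) || q <= 0 || q >= 1) {
    stop("q must be a single fraction in (0,1)", call. = FALSE)
  }
  x <- values[!is.na(values)]
  if (length(x) < 4L) {
    stop("quantile threshold needs at least 4 non-missing values, got ",
         length(x), call. = FALSE)
  }
  unname(stats::quantile(x, probs = q, type = 7, names = FALSE))
}

#' Score a single quantile marker
#'
#' Strict comparison against the national threshold: `direction = "high"`
#' scores 1 iff the value strictly exceeds the threshold, `direction = "low"`
#' iff it is strictly below.  Missing values stay missing.
#'
#' @param value Numeric vector of county measures (NA allowed).
#' @param threshold Threshold from [quantile_threshold()].
#' @param direction `"high"` or `"low"`.
#' @return Integer vector of 0/1/NA.
#' @export
score_quantile_marker <- function(value, threshold, direction = c("high", "low")) {
  direction <- match.arg(direction)
  out <- if (direction == "high") value > threshold else value < threshold
  as.integer(out)
}

#' Rurality marker from RUCC and UIC codes
#'
#' A county scores 1 when its Rural-Urban Continuum Code is 7, 8, or 9, or
#' its Urban Influence Code is 9 through 12 (noncore counties).
#'
#' @param rucc Integer vector, codes 1-9.
#' @param uic Integer vector, codes 1-12.
#' @return Integer vector of 0/1.
#' @export
rural_marker <- function(rucc, uic) {
  if (any(is.na(rucc)) || any(rucc < 1L | rucc > 9L)) {
    stop("rucc out of range 1..9", call. = FALSE)
  }
  if (any(is.na(uic)) || any(uic < 1L | uic > 12L)) {
    stop("uic out of range 1..12", call. = FALSE)
  }
  as.integer(rucc %in% 7:9 | uic %in% 9:12)
}

#' pcHPSA-county marker
#'
#' A county scores 1 when it is categorized as a whole- or partial-county
#' primary care HPSA in the county table, or has one or more pcHPSA records
#' in the (filtered) designation file.
#'
#' @param ahrf_hpsa_class Character vector: `"whole"`, `"partial"`, `"none"`.
#' @param hpsa_count Non-negative integer vector of per-county pcHPSA counts.
#' @return Integer vector of 0/1.
#' @export
pchpsa_county_marker <- function(ahrf_hpsa_class, hpsa_count) {
  bad <- setdiff(unique(ahrf_hpsa_class), c("whole", "partial", "none"))
  if (length(bad) > 0L) {
    stop("ahrf_hpsa_class must be whole/partial/none; saw: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(hpsa_count)) || any(hpsa_count < 0)) {
    stop("hpsa_count must be non-negative", call. = FALSE)
  }
  as.integer(ahrf_hpsa_class %in% c("whole", "partial") | hpsa_count >= 1)
}

#' Score every county against the fifteen marker rules
#'
#' Computes each quantile rule's threshold over the full national input
#' (marker 15 over the per-county pcHPSA counts, zeros included), applies the
#' strict comparisons and the three classification rules, and returns one
#' marker vector per county.  The burden `total` counts markers scored 1;
#' missing scores (only the low birth weight marker may be missing) count as
#' zero toward the total, and a per-county `n_missing` is carried for
#' transparency.
#'
#' @param counties County table from [read_county_table()] or
#'   [simulate_counties()].
#' @param hpsa_counts Named per-county counts from [count_hpsas_by_county()]
#'   (already filtered); must cover every county FIPS.
#' @param rules Rule set, default [marker_rules()].
#' @return A `marker_set`: a `data.frame` with columns `fips`, `m01`..`m15`,
#'   `total`, `n_missing`, and attributes `thresholds` (named vector of every
#'   computed quantile cutoff) and `rules`.
#' @examples
#' sim <- simulate_counties(sim_config(n_counties = 400, seed = 1))
#' counts <- count_hpsas_by_county(filter_hpsas(sim$hpsas), sim$counties$fips)
#' ms <- score_markers(sim$counties, counts)
#' summary(ms)
#' @export
score_markers <- function(counties, hpsa_counts, rules = marker_rules()) {
  rules <- .validate_rules(rules)
  n <- nrow(counties)
  if (n == 0L) stop("empty county table", call. = FALSE)
  if (is.null(names(hpsa_counts)) ||
      !all(counties$fips %in% names(hpsa_counts))) {
    stop("hpsa_counts must be named and cover every county FIPS",
         call. = FALSE)
  }
  counts <- unname(hpsa_counts[counties$fips])

  scores <- matrix(NA_integer_, nrow = n, ncol = 15L,
                   dimnames = list(NULL, sprintf("m%02d", 1:15)))
  thresholds <- c()
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    col <- sprintf("m%02d", r$marker_id)
    if (r$rule_kind %in% c("quantile_high", "quantile_low")) {
      vals <- if (identical(r$source_field, "hpsa_count")) counts
              else counties[[r$source_field]]
      if (is.null(vals)) {
        stop("unknown source_field '", r$source_field, "' for marker ",
             r$marker_id, call. = FALSE)
      }
      thr <- quantile_threshold(vals, r$quantile)
      thresholds[r$name] <- thr
      scores[, col] <- score_quantile_marker(vals, thr, r$direction)
    } else if (r$name == "persistent_poverty") {
      scores[, col] <- as.integer(counties$persistent_poverty)
    } else if (r$name == "rurality") {
      scores[, col] <- rural_marker(counties$rucc, counties$uic)
    } else if (r$name == "pchpsa_county") {
      scores[, col] <- pchpsa_county_marker(counties$ahrf_hpsa_class, counts)
    } else {
      stop("unknown classification rule '", r$name, "'", call. = FALSE)
    }
  }
  miss_ok <- sprintf("m%02d", rules$marker_id[rules$name == "low_birth_weight"])
  bad_missing <- setdiff(colnames(scores)[colSums(is.na(scores)) > 0L],
                         miss_ok)
  if (length(bad_missing) > 0L) {
    stop("missing scores outside the low birth weight marker: ",
         paste(bad_missing, collapse = ", "), call. = FALSE)
  }

  out <- data.frame(fips = counties$fips, scores, stringsAsFactors = FALSE)
  out$total <- as.integer(rowSums(scores == 1L, na.rm = TRUE))
  out$n_missing <- as.integer(rowSums(is.na(scores)))
  attr(out, "thresholds") <- thresholds
  attr(out, "rules") <- rules
  class(out) <- c("marker_set", "data.frame")
  out
}

#' Extract the 0/1/NA score matrix from a marker_set
#'
#' @param markers A `marker_set` from [score_markers()].
#' @return Integer matrix, one row per county, columns `m01`..`m15`.
#' @export
marker_matrix <- function(markers) {
  m <- as.matrix(as.data.frame(markers)[, sprintf("m%02d", 1:15)])
  storage.mode(m) <- "integer"
  rownames(m) <- markers$fips
  m
}

#' @export
print.marker_set <- function(x, ...) {
  cat("Marker set:", nrow(x), "counties, 15 markers\n")
  cat("Burden totals: median", stats::median(x$total),
      " max", max(x$total), "\n")
  thr <- attr(x, "thresholds")
  cat("Quantile thresholds:\n")
  print(round(thr, 3))
  invisible(x)
}

#' @export
summary.marker_set <- function(object, ...) {
  national_overview(object)
}

#' High-burden cutoff from the national distribution of marker totals
#'
#' Returns the smallest integer `t` such that "more than `t` markers" selects
#' exactly the counties whose total strictly exceeds the 75th percentile of
#' all totals (linear-interpolation quantile).  With the reference 2017 data
#' structure this cutoff is 6, i.e. high-burden counties have more than six
#' markers.
#'
#' @param totals Integer vector of per-county marker totals.
#' @return A single integer cutoff.
#' @export
high_burden_cutoff <- function(totals) {
  if (length(totals) == 0L || any(is.na(totals))) {
    stop("totals must be non-empty and complete", call. = FALSE)
  }
  p75 <- stats::quantile(totals, probs = 0.75, type = 7, names = FALSE)
  as.integer(floor(p75))
}
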