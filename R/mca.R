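# Multiple Correspondence Analysis of the binary marker matrix, written as a
# standard correspondence analysis of the complete disjunctive (indicator)
# coding: the correspondence table is the indicator matrix over its grand
# total, standardized residuals are decomposed by SVD, eigenvalues are the
# squared singular values, and category contributions are mass-weighted
# squared principal coordinates over the dimension's eigenvalue.

#' Build the complete disjunctive indicator matrix
#'
#' Each included marker contributes an (absent, present) column pair; every
#' row sums to the number of included markers.  The low birth weight marker
#' (id 2) is excluded by default because of its missingness; an included
#' marker with any missing score is a hard error instructing exclusion.
#'
#' @param markers A `marker_set` from [score_markers()], or a 0/1 matrix /
#'   data.frame with one column per marker.
#' @param exclude Integer marker ids to exclude (default 2, low birth
#'   weight).
#' @return A list of class `indicator_matrix`: `Z` (n x 2Q 0/1 matrix), `Q`,
#'   `J = 2Q`, `marker_ids`, `marker_names`, `fips`.
#' @export
build_indicator <- function(markers, exclude = 2L) {
  if (inherits(markers, "marker_set")) {
    rules <- attr(markers, "rules")
    m <- marker_matrix(markers)
    ids <- 1:15
    names_all <- rules$name[order(rules$marker_id)]
    fips <- markers$fips
  } else {
    m <- as.matrix(markers)
    ids <- seq_len(ncol(m))
    names_all <- colnames(m)
    if (is.null(names_all)) names_all <- sprintf("v%02d", ids)
    fips <- rownames(m)
  }
  keep <- setdiff(ids, exclude)
  if (length(keep) < 2L) stop("need at least two included markers",
                              call. = FALSE)
  m <- m[, match(keep, ids), drop = FALSE]
  nm <- names_all[match(keep, ids)]
  if (anyNA(m)) {
    bad <- nm[colSums(is.na(m)) > 0L]
    stop("included marker(s) with missing scores: ",
         paste(bad, collapse = ", "),
         "; exclude them via the `exclude` argument", call. = FALSE)
  }
  if (!all(m %in% c(0L, 1L))) stop("marker scores must be 0/1", call. = FALSE)
  n <- nrow(m)
  Q <- ncol(m)
  Z <- matrix(0L, n, 2L * Q)
  Z[, seq(1L, 2L * Q, by = 2L)] <- 1L - m   # absent
  Z[, seq(2L, 2L * Q, by = 2L)] <- m        # present
  colnames(Z) <- as.vector(rbind(paste0(nm, ".absent"),
                                 paste0(nm, ".present")))
  out <- list(Z = Z, Q = Q, J = 2L * Q, marker_ids = keep,
              marker_names = nm, fips = fips)
  class(out) <- "indicator_matrix"
  out
}

#' Fit a Multiple Correspondence Analysis
#'
#' Correspondence analysis of the indicator matrix.  Markers that are
#' constant over the rows in scope carry no variance and are dropped with a
#' message (reducing Q); total inertia of the retained coding is
#' `J'/Q' - 1`.  Contributions are reported for every dimension whose
#' eigenvalue is numerically non-trivial.
#'
#' @param indicator An `indicator_matrix` from [build_indicator()], or an
#'   object accepted by it.
#' @param exclude Passed to [build_indicator()] when `indicator` is not
#'   already an indicator matrix.
#' @param correction `"none"` (default) reports raw principal inertias;
#'   `"benzecri"` additionally reports Benzecri-adjusted inertia rates for
#'   dimensions with eigenvalue above `1/Q'`.
#' @return An object of class `sdoh_mca`: `eigenvalues` (all non-trivial
#'   principal inertias, non-increasing), `total_inertia`, `n_dims`,
#'   `category_coords` (principal coordinates, J' x K), `category_contrib`
#'   and `variable_contrib` (contribution fractions, each dimension summing
#'   to 1), `category_mass`, `marker_names` (retained), `dropped` (constant
#'   markers removed), `n`, `Q`, `J`, and optionally `adjusted_rates`.
#' @examples
#' m <- matrix(rbinom(200, 1, 0.4), 50, 4,
#'             dimnames = list(NULL, paste0("v", 1:4)))
#' fit <- run_mca(build_indicator(m, exclude = integer()))
#' fit$total_inertia  # (2*4)/4 - 1 = 1
#' @export
run_mca <- function(indicator, exclude = 2L,
                    correction = c("none", "benzecri")) {
  correction <- match.arg(correction)
  if (!inherits(indicator, "indicator_matrix")) {
    indicator <- build_indicator(indicator, exclude = exclude)
  }
  Z <- indicator$Z
  n <- nrow(Z)
  # Drop markers constant in scope (their 'present' column sums to 0 or n).
  pres <- seq(2L, ncol(Z), by = 2L)
  const <- colSums(Z[, pres, drop = FALSE]) %in% c(0L, n)
  if (any(const)) {
    message("dropping constant marker(s) in scope: ",
            paste(indicator$marker_names[const], collapse = ", "))
    keep_cols <- rep(!const, each = 2L)
    Z <- Z[, keep_cols, drop = FALSE]
  }
  marker_names <- indicator$marker_names[!const]
  Q <- length(marker_names)
  J <- 2L * Q
  if (Q < 2L) stop("fewer than two non-constant markers in scope",
                   call. = FALSE)
  if (n < Q + 1L) stop("MCA needs more rows than variables (n = ", n,
                       ", Q = ", Q, ")", call. = FALSE)

  N <- sum(Z)                      # n * Q
  P <- Z / N
  r <- rowSums(P)                  # row masses, all 1/n
  cm <- colSums(P)                 # category masses
  S <- (P - tcrossprod(r, cm)) / sqrt(tcrossprod(r, cm))
  sv <- svd(S)
  lambda <- sv$d^2
  total_inertia <- J / Q - 1
  if (max(lambda) < 1e-12) {
    stop("degenerate indicator matrix: no variation across rows",
         call. = FALSE)
  }
  # Numerically non-trivial dimensions (at most J - Q for disjunctive data).
  nontriv <- which(lambda > 1e-10 * total_inertia)
  K <- length(nontriv)
  # Principal category coordinates G = Dc^{-1/2} V Sigma.
  G <- sweep(sv$v[, nontriv, drop = FALSE], 1L, sqrt(cm), "/")
  G <- sweep(G, 2L, sv$d[nontriv], "*")
  ctr <- sweep(G^2 * cm, 2L, lambda[nontriv], "/")
  dimnames(G) <- dimnames(ctr) <-
    list(colnames(Z), paste0("dim", seq_len(K)))
  var_ctr <- rowsum(ctr, rep(marker_names, each = 2L), reorder = FALSE)

  out <- list(eigenvalues = lambda[nontriv], total_inertia = total_inertia,
              n_dims = K, category_coords = G, category_contrib = ctr,
              variable_contrib = var_ctr, category_mass = cm,
              marker_names = marker_names,
              dropped = indicator$marker_names[const],
              n = n, Q = Q, J = J,
              eigenvalue_sum_all = sum(lambda))
  if (correction == "benzecri") {
    lam <- out$eigenvalues
    adj <- ((Q / (Q - 1)) * (lam - 1 / Q))^2
    adj[lam <= 1 / Q] <- 0
    out$adjusted_rates <- if (sum(adj) > 0) adj / sum(adj) else adj
  }
  class(out) <- "sdoh_mca"
  out
}

#' @export
print.sdoh_mca <- function(x, ...) {
  cat("Multiple Correspondence Analysis:", x$n, "counties,",
      x$Q, "markers\n")
  if (length(x$dropped) > 0L) {
    cat("Dropped constant markers:", paste(x$dropped, collapse = ", "), "\n")
  }
  cat("Total inertia:", format(x$total_inertia), "\n")
  k <- min(5L, x$n_dims)
  pct <- 100 * x$eigenvalues / x$total_inertia
  cat("Leading principal inertias (% of total):\n")
  for (i in seq_len(k)) {
    cat(sprintf("  dim%-2d %.5f (%4.1f%%)\n", i, x$eigenvalues[i], pct[i]))
  }
  invisible(x)
}

#' @export
summary.sdoh_mca <- function(object, dims = 2L, ...) {
  dims <- min(dims, object$n_dims)
  cat("Variable contributions (fractions), leading", dims, "dimensions:\n")
  print(round(object$variable_contrib[, seq_len(dims), drop = FALSE], 3))
  invisible(object)
}

#' @export
plot.sdoh_mca <- function(x, ...) {
  pct <- 100 * x$eigenvalues / x$total_inertia
  graphics::barplot(pct, names.arg = seq_along(pct),
                    xlab = "dimension", ylab = "% of total inertia",
                    main = "MCA principal inertias", ...)
  invisible(x)
}

#' Rank markers by their contribution to cross-county variability
#'
#' `mode = "dim1"` (the default) ranks markers by their contribution to the
#' first principal dimension — the single largest axis of association, which
#' is what "greatest variability" identifies in this analysis.  `mode =
#' "weighted"` instead sums eigenvalue-weighted contributions over the
#' smallest leading set of dimensions jointly explaining at least half the
#' total inertia.  The weighted mode is kept as an option but is not the
#' default: for near-independent binary variables every variable owns a
#' dimension with inertia close to `1/Q` and contribution close to 1, so the
#' weighted sum systematically favors markers *uncorrelated* with the rest
#' over members of the correlated block that dimension 1 captures.  Ties
#' break by marker order.
#'
#' @param fit An `sdoh_mca` from [run_mca()].
#' @param top_k How many marker names to return (default 2).
#' @param mode `"dim1"` (default) or `"weighted"`.
#' @return Character vector of marker names, strongest first.
#' @export
variability_sources <- function(fit, top_k = 2L,
                                mode = c("dim1", "weighted")) {
  mode <- match.arg(mode)
  stopifnot(top_k >= 1L)
  vc <- fit$variable_contrib
  if (mode == "dim1") {
    score <- vc[, 1L]
  } else {
    cum <- cumsum(fit$eigenvalues) / fit$total_inertia
    m <- which(cum >= 0.5)[1L]
    if (is.na(m)) m <- fit$n_dims
    w <- fit$eigenvalues[seq_len(m)]
    score <- as.vector(vc[, seq_len(m), drop = FALSE] %*% w)
    names(score) <- rownames(vc)
  }
  if (top_k > length(score)) {
    message("top_k exceeds the number of markers; returning all ",
            length(score))
    top_k <- length(score)
  }
  ord <- order(-score, seq_along(score))
  names(score)[ord][seq_len(top_k)]
}

#' Regional MCA and variability-source ranking
#'
#' Composes [build_indicator()], [run_mca()], and [variability_sources()]
#' on one HHS Region's (or the nation's) pcHPSA counties.
#'
#' @inheritParams marker_frequencies
#' @param exclude Marker ids excluded from the indicator coding (default 2).
#' @param top_k Number of variability sources to report (default 2).
#' @param mode Ranking mode, see [variability_sources()].
#' @return A list with `fit` (the `sdoh_mca`), `sources` (character vector),
#'   `region`, and `n` (rows analysed).
#' @export
regional_mca <- function(markers, counties, region = "ALL",
                         restrict_to_pchpsa = TRUE, exclude = 2L,
                         top_k = 2L, mode = c("dim1", "weighted")) {
  mode <- match.arg(mode)
  fips <- .scope_fips(markers, counties, region)
  rows <- markers$fips %in% fips
  if (restrict_to_pchpsa) rows <- rows & markers$m14 == 1L
  n <- sum(rows)
  if (n < 15L) {
    stop("region ", region, " has only ", n,
         " counties in scope; at least 15 are required for a stable MCA",
         call. = FALSE)
  }
  sub <- markers[rows, , drop = FALSE]
  attr(sub, "rules") <- attr(markers, "rules")
  class(sub) <- c("marker_set", "data.frame")
  ind <- build_indicator(sub, exclude = exclude)
  fit <- run_mca(ind)
  list(fit = fit, sources = variability_sources(fit, top_k, mode),
       region = region, n = n)
}
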