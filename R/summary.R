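# Burden summaries: national overview, regional Table-2-style summaries,
# marker frequency rankings among pcHPSA counties, and pairwise conditional
# co-occurrence.

#' Round half away from zero
#'
#' The percentage rounding convention used throughout the package's printed
#' summaries (0.05 at one decimal rounds up, never to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Shared percentage arithmetic: 100 * count / denom, half-away-from-zero to
# one decimal.
.pct_of <- function(count, denom, digits = 1L) {
  round_half_up(100 * count / denom, digits)
}

#' National overview of marker burden
#'
#' Counts (with percentages of all counties, one decimal, half-away-from-zero
#' rounding) of counties with no markers, with ten or more markers, and at
#' the observed maximum total, plus the share of counties with at least one
#' marker or pcHPSA status (reported to the nearest whole percent).
#'
#' @param markers A `marker_set` from [score_markers()].
#' @return A list of class `sdoh_overview` with elements `n_total`,
#'   `n_zero_markers`, `pct_zero_markers`, `n_ge_10`, `pct_ge_10`,
#'   `max_total`, `n_max`, `pct_max`, `n_any`, `pct_any_whole`.
#' @export
national_overview <- function(markers) {
  totals <- markers$total
  n <- length(totals)
  if (n == 0L) stop("empty marker set", call. = FALSE)
  n_zero <- sum(totals == 0L)
  n_ge10 <- sum(totals >= 10L)
  mx <- max(totals)
  n_max <- sum(totals == mx)
  out <- list(
    n_total = n,
    n_zero_markers = n_zero,
    pct_zero_markers = .pct_of(n_zero, n),
    n_ge_10 = n_ge10,
    pct_ge_10 = .pct_of(n_ge10, n),
    max_total = mx,
    n_max = n_max,
    pct_max = .pct_of(n_max, n),
    n_any = n - n_zero,
    pct_any_whole = .pct_of(n - n_zero, n, digits = 0L)
  )
  class(out) <- "sdoh_overview"
  out
}

#' @export
print.sdoh_overview <- function(x, ...) {
  cat("Counties:", x$n_total, "\n")
  cat(sprintf("  no markers:        %5d (%.1f%%)\n",
              x$n_zero_markers, x$pct_zero_markers))
  cat(sprintf("  >= 10 markers:     %5d (%.1f%%)\n", x$n_ge_10, x$pct_ge_10))
  cat(sprintf("  at maximum (%d):   %5d (%.1f%%)\n",
              x$max_total, x$n_max, x$pct_max))
  cat(sprintf("  >= 1 marker:       %5d (%.0f%%)\n", x$n_any, x$pct_any_whole))
  invisible(x)
}

.scope_fips <- function(markers, counties, region) {
  if (identical(region, "ALL")) return(counties$fips)
  region <- as.integer(region)
  if (is.na(region) || region < 1L || region > 10L) {
    stop("region must be 1..10 or \"ALL\"", call. = FALSE)
  }
  counties$fips[counties$hhs_region == region]
}

#' Regional summary of pcHPSA counties and high marker burden
#'
#' For one HHS Region (or `"ALL"`): the county count, the number and share of
#' pcHPSA counties (marker 14), and the number and share of pcHPSA counties
#' whose marker total strictly exceeds the high-burden cutoff.  Both
#' percentages use the region's total county count as denominator.  The
#' three most frequent markers among the region's pcHPSA counties are
#' attached (excluding the pcHPSA-county marker itself, which is 100% among
#' pcHPSA counties by construction).
#'
#' @param markers A `marker_set`.
#' @param counties The county table the markers were scored from.
#' @param cutoff High-burden cutoff from [high_burden_cutoff()].
#' @param region HHS Region number 1-10, or `"ALL"`.
#' @return A list of class `regional_summary`.
#' @export
regional_summary <- function(markers, counties, cutoff, region = "ALL") {
  fips <- .scope_fips(markers, counties, region)
  if (length(fips) == 0L) {
    stop("region ", region, " has zero counties", call. = FALSE)
  }
  rows <- markers$fips %in% fips
  m14 <- markers$m14[rows]
  tot <- markers$total[rows]
  n <- sum(rows)
  n_pchpsa <- sum(m14 == 1L)
  n_hb <- sum(m14 == 1L & tot > cutoff)
  if (n_pchpsa > 0L) {
    freq <- marker_frequencies(markers, counties, region,
                               restrict_to_pchpsa = TRUE)
    # the conditioning marker is 100% by construction; not informative here
    top <- utils::head(freq[freq$name != "pchpsa_county", ], 3L)
  } else {
    message("region ", region, " has no pcHPSA counties; no marker ranking")
    top <- marker_frequencies(markers, counties, region,
                              restrict_to_pchpsa = FALSE)[0, ]
  }
  out <- list(hhs_region = region, n_counties = n, n_pchpsa = n_pchpsa,
              pct_pchpsa = .pct_of(n_pchpsa, n),
              n_high_burden_pchpsa = n_hb,
              pct_high_burden = .pct_of(n_hb, n),
              cutoff = cutoff, top_markers = top)
  class(out) <- "regional_summary"
  out
}

#' @export
print.regional_summary <- function(x, ...) {
  cat(sprintf("HHS Region %s: %d counties, %d pcHPSA (%s%%), %d with > %d markers (%s%%)\n",
              as.character(x$hhs_region), x$n_counties, x$n_pchpsa,
              format_pct(x$pct_pchpsa), x$n_high_burden_pchpsa, x$cutoff,
              format_pct(x$pct_high_burden)))
  if (nrow(x$top_markers) > 0L) {
    cat("Top markers among pcHPSA counties:\n")
    for (i in seq_len(nrow(x$top_markers))) {
      cat(sprintf("  %s (%.1f%%)\n", x$top_markers$label[i],
                  x$top_markers$pct[i]))
    }
  }
  invisible(x)
}

#' Format a percentage in the reference tables' style
#'
#' One decimal, except exact whole hundreds which print without decimals
#' ("100" not "100.0").
#'
#' @param x Numeric percentage.
#' @return Character vector.
#' @export
format_pct <- function(x) {
  ifelse(x == round(x) & x >= 100, sprintf("%.0f", x), sprintf("%.1f", x))
}

#' Regional summary table over all ten regions plus the national row
#'
#' @inheritParams regional_summary
#' @param regions List of regions to summarize (default: 1-10 plus `"ALL"`).
#' @return A `data.frame` with one row per HHS Region 1-10 plus an `ALL`
#'   row, columns `hhs_region`, `n_counties`, `n_pchpsa`, `pct_pchpsa`,
#'   `n_high_burden_pchpsa`, `pct_high_burden`.
#' @export
regional_summary_table <- function(markers, counties, cutoff,
                                   regions = c(as.list(1:10), list("ALL"))) {
  rows <- lapply(regions, function(r) {
    s <- suppressMessages(regional_summary(markers, counties, cutoff, r))
    data.frame(hhs_region = as.character(r), n_counties = s$n_counties,
               n_pchpsa = s$n_pchpsa, pct_pchpsa = s$pct_pchpsa,
               n_high_burden_pchpsa = s$n_high_burden_pchpsa,
               pct_high_burden = s$pct_high_burden,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Marker frequency ranking within a region
#'
#' Frequency of each marker among in-scope counties (pcHPSA counties by
#' default, matching the reference tables' denominator), sorted
#' non-increasing with ties broken by marker id.  Counties with a missing
#' score are excluded from the numerator only.
#'
#' @inheritParams regional_summary
#' @param restrict_to_pchpsa If `TRUE` (default) the denominator is the
#'   region's pcHPSA counties (marker 14 = 1); otherwise all counties in the
#'   region.
#' @return A `data.frame` with columns `marker_id`, `name`, `label`, `n`,
#'   `pct` (unrounded percent) sorted by decreasing frequency.
#' @export
marker_frequencies <- function(markers, counties, region = "ALL",
                               restrict_to_pchpsa = TRUE) {
  fips <- .scope_fips(markers, counties, region)
  rows <- markers$fips %in% fips
  if (restrict_to_pchpsa) rows <- rows & markers$m14 == 1L
  n_scope <- sum(rows)
  if (n_scope == 0L) stop("no counties in scope", call. = FALSE)
  rules <- attr(markers, "rules")
  if (is.null(rules)) rules <- marker_rules()
  m <- marker_matrix(markers)[rows, , drop = FALSE]
  cnt <- colSums(m == 1L, na.rm = TRUE)
  out <- data.frame(marker_id = 1:15, name = rules$name, label = rules$label,
                    n = as.integer(cnt), pct = 100 * cnt / n_scope,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$pct, out$marker_id), ]
  rownames(out) <- NULL
  out
}

#' Conditional co-occurrence of two markers
#'
#' The percent of in-scope counties with `a = 1` that also have `b = 1`
#' (asymmetric; missing `b` scores count against co-occurrence in the
#' numerator only).  Undefined — flagged, with `pct = NA` — when no county
#' has `a = 1`.
#'
#' @inheritParams marker_frequencies
#' @param a,b Marker names (see [marker_rules()]) or marker ids.
#' @return A list with `marker_a`, `marker_b`, `n_a`, `n_ab`, `pct`,
#'   `defined`.
#' @export
cooccurrence <- function(markers, a, b, restrict_to_pchpsa = TRUE) {
  rules <- attr(markers, "rules")
  if (is.null(rules)) rules <- marker_rules()
  to_id <- function(x) {
    if (is.numeric(x)) return(as.integer(x))
    id <- rules$marker_id[rules$name == x]
    if (length(id) != 1L) stop("unknown marker: ", x, call. = FALSE)
    id
  }
  ia <- to_id(a); ib <- to_id(b)
  m <- marker_matrix(markers)
  if (restrict_to_pchpsa) m <- m[m[, "m14"] == 1L, , drop = FALSE]
  av <- m[, sprintf("m%02d", ia)]
  bv <- m[, sprintf("m%02d", ib)]
  sel <- !is.na(av) & av == 1L
  n_a <- sum(sel)
  if (n_a == 0L) {
    return(list(marker_a = rules$name[ia], marker_b = rules$name[ib],
                n_a = 0L, n_ab = 0L, pct = NA_real_, defined = FALSE))
  }
  n_ab <- sum(bv[sel] == 1L, na.rm = TRUE)
  list(marker_a = rules$name[rules$marker_id == ia],
       marker_b = rules$name[rules$marker_id == ib],
       n_a = n_a, n_ab = n_ab, pct = 100 * n_ab / n_a, defined = TRUE)
}

#' Full 15 x 15 conditional co-occurrence matrix
#'
#' Entry (a, b) is the percent of in-scope counties with marker `a` that also
#' have marker `b`; rows with no positive county are `NA`.
#'
#' @inheritParams marker_frequencies
#' @return A 15 x 15 numeric matrix with marker names as dimnames.
#' @export
cooccurrence_matrix <- function(markers, restrict_to_pchpsa = TRUE) {
  rules <- attr(markers, "rules")
  if (is.null(rules)) rules <- marker_rules()
  nm <- rules$name[order(rules$marker_id)]
  out <- matrix(NA_real_, 15L, 15L, dimnames = list(nm, nm))
  for (a in 1:15) for (b in 1:15) {
    out[a, b] <- cooccurrence(markers, a, b, restrict_to_pchpsa)$pct
  }
  out
}
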