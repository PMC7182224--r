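test_that("quantile threshold uses linear interpolation and skips missing", {
  expect_equal(quantile_threshold(rep(5, 5), 0.75), 5)
  expect_equal(quantile_threshold(1:100, 0.75), 75.25)

  # brute-force rank-interpolation oracle: h = 1 + (n-1)q
  set.seed(3)
  for (q in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
    x <- rnorm(37)
    s <- sort(x)
    h <- 1 + (length(x) - 1) * q
    expected <- s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)])
    expect_equal(quantile_threshold(x, q), expected)
  }

  # missing values are excluded, not imputed
  x <- as.numeric(1:100)
  set.seed(9)
  x[sample(100, 20)] <- NA
  expect_equal(quantile_threshold(x, 0.25),
               unname(quantile(x[!is.na(x)], 0.25, type = 7)))

  expect_error(quantile_threshold(c(1, 2, 3, NA, NA), 0.5), "at least 4")
  expect_error(quantile_threshold(1:10, 0), "in \\(0,1\\)")
})

test_that("quantile marker comparisons are strict and missing-preserving", {
  expect_equal(score_quantile_marker(10.0, 10.0, "high"), 0L)
  expect_equal(score_quantile_marker(10.0, 10.0, "low"), 0L)
  expect_equal(score_quantile_marker(30000, 41000, "low"), 1L)
  expect_equal(score_quantile_marker(c(9, 11, NA), 10, "high"),
               c(0L, 1L, NA))
})

test_that("rurality marker matches the code-combination truth table", {
  # exhaustive enumeration over every valid (rucc, uic) pair
  grid <- expand.grid(rucc = 1:9, uic = 1:12)
  got <- rural_marker(grid$rucc, grid$uic)
  expected <- as.integer(grid$rucc %in% c(7, 8, 9) |
                           grid$uic %in% c(9, 10, 11, 12))
  expect_identical(got, expected)
  expect_equal(rural_marker(7L, 5L), 1L)
  expect_equal(rural_marker(5L, 9L), 1L)
  expect_equal(rural_marker(1L, 1L), 0L)
  expect_error(rural_marker(0L, 5L), "rucc")
  expect_error(rural_marker(3L, 13L), "uic")
})

test_that("pcHPSA-county marker ORs the AHRF class with the record count", {
  grid <- expand.grid(cls = c("whole", "partial", "none"), cnt = 0:3,
                      stringsAsFactors = FALSE)
  got <- pchpsa_county_marker(grid$cls, grid$cnt)
  expect_identical(got, as.integer(grid$cls %in% c("whole", "partial") |
                                     grid$cnt >= 1))
  expect_error(pchpsa_county_marker("total", 0), "total")
  expect_error(pchpsa_county_marker("none", -1), "non-negative")
})

test_that("full scoring handles the null and maximal county profiles", {
  n <- 41
  df <- make_counties(n)
  # county 21 sits at the median of every symmetric sequence; keep it metro,
  # unflagged, no designations -> zero markers
  counts <- zero_counts(df)
  ms <- score_markers(df, counts)
  mid <- (n + 1) / 2
  expect_equal(ms$total[mid], 0L)

  # maximal case: push one county beyond every threshold
  df2 <- df
  hi <- c("pct_65plus", "lbw_rate", "unemployment_rate", "pct_below_fpl",
          "pct_65plus_deep_poverty", "pct_under18_deep_poverty", "pct_no_hs",
          "pct_nonwhite_hispanic", "pct_uninsured_lowincome")
  for (f in hi) df2[[f]][1] <- max(df2[[f]]) + 1
  df2$median_hh_income[1] <- min(df2$median_hh_income) - 1
  df2$pop_density[1] <- min(df2$pop_density) / 2
  df2$rucc[1] <- 9L
  df2$persistent_poverty[1] <- TRUE
  df2$ahrf_hpsa_class[1] <- "whole"
  counts2 <- counts
  counts2[df2$fips[1]] <- 10L
  ms2 <- score_markers(df2, counts2)
  expect_equal(ms2$total[1], 15L)
  expect_equal(unname(unlist(ms2[1, sprintf("m%02d", 1:15)])), rep(1L, 15))
})

test_that("strict-quantile markers flag about a quarter of tie-free data", {
  # oracle: count values strictly beyond the type-7 quantile by sorting
  set.seed(21)
  for (n in c(97, 400, 1000)) {
    df <- make_counties(n)
    for (f in c("pct_below_fpl", "median_hh_income", "pct_no_hs")) {
      df[[f]] <- runif(n, 1, 99)  # continuous, ties impossible a.s.
    }
    ms <- score_markers(df, zero_counts(df))
    for (spec in list(c("m05", "pct_below_fpl", "high"),
                      c("m09", "pct_no_hs", "high"),
                      c("m03", "median_hh_income", "low"))) {
      x <- df[[spec[2]]]
      thr <- quantile(x, if (spec[3] == "high") 0.75 else 0.25, type = 7)
      oracle <- if (spec[3] == "high") sum(x > thr) else sum(x < thr)
      got <- sum(ms[[spec[1]]])
      expect_equal(got, oracle)
      expect_lte(got, ceiling(0.25 * n))
      expect_gte(got, ceiling(0.25 * n) - 1)
    }
  }
})

test_that("scoring is permutation invariant and totals add up", {
  sim <- simulate_counties(sim_config(n_counties = 300, seed = 5))
  counts <- count_hpsas_by_county(filter_hpsas(sim$hpsas), sim$counties$fips)
  ms <- score_markers(sim$counties, counts)

  set.seed(1)
  perm <- sample(nrow(sim$counties))
  ms_p <- score_markers(sim$counties[perm, ], counts)
  reord <- as.data.frame(ms_p)[match(ms$fips, ms_p$fips), ]
  rownames(reord) <- NULL
  expect_equal(reord, as.data.frame(ms), ignore_attr = TRUE)

  # total = count of 1s among non-missing scores, always
  m <- marker_matrix(ms)
  expect_equal(ms$total, unname(as.integer(rowSums(m == 1L, na.rm = TRUE))))
  expect_equal(ms$n_missing, unname(as.integer(rowSums(is.na(m)))))
  # missing only ever occurs on the low birth weight marker
  expect_true(all(is.na(m[, setdiff(colnames(m), "m02")]) == FALSE))
})

test_that("raising a county's poverty rate never clears its poverty marker", {
  set.seed(33)
  df <- make_counties(60)
  df$pct_below_fpl <- runif(60, 5, 40)
  counts <- zero_counts(df)
  base <- score_markers(df, counts)
  for (delta in c(0.5, 3, 10)) {
    df2 <- df
    df2$pct_below_fpl[7] <- min(df2$pct_below_fpl[7] + delta, 100)
    bumped <- score_markers(df2, counts)
    expect_gte(bumped$m05[7], base$m05[7])
  }
})

test_that("high-burden cutoff tracks the 75th percentile of totals", {
  expect_equal(high_burden_cutoff(rep(3L, 10)), 3L)
  expect_equal(sum(rep(3L, 10) > high_burden_cutoff(rep(3L, 10))), 0L)
  # uniform multiset 0..12: brute-force type-7 quantile is 9
  totals <- rep(0:12, times = 50)
  expect_equal(high_burden_cutoff(totals), 9L)
  # a distribution whose 75th percentile is exactly 6.0 -> "> 6"
  totals6 <- c(rep(2L, 75), rep(6L, 15), rep(9L, 11))
  expect_equal(unname(quantile(totals6, 0.75, type = 7)), 6)
  expect_equal(high_burden_cutoff(totals6), 6L)
})

test_that("a rule-set config round-trips and drives scoring", {
  rules <- marker_rules()
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rules, path, row.names = FALSE)
  back <- read_marker_rules(path)
  expect_equal(back$quantile, rules$quantile)
  # a sensitivity variant: 90th percentile poverty rule
  rules$quantile[rules$name == "poverty"] <- 0.90
  utils::write.csv(rules, path, row.names = FALSE)
  alt <- read_marker_rules(path)
  df <- make_counties(50)
  set.seed(2)
  df$pct_below_fpl <- runif(50, 5, 40)
  n_default <- sum(score_markers(df, zero_counts(df))$m05)
  n_strict <- sum(score_markers(df, zero_counts(df), alt)$m05)
  expect_lt(n_strict, n_default)
})
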