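test_that("percentage rounding is half-away-from-zero", {
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(2.25, 1), 2.3)
  expect_equal(round_half_up(-2.25, 1), -2.3)
  expect_equal(round_half_up(95.5, 0), 96)
  expect_equal(round_half_up(2.35, 1), 2.4)
  expect_equal(round_half_up(21.0694, 1), 21.1)
})

test_that("national overview enumerates burden classes correctly", {
  fake <- function(totals) {
    structure(data.frame(fips = sprintf("%05d", seq_along(totals)),
                         total = totals), class = c("marker_set",
                                                    "data.frame"))
  }
  ov <- national_overview(fake(c(13L, 13L, 5L, 0L)))
  expect_equal(ov$n_zero_markers, 1L)
  expect_equal(ov$pct_zero_markers, 25.0)
  expect_equal(ov$n_ge_10, 2L)
  expect_equal(ov$pct_ge_10, 50.0)
  expect_equal(ov$max_total, 13L)
  expect_equal(ov$n_max, 2L)

  all_zero <- national_overview(fake(rep(0L, 7)))
  expect_equal(all_zero$n_zero_markers, all_zero$n_total)
  expect_equal(all_zero$n_ge_10, 0L)
})

test_that("regional and national percentage arithmetic reproduces the
           reference counts", {
  # printed regional count columns: total counties, pcHPSA counties,
  # high-burden pcHPSA counties, and their printed percentages
  ref <- data.frame(
    n = c(67, 83, 283, 736, 524, 503, 412, 291, 95, 148, 3142),
    pchpsa = c(62, 69, 223, 672, 443, 459, 358, 271, 95, 145, 2797),
    pct = c(92.5, 83.1, 78.8, 91.3, 84.5, 91.3, 86.9, 93.1, 100.0, 98.0,
            89.0),
    hb = c(NA, 3, 49, 288, 22, 184, 29, 44, 24, 19, 662),
    hb_pct = c(NA, 3.6, 17.3, 39.1, 4.2, 36.6, 7.0, 15.1, 25.3, 12.8, 21.1)
  )
  expect_equal(round_half_up(100 * ref$pchpsa / ref$n, 1), ref$pct)
  ok <- !is.na(ref$hb)
  expect_equal(round_half_up(100 * ref$hb[ok] / ref$n[ok], 1), ref$hb_pct[ok])
  # national burden distribution
  expect_equal(round_half_up(100 * 131 / 3142, 1), 4.2)
  expect_equal(round_half_up(100 * 206 / 3142, 1), 6.6)
  expect_equal(round_half_up(100 * 9 / 3142, 1), 0.3)
  expect_equal(round_half_up(100 * (3142 - 131) / 3142, 0), 96)
})

make_scored <- function(seed = 5, n = 400) {
  sim <- simulate_counties(sim_config(n_counties = n, seed = seed))
  counts <- count_hpsas_by_county(filter_hpsas(sim$hpsas), sim$counties$fips)
  list(counties = sim$counties, markers = score_markers(sim$counties, counts))
}

test_that("regional summaries partition the national row", {
  s <- make_scored()
  cutoff <- high_burden_cutoff(s$markers$total)
  tab <- regional_summary_table(s$markers, s$counties, cutoff)
  all_row <- tab[tab$hhs_region == "ALL", ]
  reg <- tab[tab$hhs_region != "ALL", ]
  expect_equal(sum(reg$n_counties), all_row$n_counties)
  expect_equal(sum(reg$n_pchpsa), all_row$n_pchpsa)
  expect_equal(sum(reg$n_high_burden_pchpsa), all_row$n_high_burden_pchpsa)
  expect_true(all(tab$n_pchpsa <= tab$n_counties))
  # percentages recompute from the counts under the rounding rule
  expect_equal(tab$pct_pchpsa,
               round_half_up(100 * tab$n_pchpsa / tab$n_counties, 1))

  one <- regional_summary(s$markers, s$counties, cutoff, region = 4)
  expect_equal(one$n_counties, sum(s$counties$hhs_region == 4))
  expect_lte(nrow(one$top_markers), 3L)
  expect_true(all(diff(one$top_markers$pct) <= 0))
})

test_that("whole-hundred percentages print without decimals", {
  expect_equal(format_pct(100.0), "100")
  expect_equal(format_pct(91.3), "91.3")
  expect_equal(format_pct(0), "0.0")
})

test_that("marker frequency ranking sorts by share then marker id", {
  # 4 pcHPSA counties: poverty in 3, rurality in 3, low income in 1
  df <- make_counties(4, ahrf_hpsa_class = "whole")
  df$pct_below_fpl <- c(30, 30, 30, 5)
  df$rucc <- c(9L, 9L, 9L, 1L)
  df$median_hh_income <- c(20000, 60000, 60000, 60000)
  ms <- score_markers(df, zero_counts(df))
  # force the exact marker pattern (thresholds over n=4 are degenerate)
  m <- as.data.frame(ms)
  m[, sprintf("m%02d", 1:15)] <- 0L
  m$m05 <- c(1L, 1L, 1L, 0L)
  m$m13 <- c(1L, 1L, 1L, 0L)
  m$m03 <- c(1L, 0L, 0L, 0L)
  m$m14 <- 1L
  ms2 <- structure(m, class = c("marker_set", "data.frame"),
                   rules = attr(ms, "rules"))
  freq <- marker_frequencies(ms2, df, "ALL", restrict_to_pchpsa = TRUE)
  # pcHPSA-county itself tops the list at 100%, then the tie resolves by id
  expect_equal(freq$name[1:4],
               c("pchpsa_county", "poverty", "rurality", "low_income"))
  expect_equal(freq$pct[1:4], c(100, 75, 75, 25))
  # denominator restriction: pcHPSA counties only
  m$m14 <- c(1L, 1L, 0L, 0L)
  ms3 <- structure(m, class = c("marker_set", "data.frame"),
                   rules = attr(ms, "rules"))
  freq3 <- marker_frequencies(ms3, df, "ALL", restrict_to_pchpsa = TRUE)
  expect_equal(freq3$pct[freq3$name == "poverty"], 100)
})

test_that("conditional co-occurrence matches direct enumeration", {
  df <- make_counties(4, ahrf_hpsa_class = "whole")
  ms <- score_markers(df, zero_counts(df))
  m <- as.data.frame(ms)
  m[, sprintf("m%02d", 1:15)] <- 0L
  m$m14 <- 1L
  m$m05 <- c(1L, 1L, 0L, 0L)  # a = {c1, c2}
  m$m03 <- c(0L, 1L, 1L, 0L)  # b = {c2, c3}
  m$m13 <- c(1L, 1L, 0L, 0L)  # identical to a
  m$m12 <- c(0L, 0L, 1L, 1L)  # disjoint from a
  ms2 <- structure(m, class = c("marker_set", "data.frame"),
                   rules = attr(ms, "rules"))
  expect_equal(cooccurrence(ms2, "poverty", "low_income")$pct, 50)
  expect_equal(cooccurrence(ms2, "poverty", "rurality")$pct, 100)
  expect_equal(cooccurrence(ms2, "poverty", "sparse_population")$pct, 0)
  # asymmetry: P(b|a) != P(a|b) in general
  expect_equal(cooccurrence(ms2, "low_income", "poverty")$pct, 50)
  # undefined when the conditioning marker never fires
  und <- cooccurrence(ms2, "education", "poverty")
  expect_false(und$defined)
  expect_true(is.na(und$pct))
  # self-co-occurrence is 100 whenever defined
  expect_equal(cooccurrence(ms2, "poverty", "poverty")$pct, 100)
})

test_that("the full co-occurrence matrix has a unit diagonal where defined", {
  s <- make_scored(seed = 8, n = 300)
  cm <- cooccurrence_matrix(s$markers)
  d <- diag(cm)
  expect_true(all(is.na(d) | d == 100))
  expect_true(all(is.na(cm) | (cm >= 0 & cm <= 100)))
})
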