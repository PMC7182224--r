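# In-code fixtures: small valid county tables and HPSA record sets.

make_counties <- function(n = 8, state = "MS", ...) {
  stopifnot(n >= 1)
  df <- data.frame(
    fips = paste0(.prefix_for(state),
                  formatC(2 * seq_len(n) - 1, width = 3, flag = "0")),
    state = state,
    hhs_region = unname(sdohmarkers::hhs_region_map()[state]),
    pct_65plus = seq(10, 25, length.out = n),
    lbw_rate = seq(60, 100, length.out = n),
    median_hh_income = seq(35000, 70000, length.out = n),
    unemployment_rate = seq(3, 8, length.out = n),
    pct_below_fpl = seq(8, 30, length.out = n),
    pct_65plus_deep_poverty = seq(1, 6, length.out = n),
    pct_under18_deep_poverty = seq(4, 15, length.out = n),
    persistent_poverty = rep(FALSE, n),
    pct_no_hs = seq(6, 25, length.out = n),
    pct_nonwhite_hispanic = seq(5, 60, length.out = n),
    pct_uninsured_lowincome = seq(8, 28, length.out = n),
    pop_density = seq(5, 500, length.out = n),
    rucc = rep(1L, n),
    uic = rep(1L, n),
    ahrf_hpsa_class = rep("none", n),
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

.prefix_for <- function(state) {
  c(AL = "01", MS = "28", CT = "09", TX = "48", CA = "06", NY = "36",
    MO = "29", MT = "30", VA = "51", WA = "53")[state]
}

make_hpsas <- function(fips, status = "designated",
                       designation_date = as.Date("2016-01-01"),
                       status_date = designation_date) {
  n <- length(fips)
  data.frame(
    hpsa_id = sprintf("T-%03d", seq_len(n)),
    county_fips = fips,
    hpsa_type = rep("geographic", n),
    status = rep_len(status, n),
    designation_date = rep_len(as.Date(designation_date), n),
    status_date = rep_len(as.Date(status_date), n),
    stringsAsFactors = FALSE
  )
}

# uniform zero counts for a county table
zero_counts <- function(counties) {
  stats::setNames(integer(nrow(counties)), counties$fips)
}
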