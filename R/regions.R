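# State -> HHS Region composition (ten federal administrative regions; DC is
# assigned to Region 3).  Regions group states, so the map is a package
# constant rather than an input.
.hhs_region_states <- list(
  `1`  = c("CT", "ME", "MA", "NH", "RI", "VT"),
  `2`  = c("NJ", "NY"),
  `3`  = c("DC", "DE", "MD", "PA", "VA", "WV"),
  `4`  = c("AL", "FL", "GA", "KY", "MS", "NC", "SC", "TN"),
  `5`  = c("IL", "IN", "MI", "MN", "OH", "WI"),
  `6`  = c("AR", "LA", "NM", "OK", "TX"),
  `7`  = c("IA", "KS", "MO", "NE"),
  `8`  = c("CO", "MT", "ND", "SD", "UT", "WY"),
  `9`  = c("AZ", "CA", "HI", "NV"),
  `10` = c("AK", "ID", "OR", "WA")
)

# 2-digit FIPS state prefixes, used by the synthetic generator to mint
# well-formed county identifiers (real prefixes, synthetic county codes).
.state_fips_prefix <- c(
  AL = "01", AK = "02", AZ = "04", AR = "05", CA = "06", CO = "08", CT = "09",
  DE = "10", DC = "11", FL = "12", GA = "13", HI = "15", ID = "16", IL = "17",
  IN = "18", IA = "19", KS = "20", KY = "21", LA = "22", ME = "23", MD = "24",
  MA = "25", MI = "26", MN = "27", MS = "28", MO = "29", MT = "30", NE = "31",
  NV = "32", NH = "33", NJ = "34", NM = "35", NY = "36", NC = "37", ND = "38",
  OH = "39", OK = "40", OR = "41", PA = "42", RI = "44", SC = "45", SD = "46",
  TN = "47", TX = "48", UT = "49", VT = "50", VA = "51", WA = "53", WV = "54",
  WI = "55", WY = "56"
)

#' State to HHS Region lookup table
#'
#' Returns the mapping from 2-letter USPS state codes (50 states plus the
#' District of Columbia) to the ten HHS Regions.  The District of Columbia is
#' part of Region 3.
#'
#' @return A named integer vector: names are USPS state codes, values are HHS
#'   Region numbers (1-10).
#' @examples
#' hhs_region_map()[["MS"]]  # 4
#' @export
hhs_region_map <- function() {
  states <- unlist(.hhs_region_states, use.names = FALSE)
  regions <- rep(as.integer(names(.hhs_region_states)),
                 lengths(.hhs_region_states))
  stats::setNames(regions, states)
}

#' @rdname hhs_region_map
#' @param state Character vector of 2-letter USPS state codes.
#' @return `hhs_region_for_state()` returns the integer HHS Region for each
#'   state; unknown codes are a hard error.
#' @export
hhs_region_for_state <- function(state) {
  map <- hhs_region_map()
  bad <- setdiff(unique(state), names(map))
  if (length(bad) > 0L) {
    stop("unknown state code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(map[state])
}
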