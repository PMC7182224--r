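# Ingest: read/validate/normalize the county measures table and the HPSA
# designation export, apply the designation-date/status filter, and aggregate
# pcHPSA counts by county.

.county_percent_fields <- c(
  "pct_65plus", "pct_below_fpl", "pct_65plus_deep_poverty",
  "pct_under18_deep_poverty", "pct_no_hs", "pct_nonwhite_hispanic",
  "pct_uninsured_lowincome", "unemployment_rate"
)

.county_fields <- c(
  "fips", "state", "hhs_region", "pct_65plus", "lbw_rate", "median_hh_income",
  "unemployment_rate", "pct_below_fpl", "pct_65plus_deep_poverty",
  "pct_under18_deep_poverty", "persistent_poverty", "pct_no_hs",
  "pct_nonwhite_hispanic", "pct_uninsured_lowincome", "pop_density",
  "rucc", "uic", "ahrf_hpsa_class"
)

.hpsa_fields <- c("hpsa_id", "county_fips", "hpsa_type", "status",
                  "designation_date", "status_date")

.hpsa_statuses <- c("designated", "proposed_withdrawal", "withdrawn")

#' Zero-pad a county FIPS code to five characters
#'
#' County identifiers are stored as character strings, never integers, so that
#' leading zeros (Connecticut, Maine, ...) survive round-trips.
#'
#' @param x Character or integer vector of FIPS codes with at most 5 digits.
#' @return Character vector of 5-character zero-padded codes.
#' @export
pad_fips <- function(x) {
  x <- trimws(as.character(x))
  bad <- !grepl("^[0-9]{1,5}$", x)
  if (any(bad)) {
    stop("malformed FIPS code(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  sprintf("%05d", as.integer(x))
}

#' Read and validate a county measures table
#'
#' Reads a CSV with one row per county (schema mirroring an Area Health
#' Resources File extract), zero-pads FIPS codes, fills the HHS Region from
#' the state when absent, and enforces the table invariants.  A missing low
#' birth weight rate (`lbw_rate`) is a first-class missing value and is never
#' imputed; every other measure must be present.
#'
#' @param path Path to a CSV file with a header row and the columns of
#'   [county_schema()] (the `hhs_region` column may be omitted or blank).
#' @param region_map Named integer vector mapping state codes to HHS Regions;
#'   defaults to [hhs_region_map()].
#' @return A `data.frame` with one validated row per county.
#' @seealso [read_hpsa_file()], [write_county_table()]
#' @export
read_county_table <- function(path, region_map = hhs_region_map()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = c(fips = "character",
                                              state = "character"),
                         stringsAsFactors = FALSE)
  required <- setdiff(.county_fields, "hhs_region")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("county table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw$fips <- pad_fips(raw$fips)
  dup <- raw$fips[duplicated(raw$fips)]
  if (length(dup) > 0L) {
    stop("duplicate FIPS code(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(raw$state), names(region_map))
  if (length(unknown) > 0L) {
    stop("unknown state code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  mapped <- unname(region_map[raw$state])
  if (!"hhs_region" %in% names(raw) || all(is.na(raw$hhs_region))) {
    raw$hhs_region <- mapped
  } else {
    fill <- is.na(raw$hhs_region)
    raw$hhs_region[fill] <- mapped[fill]
    clash <- which(raw$hhs_region != mapped)
    if (length(clash) > 0L) {
      stop("hhs_region inconsistent with state for row(s) ",
           paste(utils::head(clash, 5L), collapse = ", "), call. = FALSE)
    }
  }
  raw$hhs_region <- as.integer(raw$hhs_region)

  for (f in .county_percent_fields) {
    v <- raw[[f]]
    bad <- which(is.na(v) | v < 0 | v > 100)
    if (length(bad) > 0L) {
      stop("column '", f, "' missing or outside [0,100] at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
  }
  num_required <- c("median_hh_income", "pop_density")
  for (f in num_required) {
    bad <- which(is.na(raw[[f]]) | raw[[f]] < 0)
    if (length(bad) > 0L) {
      stop("column '", f, "' missing or negative at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
  }
  raw$rucc <- as.integer(raw$rucc)
  raw$uic <- as.integer(raw$uic)
  if (any(is.na(raw$rucc)) || any(raw$rucc < 1L | raw$rucc > 9L)) {
    stop("rucc must be an integer in 1..9", call. = FALSE)
  }
  if (any(is.na(raw$uic)) || any(raw$uic < 1L | raw$uic > 12L)) {
    stop("uic must be an integer in 1..12", call. = FALSE)
  }
  raw$persistent_poverty <- as.logical(raw$persistent_poverty)
  if (any(is.na(raw$persistent_poverty))) {
    stop("persistent_poverty must be TRUE/FALSE for every county",
         call. = FALSE)
  }
  raw$ahrf_hpsa_class <- tolower(trimws(raw$ahrf_hpsa_class))
  bad_class <- setdiff(unique(raw$ahrf_hpsa_class),
                       c("whole", "partial", "none"))
  if (length(bad_class) > 0L) {
    stop("ahrf_hpsa_class must be one of whole/partial/none; saw: ",
         paste(bad_class, collapse = ", "), call. = FALSE)
  }
  raw[, .county_fields]
}

#' @rdname read_county_table
#' @return `county_schema()` returns the ordered column names of the county
#'   CSV schema.
#' @export
county_schema <- function() .county_fields

#' Write a county measures table
#'
#' Writes the exact CSV schema consumed by [read_county_table()] (RFC-4180
#' quoting, UTF-8, missing `lbw_rate` as an empty field), so that a
#' read-write-read round trip is lossless.
#'
#' @param counties County `data.frame` as returned by [read_county_table()]
#'   or [simulate_counties()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_county_table <- function(counties, path) {
  utils::write.csv(counties[, .county_fields], path, row.names = FALSE,
                   na = "", quote = TRUE)
  invisible(path)
}

.normalize_hpsa_status <- function(x) {
  key <- gsub("[ _-]+", "_", tolower(trimws(x)))
  key[key == "proposed_for_withdrawal"] <- "proposed_withdrawal"
  bad <- setdiff(unique(key), .hpsa_statuses)
  if (length(bad) > 0L) {
    stop("unknown HPSA status value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  key
}

#' Read an HPSA designation records file
#'
#' Reads a CSV of primary care HPSA designation records (schema mirroring the
#' HRSA data-portal export): one row per (designation, county) pair with an
#' opaque id, the county FIPS, the designation type, a status, and ISO-8601
#' designation/status dates.  Statuses are normalized case-insensitively to
#' `designated`, `proposed_withdrawal`, or `withdrawn`.  No date filtering
#' happens at read time; see [filter_hpsas()].
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with columns `hpsa_id`, `county_fips`, `hpsa_type`,
#'   `status`, `designation_date`, `status_date` (`Date` columns).
#' @export
read_hpsa_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(.hpsa_fields, names(raw))
  if (length(missing_cols) > 0L) {
    stop("HPSA file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    raw$designation_date <- as.Date(character())
    raw$status_date <- as.Date(character())
    return(raw[, .hpsa_fields])
  }
  raw$county_fips <- pad_fips(raw$county_fips)
  raw$hpsa_type <- tolower(trimws(raw$hpsa_type))
  bad_type <- setdiff(unique(raw$hpsa_type),
                      c("geographic", "population", "facility"))
  if (length(bad_type) > 0L) {
    stop("unknown hpsa_type value(s): ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  raw$status <- .normalize_hpsa_status(raw$status)
  for (f in c("designation_date", "status_date")) {
    parsed <- as.Date(raw[[f]], format = "%Y-%m-%d")
    bad <- which(is.na(parsed))
    if (length(bad) > 0L) {
      stop("unparseable ", f, " at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    raw[[f]] <- parsed
  }
  raw[, .hpsa_fields]
}

#' @rdname read_hpsa_file
#' @param hpsas HPSA records `data.frame`.
#' @export
write_hpsa_file <- function(hpsas, path) {
  out <- hpsas[, .hpsa_fields]
  out$designation_date <- format(out$designation_date, "%Y-%m-%d")
  out$status_date <- format(out$status_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE)
  invisible(path)
}

#' Filter HPSA records to active designations as of a date
#'
#' Retains only records that were designated on or before `as_of` and whose
#' status is `designated`; records marked `proposed_withdrawal` or
#' `withdrawn`, and designations dated after `as_of`, are dropped.  Input
#' order is preserved and filtering is idempotent.
#'
#' @param hpsas HPSA records from [read_hpsa_file()].
#' @param as_of Cut-off date (default `2017-07-01`, the snapshot date used
#'   throughout the package's reference analysis).
#' @return The retained subset of `hpsas`.
#' @export
filter_hpsas <- function(hpsas, as_of = as.Date("2017-07-01")) {
  as_of <- as.Date(as_of)
  if (length(as_of) != 1L || is.na(as_of)) {
    stop("as_of must be a single valid date", call. = FALSE)
  }
  keep <- hpsas$status == "designated" & hpsas$designation_date <= as_of
  hpsas[keep, , drop = FALSE]
}

#' Aggregate HPSA records to per-county designation counts
#'
#' @param hpsas Filtered HPSA records (see [filter_hpsas()]).
#' @param all_fips Character vector of every county FIPS in the analysis;
#'   counties with no records get a count of zero.
#' @return A named integer vector over `all_fips` (plus, after a warning, any
#'   record FIPS absent from `all_fips`); values sum to `nrow(hpsas)`.
#' @export
count_hpsas_by_county <- function(hpsas, all_fips) {
  all_fips <- pad_fips(all_fips)
  counts <- stats::setNames(integer(length(all_fips)), all_fips)
  if (nrow(hpsas) > 0L) {
    stray <- setdiff(unique(hpsas$county_fips), all_fips)
    if (length(stray) > 0L) {
      warning("HPSA record(s) for county FIPS not in the county table: ",
              paste(stray, collapse = ", "), call. = FALSE)
      counts <- c(counts, stats::setNames(integer(length(stray)), stray))
    }
    tab <- table(hpsas$county_fips)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}
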