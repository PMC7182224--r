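# Pipeline driver and command-style entry points.  The functions here are
# the surface a shell front-end (inst/cli/sdoh-pipeline.R) wraps: simulate
# writes the two input CSVs plus a provenance sidecar; run chains ingest ->
# marker scoring -> burden summaries -> MCA and writes the seven output
# CSVs plus a run log recording every computed threshold.

.pipeline_outputs <- c("markers.csv", "regional_summary.csv",
                       "marker_frequencies.csv", "cooccurrence.csv",
                       "eigenvalues.csv", "contributions.csv",
                       "variability_sources.csv", "run_log.txt")

#' Run the full marker pipeline on in-memory inputs
#'
#' Filters the HPSA records as of the snapshot date, aggregates per-county
#' counts, scores all fifteen markers, derives the high-burden cutoff (or
#' uses a fixed one), and produces the national overview, regional
#' summaries, marker frequency rankings, the conditional co-occurrence
#' matrix, and per-region MCA variability sources.  Regions with fewer than
#' 15 in-scope counties are skipped for MCA with a note.
#'
#' @param counties County table from [read_county_table()] or
#'   [simulate_counties()].
#' @param hpsas HPSA records from [read_hpsa_file()] (unfiltered).
#' @param as_of Designation snapshot date (default `2017-07-01`).
#' @param rules Marker rule set (default [marker_rules()]).
#' @param exclude_marker Marker ids excluded from MCA (default 2).
#' @param region Optional single HHS Region to restrict regional outputs to
#'   (that region plus the ALL row); `NULL` means all ten regions.
#' @param burden_mode `"auto"` (cutoff from [high_burden_cutoff()]) or
#'   `"fixed:N"` for a fixed integer cutoff.
#' @param mca_rank_mode `"weighted"` or `"dim1"`, see
#'   [variability_sources()].
#' @return A list with `markers`, `counts`, `cutoff`, `overview`,
#'   `regional`, `frequencies`, `cooccurrence`, `mca` (per-region fits and
#'   sources), `thresholds`.
#' @export
run_pipeline <- function(counties, hpsas, as_of = as.Date("2017-07-01"),
                         rules = marker_rules(), exclude_marker = 2L,
                         region = NULL, burden_mode = "auto",
                         mca_rank_mode = c("dim1", "weighted")) {
  mca_rank_mode <- match.arg(mca_rank_mode)
  active <- filter_hpsas(hpsas, as_of)
  counts <- count_hpsas_by_county(active, counties$fips)
  markers <- score_markers(counties, counts, rules)
  cutoff <- if (identical(burden_mode, "auto")) {
    high_burden_cutoff(markers$total)
  } else if (grepl("^fixed:[0-9]+$", burden_mode)) {
    as.integer(sub("^fixed:", "", burden_mode))
  } else {
    stop("burden_mode must be \"auto\" or \"fixed:N\"", call. = FALSE)
  }
  regions <- if (is.null(region)) c(as.list(1:10), list("ALL"))
             else list(as.integer(region), "ALL")
  present <- vapply(regions, function(r) {
    identical(r, "ALL") || any(counties$hhs_region == r)
  }, logical(1))
  regions <- regions[present]

  regional <- regional_summary_table(markers, counties, cutoff, regions)
  freqs <- do.call(rbind, lapply(regions, function(r) {
    f <- marker_frequencies(markers, counties, r, restrict_to_pchpsa = TRUE)
    cbind(hhs_region = as.character(r), f, stringsAsFactors = FALSE)
  }))
  cooc <- cooccurrence_matrix(markers, restrict_to_pchpsa = TRUE)

  mca_res <- list()
  for (r in regions) {
    key <- as.character(r)
    n_scope <- sum(markers$m14 == 1L &
                     markers$fips %in% .scope_fips(markers, counties, r))
    if (n_scope < 15L) {
      message("skipping MCA for region ", key, " (", n_scope,
              " pcHPSA counties < 15)")
      next
    }
    mca_res[[key]] <- suppressMessages(
      regional_mca(markers, counties, r, restrict_to_pchpsa = TRUE,
                   exclude = exclude_marker, top_k = 2L,
                   mode = mca_rank_mode))
  }

  list(markers = markers, counts = counts, cutoff = cutoff,
       overview = national_overview(markers), regional = regional,
       frequencies = freqs, cooccurrence = cooc, mca = mca_res,
       thresholds = attr(markers, "thresholds"))
}

#' Write a pipeline result to CSV files
#'
#' Writes `markers.csv` (the per-county export usable for external
#' choropleth mapping), `regional_summary.csv`, `marker_frequencies.csv`,
#' `cooccurrence.csv`, `eigenvalues.csv`, `contributions.csv`,
#' `variability_sources.csv`, and `run_log.txt` (computed quantile
#' thresholds and the high-burden cutoff, so every binary decision is
#' auditable).
#'
#' @param result List from [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(as.data.frame(result$markers), p("markers.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(result$regional, p("regional_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(result$frequencies, p("marker_frequencies.csv"),
                   row.names = FALSE)
  cooc <- data.frame(marker = rownames(result$cooccurrence),
                     result$cooccurrence, check.names = FALSE)
  utils::write.csv(cooc, p("cooccurrence.csv"), row.names = FALSE, na = "")

  eig <- do.call(rbind, lapply(names(result$mca), function(k) {
    fit <- result$mca[[k]]$fit
    data.frame(hhs_region = k, dim = seq_len(fit$n_dims),
               eigenvalue = fit$eigenvalues,
               pct_inertia = 100 * fit$eigenvalues / fit$total_inertia,
               total_inertia = fit$total_inertia)
  }))
  utils::write.csv(eig, p("eigenvalues.csv"), row.names = FALSE)
  ctr <- do.call(rbind, lapply(names(result$mca), function(k) {
    fit <- result$mca[[k]]$fit
    vc <- fit$variable_contrib
    data.frame(hhs_region = k, marker = rep(rownames(vc), ncol(vc)),
               dim = rep(seq_len(ncol(vc)), each = nrow(vc)),
               contribution = as.vector(vc))
  }))
  utils::write.csv(ctr, p("contributions.csv"), row.names = FALSE)
  src <- do.call(rbind, lapply(names(result$mca), function(k) {
    s <- result$mca[[k]]$sources
    data.frame(hhs_region = k, source1 = s[1],
               source2 = if (length(s) > 1L) s[2] else NA_character_)
  }))
  utils::write.csv(src, p("variability_sources.csv"), row.names = FALSE)

  log_lines <- c(
    "sdohmarkers run log",
    sprintf("high_burden_cutoff: %d", result$cutoff),
    "quantile thresholds:",
    sprintf("  %s: %s", names(result$thresholds),
            format(result$thresholds, digits = 10))
  )
  writeLines(log_lines, p("run_log.txt"))
  invisible(out_dir)
}

#' Simulate-and-write command
#'
#' Writes `county.csv` and `hpsa.csv` in the schemas [read_county_table()]
#' and [read_hpsa_file()] consume, plus a `provenance.json` sidecar
#' recording the preset, seed, and size.  Re-running with the same arguments
#' produces byte-identical files.
#'
#' @param out_dir Output directory.
#' @param preset Generator preset; `"reference_2017"` is the calibrated
#'   default study design.
#' @param seed Integer RNG seed.
#' @param n_counties Number of counties (default: the preset's, 3142).
#' @return Invisible character vector of the files written.
#' @export
cmd_simulate <- function(out_dir, preset = "reference_2017", seed = 1L,
                         n_counties = NULL) {
  if (!identical(preset, "reference_2017")) {
    stop("unknown preset: ", preset, call. = FALSE)
  }
  cfg <- if (is.null(n_counties)) sim_config(seed = seed)
         else sim_config(n_counties = n_counties, seed = seed)
  sim <- simulate_counties(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(out_dir, c("county.csv", "hpsa.csv", "provenance.json"))
  write_county_table(sim$counties, files[1])
  write_hpsa_file(sim$hpsas, files[2])
  jsonlite::write_json(
    list(preset = preset, seed = cfg$seed, n_counties = cfg$n_counties,
         package = "sdohmarkers",
         version = as.character(utils::packageVersion("sdohmarkers"))),
    files[3], auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}

#' Run command: ingest CSVs, run the pipeline, write outputs
#'
#' On any stage error the partially written outputs are removed before the
#' error propagates, so an output directory is either complete or clean.
#'
#' @param county_csv,hpsa_csv Input paths.
#' @param out_dir Output directory.
#' @inheritParams run_pipeline
#' @return The [run_pipeline()] result, invisibly.
#' @export
cmd_run <- function(county_csv, hpsa_csv, out_dir,
                    as_of = as.Date("2017-07-01"), exclude_marker = 2L,
                    region = NULL, burden_mode = "auto",
                    mca_rank_mode = "dim1", rules_csv = NULL) {
  outs <- file.path(out_dir, .pipeline_outputs)
  tryCatch({
    counties <- read_county_table(county_csv)
    hpsas <- read_hpsa_file(hpsa_csv)
    rules <- if (is.null(rules_csv)) marker_rules()
             else read_marker_rules(rules_csv)
    res <- run_pipeline(counties, hpsas, as_of = as_of, rules = rules,
                        exclude_marker = exclude_marker, region = region,
                        burden_mode = burden_mode,
                        mca_rank_mode = mca_rank_mode)
    write_pipeline_outputs(res, out_dir)
    invisible(res)
  }, error = function(e) {
    file.remove(outs[file.exists(outs)])
    stop(e)
  })
}
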