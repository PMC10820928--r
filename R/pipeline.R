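# End-to-end orchestration: simulate -> qc -> bmc -> summarize -> report.
# Each step is an exported function; inst/cli/bmcscreen wraps them as
# shell subcommands.

#' Pipeline configuration
#'
#' @param endpoints endpoints to analyse (default all three).
#' @param bmr named numeric vector of BMR thresholds in percent per
#'   endpoint, or the string `"estimate"` to select them from the data
#'   with [estimate_bmr()]. Default 10 percent for every endpoint.
#' @param n_boot bootstrap curves per plate.
#' @param drop_failed exclude QC-failed plates before analysis.
#' @param tie_method rank tie handling, see [potency_ranks()].
#' @param merge_duplicates treat blind duplicates as one substance in
#'   summaries (duplicate ids collapse onto their partner).
#' @param seed root seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(endpoints = screen_endpoints(),
                            bmr = c("Mortality@24" = 10,
                                    "Mortality@120" = 10,
                                    "MalformedAny+Mort@120" = 10),
                            n_boot = 1000L, drop_failed = TRUE,
                            tie_method = "average",
                            merge_duplicates = TRUE, seed = 1L) {
  if (length(endpoints) == 0L) .stopf("endpoint list must be non-empty")
  endpoints <- match.arg(endpoints, screen_endpoints(), several.ok = TRUE)
  structure(list(endpoints = endpoints, bmr = bmr,
                 n_boot = as.integer(n_boot),
                 drop_failed = isTRUE(drop_failed),
                 tie_method = tie_method,
                 merge_duplicates = isTRUE(merge_duplicates),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Simulate a study and write the well table
#'
#' @param out output CSV path for the well table.
#' @param study_config a [synthetic_study_config()].
#' @return Invisibly, the generated [study_dataset()].
#' @export
pipeline_simulate <- function(out, study_config = synthetic_study_config()) {
  ds <- generate_study(study_config)
  write_well_table(ds, out)
  invisible(ds)
}

#' Analyse a well table into plate-level BMC results
#'
#' Reads (or accepts) a well-level dataset, applies vehicle-control QC,
#' derives the configured endpoints, resolves the BMR per endpoint (fixed
#' or estimated from the data), and runs the bootstrap BMC engine on every
#' plate series.
#'
#' @param dataset a [study_dataset()] or a path to a well-table CSV.
#' @param config a [pipeline_config()].
#' @param quiet suppress per-plate logging.
#' @return list: `results` (plate-level BMC data.frame), `qc` (QC report),
#'   `excluded` (QC-excluded plates), `bmr_used` (named vector).
#' @export
pipeline_analyze <- function(dataset, config = pipeline_config(),
                             quiet = TRUE) {
  if (is.character(dataset)) dataset <- read_well_table(dataset)
  stopifnot(inherits(dataset, "study_dataset"))
  dataset <- suppressWarnings(map_phenotypes(dataset))
  qc <- qc_plates(dataset)
  excluded <- qc[0, c("lab_id", "plate_id", "survival_120_pct")]
  excluded$reason <- character(0)
  if (config$drop_failed) {
    dropped <- drop_failed_plates(dataset, qc)
    dataset <- dropped$dataset
    excluded <- dropped$excluded
  }
  tab <- derive_endpoint(dataset, endpoint = config$endpoints)
  bmr_used <- if (identical(config$bmr, "estimate")) {
    vapply(config$endpoints, function(ep) {
      est <- estimate_bmr(tab[tab$endpoint == ep, , drop = FALSE],
                          config = bootstrap_config(n_boot = config$n_boot,
                                                    seed = config$seed))
      est$threshold_pct
    }, numeric(1))
  } else {
    bmr <- config$bmr
    if (is.null(names(bmr))) bmr <- setNames(rep(bmr[1L], length(config$endpoints)),
                                             config$endpoints)
    bmr[config$endpoints]
  }
  results <- bmc_analyze(tab, bmr = bmr_used,
                         config = bootstrap_config(n_boot = config$n_boot,
                                                   seed = config$seed),
                         quiet = quiet)
  list(results = results, qc = qc, excluded = excluded, bmr_used = bmr_used)
}

#' Summarize plate-level results into interlaboratory tables
#'
#' @param results plate-level BMC data.frame from [pipeline_analyze()].
#' @param config a [pipeline_config()].
#' @param duplicate_map optional named character vector mapping duplicate
#'   substance ids onto their partner ids (e.g. `c(S01dup = "S01")`);
#'   applied before summarizing when `merge_duplicates` is set.
#' @return list: `summary` (substance x lab x endpoint medians),
#'   `rendered` (report-form table per endpoint), `concordance` (per
#'   endpoint), `ranks` (per endpoint, when >= 2 labs and >= 1 all-active
#'   substance).
#' @export
pipeline_summarize <- function(results, config = pipeline_config(),
                               duplicate_map = NULL) {
  if (config$merge_duplicates && !is.null(duplicate_map)) {
    hit <- results$substance_id %in% names(duplicate_map)
    results$substance_id[hit] <- unname(duplicate_map[results$substance_id[hit]])
  }
  out <- list(summary = summarize_substance(results))
  out$rendered <- list(); out$concordance <- list(); out$ranks <- list()
  for (ep in unique(out$summary$endpoint)) {
    s <- out$summary[out$summary$endpoint == ep, ]
    out$rendered[[ep]] <- render_summary_table(s)
    labs <- sort(unique(s$lab_id))
    complete <- all(vapply(split(s, s$substance_id),
                           function(g) all(labs %in% g$lab_id), logical(1)))
    if (length(labs) >= 2L && complete) {
      out$concordance[[ep]] <- concordance_counts(s)
      if (any(tapply(!s$inactive, s$substance_id, all))) {
        out$ranks[[ep]] <- potency_ranks(s, tie_method = config$tie_method)
      }
    }
  }
  out
}

#' Write a run manifest
#'
#' Records everything needed to regenerate a run byte-for-byte: the
#' configuration, seed, BMR values used, package version, and every plate
#' excluded by QC with its reason.
#'
#' @param analysis output of [pipeline_analyze()].
#' @param config the [pipeline_config()] used.
#' @param path output JSON path.
#' @return Invisibly, the manifest list.
#' @export
pipeline_report <- function(analysis, config, path) {
  manifest <- list(
    package = "bmcscreen",
    version = as.character(utils::packageVersion("bmcscreen")),
    seed = config$seed,
    n_boot = config$n_boot,
    endpoints = config$endpoints,
    bmr_used = as.list(analysis$bmr_used),
    drop_failed = config$drop_failed,
    n_plates_analyzed = length(unique(paste(analysis$results$lab_id,
                                            analysis$results$plate_id))),
    excluded_plates = if (nrow(analysis$excluded) > 0L) {
      analysis$excluded
    } else {
      list()
    })
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Run the full pipeline on a synthetic study
#'
#' Convenience wrapper chaining [generate_study()], [pipeline_analyze()]
#' and [pipeline_summarize()].
#'
#' @param study_config a [synthetic_study_config()].
#' @param config a [pipeline_config()].
#' @param quiet suppress per-plate logging.
#' @return list with `dataset`, `analysis`, and `summaries`.
#' @export
run_pipeline <- function(study_config = synthetic_study_config(),
                         config = pipeline_config(), quiet = TRUE) {
  ds <- generate_study(study_config)
  analysis <- pipeline_analyze(ds, config = config, quiet = quiet)
  dup <- study_config$substances
  dup_map <- NULL
  if ("duplicate_of" %in% names(dup) && any(!is.na(dup$duplicate_of))) {
    dd <- dup[!is.na(dup$duplicate_of), ]
    dup_map <- setNames(dd$duplicate_of, dd$substance_id)
  }
  summaries <- pipeline_summarize(analysis$results, config = config,
                                  duplicate_map = dup_map)
  list(dataset = ds, analysis = analysis, summaries = summaries)
}
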