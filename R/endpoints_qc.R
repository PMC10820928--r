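# Endpoint derivation, plate-level QC on vehicle controls, and control
# performance summaries.

# Affected indicator for one endpoint, given a well table with mapped (or
# raw) phenotypes. MalformedAny+Mort@120 counts an embryo as affected if it
# is dead at 120 hpf or shows at least one recorded phenotypic alteration.
.affected_flag <- function(wells, endpoint) {
  switch(endpoint,
    "Mortality@24" = wells$dead_24,
    "Mortality@120" = wells$dead_120,
    "MalformedAny+Mort@120" = wells$dead_120 | nzchar(wells$phenotypes),
    .stopf("unknown endpoint '%s'; expected one of: %s", endpoint,
           paste(screen_endpoints(), collapse = ", "))
  )
}

#' Derive per-plate incidence dose-response series
#'
#' Aggregates test wells into one concentration-response series per
#' (lab, plate, substance, endpoint): the number of affected embryos out of
#' the total per tested concentration, and the percent response
#' `100 * affected / total`.
#'
#' @param dataset a [study_dataset()] (phenotypes should be mapped first
#'   when using the composite endpoint with a strict vocabulary, but the
#'   raw terms are sufficient since any recorded term counts as affected).
#' @param endpoint one or more of [screen_endpoints()].
#' @param roles which well roles to aggregate (default `"test"`; use
#'   `"positive"` for the positive-control series).
#' @return data.frame with columns `lab_id`, `plate_id`, `week_id`,
#'   `substance_id`, `endpoint`, `conc_uM`, `affected`, `total`,
#'   `response_pct`, ordered by increasing concentration within a series.
#' @export
derive_endpoint <- function(dataset, endpoint = screen_endpoints(),
                            roles = "test") {
  stopifnot(inherits(dataset, "study_dataset"))
  endpoint <- match.arg(endpoint, screen_endpoints(), several.ok = TRUE)
  w <- dataset$wells[dataset$wells$role %in% roles, , drop = FALSE]
  out <- list()
  for (ep in endpoint) {
    if (nrow(w) == 0L) next
    aff <- .affected_flag(w, ep)
    agg <- aggregate(
      cbind(affected = as.integer(aff), total = 1L),
      by = list(lab_id = w$lab_id, plate_id = w$plate_id,
                week_id = w$week_id, substance_id = w$substance_id,
                conc_uM = w$conc_uM),
      FUN = sum)
    agg$endpoint <- ep
    out[[ep]] <- agg
  }
  if (length(out) == 0L) {
    return(data.frame(lab_id = character(0), plate_id = character(0),
                      week_id = character(0), substance_id = character(0),
                      endpoint = character(0), conc_uM = numeric(0),
                      affected = integer(0), total = integer(0),
                      response_pct = numeric(0)))
  }
  res <- do.call(rbind, out)
  res$response_pct <- 100 * res$affected / res$total
  res <- res[order(res$lab_id, res$plate_id, res$substance_id,
                   res$endpoint, res$conc_uM), ]
  res <- res[, c("lab_id", "plate_id", "week_id", "substance_id", "endpoint",
                 "conc_uM", "affected", "total", "response_pct")]
  rownames(res) <- NULL
  .check_endpoint_nesting(res, strict = isTRUE(dataset$strict))
  res
}

# Endpoint nesting: Mortality@24 <= Mortality@120 <= MalformedAny+Mort@120
# at every plate x concentration (the affected sets are nested supersets).
.check_endpoint_nesting <- function(res, strict = FALSE) {
  eps <- screen_endpoints()
  if (!all(eps %in% unique(res$endpoint))) return(invisible(res))
  key <- paste(res$lab_id, res$plate_id, res$substance_id, res$conc_uM, sep = "\r")
  m24 <- res$affected[res$endpoint == eps[1L]][order(key[res$endpoint == eps[1L]])]
  m120 <- res$affected[res$endpoint == eps[2L]][order(key[res$endpoint == eps[2L]])]
  any120 <- res$affected[res$endpoint == eps[3L]][order(key[res$endpoint == eps[3L]])]
  if (length(m24) == length(m120) && length(m120) == length(any120) &&
      (any(m24 > m120) || any(m120 > any120))) {
    msg <- "endpoint nesting violated: expected Mortality@24 <= Mortality@120 <= MalformedAny+Mort@120 per concentration"
    if (strict) .stopf(msg) else .warnf(msg)
  }
  invisible(res)
}

#' Plate-level quality control on vehicle controls
#'
#' A plate passes QC when at least 80 percent of its vehicle-control
#' embryos survive to 120 hpf (pass at exactly 80). Failing plates are
#' flagged; [drop_failed_plates()] excludes them from downstream analyses.
#'
#' @param dataset a [study_dataset()].
#' @return data.frame with one row per plate: `lab_id`, `plate_id`,
#'   `vehicle_n`, `vehicle_dead_24`, `vehicle_dead_120`,
#'   `survival_120_pct`, `pass`, `affected_vehicle_120`.
#' @export
qc_plates <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  w <- dataset$wells
  plates <- unique(w[, c("lab_id", "plate_id")])
  veh <- w[w$role == "vehicle", , drop = FALSE]
  has_veh <- paste(plates$lab_id, plates$plate_id) %in% paste(veh$lab_id, veh$plate_id)
  if (any(!has_veh)) {
    .stopf("plate(s) without vehicle wells: %s",
           paste(plates$plate_id[!has_veh], collapse = ", "))
  }
  agg <- aggregate(
    cbind(vehicle_n = 1L,
          vehicle_dead_24 = as.integer(veh$dead_24),
          vehicle_dead_120 = as.integer(veh$dead_120),
          affected_vehicle_120 = as.integer(veh$dead_120 | nzchar(veh$phenotypes))),
    by = list(lab_id = veh$lab_id, plate_id = veh$plate_id),
    FUN = sum)
  agg$survival_120_pct <- 100 * (agg$vehicle_n - agg$vehicle_dead_120) / agg$vehicle_n
  agg$pass <- agg$survival_120_pct >= 80
  agg <- agg[order(agg$lab_id, agg$plate_id),
             c("lab_id", "plate_id", "vehicle_n", "vehicle_dead_24",
               "vehicle_dead_120", "survival_120_pct", "pass",
               "affected_vehicle_120")]
  rownames(agg) <- NULL
  agg
}

#' Drop QC-failed plates from a dataset
#'
#' @param dataset a [study_dataset()].
#' @param qc optional precomputed [qc_plates()] report.
#' @return A list with elements `dataset` (wells of failing plates removed)
#'   and `excluded` (data.frame of excluded plates with a reason code).
#' @export
drop_failed_plates <- function(dataset, qc = qc_plates(dataset)) {
  fail <- qc[!qc$pass, , drop = FALSE]
  key <- paste(dataset$wells$lab_id, dataset$wells$plate_id)
  drop <- key %in% paste(fail$lab_id, fail$plate_id)
  dataset$wells <- dataset$wells[!drop, , drop = FALSE]
  rownames(dataset$wells) <- NULL
  excluded <- fail[, c("lab_id", "plate_id", "survival_120_pct")]
  if (nrow(excluded) > 0L) {
    excluded$reason <- "vehicle_survival_below_80pct"
  } else {
    excluded$reason <- character(0)
  }
  list(dataset = dataset, excluded = excluded)
}

#' Vehicle-control performance summary
#'
#' Per-plate percent responses of the three endpoints among vehicle wells,
#' and per-lab exceedance counts: plates above 20 percent response per
#' endpoint (a reporting threshold only; it does not discard data), plates
#' with at least `k_dead` dead embryos at each assessment time, and plates
#' with at least three affected embryos.
#'
#' @param dataset a [study_dataset()].
#' @param k_dead integer threshold for the dead-embryo plate count.
#' @return list with `per_plate` and `per_lab` data.frames.
#' @export
vehicle_summary <- function(dataset, k_dead = 1L) {
  stopifnot(inherits(dataset, "study_dataset"))
  veh <- dataset$wells[dataset$wells$role == "vehicle", , drop = FALSE]
  if (nrow(veh) == 0L) .stopf("dataset has no vehicle wells")
  agg <- aggregate(
    cbind(n = 1L,
          dead_24 = as.integer(veh$dead_24),
          dead_120 = as.integer(veh$dead_120),
          affected_120 = as.integer(veh$dead_120 | nzchar(veh$phenotypes))),
    by = list(lab_id = veh$lab_id, plate_id = veh$plate_id),
    FUN = sum)
  agg$`Mortality@24` <- 100 * agg$dead_24 / agg$n
  agg$`Mortality@120` <- 100 * agg$dead_120 / agg$n
  agg$`MalformedAny+Mort@120` <- 100 * agg$affected_120 / agg$n
  per_lab <- do.call(rbind, lapply(split(agg, agg$lab_id), function(g) {
    data.frame(
      lab_id = g$lab_id[1L],
      n_plates = nrow(g),
      exceed20_mort24 = sum(g$`Mortality@24` > 20),
      exceed20_mort120 = sum(g$`Mortality@120` > 20),
      exceed20_affected120 = sum(g$`MalformedAny+Mort@120` > 20),
      plates_ge_k_dead_24 = sum(g$dead_24 >= k_dead),
      plates_ge_k_dead_120 = sum(g$dead_120 >= k_dead),
      plates_ge3_affected = sum(g$affected_120 >= 3L),
      median_mort24_pct = median(g$`Mortality@24`),
      median_mort120_pct = median(g$`Mortality@120`),
      median_affected120_pct = median(g$`MalformedAny+Mort@120`),
      row.names = NULL)
  }))
  rownames(per_lab) <- NULL
  list(per_plate = agg, per_lab = per_lab)
}

#' Pool positive-control wells by week
#'
#' Positive-control incidences are summed across plates within each
#' (lab, week, concentration) so that one pooled concentration-response
#' series per lab-week can be analysed for assay reproducibility over time.
#'
#' @param dataset a [study_dataset()].
#' @param endpoint one or more of [screen_endpoints()].
#' @return data.frame keyed by `lab_id`, `week_id`, `endpoint`, `conc_uM`
#'   with pooled `affected`, `total`, `response_pct`.
#' @export
pool_positive_weekly <- function(dataset, endpoint = screen_endpoints()) {
  stopifnot(inherits(dataset, "study_dataset"))
  endpoint <- match.arg(endpoint, screen_endpoints(), several.ok = TRUE)
  pos <- dataset$wells[dataset$wells$role == "positive", , drop = FALSE]
  if (nrow(pos) == 0L) {
    .warnf("dataset has no positive-control wells; returning empty pooling")
    return(data.frame(lab_id = character(0), week_id = character(0),
                      endpoint = character(0), conc_uM = numeric(0),
                      affected = integer(0), total = integer(0),
                      response_pct = numeric(0)))
  }
  # consistent concentration grids within a (lab, week)
  grids <- tapply(pos$conc_uM, paste(pos$lab_id, pos$week_id, pos$plate_id, sep = "\r"),
                  function(x) paste(sort(unique(x)), collapse = ","))
  lw <- sub("\r[^\r]*$", "", names(grids))
  for (g in split(unname(grids), lw)) {
    if (length(unique(g)) > 1L) {
      .stopf("inconsistent positive-control concentration grids within a lab-week")
    }
  }
  out <- list()
  for (ep in endpoint) {
    aff <- .affected_flag(pos, ep)
    agg <- aggregate(
      cbind(affected = as.integer(aff), total = 1L),
      by = list(lab_id = pos$lab_id, week_id = pos$week_id,
                conc_uM = pos$conc_uM),
      FUN = sum)
    agg$endpoint <- ep
    out[[ep]] <- agg
  }
  res <- do.call(rbind, out)
  res$response_pct <- 100 * res$affected / res$total
  res <- res[order(res$lab_id, res$week_id, res$endpoint, res$conc_uM),
             c("lab_id", "week_id", "endpoint", "conc_uM", "affected",
               "total", "response_pct")]
  rownames(res) <- NULL
  res
}
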