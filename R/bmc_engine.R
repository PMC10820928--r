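# Per-plate benchmark concentration engine: binomial bootstrap of incidence
# curves, monotonic noise filtering against a benchmark response threshold,
# activity calls from the non-noise fraction, and quantile BMC/CI.

#' Bootstrap configuration
#'
#' @param n_boot number of simulated concentration-response curves per
#'   plate (default 1000).
#' @param seed root random seed. Per-plate child seeds are derived from it
#'   by hashing the (lab, plate, substance, endpoint) key, so results do
#'   not depend on the order plates are analysed in.
#' @param ci_levels lower and upper quantiles of the bootstrap BMC
#'   distribution reported as the confidence interval (default 2.5 and
#'   97.5 percent).
#' @return list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_boot = 1000L, seed = 1L,
                             ci_levels = c(0.025, 0.975)) {
  n_boot <- as.integer(n_boot)
  if (is.na(n_boot) || n_boot < 1L) .stopf("n_boot must be >= 1")
  if (length(ci_levels) != 2L || ci_levels[1L] <= 0 || ci_levels[2L] >= 1 ||
      ci_levels[1L] >= ci_levels[2L]) {
    .stopf("ci_levels must satisfy 0 < lower < upper < 1")
  }
  structure(list(n_boot = n_boot, seed = as.integer(seed),
                 ci_levels = as.numeric(ci_levels)),
            class = "bootstrap_config")
}

.check_bmr <- function(bmr) {
  if (!is.numeric(bmr) || length(bmr) != 1L || is.na(bmr) ||
      bmr <= 0 || bmr >= 100) {
    .stopf("bmr must be a single percent response strictly between 0 and 100")
  }
  bmr
}

#' Bootstrap simulated concentration-response curves
#'
#' Resamples the incidence at each concentration as
#' `Binomial(total[i], affected[i] / total[i])` and converts the draws to
#' percent responses, producing `n_boot` simulated curves.
#'
#' @param affected integer vector, affected embryos per concentration.
#' @param total integer vector, embryos per concentration (all >= 1).
#' @param n_boot number of curves.
#' @param seed optional seed applied before drawing.
#' @return numeric matrix, `n_boot` rows by `length(affected)` columns of
#'   percent responses in \[0, 100\].
#' @export
bootstrap_curves <- function(affected, total, n_boot = 1000L, seed = NULL) {
  k <- length(affected)
  if (length(total) != k) .stopf("affected and total must have equal length")
  if (any(total < 1L)) .stopf("total must be >= 1 at every concentration")
  if (any(affected < 0L | affected > total)) {
    .stopf("affected must lie in [0, total] at every concentration")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- affected / total
  draws <- rbinom(n_boot * k, size = rep(total, each = n_boot),
                  prob = rep(p, each = n_boot))
  matrix(100 * draws / rep(total, each = n_boot), nrow = n_boot, ncol = k)
}

#' Monotonic noise filter for one response curve
#'
#' A benchmark-response-thresholded monotonization: the percent responses
#' (aligned to increasing concentrations) are projected onto the nearest
#' non-decreasing curve by weighted isotonic regression (weights default to
#' the number of embryos per concentration), then filtered values below the
#' BMR threshold are floored to zero. A curve whose filtered maximum stays
#' below the BMR is classified as baseline noise. Idempotent.
#'
#' @param response_pct numeric vector of percent responses in \[0, 100\].
#' @param bmr benchmark response threshold in percent (0 < bmr < 100).
#' @param weights optional positive weights (e.g. embryos per
#'   concentration); equal weights by default.
#' @return list with `response_filtered_pct` (non-decreasing vector) and
#'   `is_noise` (logical).
#' @export
monotone_filter <- function(response_pct, bmr, weights = NULL) {
  .check_bmr(bmr)
  if (any(response_pct < 0 | response_pct > 100)) {
    .stopf("responses must lie in [0, 100]")
  }
  if (is.null(weights)) weights <- rep(1, length(response_pct))
  if (length(weights) != length(response_pct) || any(weights <= 0)) {
    .stopf("weights must be positive and aligned to responses")
  }
  fit <- .pava(as.numeric(response_pct), as.numeric(weights))
  fit[fit < bmr] <- 0
  list(response_filtered_pct = fit, is_noise = max(fit) < bmr)
}

#' Interpolate the benchmark concentration from a filtered curve
#'
#' The BMC is the concentration at which the filtered (non-decreasing)
#' curve first reaches the BMR, linearly interpolated in log10
#' concentration between the bracketing tested concentrations. If the
#' response at the lowest tested concentration already reaches the BMR the
#' BMC is the lowest concentration and the result is flagged (the
#' substance would need retesting at lower concentrations).
#'
#' @param filtered non-decreasing filtered percent responses (see
#'   [monotone_filter()]).
#' @param concs_uM strictly increasing positive concentrations.
#' @param bmr benchmark response in percent.
#' @return list with `bmc_uM` and `at_lowest_conc`.
#' @export
bmc_interpolate <- function(filtered, concs_uM, bmr) {
  .check_bmr(bmr)
  k <- length(filtered)
  if (length(concs_uM) != k) .stopf("filtered and concs_uM must align")
  if (any(concs_uM <= 0) || any(diff(concs_uM) <= 0)) {
    .stopf("concs_uM must be strictly increasing and positive")
  }
  if (max(filtered) < bmr) {
    .stopf("cannot interpolate a BMC from a noise curve (maximum below BMR)")
  }
  if (filtered[1L] >= bmr) {
    return(list(bmc_uM = concs_uM[1L], at_lowest_conc = TRUE))
  }
  i <- which(filtered >= bmr)[1L]
  lo <- log10(concs_uM[i - 1L]); hi <- log10(concs_uM[i])
  frac <- (bmr - filtered[i - 1L]) / (filtered[i] - filtered[i - 1L])
  list(bmc_uM = 10^(lo + frac * (hi - lo)), at_lowest_conc = FALSE)
}

#' Analyse one plate's concentration-response series
#'
#' The full per-plate procedure: `n_boot` bootstrap curves are simulated
#' from the observed incidences, each is noise-filtered, and the activity
#' fraction `f` is the share of curves that are not pure baseline noise.
#' If `f > 0.5` the effect is called active. Every bootstrap curve yields a
#' BMC (noise curves contribute the highest tested concentration as a
#' sentinel); the reported BMC is the median of those values and the
#' confidence interval their quantiles. Inactive results carry the
#' sentinel BMC together with an explicit inactive flag.
#'
#' @param concs_uM strictly increasing positive concentrations.
#' @param affected,total incidence counts aligned to `concs_uM`.
#' @param bmr benchmark response in percent.
#' @param config a [bootstrap_config()].
#' @param seed optional seed overriding `config$seed` (used by
#'   [bmc_analyze()] for per-plate derived seeds).
#' @return one-row data.frame: `f_active`, `call` ("active"/"inactive"),
#'   `bmc_uM`, `ci_low_uM`, `ci_high_uM`, `at_lowest_conc`, `max_conc_uM`.
#' @export
analyze_curveset <- function(concs_uM, affected, total, bmr,
                             config = bootstrap_config(), seed = NULL) {
  .check_bmr(bmr)
  ord <- order(concs_uM)
  concs_uM <- concs_uM[ord]; affected <- affected[ord]; total <- total[ord]
  if (any(concs_uM <= 0) || any(diff(concs_uM) <= 0)) {
    .stopf("concs_uM must be strictly increasing and positive")
  }
  if (is.null(seed)) seed <- config$seed
  curves <- bootstrap_curves(affected, total, n_boot = config$n_boot, seed = seed)
  w <- as.numeric(total)
  log_concs <- log10(concs_uM)
  k <- length(concs_uM)
  n_boot <- config$n_boot
  bmcs <- numeric(n_boot)
  noise <- logical(n_boot)
  for (b in seq_len(n_boot)) {
    fit <- .pava(curves[b, ], w)
    if (fit[k] < bmr) {                       # pure baseline noise
      noise[b] <- TRUE
      bmcs[b] <- concs_uM[k]                  # sentinel: highest tested conc
    } else if (fit[1L] >= bmr) {
      bmcs[b] <- concs_uM[1L]
    } else {
      fit[fit < bmr] <- 0
      i <- which(fit >= bmr)[1L]
      frac <- (bmr - fit[i - 1L]) / (fit[i] - fit[i - 1L])
      bmcs[b] <- 10^(log_concs[i - 1L] + frac * (log_concs[i] - log_concs[i - 1L]))
    }
  }
  f_active <- mean(!noise)
  call <- if (f_active > 0.5) "active" else "inactive"
  qs <- quantile(bmcs, probs = c(0.5, config$ci_levels), names = FALSE,
                 type = 7)
  bmc_med <- qs[1L]
  at_lowest <- call == "active" && bmc_med <= concs_uM[1L] * (1 + 1e-12)
  data.frame(f_active = f_active, call = call,
             bmc_uM = if (call == "active") bmc_med else concs_uM[k],
             ci_low_uM = qs[2L], ci_high_uM = qs[3L],
             at_lowest_conc = at_lowest, max_conc_uM = concs_uM[k],
             stringsAsFactors = FALSE)
}

#' Analyse every plate series in an endpoint table
#'
#' Applies [analyze_curveset()] to each (lab, plate, substance, endpoint)
#' group of a [derive_endpoint()] table. Each group gets its own bootstrap
#' seed derived from the root seed and the group key, so the result is
#' invariant to plate order.
#'
#' @param endpoint_table output of [derive_endpoint()] (or
#'   [pool_positive_weekly()] with `plate_id` absent, in which case
#'   `week_id` keys the groups).
#' @param bmr a single benchmark response in percent, or a named vector
#'   keyed by endpoint.
#' @param config a [bootstrap_config()].
#' @param quiet suppress the one-line-per-plate progress log.
#' @return data.frame: group keys plus the [analyze_curveset()] columns.
#' @export
bmc_analyze <- function(endpoint_table, bmr = 10, config = bootstrap_config(),
                        quiet = TRUE) {
  tb <- endpoint_table
  if (!"plate_id" %in% names(tb)) tb$plate_id <- tb$week_id
  if (!"week_id" %in% names(tb)) tb$week_id <- ""
  if (!"substance_id" %in% names(tb)) tb$substance_id <- "positive_control"
  key <- paste(tb$lab_id, tb$plate_id, tb$substance_id, tb$endpoint, sep = "\r")
  groups <- split(seq_len(nrow(tb)), key)
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    g <- tb[idx, ]
    g <- g[order(g$conc_uM), ]
    ep <- g$endpoint[1L]
    bmr_ep <- if (length(bmr) > 1L || !is.null(names(bmr))) {
      if (!ep %in% names(bmr)) .stopf("no BMR supplied for endpoint '%s'", ep)
      unname(bmr[[ep]])
    } else bmr
    seed_g <- .derive_seed(config$seed,
                           paste(g$lab_id[1L], g$plate_id[1L],
                                 g$substance_id[1L], ep, sep = "\r"))
    res <- analyze_curveset(g$conc_uM, g$affected, g$total, bmr_ep,
                            config = config, seed = seed_g)
    res <- cbind(g[1L, c("lab_id", "plate_id", "week_id", "substance_id",
                         "endpoint")], res, row.names = NULL)
    if (!quiet) {
      message(sprintf("%s/%s %s [%s]: f=%.3f %s BMC=%.4g",
                      res$lab_id, res$plate_id, res$substance_id, ep,
                      res$f_active, res$call, res$bmc_uM))
    }
    out[[gi]] <- res
  }
  res <- do.call(rbind, out)
  res <- res[order(res$lab_id, res$substance_id, res$endpoint, res$plate_id), ]
  rownames(res) <- NULL
  res
}

#' Estimate an endpoint-specific benchmark response threshold
#'
#' Scans a grid of candidate BMR thresholds and, for each, pools the
#' variance of the log10 bootstrap BMC values across all series active at
#' that threshold. The selected BMR is the lowest candidate whose pooled
#' variance is within a relative tolerance of the next candidate's (the
#' stabilization elbow): the lowest threshold that already achieves the
#' potency precision the data's intrinsic variance allows.
#'
#' @param endpoint_table a [derive_endpoint()] table (one endpoint).
#' @param config a [bootstrap_config()].
#' @param grid candidate thresholds in percent (default 5 to 50 by 5).
#' @param tol relative variance-decrease tolerance (default 0.05).
#' @return list of class `bmr_estimate`: `threshold_pct`, `endpoint`, and
#'   the per-candidate `profile` (threshold, pooled variance, number of
#'   active series).
#' @export
estimate_bmr <- function(endpoint_table, config = bootstrap_config(),
                         grid = seq(5, 50, by = 5), tol = 0.05) {
  tb <- endpoint_table
  ep <- unique(tb$endpoint)
  if (length(ep) != 1L) .stopf("estimate_bmr expects a single-endpoint table")
  key <- paste(tb$lab_id, tb$plate_id, tb$substance_id, sep = "\r")
  groups <- split(seq_len(nrow(tb)), key)
  if (length(groups) < 10L) {
    .warnf("BMR estimation with fewer than 10 series is unreliable")
  }
  # Precompute bootstrap curves once per group; reuse across thresholds.
  prep <- lapply(names(groups), function(kname) {
    g <- tb[groups[[kname]], ]
    g <- g[order(g$conc_uM), ]
    seed_g <- .derive_seed(config$seed, paste(kname, ep, sep = "\r"))
    list(concs = g$conc_uM, log_concs = log10(g$conc_uM),
         w = as.numeric(g$total),
         curves = bootstrap_curves(g$affected, g$total,
                                   n_boot = config$n_boot, seed = seed_g))
  })
  profile <- data.frame(threshold_pct = grid, pooled_var = NA_real_,
                        n_active = 0L)
  for (ti in seq_along(grid)) {
    thr <- grid[ti]
    ss <- 0; df <- 0; n_active <- 0L
    for (pr in prep) {
      k <- length(pr$concs)
      nb <- nrow(pr$curves)
      bmcs <- numeric(nb); noise <- logical(nb)
      for (b in seq_len(nb)) {
        fit <- .pava(pr$curves[b, ], pr$w)
        if (fit[k] < thr) { noise[b] <- TRUE; bmcs[b] <- pr$concs[k]; next }
        fit[fit < thr] <- 0
        if (fit[1L] >= thr) { bmcs[b] <- pr$concs[1L]; next }
        i <- which(fit >= thr)[1L]
        frac <- (thr - fit[i - 1L]) / (fit[i] - fit[i - 1L])
        bmcs[b] <- 10^(pr$log_concs[i - 1L] +
                         frac * (pr$log_concs[i] - pr$log_concs[i - 1L]))
      }
      if (mean(!noise) > 0.5) {
        n_active <- n_active + 1L
        lb <- log10(bmcs[!noise])
        if (length(lb) >= 2L) {
          ss <- ss + (length(lb) - 1L) * var(lb)
          df <- df + (length(lb) - 1L)
        }
      }
    }
    profile$pooled_var[ti] <- if (df > 0) ss / df else 0
    profile$n_active[ti] <- n_active
  }
  chosen <- NA_real_
  for (ti in seq_len(length(grid) - 1L)) {
    if (profile$n_active[ti] == 0L) next     # no potency estimate at all
    v <- profile$pooled_var[ti]; vn <- profile$pooled_var[ti + 1L]
    rel_dec <- if (v > 0) max(0, (v - vn) / v) else 0
    if (rel_dec < tol) { chosen <- grid[ti]; break }
  }
  if (is.na(chosen)) {
    .warnf("no threshold stabilized the pooled BMC variance; returning the highest grid value")
    chosen <- grid[length(grid)]
  }
  structure(list(threshold_pct = chosen, endpoint = ep, profile = profile),
            class = "bmr_estimate")
}

#' @export
print.bmr_estimate <- function(x, ...) {
  cat(sprintf("BMR estimate for %s: %.1f%%\n", x$endpoint, x$threshold_pct))
  print(x$profile)
  invisible(x)
}
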