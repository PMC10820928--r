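# Interlaboratory aggregation: substance x lab medians, activity-call
# concordance, duplicate reproducibility, potency ranking, and the
# supporting statistical tests on log10 BMC values.

#' Summarize plate-level BMCs per substance, lab and endpoint
#'
#' The substance-level potency is the median over the plate BMCs, with
#' inactive plates contributing their sentinel (the highest tested
#' concentration). A substance is called inactive at a lab when the
#' majority of its plates are inactive (so the median falls on the
#' sentinel); the at-lowest-concentration flag propagates if any plate
#' crossed at the lowest tested concentration.
#'
#' @param results data.frame of plate-level results with columns
#'   `substance_id`, `lab_id`, `endpoint`, `bmc_uM`, `call` (or logical
#'   `inactive`), `at_lowest_conc`, `max_conc_uM` — the shape produced by
#'   [bmc_analyze()].
#' @return data.frame with one row per (substance, lab, endpoint):
#'   `n_plates`, `median_bmc_uM`, `inactive`, `at_lowest_conc`,
#'   `max_conc_uM`.
#' @export
summarize_substance <- function(results) {
  if (!"inactive" %in% names(results)) {
    results$inactive <- results$call == "inactive"
  }
  groups <- split(results,
                  paste(results$substance_id, results$lab_id,
                        results$endpoint, sep = "\r"))
  out <- do.call(rbind, lapply(groups, function(g) {
    n <- nrow(g)
    data.frame(substance_id = g$substance_id[1L], lab_id = g$lab_id[1L],
               endpoint = g$endpoint[1L], n_plates = n,
               median_bmc_uM = median(g$bmc_uM),
               inactive = sum(g$inactive) > n / 2,
               at_lowest_conc = any(g$at_lowest_conc),
               max_conc_uM = max(g$max_conc_uM),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out <- out[order(out$substance_id, out$endpoint, out$lab_id), ]
  rownames(out) <- NULL
  out
}

#' Render a substance x lab summary in report form
#'
#' Formats median BMCs as printed in screening reports: active cells show
#' the median (with a `*` when the effect was already present at the
#' lowest tested concentration), inactive cells render as
#' `"Inactive (<max conc>)"`.
#'
#' @param summary output of [summarize_substance()] for one endpoint.
#' @return data.frame with one row per substance and one column per lab.
#' @export
render_summary_table <- function(summary) {
  stopifnot(length(unique(summary$endpoint)) == 1L)
  cell <- ifelse(summary$inactive,
                 sprintf("Inactive (%g)", summary$max_conc_uM),
                 paste0(signif(summary$median_bmc_uM, 3),
                        ifelse(summary$at_lowest_conc, " *", "")))
  wide <- reshape(
    data.frame(substance_id = summary$substance_id, lab_id = summary$lab_id,
               cell = cell, stringsAsFactors = FALSE),
    idvar = "substance_id", timevar = "lab_id", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  rownames(wide) <- NULL
  wide[order(wide$substance_id), ]
}

#' Activity-call concordance across laboratories
#'
#' Counts, for one endpoint, how the per-lab activity calls agree across
#' substances: inactive everywhere, active everywhere, active in at least
#' one lab, and the total with the same call in every lab. Also attributes
#' to each lab the number of substances (among those active in >= 1 lab)
#' whose minimum summary BMC occurs at that lab; inactive cells enter the
#' minimum at their sentinel concentration.
#'
#' @param summary output of [summarize_substance()] for one endpoint.
#' @param labs labs required to be present for every substance (default:
#'   all labs in the summary).
#' @return list: `n_substances`, `n_inactive_all`, `n_active_all`,
#'   `n_active_any`, `n_same_call`, and `lowest_bmc_lab` (named counts).
#' @export
concordance_counts <- function(summary, labs = sort(unique(summary$lab_id))) {
  stopifnot(length(unique(summary$endpoint)) == 1L)
  summary <- summary[summary$lab_id %in% labs, ]
  bysub <- split(summary, summary$substance_id)
  missing <- names(bysub)[vapply(bysub, function(g)
    !all(labs %in% g$lab_id), logical(1))]
  if (length(missing) > 0L) {
    .stopf("substance(s) missing a lab: %s", paste(missing, collapse = ", "))
  }
  active_mat <- t(vapply(bysub, function(g)
    !g$inactive[match(labs, g$lab_id)], logical(length(labs))))
  n_active <- rowSums(active_mat)
  n_inactive_all <- sum(n_active == 0L)
  n_active_all <- sum(n_active == length(labs))
  n_active_any <- sum(n_active >= 1L)
  lowest <- vapply(bysub[n_active >= 1L], function(g) {
    labs[which.min(g$median_bmc_uM[match(labs, g$lab_id)])]
  }, character(1))
  lowest_counts <- setNames(integer(length(labs)), labs)
  tl <- table(lowest)
  lowest_counts[names(tl)] <- as.integer(tl)
  list(n_substances = length(bysub),
       n_inactive_all = n_inactive_all,
       n_active_all = n_active_all,
       n_active_any = n_active_any,
       n_same_call = n_inactive_all + n_active_all,
       lowest_bmc_lab = lowest_counts)
}

#' Potency ranking across laboratories
#'
#' Restricted to substances active in every lab, ranks the substances
#' within each lab by ascending median BMC and reports the mean and
#' standard deviation of each substance's ranks across labs.
#'
#' @param summary output of [summarize_substance()] for one endpoint.
#' @param tie_method how tied BMCs share ranks: `"average"` (default),
#'   `"min"`, `"max"`, or `"ordinal"` (first occurrence wins).
#' @return data.frame: `substance_id`, one `rank_<lab>` column per lab,
#'   `mean_rank`, `sd_rank`, sorted by mean rank.
#' @export
potency_ranks <- function(summary,
                          tie_method = c("average", "min", "max", "ordinal")) {
  tie_method <- match.arg(tie_method)
  stopifnot(length(unique(summary$endpoint)) == 1L)
  labs <- sort(unique(summary$lab_id))
  if (length(labs) < 2L) .stopf("potency ranking needs at least two labs")
  bysub <- split(summary, summary$substance_id)
  all_active <- vapply(bysub, function(g)
    all(labs %in% g$lab_id) && !any(g$inactive), logical(1))
  bysub <- bysub[all_active]
  if (length(bysub) == 0L) .stopf("no substance is active in every lab")
  bmc <- t(vapply(bysub, function(g)
    g$median_bmc_uM[match(labs, g$lab_id)], numeric(length(labs))))
  ties <- if (tie_method == "ordinal") "first" else tie_method
  ranks <- apply(bmc, 2, rank, ties.method = ties)
  out <- data.frame(substance_id = names(bysub), stringsAsFactors = FALSE)
  for (j in seq_along(labs)) out[[paste0("rank_", labs[j])]] <- ranks[, j]
  out$mean_rank <- rowMeans(ranks)
  out$sd_rank <- apply(ranks, 1, sd)
  out <- out[order(out$mean_rank, out$substance_id), ]
  rownames(out) <- NULL
  out
}

#' Welch's t-test on log10 BMC values
#'
#' Two-sample Welch test on the log10-transformed BMCs of two groups.
#' When both groups are constant and separated, the degenerate-variance
#' path reports p = 0 with a warning; identical constant groups give p = 1.
#'
#' @param group_a,group_b positive BMC vectors (each length >= 2).
#' @param adjust_m Bonferroni family size applied to the raw p-value.
#' @return one-row data.frame: `test`, `n_a`, `n_b`, `statistic`, `df`,
#'   `p_raw`, `p_adjusted`, `adjust_method`.
#' @export
welch_log_t <- function(group_a, group_b, adjust_m = 1L) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    .stopf("Welch's t-test needs at least two values per group")
  }
  if (any(c(group_a, group_b) <= 0)) .stopf("BMC values must be positive")
  a <- log10(group_a); b <- log10(group_b)
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      stat <- 0; dfree <- NA_real_; p <- 1
    } else {
      .warnf("both groups constant but separated; reporting p = 0")
      stat <- Inf; dfree <- NA_real_; p <- 0
    }
  } else {
    tt <- t.test(a, b, var.equal = FALSE)
    stat <- unname(tt$statistic); dfree <- unname(tt$parameter)
    p <- tt$p.value
  }
  data.frame(test = "welch_t", n_a = length(group_a), n_b = length(group_b),
             statistic = stat, df = dfree, p_raw = p,
             p_adjusted = min(1, adjust_m * p),
             adjust_method = "bonferroni", stringsAsFactors = FALSE)
}

#' Pairwise Wilcoxon rank-sum tests on log10 BMC values
#'
#' Run only when every group has at least `min_n` observations; smaller
#' families are flagged not-run (the test has no power there).
#'
#' @param groups named list of positive BMC vectors.
#' @param min_n minimum group size (default 6).
#' @return data.frame with one row per pair: `group_a`, `group_b`, `run`,
#'   `statistic`, `p_raw`, `p_adjusted` (Bonferroni across the family).
#' @export
wilcoxon_pairwise <- function(groups, min_n = 6L) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  nm <- names(groups)
  pairs <- utils::combn(nm, 2L)
  m <- ncol(pairs)
  run <- all(lengths(groups) >= min_n)
  rows <- lapply(seq_len(m), function(i) {
    ga <- pairs[1L, i]; gb <- pairs[2L, i]
    if (!run) {
      return(data.frame(test = "wilcoxon", group_a = ga, group_b = gb,
                        run = FALSE, statistic = NA_real_, p_raw = NA_real_,
                        p_adjusted = NA_real_, adjust_method = "bonferroni",
                        stringsAsFactors = FALSE))
    }
    wt <- suppressWarnings(wilcox.test(log10(groups[[ga]]), log10(groups[[gb]])))
    data.frame(test = "wilcoxon", group_a = ga, group_b = gb, run = TRUE,
               statistic = unname(wt$statistic), p_raw = wt$p.value,
               p_adjusted = min(1, m * wt$p.value),
               adjust_method = "bonferroni", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Shapiro-Wilk normality check of log10 BMC values
#'
#' @param group positive BMC vector (3 to 5000 values).
#' @return one-row data.frame with `statistic` and `p_raw`.
#' @export
shapiro_log <- function(group) {
  x <- log10(group)
  if (length(unique(x)) == 1L) {
    return(data.frame(test = "shapiro", n = length(x), statistic = NA_real_,
                      p_raw = NA_real_, stringsAsFactors = FALSE))
  }
  st <- shapiro.test(x)
  data.frame(test = "shapiro", n = length(x),
             statistic = unname(st$statistic), p_raw = st$p.value,
             stringsAsFactors = FALSE)
}

#' One-way ANOVA with Tukey post hoc on log10 BMC values
#'
#' @param groups named list of positive BMC vectors.
#' @return list with `anova` (one-row data.frame: F, df, p) and `tukey`
#'   (one row per pairwise contrast: estimate, confidence bounds,
#'   adjusted p).
#' @export
anova_tukey <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  dat <- data.frame(
    y = log10(unlist(groups, use.names = FALSE)),
    g = factor(rep(names(groups), lengths(groups))))
  fit <- aov(y ~ g, data = dat)
  an <- summary(fit)[[1L]]
  tk <- TukeyHSD(fit)$g
  list(
    anova = data.frame(test = "anova", statistic = an[["F value"]][1L],
                       df1 = an[["Df"]][1L], df2 = an[["Df"]][2L],
                       p_raw = an[["Pr(>F)"]][1L], stringsAsFactors = FALSE),
    tukey = data.frame(test = "tukey", contrast = rownames(tk),
                       estimate = tk[, "diff"], ci_low = tk[, "lwr"],
                       ci_high = tk[, "upr"], p_adjusted = tk[, "p adj"],
                       adjust_method = "tukey", stringsAsFactors = FALSE,
                       row.names = NULL))
}

# Trimmed mean and winsorized variance helpers.
.trim_mean <- function(x, trim) mean(x, trim = trim)
.win_var <- function(x, trim) {
  n <- length(x)
  g <- floor(trim * n)
  xs <- sort(x)
  xs[seq_len(g)] <- xs[g + 1L]
  if (g > 0L) xs[(n - g + 1L):n] <- xs[n - g]
  var(xs)
}

#' One-way trimmed-means test with pairwise contrasts
#'
#' Heteroscedastic one-way comparison of trimmed group means (Welch-type F
#' statistic with winsorized variances), a robust alternative to the
#' ordinary ANOVA, followed by pairwise Yuen-style linear contrasts with
#' Bonferroni adjustment.
#'
#' @param groups named list of positive BMC vectors (log10-transformed
#'   internally).
#' @param trim trimming proportion per tail (default 0.2).
#' @return list with `omnibus` (one-row data.frame: F, df1, df2, p) and
#'   `contrasts` (one row per pair).
#' @export
trimmed_means_contrast <- function(groups, trim = 0.2) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  lg <- lapply(groups, log10)
  k <- length(lg)
  n <- lengths(lg)
  h <- n - 2 * floor(trim * n)
  if (any(h < 2L)) .stopf("groups too small after trimming")
  tm <- vapply(lg, .trim_mean, numeric(1), trim = trim)
  wv <- vapply(lg, .win_var, numeric(1), trim = trim)
  d <- (n - 1) * wv / (h * (h - 1))
  wgt <- 1 / d
  U <- sum(wgt)
  xt <- sum(wgt * tm) / U
  A <- sum(wgt * (tm - xt)^2) / (k - 1)
  B <- 2 * (k - 2) / (k^2 - 1) * sum((1 - wgt / U)^2 / (h - 1))
  Fstat <- A / (B + 1)
  df1 <- k - 1
  df2 <- 1 / (3 / (k^2 - 1) * sum((1 - wgt / U)^2 / (h - 1)))
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  pairs <- utils::combn(names(lg), 2L)
  m <- ncol(pairs)
  contrasts <- do.call(rbind, lapply(seq_len(m), function(i) {
    ga <- pairs[1L, i]; gb <- pairs[2L, i]
    se <- sqrt(d[[ga]] + d[[gb]])
    tstat <- (tm[[ga]] - tm[[gb]]) / se
    dfy <- (d[[ga]] + d[[gb]])^2 /
      (d[[ga]]^2 / (h[[ga]] - 1) + d[[gb]]^2 / (h[[gb]] - 1))
    praw <- 2 * pt(-abs(tstat), dfy)
    data.frame(test = "trimmed_means_contrast", group_a = ga, group_b = gb,
               statistic = tstat, df = dfy, p_raw = praw,
               p_adjusted = min(1, m * praw), adjust_method = "bonferroni",
               stringsAsFactors = FALSE)
  }))
  list(omnibus = data.frame(test = "trimmed_means", statistic = Fstat,
                            df1 = df1, df2 = df2, p_raw = p,
                            stringsAsFactors = FALSE),
       contrasts = contrasts)
}

#' Fold difference in potency between two BMC groups
#'
#' Ratio of geometric means `gm(group_a) / gm(group_b)`; in paired mode the
#' geometric mean of the per-pair ratios. A value above 1 means group B is
#' the more potent (lower-BMC) group.
#'
#' @param group_a,group_b positive BMC vectors.
#' @param paired logical; groups must align element-wise when TRUE.
#' @return numeric fold ratio.
#' @export
fold_potency <- function(group_a, group_b, paired = FALSE) {
  if (any(c(group_a, group_b) <= 0)) .stopf("BMC values must be positive")
  if (paired) {
    if (length(group_a) != length(group_b)) {
      .stopf("paired groups must have equal length")
    }
    return(.geomean(group_a / group_b))
  }
  .geomean(group_a) / .geomean(group_b)
}

#' Duplicate-substance reproducibility report
#'
#' For each blinded duplicate pair, per lab and endpoint: the plate BMCs
#' of both duplicates side by side, a within-lab Welch t-test on log10
#' BMCs between the duplicates, and cross-lab Welch t-tests per duplicate.
#' Inactive plates enter all tests at their sentinel concentration.
#'
#' @param results plate-level results with columns `substance_id`,
#'   `duplicate` (1 or 2), `lab_id`, `endpoint`, `bmc_uM` (sentinel for
#'   inactive plates), e.g. the bundled duplicate reference via
#'   [reference_duplicate_bmc()], or [bmc_analyze()] output augmented
#'   with a `duplicate` column.
#' @return list with `plate_table` (input, ordered), `within_lab`
#'   (duplicate#1 vs duplicate#2 per substance x lab x endpoint) and
#'   `between_lab` (lab pair tests per substance x duplicate x endpoint,
#'   Bonferroni-adjusted within each substance x endpoint family).
#' @export
duplicate_report <- function(results) {
  need <- c("substance_id", "duplicate", "lab_id", "endpoint", "bmc_uM")
  missing_cols <- setdiff(need, names(results))
  if (length(missing_cols) > 0L) {
    .stopf("duplicate_report input missing column(s): %s",
           paste(missing_cols, collapse = ", "))
  }
  dups <- sort(unique(results$duplicate))
  if (length(dups) != 2L) .stopf("expected exactly two duplicates per substance")
  within <- list(); between <- list()
  for (sub in unique(results$substance_id)) {
    for (ep in unique(results$endpoint)) {
      g <- results[results$substance_id == sub & results$endpoint == ep, ]
      if (nrow(g) == 0L) next
      labs <- sort(unique(g$lab_id))
      # within-lab: duplicate 1 vs duplicate 2
      for (lab in labs) {
        a <- g$bmc_uM[g$lab_id == lab & g$duplicate == dups[1L]]
        b <- g$bmc_uM[g$lab_id == lab & g$duplicate == dups[2L]]
        if (length(a) < 2L || length(b) < 2L) {
          .stopf("unmatched duplicate pair for %s at %s", sub, lab)
        }
        row <- welch_log_t(a, b)
        row <- cbind(data.frame(substance_id = sub, endpoint = ep,
                                lab_id = lab, comparison = "duplicate1_vs_duplicate2",
                                stringsAsFactors = FALSE), row)
        within[[length(within) + 1L]] <- row
      }
      # between-lab per duplicate, Bonferroni over the lab-pair family
      if (length(labs) >= 2L) {
        pairs <- utils::combn(labs, 2L)
        m <- ncol(pairs)
        for (dp in dups) {
          for (i in seq_len(m)) {
            a <- g$bmc_uM[g$lab_id == pairs[1L, i] & g$duplicate == dp]
            b <- g$bmc_uM[g$lab_id == pairs[2L, i] & g$duplicate == dp]
            row <- welch_log_t(a, b, adjust_m = m)
            row <- cbind(data.frame(substance_id = sub, endpoint = ep,
                                    lab_id = paste(pairs[, i], collapse = "/"),
                                    comparison = paste0("duplicate", dp, "_between_labs"),
                                    stringsAsFactors = FALSE), row)
            between[[length(between) + 1L]] <- row
          }
        }
      }
    }
  }
  ord <- order(results$substance_id, results$endpoint, results$lab_id,
               results$duplicate)
  list(plate_table = results[ord, ],
       within_lab = do.call(rbind, within),
       between_lab = do.call(rbind, between))
}

#' Bundled interlaboratory reference: substance x lab median BMCs
#'
#' Published summary from a three-laboratory zebrafish embryo
#' dose-range-finding screen: median plate BMCs for the composite
#' malformed-or-dead endpoint at 120 hpf, for 39 test substances across
#' three labs, with inactive sentinels and at-lowest-concentration flags.
#' Used as the reference input for concordance, ranking and aggregation
#' checks.
#'
#' @return data.frame with columns `substance_id`, `casrn`, `lab_id`,
#'   `endpoint`, `median_bmc_uM`, `inactive`, `at_lowest_conc`,
#'   `max_conc_uM`.
#' @export
reference_median_bmc <- function() {
  path <- system.file("extdata", "interlab_median_bmc.csv",
                      package = "bmcscreen", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Bundled interlaboratory reference: duplicate-substance plate BMCs
#'
#' Plate-level BMCs for the three blinded duplicate substances (aldicarb,
#' bisphenol A, valproic acid) from the same screen: two duplicates x
#' three labs x two endpoints x three plates each. Inactive plates carry
#' the sentinel BMC of 100 (the highest tested concentration).
#'
#' @return data.frame with columns `substance_id`, `duplicate`, `lab_id`,
#'   `endpoint`, `plate`, `bmc_uM`, `inactive`, `at_lowest_conc`,
#'   `max_conc_uM`.
#' @export
reference_duplicate_bmc <- function() {
  path <- system.file("extdata", "interlab_duplicate_bmc.csv",
                      package = "bmcscreen", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
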