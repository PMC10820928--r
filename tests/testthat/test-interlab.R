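test_that("substance summaries take plate medians with sentinel handling", {
  # six plate BMCs pooled across the two blinded duplicates
  plates <- data.frame(
    substance_id = "Aldicarb", lab_id = "LabA",
    endpoint = "MalformedAny+Mort@120",
    bmc_uM = c(1.39, 0.53, 1.44, 0.81, 0.81, 0.58),
    call = "active", at_lowest_conc = FALSE, max_conc_uM = 100,
    stringsAsFactors = FALSE)
  s <- summarize_substance(plates)
  expect_equal(s$median_bmc_uM, 0.81)
  expect_false(s$inactive)
  expect_equal(s$n_plates, 6L)

  # all plates inactive: sentinel median, inactive flag, rendered form
  inert <- data.frame(substance_id = "X", lab_id = "L", endpoint = "E",
                      bmc_uM = 100, call = "inactive",
                      at_lowest_conc = FALSE, max_conc_uM = 100)[rep(1, 3), ]
  si <- summarize_substance(inert)
  expect_equal(si$median_bmc_uM, 100)
  expect_true(si$inactive)
  expect_equal(render_summary_table(si)$L, "Inactive (100)")

  # a 3-3 split is not a majority: the substance stays active
  split33 <- data.frame(substance_id = "Y", lab_id = "L", endpoint = "E",
                        bmc_uM = c(46.65, 58.17, 58.17, 100, 100, 100),
                        call = rep(c("active", "inactive"), each = 3),
                        at_lowest_conc = FALSE, max_conc_uM = 100)
  sy <- summarize_substance(split33)
  expect_false(sy$inactive)
  expect_equal(sy$median_bmc_uM, (58.17 + 100) / 2)

  # single plate: median equals that plate's BMC
  one <- summarize_substance(plates[1L, ])
  expect_equal(one$median_bmc_uM, 1.39)
})

test_that("concordance counting is consistent and requires full coverage", {
  s <- data.frame(
    substance_id = rep(c("A", "B", "C"), each = 2),
    lab_id = rep(c("L1", "L2"), 3), endpoint = "E",
    n_plates = 3L,
    median_bmc_uM = c(1, 2, 100, 100, 3, 100),
    inactive = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE),
    at_lowest_conc = FALSE, max_conc_uM = 100)
  cc <- concordance_counts(s)
  expect_equal(cc$n_inactive_all, 1L)
  expect_equal(cc$n_active_all, 1L)
  expect_equal(cc$n_active_any, 2L)
  expect_equal(cc$n_same_call, cc$n_inactive_all + cc$n_active_all)
  expect_equal(unname(cc$lowest_bmc_lab["L1"]), 2L)
  expect_error(concordance_counts(s[-1L, ]), "missing a lab")

  # identical labs agree on every substance
  s2 <- s; s2$median_bmc_uM <- rep(c(1, 100, 3), each = 2)
  s2$inactive <- rep(c(FALSE, TRUE, FALSE), each = 2)
  expect_equal(concordance_counts(s2)$n_same_call, 3L)
})

test_that("potency ranks are shared permutations with tie handling", {
  s <- data.frame(
    substance_id = rep(c("A", "B", "C"), each = 3),
    lab_id = rep(c("L1", "L2", "L3"), 3), endpoint = "E", n_plates = 3L,
    median_bmc_uM = c(1, 2, 3, 10, 20, 30, 100 - 1e-9, 200, 300),
    inactive = FALSE, at_lowest_conc = FALSE, max_conc_uM = 1000)
  rk <- potency_ranks(s)
  expect_equal(rk$sd_rank, rep(0, 3))          # same order in every lab
  expect_equal(rk$mean_rank, 1:3)
  # rank sums are K(K+1)/2 per lab under average ties
  expect_equal(sum(rk$rank_L1), 3 * 4 / 2)

  # a within-lab tie shares rank 1.5 under the average method
  s$median_bmc_uM[s$substance_id == "B" & s$lab_id == "L1"] <- 1
  rk2 <- potency_ranks(s)
  expect_equal(sort(rk2$rank_L1[rk2$substance_id %in% c("A", "B")]),
               c(1.5, 1.5))
  expect_equal(sum(rk2$rank_L1), 3 * 4 / 2)
  expect_error(potency_ranks(s[s$lab_id == "L1", ]), "two labs")
})

test_that("Welch tests on log BMCs handle identical and degenerate groups", {
  ident <- welch_log_t(c(1, 2, 4), c(1, 2, 4))
  expect_equal(ident$p_raw, 1, tolerance = 1e-12)
  expect_warning(sep <- welch_log_t(c(1, 1, 1), c(10, 10, 10)), "separated")
  expect_equal(sep$p_raw, 0)
  const <- welch_log_t(c(5, 5, 5), c(5, 5))
  expect_equal(const$p_raw, 1)
  expect_error(welch_log_t(1, c(1, 2)), "two values")
  expect_error(welch_log_t(c(-1, 2, 3), c(1, 2, 3)), "positive")
  # Bonferroni adjustment is min(1, m * p)
  tt <- welch_log_t(c(1, 2, 3), c(1.1, 2.2, 3.3), adjust_m = 3L)
  expect_equal(tt$p_adjusted, min(1, 3 * tt$p_raw))
})

test_that("Wilcoxon comparisons are flagged not-run below the size floor", {
  small <- list(a = c(1, 2, 3), b = c(4, 5, 6))
  out <- wilcoxon_pairwise(small)
  expect_false(any(out$run))
  expect_true(all(is.na(out$p_raw)))

  set.seed(77)
  big <- list(a = exp(rnorm(8)), b = exp(rnorm(8) + 2), c = exp(rnorm(8)))
  out2 <- wilcoxon_pairwise(big)
  expect_true(all(out2$run))
  expect_equal(out2$p_adjusted, pmin(1, 3 * out2$p_raw))
})

test_that("the trimmed-means test reduces to Welch's ANOVA at zero trim", {
  set.seed(21)
  groups <- list(a = exp(rnorm(12, 0, 0.3)), b = exp(rnorm(12, 0.5, 0.3)),
                 c = exp(rnorm(12, 1, 0.3)))
  tm <- trimmed_means_contrast(groups, trim = 0)
  ref <- oneway.test(y ~ g, data = data.frame(
    y = log10(unlist(groups, use.names = FALSE)),
    g = factor(rep(names(groups), lengths(groups)))), var.equal = FALSE)
  expect_equal(tm$omnibus$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(tm$omnibus$p_raw, ref$p.value, tolerance = 1e-10)
  # at zero trim the pairwise contrast is exactly Welch's t-test
  wt <- welch_log_t(groups$a, groups$b)
  ct <- tm$contrasts[tm$contrasts$group_a == "a" & tm$contrasts$group_b == "b", ]
  expect_equal(ct$statistic, wt$statistic, tolerance = 1e-10)
  expect_equal(ct$p_raw, wt$p_raw, tolerance = 1e-10)

  # with trimming, separated groups are still detected
  tm2 <- trimmed_means_contrast(groups, trim = 0.2)
  expect_lt(tm2$omnibus$p_raw, 0.01)
})

test_that("ANOVA with Tukey post hoc separates shifted groups", {
  set.seed(31)
  groups <- list(a = exp(rnorm(10, 0, 0.2)), b = exp(rnorm(10, 0, 0.2)),
                 c = exp(rnorm(10, 2, 0.2)))
  out <- anova_tukey(groups)
  expect_lt(out$anova$p_raw, 1e-6)
  tk <- out$tukey
  expect_lt(tk$p_adjusted[tk$contrast == "c-a"], 0.001)
  expect_gt(tk$p_adjusted[tk$contrast == "b-a"], 0.05)
  # normality check runs on the same groups
  sh <- shapiro_log(groups$a)
  expect_true(sh$p_raw > 0 && sh$p_raw <= 1)
})

test_that("fold potency is the ratio of geometric means", {
  expect_equal(fold_potency(c(1, 2, 4), c(1, 2, 4)), 1)
  expect_equal(fold_potency(c(2, 4, 8), c(1, 2, 4), paired = TRUE), 2)
  expect_error(fold_potency(c(0, 1), c(1, 2)), "positive")
  # recovery of a known 1.5x shift under lognormal noise
  for (rep in 1:20) {
    set.seed(100 + rep)
    b <- 10^rnorm(20, mean = 0.5, sd = 0.05)
    a <- 1.5 * b * 10^rnorm(20, 0, 0.05)
    fold <- fold_potency(a, b, paired = TRUE)
    expect_gt(fold, 1.3)
    expect_lt(fold, 1.7)
  }
})

test_that("duplicate reproducibility reporting matches the reference screen", {
  dup <- reference_duplicate_bmc()
  suppressWarnings(rep <- duplicate_report(dup))
  wl <- rep$within_lab

  # valproic acid at the lab with one active and one inactive duplicate is
  # significantly different; bisphenol A at the same lab is not
  vpa <- wl[wl$substance_id == "Valproic acid" & wl$lab_id == "LabA" &
              wl$endpoint == "MalformedAny+Mort@120", ]
  expect_lt(vpa$p_raw, 0.05)
  bpa <- wl[wl$substance_id == "Bisphenol A" & wl$lab_id == "LabA" &
              wl$endpoint == "MalformedAny+Mort@120", ]
  expect_gt(bpa$p_raw, 0.05)

  # identical duplicate plate sets: t = 0, p = 1
  same <- data.frame(substance_id = "Z", duplicate = rep(1:2, each = 3),
                     lab_id = "L", endpoint = "E", plate = rep(1:3, 2),
                     bmc_uM = rep(c(5, 6, 7), 2))
  out <- duplicate_report(same)
  expect_equal(out$within_lab$statistic, 0)
  expect_equal(out$within_lab$p_raw, 1)

  # a duplicate missing entirely at a lab is an input error
  expect_error(duplicate_report(same[same$duplicate == 1L, ]),
               "two duplicates")
})
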