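test_that("bootstrap draws respect degenerate and binomial incidences", {
  # zero incidence everywhere: every curve identically zero
  z <- bootstrap_curves(c(0, 0, 0), c(12, 12, 12), n_boot = 50L, seed = 1L)
  expect_true(all(z == 0))
  # saturated incidence: every curve identically 100
  s <- bootstrap_curves(c(12, 12, 12), c(12, 12, 12), n_boot = 50L, seed = 1L)
  expect_true(all(s == 100))
  # 6 of 12: mean ~= 50, sd ~= 100 * sqrt(0.25 / 12) = 14.43
  b <- bootstrap_curves(6L, 12L, n_boot = 10000L, seed = 2L)
  expect_equal(mean(b), 50, tolerance = 0.02)
  expect_equal(sd(b), 100 * sqrt(0.25 / 12), tolerance = 0.05)
  expect_error(bootstrap_curves(1L, 0L), "total")
  expect_error(bootstrap_curves(5L, 4L), "affected")
})

test_that("the monotone filter matches the isotonic fixed points", {
  f <- monotone_filter(c(0, 40, 20, 80), 10)
  expect_equal(f$response_filtered_pct, c(0, 30, 30, 80))
  expect_false(f$is_noise)

  # everything below threshold is noise, floored to zero
  f2 <- monotone_filter(c(5, 3, 6, 4), 10)
  expect_true(f2$is_noise)
  expect_equal(f2$response_filtered_pct, rep(0, 4))

  # a non-decreasing curve above threshold is a fixed point
  f3 <- monotone_filter(c(0, 20, 60), 10)
  expect_equal(f3$response_filtered_pct, c(0, 20, 60))
  expect_false(f3$is_noise)
})

test_that("the monotone filter is idempotent and non-decreasing", {
  set.seed(42)
  for (i in 1:200) {
    y <- round(100 * rbinom(7, 12, runif(1, 0, 0.8)) / 12, 6)
    bmr <- sample(c(5, 10, 25, 40), 1L)
    f1 <- monotone_filter(y, bmr)
    expect_true(all(diff(f1$response_filtered_pct) >= -1e-12))
    f2 <- monotone_filter(f1$response_filtered_pct, bmr)
    expect_equal(f2$response_filtered_pct, f1$response_filtered_pct)
    expect_identical(f2$is_noise, f1$is_noise)
    expect_identical(f1$is_noise, max(f1$response_filtered_pct) < bmr)
    # isotonic property: the filtered maximum never exceeds the raw maximum
    expect_lte(max(f1$response_filtered_pct), max(y) + 1e-12)
  }
})

test_that("BMC interpolation is log-linear between bracketing concentrations", {
  r <- bmc_interpolate(c(0, 0, 100), c(1, 10, 100), 10)
  expect_equal(r$bmc_uM, 10^1.1)
  expect_false(r$at_lowest_conc)

  # response already above the threshold at the lowest tested concentration
  r2 <- bmc_interpolate(c(50, 60, 70), c(1, 10, 100), 10)
  expect_equal(r2$bmc_uM, 1)
  expect_true(r2$at_lowest_conc)

  # exact crossing at a tested concentration needs no interpolation
  r3 <- bmc_interpolate(c(0, 10, 50), c(1, 10, 100), 10)
  expect_equal(r3$bmc_uM, 10)

  expect_error(bmc_interpolate(c(0, 0, 5), c(1, 10, 100), 10), "noise")
})

test_that("degenerate curvesets give trivial calls", {
  inert <- analyze_curveset(c(1, 10, 100), c(0, 0, 0), c(12, 12, 12), 10,
                            bootstrap_config(200L, seed = 1L))
  expect_equal(inert$f_active, 0)
  expect_identical(inert$call, "inactive")
  expect_equal(inert$bmc_uM, 100)  # sentinel at the highest tested conc

  sat <- analyze_curveset(c(1, 10, 100), c(12, 12, 12), c(12, 12, 12), 10,
                          bootstrap_config(200L, seed = 1L))
  expect_equal(sat$f_active, 1)
  expect_identical(sat$call, "active")
  expect_true(sat$at_lowest_conc)
})

test_that("bootstrap f and median BMC agree with exact enumeration", {
  cfg <- bootstrap_config(n_boot = 10000L, seed = 7L)
  cases <- list(
    list(affected = c(0L, 1L, 2L), total = c(2L, 2L, 2L), bmr = 25),
    list(affected = c(0L, 1L, 1L), total = c(2L, 2L, 2L), bmr = 40),
    list(affected = c(1L, 2L, 3L), total = c(3L, 3L, 3L), bmr = 30),
    list(affected = c(0L, 1L, 3L), total = c(3L, 3L, 3L), bmr = 20))
  for (cs in cases) {
    exact <- oracle_enumerate(cs$affected, cs$total, cs$bmr)
    got <- analyze_curveset(c(1, 10, 100), cs$affected, cs$total, cs$bmr, cfg)
    expect_lt(abs(got$f_active - exact$f), 0.02)
    # median BMC within one half-grid cell (one log10 unit) of the exact one
    expect_lt(abs(log10(got$bmc_uM) - log10(exact$median_bmc)), 1)
  }
})

test_that("the activity fraction is non-increasing in the BMR threshold", {
  cfg <- bootstrap_config(n_boot = 2000L, seed = 5L)
  concs <- 10^seq(-1, 2, by = 0.5)
  set.seed(8)
  for (rep in 1:5) {
    aff <- rbinom(7, 12, pmin(1, seq(0, 0.6, length.out = 7) + runif(1, 0, 0.2)))
    fs <- vapply(c(5, 10, 20, 30, 40, 50), function(bmr) {
      analyze_curveset(concs, aff, rep(12L, 7), bmr, cfg)$f_active
    }, numeric(1))
    expect_true(all(diff(fs) <= 1e-12))
  }
})

test_that("the BMC is non-decreasing in the BMR for a fixed filtered curve", {
  filt <- c(0, 0, 25, 60, 90)
  concs <- 10^(0:4)
  bmcs <- vapply(c(5, 10, 20, 25, 40, 55),
                 function(b) bmc_interpolate(filt, concs, b)$bmc_uM, numeric(1))
  expect_true(all(diff(bmcs) >= 0))
})

test_that("identical inputs and seed give bit-identical results", {
  cfg <- bootstrap_config(n_boot = 500L, seed = 123L)
  a <- analyze_curveset(c(1, 10, 100), c(1L, 4L, 10L), c(12L, 12L, 12L), 10, cfg)
  b <- analyze_curveset(c(1, 10, 100), c(1L, 4L, 10L), c(12L, 12L, 12L), 10, cfg)
  expect_identical(a, b)

  ds <- generate_study(small_study_config(seed = 9L))
  tab <- derive_endpoint(ds, "MalformedAny+Mort@120")
  r1 <- bmc_analyze(tab, bmr = 10, config = cfg)
  r2 <- bmc_analyze(tab, bmr = 10, config = cfg)
  expect_identical(r1, r2)
  # plate order must not change results: shuffle rows and rerun
  tab_shuffled <- tab[rev(seq_len(nrow(tab))), ]
  r3 <- bmc_analyze(tab_shuffled, bmr = 10, config = cfg)
  expect_equal(r1, r3)
})

test_that("BMR estimation finds the stabilization elbow", {
  concs <- 10^seq(-1, 2, by = 0.5)
  # noiseless step curves: variance flat in threshold, lowest grid value
  step_tab <- do.call(rbind, lapply(1:12, function(i) data.frame(
    lab_id = "L", plate_id = paste0("P", i), week_id = "W1",
    substance_id = paste0("S", i), endpoint = "MalformedAny+Mort@120",
    conc_uM = concs, affected = c(0L, 0L, 0L, 12L, 12L, 12L, 12L),
    total = 12L, response_pct = c(0, 0, 0, 100, 100, 100, 100))))
  est <- estimate_bmr(step_tab, bootstrap_config(200L, seed = 3L))
  expect_equal(est$threshold_pct, 5)

  # single flat-noise curve: nothing stabilizes, highest grid value
  flat_tab <- data.frame(
    lab_id = "L", plate_id = "P1", week_id = "W1", substance_id = "S",
    endpoint = "MalformedAny+Mort@120", conc_uM = concs,
    affected = c(0L, 1L, 0L, 1L, 0L, 1L, 0L), total = 12L,
    response_pct = NA_real_)
  w <- capture_warnings(estf <- estimate_bmr(flat_tab, bootstrap_config(200L, seed = 3L)))
  expect_match(w, "stabilized", all = FALSE)
  expect_equal(estf$threshold_pct, 50)

  # binomial noise at n = 12: estimate within the grid, and no worse than
  # the lowest candidate in pooled variance
  set.seed(4)
  p <- 1 / (1 + (3 / concs)^2)
  noisy_tab <- do.call(rbind, lapply(1:12, function(i) data.frame(
    lab_id = "L", plate_id = paste0("P", i), week_id = "W1",
    substance_id = paste0("S", i), endpoint = "MalformedAny+Mort@120",
    conc_uM = concs, affected = rbinom(7, 12, p), total = 12L,
    response_pct = NA_real_)))
  estn <- estimate_bmr(noisy_tab, bootstrap_config(200L, seed = 3L))
  expect_gte(estn$threshold_pct, 5)
  expect_lte(estn$threshold_pct, 50)
  prof <- estn$profile
  expect_lte(prof$pooled_var[prof$threshold_pct == estn$threshold_pct],
             prof$pooled_var[prof$threshold_pct == 5])
})
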