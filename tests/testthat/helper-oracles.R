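# Independent oracles for the BMC engine, deliberately implemented without
# the package's filtering/interpolation code paths.

# Exact non-decreasing isotonic fit for a length-3 vector with equal
# weights, by brute force over the four contiguous block partitions:
# keep the feasible (non-decreasing block means) partition with minimal
# squared error.
oracle_iso3 <- function(y) {
  partitions <- list(list(1L, 2L, 3L), list(1:2, 3L), list(1L, 2:3), list(1:3))
  best <- NULL; best_sse <- Inf
  for (p in partitions) {
    means <- vapply(p, function(idx) mean(y[idx]), numeric(1))
    if (any(diff(means) < -1e-12)) next
    fit <- unlist(lapply(seq_along(p), function(i) rep(means[i], length(p[[i]]))))
    sse <- sum((y - fit)^2)
    if (sse < best_sse - 1e-12) { best_sse <- sse; best <- fit }
  }
  best
}

# BMC of one length-3 curve at the given BMR over concentrations concs,
# re-deriving the filter rules from first principles: isotonic fit,
# sub-threshold flooring, noise iff the maximum stays below the BMR,
# log-linear interpolation; noise curves get the top concentration.
oracle_curve_bmc3 <- function(y, bmr, concs) {
  fit <- oracle_iso3(y)
  fit[fit < bmr] <- 0
  if (max(fit) < bmr) return(list(noise = TRUE, bmc = concs[3L]))
  if (fit[1L] >= bmr) return(list(noise = FALSE, bmc = concs[1L]))
  i <- which(fit >= bmr)[1L]
  lg <- log10(concs)
  frac <- (bmr - fit[i - 1L]) / (fit[i] - fit[i - 1L])
  list(noise = FALSE, bmc = 10^(lg[i - 1L] + frac * (lg[i] - lg[i - 1L])))
}

# Exact activity fraction and BMC distribution by enumerating every
# binomial outcome of a 3-concentration incidence experiment.
oracle_enumerate <- function(affected, total, bmr, concs = c(1, 10, 100)) {
  p <- affected / total
  grid <- expand.grid(lapply(total, function(n) 0:n))
  f <- 0; bmcs <- numeric(nrow(grid)); probs <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cnt <- as.numeric(grid[i, ])
    pr <- prod(dbinom(cnt, total, p))
    r <- oracle_curve_bmc3(100 * cnt / total, bmr, concs)
    if (!r$noise) f <- f + pr
    bmcs[i] <- r$bmc; probs[i] <- pr
  }
  o <- order(bmcs)
  cdf <- cumsum(probs[o])
  list(f = f, median_bmc = bmcs[o][which(cdf >= 0.5)[1L]])
}
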