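# Internal helpers: seed derivation and weighted isotonic regression.

# Deterministic 31-bit hash of a character key. Used to derive independent
# per-group bootstrap seeds from one root seed so results do not depend on
# the order plates are analysed in.
.hash31 <- function(key) {
  h <- 0
  for (cp in utf8ToInt(key)) {
    h <- (h * 31 + cp) %% 2147483647
  }
  as.integer(h)
}

.derive_seed <- function(root_seed, key) {
  as.integer((as.numeric(root_seed) + .hash31(key)) %% 2147483647L)
}

# Weighted pool-adjacent-violators algorithm for non-decreasing isotonic
# regression. y and w are numeric vectors of equal length; returns the
# isotonic fit. Stack-based PAVA, O(n).
.pava <- function(y, w) {
  n <- length(y)
  if (n <= 1L) return(y)
  # level means, weights and right endpoints of the current blocks
  vals <- numeric(n); wts <- numeric(n); ends <- integer(n)
  nb <- 0L
  for (i in seq_len(n)) {
    nb <- nb + 1L
    vals[nb] <- y[i]; wts[nb] <- w[i]; ends[nb] <- i
    while (nb > 1L && vals[nb - 1L] > vals[nb]) {
      wsum <- wts[nb - 1L] + wts[nb]
      vals[nb - 1L] <- (vals[nb - 1L] * wts[nb - 1L] + vals[nb] * wts[nb]) / wsum
      wts[nb - 1L] <- wsum
      ends[nb - 1L] <- ends[nb]
      nb <- nb - 1L
    }
  }
  out <- numeric(n)
  start <- 1L
  for (b in seq_len(nb)) {
    out[start:ends[b]] <- vals[b]
    start <- ends[b] + 1L
  }
  out
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.geomean <- function(x) exp(mean(log(x)))
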