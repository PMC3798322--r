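# Independent brute-force oracles used to cross-check the package's
# meta-analytic and combinatorial code paths.  Deliberately written as
# plain accumulation loops, not shared with the implementation.

# Method-of-moments random-effects pooling, step by step.
dl_oracle <- function(est, se) {
  k <- length(est)
  w <- numeric(k)
  for (i in seq_len(k)) w[i] <- 1 / (se[i] * se[i])
  sw <- 0; swy <- 0
  for (i in seq_len(k)) { sw <- sw + w[i]; swy <- swy + w[i] * est[i] }
  fixed <- swy / sw
  q <- 0
  for (i in seq_len(k)) q <- q + w[i] * (est[i] - fixed)^2
  sw2 <- 0
  for (i in seq_len(k)) sw2 <- sw2 + w[i]^2
  tau2 <- if (k == 1) 0 else (q - (k - 1)) / (sw - sw2 / sw)
  if (tau2 < 0) tau2 <- 0
  num <- 0; den <- 0
  for (i in seq_len(k)) {
    ws <- 1 / (se[i]^2 + tau2)
    num <- num + ws * est[i]
    den <- den + ws
  }
  list(est = num / den, se = sqrt(1 / den), tau2 = tau2, q = q,
       p = 2 * pnorm(-abs((num / den) / sqrt(1 / den))))
}

# Exhaustive hypergeometric tail: enumerate every size-|B| draw from a
# universe of size N and count draws overlapping a fixed size-|A| set in
# at least k elements.  Feasible for N <= 12.
hyper_enum_oracle <- function(N, size_a, size_b, k) {
  draws <- utils::combn(N, size_b)
  hits <- 0
  for (j in seq_len(ncol(draws)))
    if (sum(draws[, j] <= size_a) >= k) hits <- hits + 1
  hits / ncol(draws)
}

# Minimal hand-rolled cohort for unit tests: expression matrix plus a
# survival table, wrapped without going through the simulator.
toy_bundle <- function(expr, time, event, id = "toy",
                       channel = "single", endpoint = "RFS") {
  clin <- data.frame(time = time, event = event, endpoint = endpoint,
                     row.names = colnames(expr),
                     stringsAsFactors = FALSE)
  cohort_bundle(id, expr, clin, channel = channel)
}
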