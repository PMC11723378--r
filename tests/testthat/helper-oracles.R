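# Independent brute-force oracles used to pin the fast implementations.

# autocorrelation by the definition, double loop
oracle_acf <- function(x, max_lag) {
  n <- length(x)
  m <- mean(x)
  denom <- sum((x - m)^2)
  vapply(0:max_lag, function(tau) {
    s <- 0
    for (t in seq_len(n - tau)) s <- s + (x[t] - m) * (x[t + tau] - m)
    s / denom
  }, numeric(1))
}

# plain (single-segment, rectangular-window) periodogram peak frequency
oracle_periodogram_peak <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2
  half <- n %/% 2
  freqs <- (1:half) / n
  freqs[which.max(p[2:(half + 1)])]
}

# continuous-ordinal-pattern statistic, exhaustive window loop
oracle_cop <- function(x, pattern) {
  d <- length(pattern)
  vals <- numeric(0)
  for (s in 1:(length(x) - d + 1)) {
    w <- x[s:(s + d - 1)]
    w <- w - mean(w)
    mx <- max(abs(w))
    if (mx > 0) w <- w / mx
    vals <- c(vals, mean(abs(w - pattern)))
  }
  mean(vals)
}

# Spearman rho through the classic distinct-value formula
oracle_spearman_distinct <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# OLS through the normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# a lab profile identical to the Dublin-like one but relabelled, so two-lab
# datasets can be built from exchangeable generators
twin_profile <- function(name = "twin", knobs = difference_knobs(), ...) {
  p <- dublin_profile(...)
  p$lab_name <- name
  p$knobs <- knobs
  p
}

# small, fast classifier configuration for mechanical tests
tiny_resnet <- function(epochs = 30) {
  classifier_config("resnet", desk_scale = TRUE, epochs = epochs,
                    residual_blocks = 2L, layers_per_block = 2L,
                    filters = 8L)
}

# compact two-lab dataset for classification tests
small_dataset <- function(knobs = difference_knobs(), n = 12,
                          cycles_per_side = 3, seed = 1,
                          signals = "hip_moment", profile_b = NULL) {
  profile_b <- profile_b %||% twin_profile(knobs = knobs)
  generate_dataset(dublin_profile(), profile_b, n, n,
                   cycles_per_side = cycles_per_side, seed = seed,
                   signals = signals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
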