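#' Autocorrelation curve of a series
#'
#' Biased, mean-removed autocorrelation estimator
#' `r(tau) = sum_t (x_t - xbar)(x_{t+tau} - xbar) / sum_t (x_t - xbar)^2`,
#' with `r(0) = 1` (delegates to `stats::acf`, which implements exactly
#' this estimator).
#'
#' @param series Numeric, nonconstant, longer than `max_lag + 1`.
#' @param max_lag Largest lag (samples).
#' @return A `curve_summary` list: `grid` (lags `0..max_lag`) and `values`.
#' @export
acf_curve <- function(series, max_lag = 60L) {
  if (length(series) <= max_lag + 1) {
    stop_gs("series must be longer than max_lag + 1")
  }
  if (stats::sd(series) == 0) stop_gs("constant series has no ACF")
  v <- as.numeric(stats::acf(series, lag.max = max_lag, plot = FALSE,
                             demean = TRUE)$acf)
  structure(list(grid = 0:max_lag, values = v), class = "curve_summary")
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: the series is cut into overlapping
#' segments, each mean-detrended and tapered with a Hann window; the
#' one-sided periodograms are averaged. Power is normalized so that the
#' integral of the PSD over frequency (cycles/sample, grid spacing
#' `1/segment_length`) approximates the series variance.
#'
#' @param series Numeric vector, at least `segment_length` long.
#' @param segment_length Samples per segment.
#' @param overlap Fractional overlap between consecutive segments.
#' @param taper Taper name; only `"hann"` is implemented.
#' @return A `curve_summary` list: `grid` (frequencies 0..0.5
#'   cycles/sample) and `values` (nonnegative power).
#' @export
welch_psd <- function(series, segment_length = 32L, overlap = 0.5,
                      taper = "hann") {
  n <- length(series)
  seg <- as.integer(segment_length)
  if (n < seg) stop_gs("series shorter than one segment")
  if (!identical(taper, "hann")) stop_gs("only the Hann taper is available")
  w <- 0.5 * (1 - cos(2 * pi * (0:(seg - 1)) / (seg - 1)))
  step <- max(1L, as.integer(round(seg * (1 - overlap))))
  starts <- seq(1L, n - seg + 1L, by = step)
  half <- seg %/% 2
  acc <- numeric(half + 1)
  for (s in starts) {
    x <- series[s:(s + seg - 1)]
    x <- (x - mean(x)) * w
    p <- Mod(stats::fft(x))^2 / sum(w^2)
    p1 <- p[1:(half + 1)]
    p1[2:half] <- 2 * p1[2:half]          # fold negative frequencies
    acc <- acc + p1
  }
  # density scaling: sum(values) * (1/seg) integrates to the variance
  structure(list(grid = (0:half) / seg, values = acc / length(starts)),
            class = "curve_summary")
}

#' Pointwise-median curve of a group of series
#'
#' Applies a curve function (autocorrelation or Welch PSD) to each series
#' of a group and takes the median at each grid point -- the robust
#' group-level summary used to compare the two laboratories.
#'
#' @param values Numeric matrix, one series per row (common length).
#' @param curve `"acf"` or `"welch_psd"`.
#' @param ... Passed to the curve function.
#' @return A `curve_summary` (`grid`, `values`).
#' @export
median_curve <- function(values, curve = c("acf", "welch_psd"), ...) {
  curve <- match.arg(curve)
  if (!nrow(values)) stop_gs("empty group")
  fn <- if (curve == "acf") acf_curve else welch_psd
  curves <- apply(values, 1, function(v) fn(v, ...)$values)
  grid <- fn(values[1, ], ...)$grid
  structure(list(grid = grid,
                 values = apply(matrix(curves, ncol = nrow(values)), 1,
                                stats::median)),
            class = "curve_summary")
}

#' Lag of the autocorrelation minimum
#'
#' Location (in samples) of the global minimum of an ACF curve over lags
#' `1..max_lag`; ties are resolved toward the smallest lag.
#'
#' @param curve A `curve_summary` from [acf_curve()] / [median_curve()].
#' @return Integer lag >= 1.
#' @export
find_acf_minimum <- function(curve) {
  keep <- curve$grid >= 1
  lags <- curve$grid[keep]
  as.integer(lags[which.min(curve$values[keep])])
}

#' Log-ratio distance between two characteristic lags
#'
#' `|log2(tau_a / tau_b)|`: 0 for equal lags, 1 when one lag is twice the
#' other; symmetric in its arguments.
#'
#' @param tau_a,tau_b Positive lags (samples).
#' @return Nonnegative scalar.
#' @export
delta_minima <- function(tau_a, tau_b) {
  if (tau_a <= 0 || tau_b <= 0) stop_gs("lags must be positive")
  abs(log2(tau_a / tau_b))
}

#' Area between two curves
#'
#' Trapezoidal integral of the absolute difference between two curves on a
#' common grid.
#'
#' @param curve_a,curve_b `curve_summary` objects on the same grid.
#' @return Nonnegative scalar.
#' @export
delta_area <- function(curve_a, curve_b) {
  if (!isTRUE(all.equal(curve_a$grid, curve_b$grid))) {
    stop_gs("curves are on different grids")
  }
  d <- abs(curve_a$values - curve_b$values)
  g <- curve_a$grid
  sum((d[-1] + d[-length(d)]) / 2 * diff(g))
}

#' Log-ratio distance between two spectral peak locations
#'
#' `|log2(f*_a / f*_b)|` where `f*` is the frequency of maximal power,
#' excluding the zero-frequency bin; ties resolve to the lowest frequency.
#'
#' @param psd_a,psd_b `curve_summary` objects from [welch_psd()] /
#'   [median_curve()] on a common frequency grid.
#' @return Nonnegative scalar.
#' @export
psd_delta_maxima <- function(psd_a, psd_b) {
  if (!isTRUE(all.equal(psd_a$grid, psd_b$grid))) {
    stop_gs("spectra are on different grids")
  }
  peak <- function(p) {
    keep <- p$grid > 0
    if (all(p$values[keep] == 0)) stop_gs("all-zero spectrum")
    p$grid[keep][which.max(p$values[keep])]
  }
  abs(log2(peak(psd_a) / peak(psd_b)))
}

#' Continuous-ordinal-pattern configuration
#'
#' @param pattern_length Window/pattern length `D` (>= 3).
#' @param n_patterns Number of random patterns.
#' @param seed Seed for pattern generation.
#' @return An object of class `cop_config`.
#' @export
cop_config <- function(pattern_length = 10L, n_patterns = 100L, seed = 1L) {
  if (pattern_length < 3) stop_gs("pattern_length must be >= 3")
  if (n_patterns < 1) stop_gs("n_patterns must be >= 1")
  structure(list(pattern_length = as.integer(pattern_length),
                 n_patterns = as.integer(n_patterns),
                 seed = as.integer(seed)),
            class = "cop_config")
}

# normalize a window/pattern: zero mean, max |.| = 1 (zero vector if flat)
cop_normalize <- function(x) {
  x <- x - mean(x)
  m <- max(abs(x))
  if (m == 0) x else x / m
}

#' Random continuous ordinal patterns
#'
#' Smoothed standard-normal sequences (moving average of window 3),
#' normalized to zero mean and maximum absolute value 1.
#'
#' @param n Number of patterns.
#' @param pattern_length Pattern length `D`.
#' @param seed Optional seed.
#' @return Matrix with one pattern per row.
#' @export
random_cop_patterns <- function(n, pattern_length = 10L, seed = NULL) {
  with_seed(seed, {
    t(vapply(seq_len(n), function(i) {
      z <- stats::rnorm(pattern_length + 2)
      z <- (z[1:pattern_length] + z[2:(pattern_length + 1)] +
              z[3:(pattern_length + 2)]) / 3
      cop_normalize(z)
    }, numeric(pattern_length)))
  })
}

#' Continuous-ordinal-pattern statistic of one series
#'
#' Slides a window of the pattern's length along the series (stride 1),
#' normalizes each window to zero mean and max-abs 1 (a constant window
#' becomes the zero vector), and averages the mean absolute deviation
#' `(1/D) sum_i |w_i - p_i|` between the normalized windows and the
#' pattern. Small values mean the pattern's shape occurs throughout the
#' series, so the statistic summarizes local correlation structure
#' including magnitudes, not just rank order.
#'
#' @param series Numeric vector, at least as long as the pattern.
#' @param pattern Normalized pattern (zero mean, max-abs 1).
#' @return Mean window-to-pattern distance.
#' @export
cop_value <- function(series, pattern) {
  d <- length(pattern)
  if (length(series) < d) stop_gs("series shorter than the pattern")
  n_win <- length(series) - d + 1
  tot <- 0
  for (s in seq_len(n_win)) {
    w <- cop_normalize(series[s:(s + d - 1)])
    tot <- tot + mean(abs(w - pattern))
  }
  tot / n_win
}

# vectorized cop_value over the rows of a matrix, for a set of patterns:
# returns (n_series x n_patterns)
cop_values_matrix <- function(values, patterns) {
  d <- ncol(patterns)
  n <- nrow(values)
  len <- ncol(values)
  n_win <- len - d + 1
  # stack all normalized windows: (n * n_win) x d
  W <- matrix(0, n * n_win, d)
  for (s in seq_len(n_win)) {
    w <- values[, s:(s + d - 1), drop = FALSE]
    w <- w - rowMeans(w)
    m <- apply(abs(w), 1, max)
    m[m == 0] <- 1
    W[(s - 1) * n + seq_len(n), ] <- w / m
  }
  out <- matrix(0, n, nrow(patterns))
  for (p in seq_len(nrow(patterns))) {
    dist <- rowMeans(abs(W - matrix(patterns[p, ], nrow(W), d,
                                    byrow = TRUE)))
    out[, p] <- rowMeans(matrix(dist, n, n_win))
  }
  out
}

#' Cohen's D effect size
#'
#' Standardized mean difference `(mean(x) - mean(y)) / s_pooled` with the
#' pooled SD computed from unbiased sample variances.
#'
#' @param x,y Numeric samples of length >= 2.
#' @return Signed effect size (antisymmetric in the arguments).
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop_gs("both samples need >= 2 values")
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  if (sp == 0) stop_gs("zero pooled SD")
  (mean(x) - mean(y)) / sp
}

#' Continuous-ordinal-pattern divergence between two groups
#'
#' Applies a set of random patterns to every series of both groups and
#' measures, for each pattern, the between-group Cohen's D of the
#' per-series pattern statistics. The divergence is the maximum |D| over
#' patterns: the best-discriminating local correlation structure.
#'
#' @param group_a,group_b Numeric matrices (one series per row).
#' @param config A [cop_config()].
#' @return List with `d` (max |Cohen's D|), `per_pattern` (signed D per
#'   pattern) and `patterns` (the pattern matrix).
#' @export
cop_divergence <- function(group_a, group_b, config = cop_config()) {
  if (nrow(group_a) < 2 || nrow(group_b) < 2) {
    stop_gs("each group needs >= 2 series")
  }
  patterns <- random_cop_patterns(config$n_patterns, config$pattern_length,
                                  seed = config$seed)
  va <- cop_values_matrix(group_a, patterns)
  vb <- cop_values_matrix(group_b, patterns)
  ds <- vapply(seq_len(nrow(patterns)), function(p) {
    cohens_d(va[, p], vb[, p])
  }, numeric(1))
  list(d = max(abs(ds)), per_pattern = ds, patterns = patterns)
}

#' Per-signal divergence metrics between the two laboratories
#'
#' Computes the full set of divergence statistics for one signal of a
#' two-laboratory dataset, on series preprocessed with the standardization
#' chain (truncation, smoothing, z-score, rank standardization by
#' default): the per-lab median ACF curves and their minimum-lag
#' log-ratio and inter-curve area; the per-lab median Welch spectra and
#' their peak-location log-ratio, inter-curve area and absolute peak-power
#' difference; and the continuous-ordinal-pattern Cohen's D.
#'
#' @param dataset A `gait_dataset`.
#' @param signal Canonical signal name.
#' @param preprocess A [preprocess_config()].
#' @param max_lag ACF maximum lag.
#' @param cop A [cop_config()].
#' @return One-row tibble: `signal`, `tau_a`, `tau_b`, `delta_minima_acf`,
#'   `delta_area_acf`, `delta_maxima_psd`, `delta_area_psd`,
#'   `delta_peak_power_psd`, `cop_cohens_d`.
#' @export
divergence_metrics <- function(dataset, signal,
                               preprocess = preprocess_preset("standardized"),
                               max_lag = 60L, cop = cop_config()) {
  sm <- signal_matrix(dataset, signal)
  proc <- preprocess_matrix(sm$values, preprocess)
  la <- dataset$config$lab_a
  lb <- dataset$config$lab_b
  pa <- proc[sm$meta$lab == la, , drop = FALSE]
  pb <- proc[sm$meta$lab == lb, , drop = FALSE]
  acf_a <- median_curve(pa, "acf", max_lag = max_lag)
  acf_b <- median_curve(pb, "acf", max_lag = max_lag)
  tau_a <- find_acf_minimum(acf_a)
  tau_b <- find_acf_minimum(acf_b)
  psd_a <- median_curve(pa, "welch_psd")
  psd_b <- median_curve(pb, "welch_psd")
  tibble::tibble(
    signal = signal,
    tau_a = tau_a, tau_b = tau_b,
    delta_minima_acf = delta_minima(tau_a, tau_b),
    delta_area_acf = delta_area(acf_a, acf_b),
    delta_maxima_psd = psd_delta_maxima(psd_a, psd_b),
    delta_area_psd = delta_area(psd_a, psd_b),
    delta_peak_power_psd = abs(max(psd_a$values[psd_a$grid > 0]) -
                                 max(psd_b$values[psd_b$grid > 0])),
    cop_cohens_d = cop_divergence(pa, pb, cop)$d
  )
}
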