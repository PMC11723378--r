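#' Drop the initial samples of a cycle
#'
#' Removes the first `k` samples (by default the first 30% of a 100-sample
#' cycle, i.e. the first double support and the beginning of single
#' support, where inter-laboratory fluctuations concentrate).
#'
#' @param series Numeric vector.
#' @param k Number of leading samples to drop; `0 <= k < length(series)`.
#' @return Numeric vector of length `length(series) - k`.
#' @export
truncate_initial <- function(series, k = 30L) {
  k <- as.integer(k)
  if (k < 0 || k >= length(series)) {
    stop_gs("k must satisfy 0 <= k < length(series)")
  }
  if (k == 0L) series else series[-seq_len(k)]
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing (order 3, window 9 by default).
#' Each interior point is replaced by the value of the polynomial fitted on
#' its centered window; the first and last half-windows are fitted on
#' asymmetric windows of the same length, so no samples outside the series
#' are fabricated. Delegates to `signal::sgolayfilt`.
#'
#' @param series Numeric vector, at least `window` long.
#' @param window Odd window length, greater than `order`.
#' @param order Polynomial order.
#' @return Smoothed numeric vector of the same length.
#' @export
savgol_smooth <- function(series, window = 9L, order = 3L) {
  window <- as.integer(window); order <- as.integer(order)
  if (window %% 2L == 0L) stop_gs("window must be odd")
  if (window <= order) stop_gs("window must exceed the polynomial order")
  if (length(series) < window) stop_gs("series shorter than the window")
  as.numeric(signal::sgolayfilt(series, p = order, n = window))
}

#' Rescale a series to zero mean and unit standard deviation
#'
#' Uses the population SD convention (divide by `N`, not `N - 1`), so the
#' output has SD exactly 1 under that convention.
#'
#' @param series Numeric vector with positive spread.
#' @return Standardized numeric vector.
#' @export
zscore <- function(series) {
  m <- mean(series)
  s <- sqrt(mean((series - m)^2))
  if (!is.finite(s) || s == 0) {
    stop_gs("cannot z-score a constant series (zero SD)")
  }
  (series - m) / s
}

#' Rank-to-uniform standardization
#'
#' Replaces the n-th smallest of the `L` values by `n / L`, so every series
#' of a given length acquires exactly the same value distribution (the
#' uniform grid `1/L, 2/L, ..., 1`). This removes all value-distribution
#' information while preserving the temporal ordering structure. Ties are
#' broken by temporal position (the earlier sample gets the lower rank), so
#' the output is always an exact permutation of the grid.
#'
#' @param series Nonempty numeric vector.
#' @return Numeric vector of the same length; a permutation of
#'   `seq_along(series) / length(series)`.
#' @export
rank_standardize <- function(series) {
  if (!length(series)) stop_gs("empty series")
  rank(series, ties.method = "first") / length(series)
}

#' Reduce temporal resolution by decimation
#'
#' Keeps every `factor`-th sample starting from the first one (plain
#' decimation without an anti-aliasing filter: the operation models a lower
#' acquisition resolution, not a resampling).
#'
#' @param series Numeric vector.
#' @param factor Integer decimation factor, `1 <= factor < length(series)`.
#' @return Numeric vector of length `ceiling(length(series) / factor)`.
#' @export
downsample <- function(series, factor) {
  factor <- as.integer(factor)
  if (factor < 1 || factor >= length(series)) {
    stop_gs("factor must satisfy 1 <= factor < length(series)")
  }
  series[seq(1L, length(series), by = factor)]
}

#' Sub-window grid over the gait cycle
#'
#' Index ranges of fixed-width windows used to localize where in the cycle
#' two laboratories differ: windows of `width_pct` % of the cycle, starting
#' after an excluded prefix and advancing by `stride_pct`, the last window
#' ending exactly at the end of the cycle.
#'
#' @param cycle_length Number of samples per cycle.
#' @param width_pct Window width in % of the cycle.
#' @param excluded_prefix_pct Initial % of the cycle to exclude.
#' @param stride_pct Window stride in % of the cycle.
#' @return A tibble with columns `start` and `end`: half-open 0-based
#'   sample ranges `[start, end)`, i.e. 1-based R indices
#'   `(start + 1):end`.
#' @export
#' @examples
#' subwindows()  # starts 30, 40, ..., 80, width 20
subwindows <- function(cycle_length = 100L, width_pct = 20,
                       excluded_prefix_pct = 30, stride_pct = 10) {
  if (excluded_prefix_pct + width_pct > 100) {
    stop_gs("excluded_prefix_pct + width_pct must be <= 100")
  }
  if (width_pct <= 0 || stride_pct <= 0) {
    stop_gs("width_pct and stride_pct must be positive")
  }
  to_samples <- function(p) as.integer(round(p * cycle_length / 100))
  width <- to_samples(width_pct)
  stride <- to_samples(stride_pct)
  starts <- seq(to_samples(excluded_prefix_pct), cycle_length - width,
                by = stride)
  tibble::tibble(start = as.integer(starts),
                 end = as.integer(starts + width))
}

#' Preprocessing configuration
#'
#' Declarative description of the preprocessing chain applied to each raw
#' 100-sample cycle, in this fixed order: initial truncation,
#' Savitzky-Golay smoothing, z-scoring, optional rank-to-uniform
#' standardization, optional decimation, optional sub-window slice.
#'
#' Three named presets cover the standard analyses: `"raw"` (no transform),
#' `"smoothed"` (truncate 30, Savitzky-Golay 9/3, z-score) and
#' `"standardized"` (the smoothed chain followed by rank standardization).
#'
#' @param truncate_start Leading samples to drop (0 disables).
#' @param sg_window,sg_order Savitzky-Golay window/order; `sg_window = 0`
#'   disables smoothing.
#' @param zscore Logical: rescale to zero mean, unit SD.
#' @param rank_standardize Logical: map values onto the uniform grid.
#' @param downsample_factor Decimation factor (1 disables).
#' @param subwindow Optional `c(start, end)` 0-based half-open sample range
#'   applied to the *raw* 100-sample indexing, before truncation-induced
#'   reindexing (windows from [subwindows()] can be passed directly).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(truncate_start = 30L, sg_window = 9L,
                              sg_order = 3L, zscore = TRUE,
                              rank_standardize = FALSE,
                              downsample_factor = 1L, subwindow = NULL) {
  if (sg_window != 0 && (sg_window %% 2 == 0 || sg_window <= sg_order)) {
    stop_gs("sg_window must be odd and > sg_order")
  }
  if (downsample_factor < 1) stop_gs("downsample_factor must be >= 1")
  if (!is.null(subwindow) && length(subwindow) != 2) {
    stop_gs("subwindow must be c(start, end)")
  }
  structure(list(truncate_start = as.integer(truncate_start),
                 sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order),
                 zscore = isTRUE(zscore),
                 rank_standardize = isTRUE(rank_standardize),
                 downsample_factor = as.integer(downsample_factor),
                 subwindow = if (!is.null(subwindow)) as.integer(subwindow)),
            class = "preprocess_config")
}

#' @rdname preprocess_config
#' @param name Preset name: `"raw"`, `"smoothed"` or `"standardized"`.
#' @export
preprocess_preset <- function(name = c("raw", "smoothed", "standardized")) {
  name <- match.arg(name)
  switch(name,
    raw = preprocess_config(truncate_start = 0L, sg_window = 0L,
                            zscore = FALSE),
    smoothed = preprocess_config(),
    standardized = preprocess_config(rank_standardize = TRUE)
  )
}

#' Apply the preprocessing chain to one cycle
#'
#' @param cycle A `gait_cycle` (from [generate_cycle()]) or a plain numeric
#'   vector.
#' @param config A [preprocess_config()].
#' @return A `processed_series` list with `values`, the ordered `steps` log
#'   (transform names and parameters) and the `source` cycle identity.
#' @export
standard_pipeline <- function(cycle, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  if (inherits(cycle, "gait_cycle")) {
    x <- cycle$values
    src <- cycle[c("subject_id", "lab", "side", "cycle_index", "signal")]
  } else {
    x <- as.numeric(cycle)
    src <- NULL
  }
  steps <- list()
  log_step <- function(name, ...) {
    steps[[length(steps) + 1L]] <<- c(list(step = name), list(...))
  }
  if (!is.null(config$subwindow)) {
    w <- config$subwindow
    if (w[1] < 0 || w[2] > length(x) || w[1] >= w[2]) {
      stop_gs("subwindow out of range")
    }
  }
  if (config$truncate_start > 0) {
    x <- truncate_initial(x, config$truncate_start)
    log_step("truncate_initial", k = config$truncate_start)
  }
  if (config$sg_window > 0) {
    x <- savgol_smooth(x, config$sg_window, config$sg_order)
    log_step("savgol_smooth", window = config$sg_window,
             order = config$sg_order)
  }
  if (config$zscore) {
    x <- zscore(x)
    log_step("zscore")
  }
  if (config$rank_standardize) {
    x <- rank_standardize(x)
    log_step("rank_standardize")
  }
  if (config$downsample_factor > 1) {
    x <- downsample(x, config$downsample_factor)
    log_step("downsample", factor = config$downsample_factor)
  }
  if (!is.null(config$subwindow)) {
    # window indices refer to the raw cycle; shift for truncation/decimation
    idx <- (config$subwindow[1] + 1):config$subwindow[2]
    idx <- idx - config$truncate_start
    if (config$downsample_factor > 1) {
      idx <- unique(pmax(1L, ceiling(idx / config$downsample_factor)))
    }
    idx <- idx[idx >= 1 & idx <= length(x)]
    if (!length(idx)) stop_gs("subwindow removed by earlier steps")
    x <- x[idx]
    log_step("subwindow", start = config$subwindow[1],
             end = config$subwindow[2])
  }
  structure(list(values = x, steps = steps, source = src),
            class = "processed_series")
}

# Vectorized pipeline over the rows of a cycle matrix (used by classify /
# divergence). Returns a matrix with one processed series per row.
preprocess_matrix <- function(values, config) {
  out <- t(apply(values, 1, function(v) standard_pipeline(v, config)$values))
  if (nrow(values) == 1) out <- matrix(out, nrow = 1)
  out
}
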