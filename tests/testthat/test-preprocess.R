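test_that("initial truncation keeps the final segment", {
  x <- rnorm(100)
  y <- truncate_initial(x, 30)
  expect_length(y, 70)
  expect_equal(y[1], x[31])
  expect_identical(truncate_initial(x, 0), x)
  expect_error(truncate_initial(x, 100), "k must satisfy")
})

test_that("Savitzky-Golay reproduces low-order polynomials and smooths", {
  t <- seq(-1, 1, length.out = 60)
  cubic <- 2 + t - 0.5 * t^2 + 3 * t^3
  expect_equal(savgol_smooth(cubic, 9, 3), cubic, tolerance = 1e-8)
  expect_equal(savgol_smooth(rep(4, 40)), rep(4, 40), tolerance = 1e-10)
  # high-frequency component attenuated, by Welch comparison
  x <- sin(2 * pi * (0:69) / 35)
  noisy <- x + 0.5 * sin(2 * pi * (0:69) * 0.45)
  hi_band <- function(v) {
    psd <- welch_psd(v)
    sum(psd$values[psd$grid > 0.35])
  }
  expect_lt(hi_band(savgol_smooth(noisy)), 0.25 * hi_band(noisy))
  expect_error(savgol_smooth(x, 8, 3), "odd")
  expect_error(savgol_smooth(x, 3, 3), "exceed")
  expect_error(savgol_smooth(x[1:5], 9, 3), "shorter")
})

test_that("z-scoring uses the population SD convention", {
  expect_equal(zscore(c(0, 2)), c(-1, 1))
  x <- rnorm(50)
  expect_equal(zscore(3 * x + 7), zscore(x), tolerance = 1e-12)
  y <- zscore(x)
  expect_lt(abs(mean(y)), 1e-10)
  expect_lt(abs(sqrt(mean((y - mean(y))^2)) - 1), 1e-10)
  expect_error(zscore(rep(2, 10)), "constant")
})

test_that("rank standardization maps the n-th smallest value to n/L", {
  x <- rnorm(70)
  y <- rank_standardize(x)
  expect_equal(sort(y), (1:70) / 70)
  expect_equal(y[which.min(x)], 1 / 70)
  expect_equal(y[which.max(x)], 1)
  sorted <- sort(rnorm(12))
  expect_equal(rank_standardize(sorted), (1:12) / 12)
  # invariance under strictly increasing transforms, vs a ranking oracle
  for (i in 1:5) {
    z <- rnorm(40)
    expect_equal(rank_standardize(exp(z) + 2), rank_standardize(z))
    expect_equal(rank_standardize(z), rank(z) / 40)
  }
  # ties broken by temporal position
  expect_equal(rank_standardize(c(1, 1, 0)), c(2 / 3, 1, 1 / 3))
})

test_that("rank standardization equalizes value distributions exactly", {
  a <- rank_standardize(rnorm(70))
  b <- rank_standardize(rcauchy(70))
  expect_equal(sort(a), sort(b))
})

test_that("decimation keeps every factor-th sample", {
  x <- rnorm(70)
  expect_identical(downsample(x, 1), x)
  y <- downsample(x, 2)
  expect_length(y, 35)
  expect_equal(y[3], x[5])
  expect_error(downsample(x, 70), "factor")
})

test_that("sub-window grid matches the excluded-prefix design", {
  w <- subwindows()
  expect_equal(w$start, c(30, 40, 50, 60, 70, 80))
  expect_true(all(w$end - w$start == 20))
  expect_equal(max(w$end), 100)
  single <- subwindows(width_pct = 70)
  expect_equal(nrow(single), 1)
  expect_equal(c(single$start, single$end), c(30, 100))
  expect_error(subwindows(excluded_prefix_pct = 90), "<= 100")
})

test_that("the standard pipeline applies steps in order and logs them", {
  p <- dublin_profile()
  cyc <- generate_cycle(sample_subject(p, seed = 2), "hip_moment", p,
                        seed = 3)
  raw <- standard_pipeline(cyc, preprocess_preset("raw"))
  expect_equal(raw$values, cyc$values)
  expect_length(raw$steps, 0)

  sm <- standard_pipeline(cyc, preprocess_preset("smoothed"))
  expect_length(sm$values, 70)
  expect_lt(abs(mean(sm$values)), 1e-10)
  expect_equal(vapply(sm$steps, `[[`, "", "step"),
               c("truncate_initial", "savgol_smooth", "zscore"))

  st <- standard_pipeline(cyc, preprocess_preset("standardized"))
  expect_equal(sort(st$values), (1:70) / 70)

  # the step log is sufficient to replay the output from the raw cycle
  replayed <- cyc$values
  for (step in sm$steps) {
    replayed <- switch(step$step,
      truncate_initial = truncate_initial(replayed, step$k),
      savgol_smooth = savgol_smooth(replayed, step$window, step$order),
      zscore = zscore(replayed))
  }
  expect_equal(replayed, sm$values)
})

test_that("pipeline transforms are pure", {
  x <- rnorm(100)
  cfg <- preprocess_config(rank_standardize = TRUE, downsample_factor = 2)
  expect_identical(standard_pipeline(x, cfg)$values,
                   standard_pipeline(x, cfg)$values)
})

test_that("sub-window slicing maps raw indices through truncation", {
  x <- rnorm(100)
  cfg <- preprocess_config(truncate_start = 30, sg_window = 0,
                           zscore = FALSE, subwindow = c(30, 50))
  out <- standard_pipeline(x, cfg)$values
  expect_equal(out, x[31:50])
})
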