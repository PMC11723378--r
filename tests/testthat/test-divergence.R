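test_that("autocorrelation matches the double-loop oracle", {
  set.seed(1)
  for (i in 1:5) {
    x <- rnorm(20)
    expect_equal(acf_curve(x, max_lag = 10)$values, oracle_acf(x, 10),
                 tolerance = 1e-10)
  }
  x <- rnorm(70)
  a <- acf_curve(x, 60)
  expect_equal(a$values[1], 1)
  expect_true(all(abs(a$values) <= 1 + 1e-12))
  expect_error(acf_curve(rep(1, 70), 60), "constant")
  expect_error(acf_curve(rnorm(30), 60), "longer")
})

test_that("white-noise autocorrelations stay inside the null envelope", {
  set.seed(2)
  vals <- replicate(100, {
    a <- acf_curve(rnorm(70), 20)$values[-1]
    mean(abs(a) < 0.35)
  })
  expect_gt(mean(vals), 0.93)
})

test_that("a period-50 cosine has its ACF minimum near lag 25", {
  x <- cos(2 * pi * (0:69) / 50)
  tau <- find_acf_minimum(acf_curve(x, 60))
  expect_lte(abs(tau - 25), 2)
})

test_that("ACF minimum detection uses the global minimum with early ties", {
  mk <- function(v) structure(list(grid = 0:(length(v) - 1), values = v),
                              class = "curve_summary")
  v <- rep(0.5, 61); v[31] <- -0.9
  expect_equal(find_acf_minimum(mk(v)), 30)
  expect_equal(find_acf_minimum(mk(seq(1, -1, length.out = 61))), 60)
  v <- rep(0.5, 61); v[c(26, 41)] <- -0.9
  expect_equal(find_acf_minimum(mk(v)), 25)
})

test_that("delta minima is the symmetric log2 lag ratio", {
  expect_equal(delta_minima(30, 30), 0)
  expect_equal(delta_minima(60, 30), 1)
  expect_equal(delta_minima(30, 60), 1)
  expect_error(delta_minima(0, 30), "positive")
})

test_that("delta area matches closed forms and the trapezoid oracle", {
  mk <- function(v, g = 0:(length(v) - 1)) {
    structure(list(grid = g, values = v), class = "curve_summary")
  }
  a <- mk(rnorm(61))
  expect_equal(delta_area(a, a), 0)
  b <- mk(a$values + 0.3)
  expect_equal(delta_area(a, b), 0.3 * 60)
  set.seed(3)
  c1 <- mk(rnorm(40)); c2 <- mk(rnorm(40))
  expect_equal(delta_area(c1, c2), delta_area(c2, c1))
  skip_if_not_installed("pracma")
  expect_equal(delta_area(c1, c2),
               pracma::trapz(c1$grid, abs(c1$values - c2$values)),
               tolerance = 1e-12)
  expect_error(delta_area(c1, mk(rnorm(40), g = seq(0, 39) / 2)), "grids")
})

test_that("Welch PSD localizes tones and conserves power", {
  # exact-bin sinusoid: peak at that bin, agreeing with the periodogram
  x <- sin(2 * pi * (0:69) * 4 / 32)
  psd <- welch_psd(x)
  expect_equal(psd$grid[which.max(psd$values)], 4 / 32)
  expect_equal(psd$grid[which.max(psd$values)],
               round(oracle_periodogram_peak(x[1:32]) * 32) / 32)
  # constant series has (numerically) no power
  flat <- welch_psd(rep(3, 70))
  expect_lt(max(flat$values), 1e-20)
  # white-noise power conservation within Welch bias tolerance
  set.seed(4)
  ratio <- replicate(100, {
    z <- rnorm(70)
    psd <- welch_psd(z)
    sum(psd$values) / 32 / stats::var(z)
  })
  expect_lt(abs(stats::median(ratio) - 1), 0.2)
  expect_error(welch_psd(rnorm(20)), "shorter")
})

test_that("PSD peak-location delta is a symmetric log2 ratio", {
  mk <- function(peak_bin) {
    v <- rep(0.01, 17)
    v[peak_bin + 1] <- 1
    structure(list(grid = (0:16) / 32, values = v),
              class = "curve_summary")
  }
  a <- mk(2); b <- mk(4)  # peaks at 2/32 and 4/32 cycles/sample
  expect_equal(psd_delta_maxima(a, a), 0)
  expect_equal(psd_delta_maxima(a, b), 1)
  expect_equal(psd_delta_maxima(b, a), 1)
})

test_that("cop_value agrees with the exhaustive-window oracle", {
  set.seed(5)
  for (i in 1:5) {
    x <- rnorm(14)
    p <- random_cop_patterns(1, 5, seed = i)[1, ]
    expect_equal(cop_value(x, p), oracle_cop(x, p), tolerance = 1e-10)
  }
  # a series equal to the pattern itself is at distance zero from it
  p <- random_cop_patterns(1, 10, seed = 9)[1, ]
  expect_equal(cop_value(p, p), 0)
  # constant series: every window is the zero vector
  expect_equal(cop_value(rep(2, 12), p), mean(abs(p)))
  expect_error(cop_value(rnorm(5), p), "shorter")
})

test_that("vectorized COP values match the scalar implementation", {
  set.seed(6)
  vals <- matrix(rnorm(4 * 20), 4, 20)
  pats <- random_cop_patterns(3, 6, seed = 2)
  m <- gaitshift:::cop_values_matrix(vals, pats)
  for (i in 1:4) for (j in 1:3) {
    expect_equal(m[i, j], cop_value(vals[i, ], pats[j, ]),
                 tolerance = 1e-12)
  }
})

test_that("random patterns are normalized", {
  pats <- random_cop_patterns(20, 10, seed = 3)
  expect_equal(rowMeans(pats), rep(0, 20), tolerance = 1e-12)
  expect_equal(apply(abs(pats), 1, max), rep(1, 20), tolerance = 1e-12)
  expect_identical(pats, random_cop_patterns(20, 10, seed = 3))
})

test_that("Cohen's D matches the pooled-SD formula", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(0, 1), c(1, 2)), -1.41421, tolerance = 1e-4)
  x <- rnorm(20); y <- rnorm(20, 1)
  expect_equal(cohens_d(x, y), -cohens_d(y, x))
  expect_error(cohens_d(1, c(1, 2)), ">= 2")
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), "pooled SD")
})

test_that("COP divergence separates labs that differ in HF content", {
  mk <- function(hf, seed) {
    p <- twin_profile(knobs = difference_knobs(delta_hf = hf),
                      sigma_noise = 0.03)
    s <- sample_subjects(p, 20, seed = seed)
    set.seed(seed + 50)
    do.call(rbind, lapply(s, function(si) {
      gaitshift:::gen_cycle_block(5, p$templates[["hip_moment"]],
                                  si$eta["hip_moment", ], si$stance_pct, p)
    }))
  }
  base <- mk(0, 1)
  same <- mk(0, 2)
  diff <- mk(0.5, 3)
  cfg <- cop_config(n_patterns = 30, seed = 7)
  # the summary is a maximum over patterns, so its null level is the
  # extreme of ~30 correlated effect sizes, well below the knob signal
  expect_lt(cop_divergence(base, same, cfg)$d, 0.6)
  expect_gt(cop_divergence(base, diff, cfg)$d, 1)
  expect_identical(cop_divergence(base, diff, cfg)$d,
                   cop_divergence(base, diff, cfg)$d)
  expect_error(cop_divergence(base[1, , drop = FALSE], diff, cfg), ">= 2")
})

test_that("median curves behave like medians", {
  x <- rnorm(70)
  single <- median_curve(matrix(x, 1), "acf", max_lag = 30)
  expect_equal(single$values, acf_curve(x, 30)$values)
  base <- acf_curve(x, 30)$values
  pert <- rbind(x, x * 1.5, x * (1 / 1.5))  # symmetric scalings share the ACF
  med <- median_curve(pert, "acf", max_lag = 30)
  expect_equal(med$values, base, tolerance = 1e-10)
})

test_that("divergence metrics are near zero for exchangeable labs", {
  ds <- small_dataset(n = 15, cycles_per_side = 4, seed = 8)
  m <- divergence_metrics(ds, "hip_moment",
                          cop = cop_config(n_patterns = 30, seed = 1))
  expect_true(all(c(m$delta_minima_acf, m$delta_area_acf,
                    m$delta_maxima_psd, m$delta_area_psd) >= 0))
  expect_lt(m$delta_minima_acf, 0.3)
  expect_lt(m$cop_cohens_d, 0.5)
  expect_gte(m$tau_a, 1)
})
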