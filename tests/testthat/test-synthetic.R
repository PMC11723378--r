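test_that("subject sampling recovers profile medians and ranges", {
  subs <- sample_subjects(dublin_profile(), 4000, seed = 11)
  stance <- vapply(subs, function(s) s$stance_pct, numeric(1))
  speed <- vapply(subs, function(s) s$speed, numeric(1))
  expect_lt(abs(stats::median(stance) - 61.2), 0.5)
  expect_lt(abs(stats::median(speed) - 1.74), 0.02 * 1.74)
  expect_true(all(stance >= 57.8 & stance <= 66.7))
  expect_true(all(speed >= 1.16 & speed <= 2.44))
})

test_that("degenerate spatiotemporal spread collapses to the median", {
  p <- dublin_profile()
  p$spatiotemporal$stance <- c(median = 61, min = 61, max = 61)
  s <- sample_subject(p, seed = 3)
  expect_equal(s$stance_pct, 61)
})

test_that("subject sampling is seed-deterministic", {
  a <- sample_subject(madrid_profile(), seed = 42)
  b <- sample_subject(madrid_profile(), seed = 42)
  expect_identical(a, b)
})

test_that("profile validation rejects a median outside its range", {
  expect_error(spatiotemporal_profile(speed = c(3, 1, 2),
                                      cadence = c(2, 1, 3),
                                      stance = c(61, 58, 67)),
               "min <= median <= max")
  expect_error(spatiotemporal_profile(speed = c(1.7, 1.2, 2.4),
                                      cadence = c(2, 1, 3),
                                      stance = c(48, 40, 49)),
               "stance")
})

test_that("a noiseless cycle equals the deterministic warped template", {
  p <- dublin_profile(sigma_subject = 0, sigma_cycle = 0, sigma_noise = 0)
  s <- sample_subject(p, seed = 5)
  c1 <- generate_cycle(s, "hip_moment", p, seed = 1)
  c2 <- generate_cycle(s, "hip_moment", p, seed = 99)
  expect_equal(c1$values, c2$values)  # no stochastic component left
  expect_length(c1$values, 100)
  # hand-computed harmonic sum with the piecewise-linear stance warp
  tm <- p$templates[["hip_moment"]]
  st <- s$stance_pct / 100
  r <- p$reference_stance / 100
  u <- (0:99) / 100
  phi <- ifelse(u <= st, u * r / st, r + (u - st) * (1 - r) / (1 - st))
  expected <- drop(cos(outer(2 * pi * phi, 1:6) +
                         matrix(tm$theta, 100, 6, byrow = TRUE)) %*% tm$a)
  expect_equal(c1$values, expected, tolerance = 1e-12)
})

test_that("cycle generation validates signal and lab membership", {
  p <- dublin_profile()
  s <- sample_subject(p, seed = 1)
  expect_error(generate_cycle(s, "elbow_angle", p), "unknown signal")
  expect_error(generate_cycle(s, "hip_moment", madrid_profile()),
               "belongs to lab")
})

test_that("delta_init inflates only the first 30 samples", {
  p <- twin_profile(knobs = difference_knobs(delta_init = 1),
                    sigma_subject = 0, sigma_cycle = 0, sigma_noise = 0.01)
  s <- sample_subject(p, seed = 2)
  tm <- p$templates[["hip_moment"]]
  set.seed(7)
  block <- gaitshift:::gen_cycle_block(400, tm, s$eta["hip_moment", ],
                                       s$stance_pct, p)
  template <- {
    p0 <- p; p0$knobs <- difference_knobs(); p0$sigma_noise <- 0
    gaitshift:::gen_cycle_block(1, tm, s$eta["hip_moment", ],
                                s$stance_pct, p0)
  }
  resid <- sweep(block, 2, drop(template))
  expect_gt(stats::var(as.vector(resid[, 1:30])),
            4 * stats::var(as.vector(resid[, 31:100])))
})

test_that("delta_hf adds power above the 10th harmonic", {
  mk <- function(hf) {
    p <- twin_profile(knobs = difference_knobs(delta_hf = hf),
                      sigma_subject = 0, sigma_cycle = 0,
                      sigma_noise = 0.02)
    s <- sample_subject(p, seed = 4)
    set.seed(9)
    gaitshift:::gen_cycle_block(200, p$templates[["hip_moment"]],
                                s$eta["hip_moment", ], s$stance_pct, p)
  }
  hi_power <- function(block) {
    apply(block, 1, function(v) {
      psd <- welch_psd(v)
      sum(psd$values[psd$grid > 0.10])  # above the 10th cycle harmonic
    })
  }
  expect_gt(stats::median(hi_power(mk(0.5))),
            3 * stats::median(hi_power(mk(0))))
})

test_that("dataset generation respects counts, limits and determinism", {
  ds <- generate_dataset(dublin_profile(), madrid_profile(), 4, 3,
                         cycles_per_side = 2, seed = 21,
                         signals = c("hip_moment", "grf_vertical"))
  expect_equal(nrow(ds$subjects), 7)
  expect_equal(nrow(ds$cycles), 7 * 2 * 2 * 2)
  counts <- dplyr::count(ds$cycles, subject_id, side, signal)
  expect_true(all(counts$n <= 5))
  expect_true(all(ds$cycles$subject_id %in% ds$subjects$subject_id))
  expect_true(all(is.finite(ds$values)))
  ds2 <- generate_dataset(dublin_profile(), madrid_profile(), 4, 3,
                          cycles_per_side = 2, seed = 21,
                          signals = c("hip_moment", "grf_vertical"))
  expect_identical(ds$values, ds2$values)
  expect_identical(ds$cycles, ds2$cycles)
  expect_error(generate_dataset(dublin_profile(), madrid_profile(),
                                2, 2, cycles_per_side = 6),
               "cycles_per_side")
  expect_error(generate_dataset(dublin_profile(), dublin_profile(), 2, 2),
               "distinct lab_name")
})

test_that("zero knobs and identical profiles make the labs exchangeable", {
  sigs <- c("hip_moment", "grf_vertical", "knee_sagittal_angle",
            "ankle_power")
  ds <- small_dataset(n = 25, cycles_per_side = 5, seed = 31,
                      signals = sigs)
  # per-subject means are the independent units (cycles of one subject
  # share its random effect); compare their distributions per signal
  ps <- vapply(sigs, function(sig) {
    sm <- signal_matrix(ds, sig)
    m <- rowMeans(sm$values[, 31:100])
    bysub <- tapply(m, list(sm$meta$subject_id, sm$meta$lab), mean)
    a <- stats::na.omit(bysub[, "dublin"])
    b <- stats::na.omit(bysub[, "twin"])
    suppressWarnings(stats::ks.test(a, b))$p.value
  }, numeric(1))
  expect_gt(stats::median(ps), 0.01)
})

test_that("generated amplitudes stay mostly inside (-2, 2)", {
  ds <- generate_dataset(dublin_profile(), madrid_profile(), 8, 8,
                         cycles_per_side = 3, seed = 41)
  expect_gt(mean(abs(ds$values) < 2), 0.95)
})

test_that("seed folding is deterministic, bounded and index-sensitive", {
  expect_identical(fold_seed(7, 1, 2), fold_seed(7, 1, 2))
  expect_false(fold_seed(7, 1, 2) == fold_seed(7, 2, 1))
  s <- vapply(1:200, function(i) fold_seed(3, i), integer(1))
  expect_true(all(s >= 1 & s < 2^31))
  expect_false(anyDuplicated(s) > 0)
})
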