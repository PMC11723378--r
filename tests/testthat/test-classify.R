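test_that("balanced sampling equalizes laboratory counts", {
  ds <- generate_dataset(dublin_profile(), madrid_profile(), 10, 4,
                         cycles_per_side = 2, seed = 1,
                         signals = "hip_moment")
  bal <- balanced_sample(ds, "hip_moment", seed = 2)
  expect_equal(unname(table(bal$meta$lab)["dublin"]),
               unname(table(bal$meta$lab)["madrid"]))
  expect_equal(sum(bal$labels == 0), sum(bal$labels == 1))
  expect_equal(nrow(bal$values), 2 * 4 * 2 * 2)
  expect_identical(balanced_sample(ds, "hip_moment", seed = 2)$meta,
                   bal$meta)
  # equal counts in: everything retained
  dse <- generate_dataset(dublin_profile(), madrid_profile(), 4, 4,
                          cycles_per_side = 2, seed = 3,
                          signals = "hip_moment")
  expect_equal(nrow(balanced_sample(dse, "hip_moment", seed = 1)$values),
               nrow(signal_matrix(dse, "hip_moment")$values))
})

test_that("LOCO splits use floor arithmetic on the instance count", {
  fake <- list(values = matrix(0, 620, 5),
               meta = tibble::tibble(
                 subject_id = rep(sprintf("s%03d", 1:62), each = 10),
                 lab = rep(c("a", "b"), each = 310)),
               labels = rep(0:1, each = 310))
  sp <- split_instances(fake, "LOCO", 0.8, seed = 4)
  expect_length(sp$train, 496)
  expect_length(sp$test, 124)
  expect_length(intersect(sp$train, sp$test), 0)
})

test_that("LOPO keeps each subject entirely on one side", {
  ds <- generate_dataset(dublin_profile(), madrid_profile(), 8, 6,
                         cycles_per_side = 2, seed = 5,
                         signals = "hip_moment")
  bal <- balanced_sample(ds, "hip_moment", seed = 1)
  sp <- split_instances(bal, "LOPO", 0.8, seed = 2)
  expect_length(intersect(unique(bal$meta$subject_id[sp$train]),
                          unique(bal$meta$subject_id[sp$test])), 0)
  expect_equal(length(unique(bal$labels[sp$train])), 2)
  expect_equal(length(unique(bal$labels[sp$test])), 2)
  # one subject per lab cannot be partitioned
  one <- generate_dataset(dublin_profile(), madrid_profile(), 1, 1,
                          cycles_per_side = 3, seed = 6,
                          signals = "hip_moment")
  expect_error(split_instances(balanced_sample(one, "hip_moment", seed = 1),
                               "LOPO"),
               "2 subjects")
})

test_that("every architecture separates offset classes perfectly", {
  set.seed(7)
  mk <- function(n, off) {
    t(vapply(seq_len(n), function(i) rnorm(20, off, 0.2), numeric(20)))
  }
  X <- rbind(mk(40, 0), mk(40, 2))
  y <- rep(0:1, each = 40)
  idx <- sample(80)
  tr <- idx[1:60]; te <- idx[61:80]
  configs <- list(
    tiny_resnet(),
    classifier_config("cnn", desk_scale = TRUE, epochs = 30),
    classifier_config("mlp", desk_scale = TRUE, epochs = 30,
                      hidden = c(32L, 32L)),
    classifier_config("lstm", desk_scale = TRUE, epochs = 15,
                      units = 12L),
    classifier_config("transformer", desk_scale = TRUE, epochs = 40,
                      patch = 4L, blocks = 2L)
  )
  for (cfg in configs) {
    acc <- train_and_score(X[tr, ], y[tr], X[te, ], y[te], cfg, seed = 1)
    expect_equal(acc, 1, info = cfg$architecture)
  }
})

test_that("shuffled labels give chance-level accuracy", {
  set.seed(8)
  X <- matrix(rnorm(300 * 20), 300, 20)
  accs <- vapply(1:5, function(r) {
    y <- sample(rep(0:1, each = 150))
    tr <- 1:180; te <- 181:300
    train_and_score(X[tr, ], y[tr], X[te, ], y[te],
                    classifier_config("mlp", epochs = 20,
                                      hidden = c(32L, 32L)),
                    seed = r)
  }, numeric(1))
  expect_lt(abs(stats::median(accs) - 0.5), 0.1)
})

test_that("training is deterministic under a fixed seed", {
  set.seed(9)
  X <- matrix(rnorm(120 * 15), 120, 15)
  y <- rep(0:1, 60)
  a1 <- train_and_score(X[1:90, ], y[1:90], X[91:120, ], y[91:120],
                        tiny_resnet(epochs = 10), seed = 33)
  a2 <- train_and_score(X[1:90, ], y[1:90], X[91:120, ], y[91:120],
                        tiny_resnet(epochs = 10), seed = 33)
  expect_identical(a1, a2)
})

test_that("train_and_score validates its inputs", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(train_and_score(X, rep(0, 10), X, rep(0:1, 5)),
               "single class")
  expect_error(train_and_score(X, rep(0:1, 5), matrix(0, 4, 7),
                               rep(0:1, 2)),
               "lengths differ")
  expect_error(classifier_config("resnet", filters = -1), "positive")
  expect_error(classifier_config("resnet", bogus = 2), "unknown")
  expect_error(evaluation_config(train_fraction = 1.2), "train_fraction")
})

test_that("a single repetition's score is its own median", {
  ds <- small_dataset(knobs = difference_knobs(delta_amp = c(2, 1)),
                      n = 8, cycles_per_side = 2, seed = 10)
  res <- evaluate_signal(ds, "hip_moment",
                         preprocess = preprocess_preset("raw"),
                         classifier = tiny_resnet(epochs = 15),
                         evaluation = evaluation_config(n_repetitions = 1,
                                                        seed = 3))
  expect_length(res$accuracies, 1)
  expect_identical(res$score, res$accuracies[1])
})

test_that("rank standardization destroys pure amplitude differences", {
  # labs differing only by gain+offset: separable raw, chance-level after
  # the value-distribution is equalized
  ds <- small_dataset(knobs = difference_knobs(delta_amp = c(0.4, 0.6)),
                      n = 10, cycles_per_side = 3, seed = 11)
  ev <- function(preset) {
    evaluate_signal(ds, "hip_moment",
                    preprocess = preprocess_preset(preset),
                    classifier = tiny_resnet(epochs = 25),
                    evaluation = evaluation_config(n_repetitions = 5,
                                                   seed = 7))$score
  }
  expect_gt(ev("raw"), 0.9)
  expect_lt(abs(ev("standardized") - 0.5), 0.1)
})

test_that("decimation does not increase the score on HF-differing labs", {
  ds <- small_dataset(knobs = difference_knobs(delta_hf = 0.5),
                      n = 10, cycles_per_side = 3, seed = 12)
  ev <- function(factor) {
    pc <- preprocess_preset("smoothed")
    pc$downsample_factor <- factor
    evaluate_signal(ds, "hip_moment", preprocess = pc,
                    classifier = tiny_resnet(epochs = 25),
                    evaluation = evaluation_config(n_repetitions = 5,
                                                   seed = 9))$score
  }
  expect_lte(ev(10), ev(1) + 0.05)
})

test_that("localization scan covers the grid and matches single windows", {
  ds <- small_dataset(knobs = difference_knobs(delta_hf = 0.6),
                      n = 8, cycles_per_side = 2, seed = 13)
  win <- subwindows(width_pct = 70)  # the single full post-prefix window
  ev_cfg <- evaluation_config(n_repetitions = 2, seed = 5)
  scan <- localization_scan(ds, "hip_moment", windows = win,
                            classifier = tiny_resnet(epochs = 15),
                            evaluation = ev_cfg)
  expect_equal(nrow(scan$table), 1)
  expect_equal(scan$best, 1)
  direct <- evaluate_signal(ds, "hip_moment",
                            preprocess = preprocess_preset("smoothed"),
                            classifier = tiny_resnet(epochs = 15),
                            evaluation = ev_cfg)
  expect_equal(scan$table$score[1], direct$score)
})
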