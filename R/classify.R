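#' Classifier configuration
#'
#' Architecture and training hyperparameters of a lab-of-origin classifier.
#' Full-scale defaults follow the published time-series benchmarks: a
#' ResNet with 5 residual blocks of 5 convolutional layers (32 filters of
#' size 10), an MLP with two hidden layers of 320 units, a CNN with two
#' convolutional layers of 24 filters (kernel 10), a transformer with 4
#' blocks / 4 heads / embedding 4, and a 2-layer LSTM of 128 units with
#' dropout 0.5; training runs 200 epochs. The optimizer (Adam, learning
#' rate 1e-3, batch 32) is a package default, exposed here.
#'
#' `desk_scale = TRUE` switches to the reduced evaluation preset used for
#' single-CPU experimentation: 50 epochs and, for the ResNet, 3 residual
#' blocks of 2 layers with 16 filters.
#'
#' @param architecture One of `"resnet"`, `"mlp"`, `"cnn"`,
#'   `"transformer"`, `"lstm"`.
#' @param desk_scale Use the reduced preset.
#' @param epochs,learning_rate,batch_size Training loop settings.
#' @param ... Architecture-specific overrides (e.g. `filters`, `units`,
#'   `residual_blocks`).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(architecture = c("resnet", "mlp", "cnn",
                                               "transformer", "lstm"),
                              desk_scale = FALSE, epochs = NULL,
                              learning_rate = 1e-3, batch_size = 32L, ...) {
  architecture <- match.arg(architecture)
  epochs <- as.integer(epochs %||% if (desk_scale) 50L else 200L)
  if (epochs < 1) stop_gs("epochs must be >= 1")
  hyper <- switch(architecture,
    resnet = if (desk_scale) {
      list(residual_blocks = 3L, layers_per_block = 2L, filters = 16L,
           kernel_size = 10L)
    } else {
      list(residual_blocks = 5L, layers_per_block = 5L, filters = 32L,
           kernel_size = 10L)
    },
    mlp = list(hidden = c(320L, 320L)),
    cnn = list(layers = 2L, filters = 24L, kernel_size = 10L),
    transformer = list(blocks = 4L, heads = 4L, embedding = 4L,
                       patch = 5L),
    lstm = list(layers = 2L, units = 128L, dropout = 0.5)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(hyper))
  if (length(bad)) stop_gs("unknown hyperparameters: ",
                           paste(bad, collapse = ", "))
  hyper[names(over)] <- over
  if (any(unlist(hyper[names(hyper) != "dropout"]) <= 0)) {
    stop_gs("hyperparameters must be positive")
  }
  structure(list(architecture = architecture, epochs = epochs,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 hyper = hyper, desk_scale = desk_scale),
            class = "classifier_config")
}

#' Evaluation protocol configuration
#'
#' The repeated-training protocol: each repetition draws a fresh balanced
#' sample, a fresh train/test split under the chosen cross-validation
#' scheme, and trains a fresh classifier; the classification score is the
#' median of the per-repetition test accuracies.
#'
#' @param n_repetitions Number of independent repetitions (100 at full
#'   scale; 10 in the desk-scale preset).
#' @param cv_scheme `"LOCO"` (leave-one-cycle-out: cycles split at random,
#'   a subject may appear on both sides) or `"LOPO"`
#'   (leave-one-patient-out: subjects are partitioned, so all cycles of a
#'   subject fall on one side).
#' @param train_fraction Fraction of instances (LOCO) or subjects (LOPO)
#'   assigned to training.
#' @param seed Master seed; per-repetition seeds are derived with
#'   [fold_seed()].
#' @param desk_scale If `TRUE` and `n_repetitions` is not given, use 10
#'   repetitions.
#' @return An object of class `evaluation_config`.
#' @export
evaluation_config <- function(n_repetitions = NULL,
                              cv_scheme = c("LOCO", "LOPO"),
                              train_fraction = 0.8, seed = 1L,
                              desk_scale = FALSE) {
  cv_scheme <- match.arg(cv_scheme)
  n_repetitions <- as.integer(n_repetitions %||%
                                if (desk_scale) 10L else 100L)
  if (n_repetitions < 1) stop_gs("n_repetitions must be >= 1")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_gs("train_fraction must be in (0, 1)")
  }
  structure(list(n_repetitions = n_repetitions, cv_scheme = cv_scheme,
                 train_fraction = train_fraction, seed = as.integer(seed),
                 desk_scale = desk_scale),
            class = "evaluation_config")
}

#' Balanced sample of one signal's cycles
#'
#' Returns all cycles of `signal` with equal counts per laboratory: the
#' over-represented laboratory is subsampled uniformly at random. Labels
#' are 0 for the dataset's first laboratory and 1 for the second.
#'
#' @param dataset A `gait_dataset`.
#' @param signal Canonical signal name.
#' @param seed Optional integer seed for the subsampling.
#' @return List with `meta` (cycle identities), `values` (matrix) and
#'   `labels` (0/1 integer vector).
#' @export
balanced_sample <- function(dataset, signal, seed = NULL) {
  sm <- signal_matrix(dataset, signal)
  lab_a <- dataset$config$lab_a
  lab_b <- dataset$config$lab_b
  ia <- which(sm$meta$lab == lab_a)
  ib <- which(sm$meta$lab == lab_b)
  if (!length(ia) || !length(ib)) {
    stop_gs("both laboratories must have cycles for signal '", signal, "'")
  }
  n <- min(length(ia), length(ib))
  keep <- with_seed(seed, c(
    if (length(ia) > n) sample(ia, n) else ia,
    if (length(ib) > n) sample(ib, n) else ib
  ))
  keep <- sort(keep)
  list(meta = sm$meta[keep, ],
       values = sm$values[keep, , drop = FALSE],
       labels = as.integer(sm$meta$lab[keep] == lab_b))
}

#' Train/test split under a cross-validation scheme
#'
#' LOCO assigns cycles to train/test uniformly at random, irrespective of
#' which subject they come from; LOPO partitions subjects (per laboratory)
#' so that no subject contributes cycles to both sides.
#'
#' @param sample A balanced sample from [balanced_sample()].
#' @param scheme `"LOCO"` or `"LOPO"`.
#' @param train_fraction Fraction of cycles (LOCO) or of each lab's
#'   subjects (LOPO) assigned to training.
#' @param seed Optional integer seed.
#' @return List with integer index vectors `train` and `test` into the
#'   rows of `sample$values`.
#' @export
split_instances <- function(sample, scheme = c("LOCO", "LOPO"),
                            train_fraction = 0.8, seed = NULL) {
  scheme <- match.arg(scheme)
  n <- nrow(sample$values)
  with_seed(seed, {
    if (scheme == "LOCO") {
      n_train <- floor(train_fraction * n)
      if (n_train < 1 || n_train >= n) stop_gs("degenerate split")
      train <- sample.int(n, n_train)
      test <- setdiff(seq_len(n), train)
    } else {
      labs <- unique(sample$meta$lab)
      train_subj <- character(0)
      test_subj <- character(0)
      for (lb in labs) {
        subj <- unique(sample$meta$subject_id[sample$meta$lab == lb])
        if (length(subj) < 2) {
          stop_gs("LOPO needs at least 2 subjects per laboratory")
        }
        n_tr <- max(1L, min(length(subj) - 1L,
                            round(train_fraction * length(subj))))
        tr <- sample(subj, n_tr)
        train_subj <- c(train_subj, tr)
        test_subj <- c(test_subj, setdiff(subj, tr))
      }
      train <- which(sample$meta$subject_id %in% train_subj)
      test <- which(sample$meta$subject_id %in% test_subj)
    }
    for (side in list(train, test)) {
      if (length(unique(sample$labels[side])) < 2) {
        stop_gs("degenerate split: a side is missing a laboratory")
      }
    }
    list(train = train, test = test)
  })
}

#' Train one classifier and score it on a test set
#'
#' Fits the configured architecture on the training series (softmax
#' cross-entropy, two-way output, arg-max prediction) and returns the test
#' accuracy.
#'
#' @param train_x,test_x Numeric matrices (one series per row, equal
#'   lengths).
#' @param train_y,test_y Integer 0/1 labels.
#' @param config A [classifier_config()].
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return Test accuracy in `[0, 1]`.
#' @export
train_and_score <- function(train_x, train_y, test_x, test_y,
                            config = classifier_config("resnet"),
                            seed = 1L) {
  stopifnot(inherits(config, "classifier_config"))
  if (ncol(train_x) != ncol(test_x)) {
    stop_gs("train and test series lengths differ")
  }
  if (length(unique(train_y)) < 2) {
    stop_gs("training set contains a single class")
  }
  h <- config$hyper
  arch <- config$architecture
  if (arch %in% c("resnet", "cnn")) {
    blocks <- if (arch == "resnet") h$residual_blocks else 1L
    per_block <- if (arch == "resnet") h$layers_per_block else h$layers
    res <- cpp_train_convnet(train_x, as.integer(train_y), test_x,
                             as.integer(test_y), as.integer(blocks),
                             as.integer(per_block), as.integer(h$filters),
                             as.integer(h$kernel_size), arch == "resnet",
                             config$epochs, config$batch_size,
                             config$learning_rate, as.integer(seed))
    res$accuracy
  } else if (arch == "mlp") {
    cpp_train_mlp(train_x, as.integer(train_y), test_x,
                  as.integer(test_y), as.integer(h$hidden), config$epochs,
                  config$batch_size, config$learning_rate,
                  as.integer(seed))$accuracy
  } else if (arch == "lstm") {
    train_lstm(train_x, train_y, test_x, test_y, units = h$units,
               n_layers = h$layers, dropout = h$dropout,
               epochs = config$epochs, batch = config$batch_size,
               lr = config$learning_rate, seed = seed)
  } else {
    train_transformer(train_x, train_y, test_x, test_y,
                      blocks = h$blocks, heads = h$heads,
                      embed = h$embedding, patch = h$patch,
                      epochs = config$epochs, batch = config$batch_size,
                      lr = config$learning_rate, seed = seed)
  }
}

#' Repeated balanced evaluation of one signal
#'
#' The full per-signal protocol: for each repetition, draw a balanced
#' sample, preprocess, split under the chosen scheme, train a fresh
#' classifier and record its test accuracy. The classification score is
#' the median accuracy over repetitions.
#'
#' @param dataset A `gait_dataset`.
#' @param signal Canonical signal name.
#' @param preprocess A [preprocess_config()] (or preset).
#' @param classifier A [classifier_config()].
#' @param evaluation An [evaluation_config()].
#' @return A `classification_result`: list with `signal`, `accuracies`
#'   (length `n_repetitions`), `score` (their median), the configs and the
#'   master seed.
#' @export
evaluate_signal <- function(dataset, signal,
                            preprocess = preprocess_preset("smoothed"),
                            classifier = classifier_config("resnet",
                                                           desk_scale = TRUE),
                            evaluation = evaluation_config(desk_scale = TRUE)) {
  stopifnot(inherits(evaluation, "evaluation_config"))
  sm <- signal_matrix(dataset, signal)
  proc <- preprocess_matrix(sm$values, preprocess)
  accs <- vapply(seq_len(evaluation$n_repetitions), function(r) {
    bal <- balanced_sample_pre(dataset, signal, sm$meta, proc,
                               seed = fold_seed(evaluation$seed, 1, r))
    sp <- split_instances(bal, evaluation$cv_scheme,
                          evaluation$train_fraction,
                          seed = fold_seed(evaluation$seed, 2, r))
    train_and_score(bal$values[sp$train, , drop = FALSE],
                    bal$labels[sp$train],
                    bal$values[sp$test, , drop = FALSE],
                    bal$labels[sp$test],
                    classifier, seed = fold_seed(evaluation$seed, 3, r))
  }, numeric(1))
  structure(list(signal = signal, accuracies = accs,
                 score = stats::median(accs),
                 preprocess = preprocess, classifier = classifier,
                 evaluation = evaluation, seed = evaluation$seed),
            class = "classification_result")
}

# balanced_sample() on already-preprocessed values
balanced_sample_pre <- function(dataset, signal, meta, proc, seed) {
  lab_a <- dataset$config$lab_a
  lab_b <- dataset$config$lab_b
  ia <- which(meta$lab == lab_a)
  ib <- which(meta$lab == lab_b)
  if (!length(ia) || !length(ib)) {
    stop_gs("both laboratories must have cycles for signal '", signal, "'")
  }
  n <- min(length(ia), length(ib))
  keep <- with_seed(seed, c(
    if (length(ia) > n) sample(ia, n) else ia,
    if (length(ib) > n) sample(ib, n) else ib
  ))
  keep <- sort(keep)
  list(meta = meta[keep, ], values = proc[keep, , drop = FALSE],
       labels = as.integer(meta$lab[keep] == lab_b))
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result> ", x$signal, " (",
      x$classifier$architecture, ", ", x$evaluation$cv_scheme, "): score ",
      format(x$score, digits = 3), " over ",
      length(x$accuracies), " repetitions\n", sep = "")
  invisible(x)
}

#' Localization scan over sub-windows of the gait cycle
#'
#' Evaluates the lab-of-origin classifier on each sub-window of the cycle
#' (see [subwindows()]) and reports the window with the highest
#' classification score (ties broken toward the earliest window).
#'
#' @inheritParams evaluate_signal
#' @param windows Tibble of half-open sample ranges from [subwindows()].
#' @return List with `table` (tibble: window start/end and score) and
#'   `best` (row index of the best window).
#' @export
localization_scan <- function(dataset, signal, windows = subwindows(),
                              preprocess = preprocess_preset("smoothed"),
                              classifier = classifier_config("resnet",
                                                             desk_scale = TRUE),
                              evaluation = evaluation_config(desk_scale = TRUE)) {
  if (!nrow(windows)) stop_gs("empty window set")
  scores <- vapply(seq_len(nrow(windows)), function(i) {
    pc <- preprocess
    pc$subwindow <- c(windows$start[i], windows$end[i])
    evaluate_signal(dataset, signal, pc, classifier, evaluation)$score
  }, numeric(1))
  tab <- dplyr::mutate(windows, score = scores)
  list(table = tab, best = which.max(scores))
}
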