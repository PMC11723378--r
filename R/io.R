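#' Write / read a gait dataset as portable CSV
#'
#' The dataset is stored in long format (`cycles.csv`: one row per sample,
#' columns `subject_id`, `lab`, `side`, `cycle_index`, `signal`, `epoch`
#' 0-99, `value`), together with the subject table (`subjects.csv`) and a
#' YAML snapshot of the generation configuration (`config.yaml`: labs,
#' sizes, seed, difference knobs and variance components).
#'
#' @param dataset A `gait_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_gait_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "gait_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- dataset$cycles
  n <- nrow(m)
  long <- data.frame(
    subject_id = rep(m$subject_id, each = 100),
    lab = rep(m$lab, each = 100),
    side = rep(m$side, each = 100),
    cycle_index = rep(m$cycle_index, each = 100),
    signal = rep(m$signal, each = 100),
    epoch = rep(0:99, n),
    value = as.vector(t(dataset$values))
  )
  utils::write.csv(long, file.path(dir, "cycles.csv"), row.names = FALSE)
  utils::write.csv(dataset$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  cfg <- dataset$config
  snap <- list(
    lab_a = cfg$lab_a, lab_b = cfg$lab_b, n_a = cfg$n_a, n_b = cfg$n_b,
    cycles_per_side = cfg$cycles_per_side, signals = cfg$signals,
    seed = dataset$seed,
    knobs = lapply(cfg$profiles, function(p) {
      k <- p$knobs
      list(delta_init = k$delta_init, delta_hf = k$delta_hf,
           delta_warp = k$delta_warp,
           delta_amp = as.list(k$delta_amp), delta_freq = k$delta_freq)
    })
  )
  yaml::write_yaml(snap, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_gait_dataset
#' @export
read_gait_dataset <- function(dir) {
  long <- utils::read.csv(file.path(dir, "cycles.csv"),
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "lab", "side", "cycle_index", "signal", "epoch",
            "value")
  if (!all(need %in% names(long))) {
    stop_gs("cycles.csv lacks required columns")
  }
  long <- long[order(match(long$subject_id, unique(long$subject_id)),
                     match(long$signal, unique(long$signal)),
                     long$side, long$cycle_index, long$epoch), ]
  key <- paste(long$subject_id, long$signal, long$side, long$cycle_index)
  first <- !duplicated(key)
  meta <- tibble::as_tibble(long[first, c("subject_id", "lab", "side",
                                          "cycle_index", "signal")])
  values <- matrix(long$value, nrow = sum(first), ncol = 100, byrow = TRUE)
  subjects <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "subjects.csv"),
                    stringsAsFactors = FALSE))
  snap_path <- file.path(dir, "config.yaml")
  snap <- if (file.exists(snap_path)) yaml::read_yaml(snap_path) else NULL
  labs <- unique(meta$lab)
  structure(list(
    cycles = meta, values = values, subjects = subjects,
    seed = snap$seed,
    config = list(lab_a = snap$lab_a %||% labs[1],
                  lab_b = snap$lab_b %||% labs[2],
                  profiles = NULL,
                  n_a = snap$n_a, n_b = snap$n_b,
                  cycles_per_side = snap$cycles_per_side,
                  signals = snap$signals %||% unique(meta$signal),
                  snapshot = snap)
  ), class = "gait_dataset")
}
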