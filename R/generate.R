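# Synthesize `n` cycles of one signal for one subject.
#
# Each cycle is a harmonic waveform over normalized time, warped so the
# subject's stance fraction lines up with the template's reference stance,
# plus hierarchical noise:
#   y(i) = gain * sum_k a_k (1 + eta_k) cos(2 pi k phi(i/100) + theta_k + xi_k)
#          + offset + e_init(i) + e_hf(i) + e_0(i)
# with xi_k = k * dc + nu_k, dc ~ N(0, sigma_cycle) a common per-cycle
# time-origin/period perturbation and nu_k ~ N(0, delta_freq) the
# per-harmonic jitter knob; e_init is white noise on samples 1..30 only
# (SD delta_init), e_hf is high-pass noise (power above the profile's
# cutoff harmonic, SD delta_hf) and e_0 baseline white noise.
gen_cycle_block <- function(n, template, eta_row, stance_pct, profile) {
  k_harm <- length(template$a)
  knobs <- profile$knobs
  s <- (stance_pct + knobs$delta_warp) / 100
  s <- min(max(s, 0.40), 0.80)
  r <- profile$reference_stance / 100
  u <- (0:99) / 100
  phi <- ifelse(u <= s, u * r / s, r + (u - s) * (1 - r) / (1 - s))
  amp <- template$a * (1 + eta_row)
  gain <- 1 + knobs$delta_amp[["gain"]]
  offset <- knobs$delta_amp[["offset"]]
  base_arg <- outer(2 * pi * phi, seq_len(k_harm)) +
    matrix(template$theta, 100, k_harm, byrow = TRUE)

  out <- matrix(0, n, 100)
  for (c_i in seq_len(n)) {
    dc <- stats::rnorm(1, 0, profile$sigma_cycle)
    nu <- if (knobs$delta_freq > 0) {
      stats::rnorm(k_harm, 0, knobs$delta_freq)
    } else {
      numeric(k_harm)
    }
    xi <- seq_len(k_harm) * dc + nu
    wave <- drop(cos(base_arg + matrix(xi, 100, k_harm, byrow = TRUE)) %*% amp)
    y <- gain * wave + offset
    if (knobs$delta_init > 0) {
      y[1:30] <- y[1:30] + stats::rnorm(30, 0, knobs$delta_init)
    }
    if (knobs$delta_hf > 0) {
      y <- y + highpass_noise(100, profile$hf_cutoff_harmonic) * knobs$delta_hf
    }
    if (profile$sigma_noise > 0) {
      y <- y + stats::rnorm(100, 0, profile$sigma_noise)
    }
    out[c_i, ] <- y
  }
  out
}

# White noise restricted to harmonics above `cutoff` (unit SD).
highpass_noise <- function(len, cutoff) {
  w <- stats::fft(stats::rnorm(len))
  keep <- rep(TRUE, len)
  keep[1] <- FALSE                                   # DC
  if (cutoff >= 1) {
    keep[2:(cutoff + 1)] <- FALSE                    # positive harmonics
    keep[(len - cutoff + 1):len] <- FALSE            # negative harmonics
  }
  z <- Re(stats::fft(w * keep, inverse = TRUE)) / len
  z / stats::sd(z)
}

#' Generate a single gait cycle
#'
#' Draws one cycle of `signal` for `subject` under `profile`'s generative
#' model; see [generate_dataset()] for the model description. Mainly useful
#' for inspecting the generator; whole datasets should be produced with
#' [generate_dataset()].
#'
#' @param subject A `gait_subject` from [sample_subject()].
#' @param signal Canonical signal name (see [canonical_signal_set()]).
#' @param profile The subject's [lab_profile()].
#' @param seed Optional integer seed.
#' @param side `"L"` or `"R"` label attached to the cycle.
#' @param cycle_index Cycle number (1..5) attached to the cycle.
#' @return A `gait_cycle` list with the cycle identity fields and `values`,
#'   a numeric vector of length 100 (one sample per % of the gait cycle).
#' @export
generate_cycle <- function(subject, signal, profile, seed = NULL,
                           side = "L", cycle_index = 1L) {
  stopifnot(inherits(subject, "gait_subject"), inherits(profile, "lab_profile"))
  check_signal(signal)
  if (subject$lab_name != profile$lab_name) {
    stop_gs("subject belongs to lab '", subject$lab_name,
            "', not to profile '", profile$lab_name, "'")
  }
  vals <- with_seed(seed,
    gen_cycle_block(1, profile$templates[[signal]], subject$eta[signal, ],
                    subject$stance_pct, profile))
  structure(list(subject_id = subject$subject_id, lab = subject$lab_name,
                 side = side, cycle_index = as.integer(cycle_index),
                 signal = signal, values = drop(vals)),
            class = "gait_cycle")
}

#' Generate a two-laboratory synthetic gait dataset
#'
#' Draws `n_a` subjects from `profile_a` and `n_b` from `profile_b`, then
#' for every subject, signal and side generates `cycles_per_side` gait
#' cycles of 100 samples each. Left and right cycles are i.i.d. given the
#' subject. The full procedure is deterministic given `seed`.
#'
#' @param profile_a,profile_b [lab_profile()] objects with distinct
#'   `lab_name`s (e.g. [dublin_profile()] and [madrid_profile()]).
#' @param n_a,n_b Number of subjects per laboratory (>= 1).
#' @param cycles_per_side Cycles per subject per side, between 1 and 5.
#' @param seed Optional integer seed.
#' @param signals Character vector of canonical signal names to generate
#'   (default: all 24).
#' @return A `gait_dataset`: list with `cycles` (tibble of cycle identities:
#'   `subject_id`, `lab`, `side`, `cycle_index`, `signal`), `values` (numeric
#'   matrix, one row per cycle, 100 columns), `subjects` (tibble), `seed`
#'   and `config` (generation snapshot).
#' @export
#' @examples
#' ds <- generate_dataset(dublin_profile(), madrid_profile(), 4, 3,
#'                        cycles_per_side = 2, seed = 1,
#'                        signals = "hip_moment")
#' nrow(ds$cycles)  # (4 + 3) subjects x 2 sides x 2 cycles
generate_dataset <- function(profile_a, profile_b, n_a = 96, n_b = 31,
                             cycles_per_side = 5, seed = NULL,
                             signals = NULL) {
  stopifnot(inherits(profile_a, "lab_profile"),
            inherits(profile_b, "lab_profile"))
  if (n_a < 1 || n_b < 1) stop_gs("n_a and n_b must be >= 1")
  if (cycles_per_side < 1 || cycles_per_side > 5) {
    stop_gs("cycles_per_side must be between 1 and 5")
  }
  if (profile_a$lab_name == profile_b$lab_name) {
    stop_gs("the two profiles must have distinct lab_name")
  }
  signals <- signals %||% canonical_signal_set()$signal
  vapply(signals, check_signal, character(1))

  with_seed(seed, {
    subjects <- c(sample_subjects(profile_a, n_a),
                  sample_subjects(profile_b, n_b))
    profiles <- stats::setNames(list(profile_a, profile_b),
                                c(profile_a$lab_name, profile_b$lab_name))
    cps <- as.integer(cycles_per_side)
    n_block <- 2L * cps                       # L then R cycles per signal
    n_rows <- length(subjects) * length(signals) * n_block
    values <- matrix(NA_real_, n_rows, 100)
    meta <- vector("list", length(subjects) * length(signals))
    row0 <- 0L
    bi <- 0L
    for (subj in subjects) {
      prof <- profiles[[subj$lab_name]]
      for (sig in signals) {
        block <- gen_cycle_block(n_block, prof$templates[[sig]],
                                 subj$eta[sig, ], subj$stance_pct, prof)
        values[row0 + seq_len(n_block), ] <- block
        bi <- bi + 1L
        meta[[bi]] <- tibble::tibble(
          subject_id = subj$subject_id, lab = subj$lab_name,
          side = rep(c("L", "R"), each = cps),
          cycle_index = rep(seq_len(cps), 2L), signal = sig
        )
        row0 <- row0 + n_block
      }
    }
    structure(list(
      cycles = dplyr::bind_rows(meta),
      values = values,
      subjects = subjects_to_tibble(subjects),
      seed = seed,
      config = list(lab_a = profile_a$lab_name, lab_b = profile_b$lab_name,
                    profiles = profiles, n_a = n_a, n_b = n_b,
                    cycles_per_side = cps, signals = signals)
    ), class = "gait_dataset")
  })
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat("<gait_dataset> ", nrow(x$subjects), " subjects (",
      paste(sprintf("%s: %d", names(table(x$subjects$lab)),
                    as.integer(table(x$subjects$lab))), collapse = ", "),
      "), ", nrow(x$cycles), " cycles, ",
      length(x$config$signals), " signals, ",
      x$config$cycles_per_side, " cycles/side\n", sep = "")
  invisible(x)
}

#' Extract one signal's cycles as a matrix
#'
#' @param dataset A `gait_dataset`.
#' @param signal Canonical signal name present in the dataset.
#' @return List with `meta` (tibble of cycle identities) and `values`
#'   (matrix, one cycle per row).
#' @export
signal_matrix <- function(dataset, signal) {
  stopifnot(inherits(dataset, "gait_dataset"))
  idx <- which(dataset$cycles$signal == signal)
  if (!length(idx)) stop_gs("signal '", signal, "' not in dataset")
  list(meta = dataset$cycles[idx, ], values = dataset$values[idx, , drop = FALSE])
}
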