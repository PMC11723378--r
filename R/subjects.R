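# Median-anchored triangular draw on [lo, hi] with P(X <= med) = 1/2.
# A fair coin picks the rising left piece on [lo, med] or the falling right
# piece on [med, hi]; each piece is a triangular density peaking at the
# median, so the population median is exactly `med` while the support is
# exactly [lo, hi]. Degenerate ranges collapse to the median.
rtri_median <- function(n, med, lo, hi) {
  if (lo > med || med > hi) stop_gs("need min <= median <= max")
  left <- stats::runif(n) < 0.5
  v <- sqrt(stats::runif(n))
  ifelse(left,
         med - (med - lo) * (1 - v),
         med + (hi - med) * (1 - v))
}

#' Draw synthetic subjects from a laboratory profile
#'
#' Samples subject-level parameters: demographics, spatiotemporal gait
#' values (normalized walking speed, cadence, stance time) drawn from
#' median-anchored triangular distributions on the profile's
#' `[min, max]` ranges (so the population median equals the profile
#' median), and a per-signal, per-harmonic amplitude-perturbation matrix
#' `eta` with SD `sigma_subject` (the subject effect shared by all of that
#' subject's cycles).
#'
#' @param profile A [lab_profile()].
#' @param n Number of subjects to draw.
#' @param seed Optional integer seed; the ambient RNG is used when `NULL`.
#' @param id_prefix Prefix for generated subject ids.
#' @return A list of `gait_subject` objects (for `n = 1`,
#'   `sample_subject()` returns the single subject directly). Each subject
#'   has fields `subject_id`, `lab_name`, `sex`, `age`, `weight`, `height`,
#'   `speed`, `cadence`, `stance_pct` and the `eta` matrix
#'   (signals x harmonics).
#' @export
#' @examples
#' s <- sample_subject(dublin_profile(), seed = 1)
#' s$stance_pct
sample_subjects <- function(profile, n, seed = NULL, id_prefix = NULL) {
  stopifnot(inherits(profile, "lab_profile"))
  sp <- profile$spatiotemporal
  id_prefix <- id_prefix %||% paste0(profile$lab_name, "_")
  n_sig <- nrow(canonical_signal_set())
  k_harm <- length(profile$templates[[1]]$a)
  with_seed(seed, {
    speed <- rtri_median(n, sp$speed[1], sp$speed[2], sp$speed[3])
    cadence <- rtri_median(n, sp$cadence[1], sp$cadence[2], sp$cadence[3])
    stance <- rtri_median(n, sp$stance[1], sp$stance[2], sp$stance[3])
    age <- stats::runif(n, sp$age_range[1], sp$age_range[2])
    weight <- rtri_median(n, sp$weight[1], sp$weight[2], sp$weight[3])
    height <- rtri_median(n, sp$height[1], sp$height[2], sp$height[3])
    sex <- ifelse(stats::runif(n) < sp$sex_ratio, "F", "M")
    lapply(seq_len(n), function(i) {
      structure(list(
        subject_id = sprintf("%s%03d", id_prefix, i),
        lab_name = profile$lab_name,
        sex = sex[i], age = age[i], weight = weight[i], height = height[i],
        speed = speed[i], cadence = cadence[i], stance_pct = stance[i],
        eta = matrix(stats::rnorm(n_sig * k_harm, 0, profile$sigma_subject),
                     n_sig, k_harm,
                     dimnames = list(canonical_signal_set()$signal, NULL))
      ), class = "gait_subject")
    })
  })
}

#' @rdname sample_subjects
#' @export
sample_subject <- function(profile, seed = NULL) {
  sample_subjects(profile, 1L, seed = seed)[[1]]
}

subjects_to_tibble <- function(subjects) {
  dplyr::bind_rows(lapply(subjects, function(s) {
    tibble::tibble(subject_id = s$subject_id, lab = s$lab_name, sex = s$sex,
                   age = s$age, weight = s$weight, height = s$height,
                   speed = s$speed, cadence = s$cadence,
                   stance_pct = s$stance_pct)
  }))
}
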