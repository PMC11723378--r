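#' Spatiotemporal profile of a laboratory's subject population
#'
#' Median and range of the spatiotemporal gait parameters of the children
#' assessed in one laboratory, plus demographic ranges. Each gait parameter
#' is a numeric triple `c(median, min, max)`.
#'
#' @param speed Normalized walking speed (1/s), `c(median, min, max)`.
#' @param cadence Cadence (steps/s), `c(median, min, max)`.
#' @param stance Stance time (% of gait cycle), `c(median, min, max)`;
#'   the median must lie in (50, 75).
#' @param age_range Age range in years, `c(min, max)`.
#' @param sex_ratio Proportion of female subjects in `[0, 1]`.
#' @param weight Body weight (kg), `c(median, min, max)`.
#' @param height Body height (m), `c(median, min, max)`.
#' @return An object of class `spatiotemporal_profile`.
#' @export
spatiotemporal_profile <- function(speed, cadence, stance,
                                   age_range = c(4, 16), sex_ratio = 0.5,
                                   weight = c(30, 15, 95),
                                   height = c(1.37, 1.0, 1.85)) {
  triple <- function(x, nm) {
    if (length(x) != 3 || anyNA(x)) {
      stop_gs(nm, " must be c(median, min, max)")
    }
    x <- as.numeric(x)
    if (!(x[2] <= x[1] && x[1] <= x[3])) {
      stop_gs(nm, ": need min <= median <= max")
    }
    stats::setNames(x, c("median", "min", "max"))
  }
  out <- list(
    speed = triple(speed, "speed"),
    cadence = triple(cadence, "cadence"),
    stance = triple(stance, "stance"),
    age_range = as.numeric(age_range),
    sex_ratio = as.numeric(sex_ratio),
    weight = triple(weight, "weight"),
    height = triple(height, "height")
  )
  if (out$stance[["median"]] <= 50 || out$stance[["median"]] >= 75) {
    stop_gs("stance median must lie in (50, 75) % of the gait cycle")
  }
  structure(out, class = "spatiotemporal_profile")
}

#' Inter-laboratory difference knobs
#'
#' Controllable generator parameters that inject the qualitative differences
#' observed between gait laboratories. With all knobs at zero (and identical
#' templates and spatiotemporal profiles) the two laboratories' generative
#' distributions are identical, which is the exchangeability baseline used
#' for null calibration.
#'
#' @param delta_init SD (>= 0) of extra white noise added to the first 30
#'   samples of each cycle (larger initial-double-support fluctuations).
#' @param delta_hf Gain (>= 0) of high-frequency noise whose power is
#'   concentrated above the `hf_cutoff_harmonic` of the lab profile.
#' @param delta_warp Signed shift of the subjects' stance fraction, in
#'   percentage points of the gait cycle.
#' @param delta_amp Length-2 numeric `c(gain, offset)`: multiplicative gain
#'   added to 1 and additive offset applied to the whole cycle.
#' @param delta_freq SD (>= 0, radians) of extra per-harmonic phase jitter
#'   drawn independently per cycle (perturbs the oscillation frequency
#'   content).
#' @return An object of class `difference_knobs`.
#' @export
difference_knobs <- function(delta_init = 0, delta_hf = 0, delta_warp = 0,
                             delta_amp = c(gain = 0, offset = 0),
                             delta_freq = 0) {
  if (delta_init < 0 || delta_hf < 0 || delta_freq < 0) {
    stop_gs("delta_init, delta_hf and delta_freq must be >= 0")
  }
  if (length(delta_amp) == 1) delta_amp <- c(gain = delta_amp, offset = 0)
  delta_amp <- stats::setNames(as.numeric(delta_amp), c("gain", "offset"))
  structure(list(delta_init = delta_init, delta_hf = delta_hf,
                 delta_warp = delta_warp, delta_amp = delta_amp,
                 delta_freq = delta_freq),
            class = "difference_knobs")
}

# all-zero knob test (exchangeability baseline)
knobs_all_zero <- function(k) {
  k$delta_init == 0 && k$delta_hf == 0 && k$delta_warp == 0 &&
    all(k$delta_amp == 0) && k$delta_freq == 0
}

#' Default harmonic waveform templates
#'
#' One Fourier template per canonical signal: amplitudes `a[k]` and phases
#' `theta[k]` for harmonics `k = 1..6` of the gait cycle. The waveform of a
#' noiseless cycle is `sum_k a_k cos(2 pi k u + theta_k)` over normalized
#' time `u`. Amplitudes are scaled so each template peaks at 1.3 (unitless),
#' keeping generated samples mostly inside (-2, 2) under the default noise
#' levels. Kinematic signals are dominated by the first harmonic (one
#' oscillation per stride), vertical GRF and the kinetic (moment/power)
#' signals by the second (the double-bump pattern of stance), a mix
#' calibrated once so that the median autocorrelation of preprocessed
#' kinetic cycles attains its minimum near lag 30. The per-signal phase
#' offsets de-synchronize the signals without changing their correlation
#' structure.
#'
#' @return Named list (one entry per canonical signal) of lists with
#'   numeric vectors `a` and `theta` of length 6.
#' @export
default_waveform_templates <- function() {
  sigs <- canonical_signal_set()
  base <- list(
    kinematic = c(1.00, 0.35, 0.12, 0.05, 0.025, 0.012),
    grf_ml_ap = c(0.80, 0.50, 0.20, 0.08, 0.040, 0.020),
    grf_vert  = c(0.45, 0.95, 0.25, 0.10, 0.050, 0.020),
    kinetic   = c(0.70, 0.90, 0.12, 0.06, 0.030, 0.015)
  )
  # calibrated phases of the two leading harmonics of the kinetic signals
  # (frozen: they place the post-truncation median ACF minimum at lag 30)
  kinetic_theta12 <- c(0.0, 1.8)
  out <- vector("list", nrow(sigs))
  names(out) <- sigs$signal
  for (i in seq_len(nrow(sigs))) {
    cat_i <- sigs$category[i]
    kinetic <- cat_i %in% c("moment", "power")
    a <- switch(cat_i,
      kinematic = base$kinematic,
      grf = if (sigs$target[i] == "vertical") base$grf_vert else base$grf_ml_ap,
      moment = base$kinetic,
      power = base$kinetic
    )
    theta <- 0.25 * seq_len(6) + 0.4 * ((i - 1) %% 7 - 3) / 3
    if (kinetic) theta[1:2] <- kinetic_theta12
    # scale so the noiseless waveform peaks at 1.3
    u <- (0:999) / 1000
    wave <- drop(cos(outer(2 * pi * u, seq_len(6)) +
                       matrix(theta, 1000, 6, byrow = TRUE)) %*% a)
    a <- a * 1.3 / max(abs(wave))
    out[[i]] <- list(a = a, theta = theta)
  }
  out
}

#' Laboratory generative profile
#'
#' Full parameterization of one laboratory's synthetic gait generator: the
#' spatiotemporal profile of its population, per-signal harmonic waveform
#' templates, the variance components of the hierarchical noise model and
#' the inter-laboratory difference knobs.
#'
#' @param lab_name Laboratory label (used in generated datasets).
#' @param spatiotemporal A [spatiotemporal_profile()].
#' @param templates Named list of harmonic templates, one per canonical
#'   signal (see [default_waveform_templates()]).
#' @param sigma_subject SD of the per-subject relative perturbation of each
#'   harmonic amplitude (subject effect).
#' @param sigma_cycle SD (radians) of the per-cycle common phase
#'   perturbation; harmonic `k` receives `k` times the draw, i.e. a small
#'   random shift of the cycle's time origin/period.
#' @param sigma_noise SD of baseline white measurement noise.
#' @param knobs A [difference_knobs()] object.
#' @param hf_cutoff_harmonic High-frequency noise injected by `delta_hf` has
#'   its power above this harmonic of the cycle.
#' @param reference_stance Stance fraction (% of cycle) at which the
#'   templates are defined; a subject's drawn stance warps the waveform
#'   from this reference.
#' @return An object of class `lab_profile`.
#' @export
lab_profile <- function(lab_name, spatiotemporal,
                        templates = default_waveform_templates(),
                        sigma_subject = 0.15, sigma_cycle = 0.05,
                        sigma_noise = 0.05,
                        knobs = difference_knobs(),
                        hf_cutoff_harmonic = 10,
                        reference_stance = 61.5) {
  stopifnot(inherits(spatiotemporal, "spatiotemporal_profile"),
            inherits(knobs, "difference_knobs"))
  if (sigma_subject < 0 || sigma_cycle < 0 || sigma_noise < 0) {
    stop_gs("variance components must be >= 0")
  }
  missing_t <- setdiff(canonical_signal_set()$signal, names(templates))
  if (length(missing_t)) {
    stop_gs("templates missing for: ", paste(missing_t, collapse = ", "))
  }
  structure(list(lab_name = lab_name, spatiotemporal = spatiotemporal,
                 templates = templates, sigma_subject = sigma_subject,
                 sigma_cycle = sigma_cycle, sigma_noise = sigma_noise,
                 knobs = knobs, hf_cutoff_harmonic = hf_cutoff_harmonic,
                 reference_stance = reference_stance),
            class = "lab_profile")
}

#' Built-in laboratory profiles
#'
#' Two ready-made profiles calibrated to the published demographic and
#' spatiotemporal summaries of the two reference laboratories: a Dublin-like
#' population (n = 96 in the original cohort; faster, shorter stance) and a
#' Madrid-like population (n = 31; slower walking on a shorter walkway,
#' longer stance). The Dublin-like profile carries all-zero difference
#' knobs; inter-laboratory differences beyond the spatiotemporal contrast
#' are injected through the `knobs` of the Madrid-like profile.
#'
#' @param knobs A [difference_knobs()] object (Madrid-like profile only;
#'   the Dublin-like profile is the zero-knob reference).
#' @param ... Passed on to [lab_profile()] (e.g. `sigma_subject`).
#' @return A `lab_profile`.
#' @export
dublin_profile <- function(...) {
  lab_profile(
    "dublin",
    spatiotemporal_profile(
      speed = c(1.74, 1.16, 2.44),
      cadence = c(2.18, 1.70, 2.95),
      stance = c(61.2, 57.8, 66.7),
      age_range = c(4, 16), sex_ratio = 0.50,
      weight = c(31.3, 14.6, 94.7),
      height = c(1.37, 1.05, 1.83)
    ),
    ...
  )
}

#' @rdname dublin_profile
#' @export
madrid_profile <- function(knobs = difference_knobs(), ...) {
  lab_profile(
    "madrid",
    spatiotemporal_profile(
      speed = c(1.49, 1.15, 2.03),
      cadence = c(1.92, 1.56, 2.73),
      stance = c(63.3, 60.2, 66.8),
      age_range = c(5, 16), sex_ratio = 12 / 31,
      weight = c(28.6, 18.5, 75.3),
      height = c(1.38, 1.00, 1.82)
    ),
    knobs = knobs,
    ...
  )
}
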