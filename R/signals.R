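#' The canonical set of gait-cycle signals
#'
#' Enumerates the 24 signals recorded per gait cycle in a standard clinical
#' gait analysis: 15 kinematic joint-angle trajectories (5 joints -- pelvis,
#' hip, knee, ankle, forefoot -- in the sagittal, coronal and transverse
#' planes), 3 ground-reaction-force components (mediolateral,
#' anteroposterior, vertical), and hip/knee/ankle moment and power time
#' series in the sagittal plane. The third GRF component is sometimes
#' labelled "sagittal" in the clinical literature; this package names it
#' `vertical`.
#'
#' The order is fixed and documented: kinematics first (joints in the order
#' above, planes sagittal/coronal/transverse within each joint), then GRFs,
#' then moments, then powers.
#'
#' @return A tibble with one row per signal and columns `signal`
#'   (unique canonical name), `category` (`kinematic`, `grf`, `moment`,
#'   `power`), `target` (joint or force component) and `plane`.
#' @export
#' @examples
#' sigs <- canonical_signal_set()
#' table(sigs$category)
canonical_signal_set <- function() {
  joints <- c("pelvis", "hip", "knee", "ankle", "forefoot")
  planes <- c("sagittal", "coronal", "transverse")
  kin <- expand.grid(plane = planes, target = joints,
                     stringsAsFactors = FALSE)[, 2:1]
  kin <- tibble::tibble(
    signal = paste(kin$target, kin$plane, "angle", sep = "_"),
    category = "kinematic", target = kin$target, plane = kin$plane
  )
  grf <- tibble::tibble(
    signal = paste0("grf_", c("mediolateral", "anteroposterior", "vertical")),
    category = "grf",
    target = c("mediolateral", "anteroposterior", "vertical"),
    plane = "sagittal"
  )
  mom <- tibble::tibble(
    signal = paste0(c("hip", "knee", "ankle"), "_moment"),
    category = "moment", target = c("hip", "knee", "ankle"),
    plane = "sagittal"
  )
  pow <- tibble::tibble(
    signal = paste0(c("hip", "knee", "ankle"), "_power"),
    category = "power", target = c("hip", "knee", "ankle"),
    plane = "sagittal"
  )
  dplyr::bind_rows(kin, grf, mom, pow)
}

# internal: validate a signal name against the canonical set
check_signal <- function(signal) {
  ok <- canonical_signal_set()$signal
  if (!signal %in% ok) {
    stop_gs("unknown signal '", signal, "'; see canonical_signal_set()")
  }
  signal
}
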