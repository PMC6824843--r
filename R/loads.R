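#' The canonical set of eight joint-torque load combinations
#'
#' Step torques applied at the shoulder and/or elbow span joint-torque space
#' at 45 degree intervals: four single-joint loads of 0.20 Nm (shoulder or
#' elbow, flexion or extension) and four multi-joint loads of 0.14 Nm at each
#' joint. Flexion torque is positive at both joints; the angle is measured
#' counter-clockwise from the shoulder-flexion axis, so the shoulder axis is
#' 0 degrees and the elbow axis 90 degrees.
#'
#' @return A data frame with one row per load combination, ordered by angle:
#'   `index` (0-7), `label` (e.g. `"SF"`, `"SE/EF"`), `shoulder_torque_nm`,
#'   `elbow_torque_nm`, and `angle_deg` in `[0, 360)`.
#' @examples
#' canonical_load_set()
#' @export
canonical_load_set <- function() {
  single <- 0.20
  multi <- 0.14
  loads <- data.frame(
    index = 0:7,
    label = c("SF", "SF/EF", "EF", "SE/EF", "SE", "SE/EE", "EE", "SF/EE"),
    shoulder_torque_nm = c(single, multi, 0, -multi, -single, -multi, 0, multi),
    elbow_torque_nm = c(0, multi, single, multi, 0, -multi, -single, -multi),
    angle_deg = seq(0, 315, by = 45),
    stringsAsFactors = FALSE
  )
  stopifnot(all(abs(load_angle(loads$shoulder_torque_nm, loads$elbow_torque_nm) -
                      loads$angle_deg) < 1e-9))
  loads
}

#' Angle of a torque vector in joint-torque space
#'
#' @param shoulder_torque_nm,elbow_torque_nm torque components in Nm
#'   (flexion positive).
#' @return Angle in degrees in `[0, 360)`.
#' @export
load_angle <- function(shoulder_torque_nm, elbow_torque_nm) {
  a <- atan2(elbow_torque_nm, shoulder_torque_nm) * 180 / pi
  (a + 360) %% 360
}

#' Match torque pairs to the canonical load set
#'
#' @param shoulder,elbow torque vectors in Nm.
#' @param tol absolute tolerance in Nm.
#' @return Integer vector of canonical load indices (0-7).
#' @keywords internal
match_load_index <- function(shoulder, elbow, tol = 1e-9) {
  loads <- canonical_load_set()
  idx <- integer(length(shoulder))
  for (i in seq_along(shoulder)) {
    hit <- which(abs(loads$shoulder_torque_nm - shoulder[i]) <= tol &
                   abs(loads$elbow_torque_nm - elbow[i]) <= tol)
    if (length(hit) != 1L) {
      stop(sprintf(
        "torque pair (%g, %g) Nm does not match any canonical load combination",
        shoulder[i], elbow[i]
      ))
    }
    idx[i] <- loads$index[hit]
  }
  idx
}

#' Analysis epoch windows relative to load onset
#'
#' Baseline is the 200 ms immediately before load onset, the perturbation
#' epoch the first 300 ms after it, and the steady-state epoch the final
#' 1000 ms of the trial. All windows are half-open `[start, end)`.
#'
#' @param baseline,perturbation numeric length-2 windows in ms relative to
#'   load onset.
#' @param steady_state_ms width in ms of the steady-state window at the end
#'   of each trial.
#' @return An object of class `epoch_windows`.
#' @export
epoch_windows <- function(baseline = c(-200, 0), perturbation = c(0, 300),
                          steady_state_ms = 1000) {
  stopifnot(length(baseline) == 2, length(perturbation) == 2,
            baseline[1] < baseline[2], perturbation[1] < perturbation[2],
            steady_state_ms > 0)
  structure(
    list(baseline = as.numeric(baseline),
         perturbation = as.numeric(perturbation),
         steady_state_ms = as.numeric(steady_state_ms)),
    class = "epoch_windows"
  )
}
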