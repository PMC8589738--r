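#' Tracked biopsy needle model
#'
#' Describes the rigid geometry of a biopsy needle carrying a fiducial
#' marker: the calibration transform from the marker (board) frame to the
#' needle-tip frame, and the shaft dimensions. The tip frame convention is
#' +z along the shaft toward the tip; by default the marker sits on the hub
#' and `marker_to_tip` is a pure translation by `shaft_length` along -z.
#'
#' @param marker_to_tip [rigid_transform()] from marker frame to tip frame.
#' @param shaft_length shaft length in mm (> 0).
#' @param shaft_diameter shaft diameter in mm (> 0).
#' @return An object of class `needle_model`.
#' @export
needle_model <- function(marker_to_tip = NULL, shaft_length = 150,
                         shaft_diameter = 3) {
  if (shaft_length <= 0 || shaft_diameter <= 0) {
    abort_ct("validation_error", "shaft dimensions must be positive")
  }
  if (is.null(marker_to_tip)) {
    marker_to_tip <- rigid_transform(diag(3), c(0, 0, -shaft_length))
  }
  stopifnot(inherits(marker_to_tip, "rigid_transform"))
  structure(list(marker_to_tip = marker_to_tip, shaft_length = shaft_length,
                 shaft_diameter = shaft_diameter),
            class = "needle_model")
}

#' World-frame needle state (tip and axis)
#'
#' @param tip world tip position in mm.
#' @param axis unit vector pointing from hub toward tip (normalised on
#'   construction; must be non-zero).
#' @param inserted_length optional known inserted length in mm; when `NULL`
#'   the scan simulator derives it from the body surface.
#' @return An object of class `needle_state`.
#' @export
needle_state <- function(tip, axis, inserted_length = NULL) {
  tip <- as.numeric(tip)
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) abort_ct("validation_error", "needle axis must be non-zero")
  structure(list(tip = tip, axis = axis / n, inserted_length = inserted_length),
            class = "needle_state")
}

#' Derive the needle state from a tracked marker pose
#'
#' The tip is the origin of the tip frame mapped to world:
#' `(marker_pose_world o marker_to_tip)` applied to (0,0,0); the axis is the
#' tip frame's +z unit vector rotated into world.
#'
#' @param marker_pose_world marker-to-world [rigid_transform()].
#' @param needle A [needle_model()].
#' @return A [needle_state()].
#' @export
needle_state_from_marker <- function(marker_pose_world, needle = needle_model()) {
  tip_frame <- compose(marker_pose_world, needle$marker_to_tip)
  needle_state(tip = tip_frame$translation,
               axis = as.vector(tip_frame$rotation %*% c(0, 0, 1)))
}
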