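#' Screening cutoffs for the gait indices
#'
#' The published screening cutoffs: a gait is flagged when the index
#' crosses the cutoff strictly in the stated direction (`below` = value
#' strictly less than the cutoff is positive, `above` = strictly greater).
#' Angle ranges are degrees; amplitudes and shifts are leg-length
#' normalized (leg = 1).
#'
#' @return Data frame with columns `index`, `cutoff`, `direction`,
#'   `feature` (the gait feature each index screens for).
#' @export
default_cutoffs <- function() {
  data.frame(
    index = c("hip_angle_range", "knee_angle_range", "heel_vertical_amplitude",
              "heel_outward_shift", "toe_outward_shift", "leg_outward_shift"),
    cutoff = c(30, 45, 0.1, -0.08, 0.18, 0.1),
    direction = c("below", "below", "below", "above", "above", "above"),
    feature = c("shuffling", "shuffling", "shuffling",
                "wide_based", "wide_based", "wide_based"),
    stringsAsFactors = FALSE)
}

# fit one side's ellipse for a plane/keypoint, or NULL when too few points
.side_ellipse <- function(tracks, plane, base, side, level) {
  pts <- track_points(tracks, plane, paste0(base, "_", side))
  if (nrow(pts) < 3L) return(NULL)
  fit_tolerance_ellipse(pts, level)
}

.angle_deg <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12) return(NA_real_)
  acos(.clamp1(sum(v1 * v2) / (n1 * n2))) * 180 / pi
}

# shared machinery for the two joint angle-range indices: the angle
# subtended at the proximal keypoint's ellipse center by the two
# major-axis endpoints of the distal keypoint's ellipse (sagittal plane)
.joint_angle_range <- function(tracks, proximal, distal, level) {
  sides <- c(l = NA_real_, r = NA_real_)
  for (side in c("l", "r")) {
    ep <- .side_ellipse(tracks, "sagittal", proximal, side, level)
    ed <- .side_ellipse(tracks, "sagittal", distal, side, level)
    if (is.null(ep) || is.null(ed)) next
    if (ed$degenerate) {
      warning("degenerate ", distal, " ellipse (", side,
              "): angle range set to 0")
      sides[[side]] <- 0
      next
    }
    endpoints <- major_axis_endpoints(ed)
    v1 <- endpoints[1L, ] - ep$center
    v2 <- endpoints[2L, ] - ep$center
    if (sqrt(sum(v1^2)) < 1e-12 || sqrt(sum(v2^2)) < 1e-12) {
      # proximal center sits on an endpoint: the subtended angle is 180
      sides[[side]] <- 180
    } else {
      sides[[side]] <- .angle_deg(v1, v2)
    }
  }
  value <- if (all(is.na(sides))) NA_real_ else mean(sides, na.rm = TRUE)
  list(value = value, sides = sides)
}

#' Hip joint angle range
#'
#' Angle subtended at the hip ellipse center (sagittal plane) by the two
#' major-axis endpoints of the same side's knee ellipse; sides are
#' averaged. Values below 30 degrees screen for a shuffling gait.
#'
#' @param tracks A [project_recording()] result.
#' @param level Tolerance-ellipse level (default 0.75).
#' @return List with `value` (mean of sides, degrees) and `sides`.
#' @export
hip_angle_range <- function(tracks, level = 0.75) {
  .joint_angle_range(tracks, "hip", "knee", level)
}

#' Knee joint angle range
#'
#' Angle subtended at the knee ellipse center (sagittal plane) by the two
#' major-axis endpoints of the same side's heel ellipse; sides are
#' averaged. Values below 45 degrees screen for shuffling and
#' short-stepped gaits.
#'
#' @inheritParams hip_angle_range
#' @return List with `value` (degrees) and `sides`.
#' @export
knee_angle_range <- function(tracks, level = 0.75) {
  .joint_angle_range(tracks, "knee", "heel", level)
}

#' Relative vertical heel amplitude
#'
#' Vertical extent of the heel scatter on the sagittal plane, in
#' leg-length units. The default `"ellipse"` mode uses the fitted
#' tolerance ellipse's vertical extent ([ellipse_y_width()],
#' outlier-robust); `"raw"` uses the raw max-minus-min of the y
#' coordinates. Values below 0.1 screen for a shuffling gait.
#'
#' @inheritParams hip_angle_range
#' @param mode `"ellipse"` (default) or `"raw"`.
#' @return List with `value` (mean of sides) and `sides`.
#' @export
heel_vertical_amplitude <- function(tracks, level = 0.75,
                                    mode = c("ellipse", "raw")) {
  mode <- match.arg(mode)
  sides <- c(l = NA_real_, r = NA_real_)
  for (side in c("l", "r")) {
    pts <- track_points(tracks, "sagittal", paste0("heel_", side))
    if (nrow(pts) < 3L) next
    sides[[side]] <- if (mode == "raw") {
      max(pts[, 2L]) - min(pts[, 2L])
    } else {
      ellipse_y_width(fit_tolerance_ellipse(pts, level))
    }
  }
  value <- if (all(is.na(sides))) NA_real_ else mean(sides, na.rm = TRUE)
  list(value = value, sides = sides)
}

#' Foot angle (outward rotation of the feet)
#'
#' Angle on the axial plane between the right heel-to-toe direction and
#' the left heel-to-toe direction, each taken between the respective
#' ellipse centers. Parallel feet give 0 degrees.
#'
#' @inheritParams hip_angle_range
#' @return List with `value` (degrees; `NA` when a heel and toe center
#'   coincide) .
#' @export
foot_angle <- function(tracks, level = 0.75) {
  vecs <- list()
  for (side in c("l", "r")) {
    eh <- .side_ellipse(tracks, "axial", "heel", side, level)
    et <- .side_ellipse(tracks, "axial", "toe", side, level)
    if (is.null(eh) || is.null(et)) return(list(value = NA_real_))
    vecs[[side]] <- et$center - eh$center
  }
  list(value = .angle_deg(vecs$r, vecs$l))
}

#' Outward shifts of heel, toe, and leg
#'
#' Lateral (axial-plane x, positive toward the subject's right)
#' displacement between ellipse centers, signed so that positive means
#' away from the midline: on each side `toe_shift = s*(x_toe - x_heel)`
#' and `heel_shift = s*(x_heel - x_hip)` with `s = +1` on the right and
#' `-1` on the left; sides are averaged, and the leg outward shift is the
#' sum of the heel and toe shifts (an exact identity). Negative values
#' mean the distal point sits toward the midline of its proximal
#' reference. Units are leg-length normalized.
#'
#' @inheritParams hip_angle_range
#' @return List with `heel`, `toe`, `leg` combined values and a `sides`
#'   matrix.
#' @export
outward_shifts <- function(tracks, level = 0.75) {
  sides <- matrix(NA_real_, 2L, 3L,
                  dimnames = list(c("l", "r"), c("heel", "toe", "leg")))
  for (side in c("l", "r")) {
    s <- if (side == "r") 1 else -1
    ehip <- .side_ellipse(tracks, "axial", "hip", side, level)
    eheel <- .side_ellipse(tracks, "axial", "heel", side, level)
    etoe <- .side_ellipse(tracks, "axial", "toe", side, level)
    toe <- if (!is.null(eheel) && !is.null(etoe))
      s * (etoe$center[[1L]] - eheel$center[[1L]]) else NA_real_
    heel <- if (!is.null(ehip) && !is.null(eheel))
      s * (eheel$center[[1L]] - ehip$center[[1L]]) else NA_real_
    sides[side, ] <- c(heel, toe, heel + toe)
  }
  heel <- mean(sides[, "heel"])
  toe <- mean(sides[, "toe"])
  list(heel = heel, toe = toe, leg = heel + toe, sides = sides)
}

#' Compute the seven gait indices of a recording
#'
#' Runs all index computations on projected tracks and applies the
#' screening cutoffs. Flags use strict inequalities in the published
#' direction; an index that cannot be computed yields an `NA` flag
#' (absent), never `FALSE`.
#'
#' @param tracks A [project_recording()] result.
#' @param level Tolerance-ellipse level (default 0.75).
#' @param cutoffs Cutoff table as from [default_cutoffs()].
#' @param amplitude_mode Passed to [heel_vertical_amplitude()].
#' @return Object of class `gait_indices`: `indices` (named numeric,
#'   the seven indices), `sides` (per-side values), `flags` (named
#'   logical per cutoff row), plus the configuration used.
#' @export
compute_gait_indices <- function(tracks, level = 0.75,
                                 cutoffs = default_cutoffs(),
                                 amplitude_mode = c("ellipse", "raw")) {
  amplitude_mode <- match.arg(amplitude_mode)
  hip <- hip_angle_range(tracks, level)
  knee <- knee_angle_range(tracks, level)
  amp <- heel_vertical_amplitude(tracks, level, amplitude_mode)
  fa <- foot_angle(tracks, level)
  sh <- outward_shifts(tracks, level)
  indices <- c(hip_angle_range = hip$value,
               knee_angle_range = knee$value,
               heel_vertical_amplitude = amp$value,
               foot_angle = fa$value,
               heel_outward_shift = sh$heel,
               toe_outward_shift = sh$toe,
               leg_outward_shift = sh$leg)
  sides <- rbind(
    hip_angle_range = hip$sides,
    knee_angle_range = knee$sides,
    heel_vertical_amplitude = amp$sides,
    heel_outward_shift = sh$sides[, "heel"],
    toe_outward_shift = sh$sides[, "toe"],
    leg_outward_shift = sh$sides[, "leg"])
  structure(list(indices = indices, sides = sides,
                 flags = apply_cutoffs(indices, cutoffs),
                 level = level, cutoffs = cutoffs,
                 amplitude_mode = amplitude_mode),
            class = "gait_indices")
}

#' Apply screening cutoffs to index values
#'
#' @param indices Named numeric vector of index values.
#' @param cutoffs Cutoff table as from [default_cutoffs()].
#' @return Named logical vector (one element per cutoff row, named by
#'   index): `TRUE` when the value crosses the cutoff strictly in the
#'   flag direction, `NA` when the index is missing. Boundary values do
#'   not flag.
#' @export
apply_cutoffs <- function(indices, cutoffs = default_cutoffs()) {
  flags <- logical(nrow(cutoffs))
  for (i in seq_len(nrow(cutoffs))) {
    v <- indices[[cutoffs$index[i]]]
    flags[i] <- if (is.null(v) || is.na(v)) NA else
      if (cutoffs$direction[i] == "below") v < cutoffs$cutoff[i] else v > cutoffs$cutoff[i]
  }
  setNames(flags, cutoffs$index)
}

#' @export
print.gait_indices <- function(x, ...) {
  cat("<gait_indices> (level ", x$level, ", amplitude mode '",
      x$amplitude_mode, "')\n", sep = "")
  print(round(x$indices, 4))
  flagged <- names(x$flags)[which(x$flags)]
  cat("flags:", if (length(flagged)) paste(flagged, collapse = ", ") else "none", "\n")
  invisible(x)
}
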