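#' Canonical keypoint names
#'
#' The 24 full-body landmarks tracked by the markerless capture app: the
#' body center (navel), nose, and left/right ears, eyes, shoulders, elbows,
#' wrists, thumbs, middle fingers, hips, knees, heels, and toes.
#'
#' @return Character vector of length 24, in canonical column order.
#' @export
#' @examples
#' keypoint_names()
keypoint_names <- function() {
  c("center", "nose",
    "ear_l", "ear_r", "eye_l", "eye_r",
    "shoulder_l", "shoulder_r", "elbow_l", "elbow_r",
    "wrist_l", "wrist_r", "thumb_l", "thumb_r",
    "middle_finger_l", "middle_finger_r",
    "hip_l", "hip_r", "knee_l", "knee_r",
    "heel_l", "heel_r", "toe_l", "toe_r")
}

# keypoint groups used for normalization and index computation
.lower_keypoints <- function() {
  c("hip_l", "hip_r", "knee_l", "knee_r", "heel_l", "heel_r", "toe_l", "toe_r")
}

.arm_keypoints <- function() {
  c("elbow_l", "elbow_r", "wrist_l", "wrist_r",
    "thumb_l", "thumb_r", "middle_finger_l", "middle_finger_r")
}

#' Construct a gait recording
#'
#' A recording holds per-frame navel-relative 3D positions and confidence
#' scores for up to 24 named keypoints, plus capture metadata. Missing
#' samples are `NA`.
#'
#' @param time Numeric vector of frame timestamps (seconds), strictly
#'   increasing.
#' @param pos Numeric array `n_frames x 24 x 3` with dimnames
#'   `(NULL, keypoint_names(), c("x","y","z"))`.
#' @param score Numeric matrix `n_frames x 24` of confidences in `[0, 1]`
#'   (`NA` where the sample is absent).
#' @param fps Nominal frame rate (frames/second), `> 0`.
#' @param direction One of `"clockwise"`, `"counterclockwise"`,
#'   `"unknown"` (recordings covering both walking directions use
#'   `"unknown"`).
#' @param subject_id Opaque subject label.
#' @param labels Optional named logical vector of gait-feature ground
#'   truth, e.g. `c(shuffling = TRUE)`.
#' @return An object of class `gait_recording`.
#' @export
gait_recording <- function(time, pos, score, fps = 30,
                           direction = c("unknown", "clockwise", "counterclockwise"),
                           subject_id = "subject", labels = NULL) {
  direction <- match.arg(direction)
  n <- length(time)
  kp <- keypoint_names()
  if (n == 0L) {
    pos <- array(NA_real_, c(0L, 24L, 3L),
                 dimnames = list(NULL, kp, c("x", "y", "z")))
    score <- matrix(NA_real_, 0L, 24L, dimnames = list(NULL, kp))
  }
  stopifnot(is.array(pos), length(dim(pos)) == 3L,
            dim(pos)[1L] == n, dim(pos)[2L] == 24L, dim(pos)[3L] == 3L,
            is.matrix(score), nrow(score) == n, ncol(score) == 24L)
  if (!identical(dimnames(pos)[[2L]], kp))
    stop("pos keypoint dimension must be named with keypoint_names() in order")
  if (n > 1L && any(diff(time) <= 0))
    stop("frame timestamps must be strictly increasing")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("fps must be a positive scalar")
  sc <- score[!is.na(score)]
  if (length(sc) && (any(sc < 0) || any(sc > 1)))
    stop("scores must lie in [0, 1]")
  if (any(!is.finite(pos[!is.na(pos)])))
    stop("positions must be finite")
  colnames(score) <- kp
  structure(
    list(time = as.numeric(time), pos = pos, score = score,
         fps = fps, direction = direction,
         subject_id = as.character(subject_id), labels = labels),
    class = "gait_recording")
}

#' @export
print.gait_recording <- function(x, ...) {
  n <- length(x$time)
  present <- sum(!is.na(x$score))
  cat(sprintf("<gait_recording> subject '%s': %d frames at %g fps (%s)\n",
              x$subject_id, n, x$fps, x$direction))
  cat(sprintf("  %d/%d keypoint samples present\n", present, n * 24L))
  if (!is.null(x$labels)) {
    on <- names(x$labels)[which(as.logical(x$labels))]
    cat("  labels:", if (length(on)) paste(on, collapse = ", ") else "(none positive)", "\n")
  }
  invisible(x)
}

#' @export
length.gait_recording <- function(x) length(x$time)
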