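#' Body-axis frames and plane projection
#'
#' Every frame of a recording defines its own body-fixed orthonormal frame
#' built from the navel (origin), shoulders, and hips:
#' the unit normal of the plane through the navel and the two shoulders
#' (oriented anteriorly) is averaged with the unit normal of the plane
#' through the navel and the two hips to give a raw forward vector; the
#' downward vector `c` points from the navel to the hip midpoint; the
#' forward vector `f` is the raw forward vector Gram-Schmidt
#' orthogonalized against `c`; and the lateral vector `n = c x f`, with
#' its sign fixed so that `n` points toward the labeled right shoulder
#' (the subject's right). The triple `(f, n, c)` is right-handed
#' (`f x n = c`) and mutually orthogonal to machine precision.
#'
#' Keypoints are orthogonally projected onto three planes through the
#' navel: sagittal `(d.f, -d.c)` (x forward, y up), coronal `(d.n, -d.c)`
#' (x to the subject's right, y up), and axial `(d.n, d.f)` (x right,
#' y forward), where `d` is the navel-relative position.
#'
#' @name body-frames
NULL

# vectorized frame construction over an n x 24 x 3 position array.
# returns list(valid, origin, f, c, n, reason)
.body_frames <- function(pos) {
  n <- dim(pos)[1L]
  ctr <- pos[, "center", , drop = FALSE]; dim(ctr) <- c(n, 3L)
  sr <- pos[, "shoulder_r", , drop = FALSE]; dim(sr) <- c(n, 3L)
  sl <- pos[, "shoulder_l", , drop = FALSE]; dim(sl) <- c(n, 3L)
  hr <- pos[, "hip_r", , drop = FALSE]; dim(hr) <- c(n, 3L)
  hl <- pos[, "hip_l", , drop = FALSE]; dim(hl) <- c(n, 3L)
  nose <- pos[, "nose", , drop = FALSE]; dim(nose) <- c(n, 3L)

  reason <- rep(NA_character_, n)
  ok <- rowSums(is.na(cbind(ctr, sr, sl, hr, hl))) == 0L
  reason[!ok] <- "missing keypoint"

  scale <- pmax(.row_norms(sr - ctr), .row_norms(sl - ctr), 1e-12)
  tol <- 1e-8

  # (left, right) cross order points anteriorly for anatomical labels
  # under the y-up convention; the nose check below covers mirrored input
  uf <- .cross3_rows(sl - ctr, sr - ctr)
  ufn <- .row_norms(uf)
  bad <- ok & ufn < tol * scale^2
  reason[bad] <- "collinear shoulders"; ok <- ok & !bad
  uf <- uf / pmax(ufn, 1e-300)

  df_ <- .cross3_rows(hl - ctr, hr - ctr)
  dfn <- .row_norms(df_)
  bad <- ok & dfn < tol * scale^2
  reason[bad] <- "collinear hips"; ok <- ok & !bad
  df_ <- df_ / pmax(dfn, 1e-300)

  # anterior orientation: align the shoulder normal with the nose offset
  # when the nose is present, then align the hip normal with it
  has_nose <- rowSums(is.na(nose)) == 0L
  dot_nose <- rowSums(uf * (nose - ctr))
  flip <- which(has_nose & !is.na(dot_nose) & dot_nose < 0)
  uf[flip, ] <- -uf[flip, ]
  dot_ud <- rowSums(uf * df_)
  flip <- which(!is.na(dot_ud) & dot_ud < 0)
  df_[flip, ] <- -df_[flip, ]

  f_raw <- (uf + df_) / 2
  bad <- ok & .row_norms(f_raw) < tol
  reason[bad] <- "opposed shoulder/hip normals"; ok <- ok & !bad

  cvec <- (hr + hl) / 2 - ctr
  cn <- .row_norms(cvec)
  bad <- ok & cn < tol * scale
  reason[bad] <- "hip midpoint coincides with navel"; ok <- ok & !bad
  cvec <- cvec / pmax(cn, 1e-300)

  f <- f_raw - rowSums(f_raw * cvec) * cvec
  fn <- .row_norms(f)
  bad <- ok & fn < tol
  reason[bad] <- "forward parallel to downward"; ok <- ok & !bad
  f <- f / pmax(fn, 1e-300)

  nvec <- .cross3_rows(cvec, f)
  dot_r <- rowSums(nvec * (sr - ctr))
  flip <- which(!is.na(dot_r) & dot_r < 0)
  nvec[flip, ] <- -nvec[flip, ]

  list(valid = ok, origin = ctr, f = f, c = cvec, n = nvec, reason = reason)
}

#' Compute the body-axis frame of a single pose
#'
#' @param kp Numeric matrix of keypoint positions with rownames drawn from
#'   [keypoint_names()] and columns x, y, z. Must contain `center`,
#'   `shoulder_l`, `shoulder_r`, `hip_l`, `hip_r` (and ideally `nose`,
#'   used to orient the forward axis anteriorly).
#' @return An object of class `body_frame`: list with `origin` and unit
#'   vectors `f` (forward), `c` (down), `n` (subject's right).
#'   Degenerate geometry (collinear landmark triples) raises an error of
#'   class `gait_degenerate_frame`, which recording-level code treats as a
#'   frame-skip signal.
#' @export
#' @examples
#' kp <- rbind(center     = c(0, 0, 0),
#'             shoulder_r = c(0.2, 0.5, 0), shoulder_l = c(-0.2, 0.5, 0),
#'             hip_r      = c(0.1, -0.3, 0), hip_l     = c(-0.1, -0.3, 0),
#'             nose       = c(0, 0.6, 0.1))
#' compute_body_frame(kp)
compute_body_frame <- function(kp) {
  stopifnot(is.matrix(kp), ncol(kp) == 3L, !is.null(rownames(kp)))
  pos <- array(NA_real_, c(1L, 24L, 3L),
               dimnames = list(NULL, keypoint_names(), c("x", "y", "z")))
  for (k in intersect(rownames(kp), keypoint_names()))
    pos[1L, k, ] <- kp[k, ]
  bf <- .body_frames(pos)
  if (!bf$valid[1L])
    stop(structure(class = c("gait_degenerate_frame", "error", "condition"),
                   list(message = paste0("degenerate frame: ", bf$reason[1L]),
                        call = sys.call())))
  structure(list(origin = bf$origin[1L, ], f = bf$f[1L, ],
                 c = bf$c[1L, ], n = bf$n[1L, ]),
            class = "body_frame")
}

#' @export
print.body_frame <- function(x, ...) {
  cat("<body_frame>\n")
  cat("  origin:", sprintf("% .4f", x$origin), "\n")
  cat("  f (fwd):", sprintf("% .4f", x$f), "\n")
  cat("  c (down):", sprintf("% .4f", x$c), "\n")
  cat("  n (right):", sprintf("% .4f", x$n), "\n")
  invisible(x)
}

#' Orthogonally project a 3D point onto a body-axis plane
#'
#' @param p Numeric 3-vector.
#' @param bf A [compute_body_frame()] result.
#' @param plane `"sagittal"` (x forward, y up), `"coronal"` (x right,
#'   y up), or `"axial"` (x right, y forward).
#' @return Numeric 2-vector.
#' @export
project_point <- function(p, bf, plane = c("sagittal", "coronal", "axial")) {
  plane <- match.arg(plane)
  stopifnot(inherits(bf, "body_frame"), is.numeric(p), length(p) == 3L)
  d <- p - bf$origin
  switch(plane,
         sagittal = c(sum(d * bf$f), -sum(d * bf$c)),
         coronal  = c(sum(d * bf$n), -sum(d * bf$c)),
         axial    = c(sum(d * bf$n), sum(d * bf$f)))
}

#' Mean segment lengths of a recording
#'
#' Leg length is the 3D distance navel-to-hip plus hip-to-knee plus
#' knee-to-heel, averaged over left and right and over all frames where
#' the required samples are present. Upper-body length is navel-to-neck
#' plus neck-to-head, where the neck center is the shoulder midpoint and
#' the head center the ear midpoint. These lengths set the normalization
#' scales (leg = 1 for the lower limbs, upper body = 1 for the head/trunk
#' group) of the projected coordinates.
#'
#' @param rec A [gait_recording()] (apply [filter_by_score()] first if
#'   confidence filtering is wanted).
#' @return List with elements `leg` and `upper` (same units as `rec`),
#'   plus frame counts used for each.
#' @export
segment_lengths <- function(rec) {
  stopifnot(inherits(rec, "gait_recording"))
  pos <- rec$pos
  n <- dim(pos)[1L]
  if (n < 1L) stop("recording has no frames")
  g <- function(k) { m <- pos[, k, , drop = FALSE]; dim(m) <- c(n, 3L); m }
  dist_rows <- function(a, b) .row_norms(a - b)

  ctr <- g("center")
  leg_side <- function(side) {
    dist_rows(ctr, g(paste0("hip_", side))) +
      dist_rows(g(paste0("hip_", side)), g(paste0("knee_", side))) +
      dist_rows(g(paste0("knee_", side)), g(paste0("heel_", side)))
  }
  legs <- c(leg_side("l"), leg_side("r"))
  if (all(is.na(legs))) stop("no frame with complete leg keypoints")
  leg <- mean(legs, na.rm = TRUE)

  neck <- (g("shoulder_l") + g("shoulder_r")) / 2
  head <- (g("ear_l") + g("ear_r")) / 2
  uppers <- dist_rows(ctr, neck) + dist_rows(neck, head)
  if (all(is.na(uppers))) stop("no frame with complete upper-body keypoints")
  upper <- mean(uppers, na.rm = TRUE)

  list(leg = leg, upper = upper,
       n_leg_frames = sum(!is.na(legs)) / 2,
       n_upper_frames = sum(!is.na(uppers)))
}

#' Project a recording onto the three body-axis planes
#'
#' Applies confidence filtering, builds a body-axis frame per frame,
#' orthogonally projects every present keypoint onto the sagittal,
#' coronal, and axial planes, and scales lower-limb points by the mean
#' leg length and all other points by the mean upper-body length (so leg
#' = 1 and upper body = 1 in the output). Frames whose frame construction
#' is degenerate or that lack any of center/shoulders/hips contribute no
#' points; their counts are recorded in the `"skipped"` attribute.
#'
#' @param rec A [gait_recording()].
#' @param score_threshold Confidence threshold passed to
#'   [filter_by_score()] (default 0.7).
#' @return A data frame of class `projected_tracks` with columns
#'   `plane`, `keypoint`, `frame`, `x`, `y`, and attributes
#'   `segment_lengths`, `skipped` (named counts by reason), and
#'   `n_frames_used`.
#' @export
project_recording <- function(rec, score_threshold = 0.7) {
  stopifnot(inherits(rec, "gait_recording"))
  rec <- filter_by_score(rec, score_threshold)
  seg <- segment_lengths(rec)
  pos <- rec$pos
  n <- dim(pos)[1L]
  bf <- .body_frames(pos)
  if (sum(bf$valid) < 2L)
    stop("fewer than 2 usable frames after filtering; cannot analyze")

  kp <- keypoint_names()
  denom <- ifelse(kp %in% .lower_keypoints(), seg$leg, seg$upper)
  names(denom) <- kp

  pieces <- vector("list", 24L)
  valid <- bf$valid
  idx <- which(valid)
  for (j in seq_along(kp)) {
    k <- kp[j]
    p <- pos[, k, , drop = FALSE]; dim(p) <- c(n, 3L)
    keep <- valid & !is.na(p[, 1L])
    if (!any(keep)) next
    d <- p[keep, , drop = FALSE] - bf$origin[keep, , drop = FALSE]
    f <- bf$f[keep, , drop = FALSE]
    cv <- bf$c[keep, , drop = FALSE]
    nv <- bf$n[keep, , drop = FALSE]
    df_ <- rowSums(d * f); dn <- rowSums(d * nv); dc <- rowSums(d * cv)
    sc <- denom[[k]]
    pieces[[j]] <- data.frame(
      plane = rep(c("sagittal", "coronal", "axial"), each = sum(keep)),
      keypoint = k,
      frame = rep(which(keep), 3L),
      x = c(df_, dn, dn) / sc,
      y = c(-dc, -dc, df_) / sc,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1L))])
  rownames(out) <- NULL
  skipped <- table(bf$reason[!valid])
  structure(out,
            class = c("projected_tracks", "data.frame"),
            segment_lengths = seg,
            skipped = setNames(as.integer(skipped), names(skipped)),
            n_frames_used = length(idx))
}

# extract one keypoint's 2D point cloud from projected tracks
track_points <- function(tracks, plane, keypoint) {
  stopifnot(inherits(tracks, "projected_tracks"))
  sel <- tracks$plane == plane & tracks$keypoint == keypoint
  as.matrix(tracks[sel, c("x", "y")])
}
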