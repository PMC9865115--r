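# shared fixtures, all generated in code; expensive recordings are cached
# per test run so several test files can reuse them

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

normal_recording <- function() {
  cached("normal_rec", simulate_recording(gait_preset("normal", seed = 42)))
}

normal_tracks <- function() {
  cached("normal_tracks", project_recording(normal_recording()))
}

# a symmetric upright standing pose; forces the body axes by symmetry
standing_pose <- function() {
  rbind(center     = c(0, 0, 0),
        shoulder_r = c(0.2, 0.5, 0),
        shoulder_l = c(-0.2, 0.5, 0),
        hip_r      = c(0.1, -0.3, 0),
        hip_l      = c(-0.1, -0.3, 0),
        nose       = c(0, 0.6, 0.1))
}

# mirror a recording across the subject's midline: negate x and swap the
# left/right keypoint labels
mirror_recording <- function(rec) {
  kp <- keypoint_names()
  swap <- ifelse(grepl("_l$", kp), sub("_l$", "_r", kp),
                 ifelse(grepl("_r$", kp), sub("_r$", "_l", kp), kp))
  pos <- rec$pos[, swap, , drop = FALSE]
  dimnames(pos)[[2L]] <- kp
  pos[, , 1L] <- -pos[, , 1L]
  score <- rec$score[, swap, drop = FALSE]
  colnames(score) <- kp
  gait_recording(rec$time, pos, score, fps = rec$fps,
                 direction = rec$direction, subject_id = rec$subject_id)
}

# apply a rigid motion (rotation matrix R, translation t) to every frame
transform_recording <- function(rec, R, t = c(0, 0, 0)) {
  out <- rec
  n <- dim(rec$pos)[1L]
  for (d in 1:3) out$pos[, , d] <- 0
  for (i in seq_len(n))
    out$pos[i, , ] <- rec$pos[i, , ] %*% t(R) + rep(t, each = 24L)
  out
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3L)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# exhaustive pairwise-comparison AUC (independent of the package path)
auc_pairwise <- function(values, labels, direction = "below") {
  v <- if (direction == "below") -values else values
  cases <- v[labels]
  ctrls <- v[!labels]
  cmp <- outer(cases, ctrls, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# closed-form eigen-decomposition of a symmetric 2x2 matrix
eig2_oracle <- function(S) {
  tr <- S[1L, 1L] + S[2L, 2L]
  dt <- S[1L, 1L] * S[2L, 2L] - S[1L, 2L]^2
  disc <- sqrt(max(0, (tr / 2)^2 - dt))
  tilt <- 0.5 * atan2(2 * S[1L, 2L], S[1L, 1L] - S[2L, 2L])
  if (tilt <= -pi / 2) tilt <- tilt + pi
  if (tilt > pi / 2) tilt <- tilt - pi
  list(l1 = tr / 2 + disc, l2 = tr / 2 - disc, tilt = tilt)
}

# build a 2D point cloud whose tolerance ellipse has a known center and
# axis-aligned semi-axes: the 4-point cross (+-h, 0), (0, +-e) around c0
cross_cloud <- function(c0, h, e) {
  rbind(c0 + c(h, 0), c0 - c(h, 0), c0 + c(0, e), c0 - c(0, e))
}

# minimal synthetic projected_tracks object built directly from clouds:
# clouds is a list like list(sagittal = list(hip_r = matrix, ...), ...)
tracks_from_clouds <- function(clouds) {
  rows <- list()
  for (plane in names(clouds)) {
    for (k in names(clouds[[plane]])) {
      m <- clouds[[plane]][[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        plane = plane, keypoint = k, frame = seq_len(nrow(m)),
        x = m[, 1L], y = m[, 2L], stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows),
            class = c("projected_tracks", "data.frame"))
}
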