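#' Gait simulation parameters
#'
#' Parameter set for the articulated gait simulator. The walker follows
#' the capture protocol: a circle of `circle_diameter` m walked for
#' `laps_per_direction` laps clockwise and the same counterclockwise, at
#' `fps` frames per second. Pelvis speed is
#' `cadence * step_length / 60` m/s; feet alternate stance and swing
#' (duty factor `duty_factor`), swing feet follow a cycloidal forward
#' profile with a sinusoidal vertical bump of height `step_height`; knees
#' are placed by two-link (thigh/shank) inverse kinematics; the upper
#' body is rigid with sinusoidal lateral sway. All 24 keypoints are
#' emitted navel-relative with Gaussian positional noise and
#' Beta-distributed confidence scores with a sub-threshold dropout rate.
#'
#' @param cadence Steps per minute.
#' @param step_length Step length, m (stride = 2 steps).
#' @param step_height Maximum heel clearance above its ground level
#'   during swing, m.
#' @param stance_width Lateral distance between left and right foot
#'   paths, m.
#' @param foot_rotation Outward rotation of each foot, degrees.
#' @param toe_out_offset Extra lateral outward offset of the toe beyond
#'   the foot-rotation geometry, m.
#' @param thigh,shank Leg segment lengths, m.
#' @param foot_length Heel-to-toe distance, m.
#' @param pelvis_half_width Navel-line to hip-keypoint lateral offset, m.
#' @param shoulder_half_width Midline-to-shoulder lateral offset, m.
#' @param navel_hip_drop Vertical drop from navel to the hip line, m.
#' @param trunk_length Navel-to-neck-center length, m.
#' @param head_offset Neck-center-to-head-center length, m.
#' @param trunk_sway Lateral sway amplitude of the upper body, m.
#' @param circle_diameter Walking-circle diameter, m.
#' @param laps_per_direction Laps walked in each direction.
#' @param fps Frames per second.
#' @param duty_factor Stance fraction of the gait cycle.
#' @param noise_sd Isotropic Gaussian positional noise SD, m.
#' @param score_mean,score_kappa Mean and concentration of the Beta
#'   confidence-score distribution.
#' @param dropout Probability that a sample's score is drawn below 0.7
#'   (uniform on (0, 0.65)), exercising confidence filtering.
#' @param seed Integer seed fixing the full output stream.
#' @return Object of class `gait_params` (a validated list).
#' @export
gait_params <- function(cadence = 100, step_length = 0.60, step_height = 0.15,
                        stance_width = 0.10, foot_rotation = 10,
                        toe_out_offset = 0.02,
                        thigh = 0.45, shank = 0.45, foot_length = 0.25,
                        pelvis_half_width = 0.16, shoulder_half_width = 0.20,
                        navel_hip_drop = 0.12, trunk_length = 0.35,
                        head_offset = 0.12, trunk_sway = 0.02,
                        circle_diameter = 1.0, laps_per_direction = 2,
                        fps = 30, duty_factor = 0.6,
                        noise_sd = 0.005, score_mean = 0.92,
                        score_kappa = 40, dropout = 0.02, seed = 1L) {
  p <- as.list(environment())
  lens <- c("cadence", "step_length", "step_height", "stance_width",
            "thigh", "shank", "foot_length", "pelvis_half_width",
            "shoulder_half_width", "navel_hip_drop", "trunk_length",
            "head_offset", "circle_diameter", "fps")
  for (nm in lens)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0)
      stop("gait parameter '", nm, "' must be a positive scalar")
  stopifnot(p$duty_factor > 0, p$duty_factor < 1,
            p$noise_sd >= 0, p$trunk_sway >= 0, p$toe_out_offset >= 0,
            p$dropout >= 0, p$dropout <= 1,
            p$laps_per_direction >= 1)
  structure(p, class = "gait_params")
}

#' Gait pattern presets
#'
#' Parameter presets for the four simulated gait patterns. Relative to
#' the `normal` baseline: `shuffling` divides the step height by 10
#' (diminished heel lift); `short_stepped` divides the step length by
#' 2.5 (reduced stride); `wide_based` triples the stance width and
#' increases the outward foot rotation and toe offset. Magnitudes are
#' engineering defaults documented in the methods vignette, not
#' measurements.
#'
#' @param name One of `"normal"`, `"shuffling"`, `"short_stepped"`,
#'   `"wide_based"`.
#' @param ... Overrides passed to [gait_params()].
#' @return A [gait_params()] object.
#' @export
gait_preset <- function(name = c("normal", "shuffling", "short_stepped",
                                 "wide_based"), ...) {
  name <- match.arg(name)
  base <- list(...)
  mods <- switch(name,
                 normal = list(),
                 shuffling = list(step_height = 0.15 / 10),
                 short_stepped = list(step_length = 0.60 / 2.5),
                 wide_based = list(stance_width = 0.10 * 3,
                                   foot_rotation = 30, toe_out_offset = 0.10))
  do.call(gait_params, modifyList(mods, base))
}

# smooth cycloidal 0 -> 1 ramp with zero end velocities
.cycloid_ramp <- function(u) u - sin(2 * pi * u) / (2 * pi)

# per-foot arc coordinate, ground height and swing phase over one segment
.foot_motion <- function(tau, p, phase_offset, heel_ground) {
  T_cycle <- 120 / p$cadence          # one stride = two steps
  L2 <- 2 * p$step_length             # arc advance per stride
  sg <- 1 - p$duty_factor             # swing fraction
  q <- tau / T_cycle + phase_offset
  j <- floor(q)
  phi <- q - j
  swing <- phi < sg
  ramp <- ifelse(swing, .cycloid_ramp(phi / sg), 1)
  a0 <- -L2 * (phase_offset + 0.5 - sg / 2)  # centers the foot under the pelvis
  arc <- a0 + L2 * (j + ramp)
  y <- heel_ground + ifelse(swing, p$step_height * sin(pi * phi / sg), 0)
  list(arc = arc, y = y, swing = swing,
       contact_arcs = a0 + L2 * unique(j + 1))
}

# map arc coordinates to world ground positions on the walking circle:
# returns position (x, z), heading and rightward unit vectors (x, z)
.circle_map <- function(arc, R, theta0, dir) {
  theta <- theta0 + dir * arc / R
  px <- R * cos(theta); pz <- R * sin(theta)
  hx <- dir * -sin(theta); hz <- dir * cos(theta)
  list(px = px, pz = pz, hx = hx, hz = hz, rx = -hz, rz = hx)
}

#' Simulate a gait recording
#'
#' Generates a full circular-walk recording (both directions) for one
#' subject under the given parameters. With `noise_sd = 0` the thigh and
#' shank 3D lengths are constant across frames to machine precision.
#' Identical parameters (including `seed`) give an identical recording.
#'
#' @param params A [gait_params()] or [gait_preset()] object.
#' @param subject_id Subject label stored in the recording.
#' @param labels Optional named logical ground-truth labels.
#' @return A [gait_recording()] with attributes `params`, `segments`
#'   (per-direction frame counts), and `footfalls` (per-side stance arc
#'   positions, used for stride-length checks).
#' @export
simulate_recording <- function(params = gait_params(), subject_id = "sim",
                               labels = NULL) {
  stopifnot(inherits(params, "gait_params"))
  p <- params
  R <- p$circle_diameter / 2
  v <- p$cadence * p$step_length / 60
  hip_height <- 0.82 * (p$thigh + p$shank)
  heel_ground <- 0.02

  # reachability of the two-link leg at the fore-aft extremes of the
  # cycle: the foot sits 0.6 * step_length along the circle from the
  # pelvis, so the straight-line offset is the chord plus the inward
  # deviation of the curved path
  x <- min(0.6 * p$step_length / R, pi)
  fwd <- 0.6 * p$step_length * (if (x > 0) sin(x) / x else 1)
  dev <- R * (1 - cos(x))
  lat <- abs(p$stance_width / 2 - p$pelvis_half_width) + dev
  reach_needed <- sqrt(fwd^2 + (hip_height - heel_ground)^2 + lat^2)
  if (reach_needed > 0.985 * (p$thigh + p$shank))
    stop("step_length ", p$step_length,
         " m exceeds the two-link leg reach (thigh + shank = ",
         p$thigh + p$shank, " m); reduce step_length or the circle curvature")

  seg_dur <- (pi * p$circle_diameter * p$laps_per_direction) / v
  n_seg <- ceiling(seg_dur * p$fps)
  n <- 2L * n_seg
  kp <- keypoint_names()
  pos <- array(NA_real_, c(n, 24L, 3L),
               dimnames = list(NULL, kp, c("x", "y", "z")))
  footfalls <- list()

  theta0 <- 0
  for (segi in 1:2) {
    dir <- if (segi == 1L) -1 else 1   # clockwise first, then counterclockwise
    rows <- if (segi == 1L) seq_len(n_seg) else n_seg + seq_len(n_seg)
    tau <- (seq_len(n_seg) - 1L) / p$fps
    s <- v * tau
    T_cycle <- 120 / p$cadence

    pel <- .circle_map(s, R, theta0, dir)
    up <- c(0, 1, 0)
    sway <- p$trunk_sway * sin(2 * pi * tau / T_cycle)

    # ground-plane helper: world 3D point from map coords + local offsets
    w3 <- function(map, along = 0, lateral = 0, height = 0) {
      cbind(map$px + along * map$hx + lateral * map$rx,
            height,
            map$pz + along * map$hz + lateral * map$rz)
    }

    navel <- w3(pel, lateral = sway, height = hip_height + p$navel_hip_drop)
    neck_y <- hip_height + p$navel_hip_drop + p$trunk_length
    head_y <- neck_y + p$head_offset
    put <- function(name, m) pos[rows, name, ] <<- m

    put("center", navel)
    for (side in c("l", "r")) {
      sgn <- if (side == "r") 1 else -1
      put(paste0("hip_", side),
          w3(pel, lateral = sgn * p$pelvis_half_width, height = hip_height))
      put(paste0("shoulder_", side),
          w3(pel, lateral = sway + sgn * p$shoulder_half_width, height = neck_y))
      put(paste0("ear_", side),
          w3(pel, lateral = sway + sgn * 0.08, height = head_y))
      put(paste0("eye_", side),
          w3(pel, along = 0.08, lateral = sway + sgn * 0.033, height = head_y + 0.02))
      # static hanging arms (excluded from all indices)
      put(paste0("elbow_", side),
          w3(pel, along = 0.02, lateral = sway + sgn * (p$shoulder_half_width + 0.02),
             height = neck_y - 0.28))
      put(paste0("wrist_", side),
          w3(pel, along = 0.07, lateral = sway + sgn * (p$shoulder_half_width + 0.03),
             height = neck_y - 0.53))
      put(paste0("thumb_", side),
          w3(pel, along = 0.11, lateral = sway + sgn * (p$shoulder_half_width + 0.02),
             height = neck_y - 0.60))
      put(paste0("middle_finger_", side),
          w3(pel, along = 0.10, lateral = sway + sgn * (p$shoulder_half_width + 0.04),
             height = neck_y - 0.63))
    }
    put("nose", w3(pel, along = 0.10, lateral = sway, height = head_y - 0.02))

    rot <- p$foot_rotation * pi / 180
    for (side in c("l", "r")) {
      sgn <- if (side == "r") 1 else -1
      fm <- .foot_motion(tau, p, if (side == "r") 0 else 0.5, heel_ground)
      fmap <- .circle_map(fm$arc, R, theta0, dir)
      heel <- w3(fmap, lateral = sgn * p$stance_width / 2, height = fm$y)
      # heel-to-toe direction: heading rotated outward by foot_rotation
      tdx <- cos(rot) * fmap$hx + sin(rot) * sgn * fmap$rx
      tdz <- cos(rot) * fmap$hz + sin(rot) * sgn * fmap$rz
      toe <- cbind(
        heel[, 1L] + p$foot_length * tdx + sgn * p$toe_out_offset * fmap$rx,
        0.01 + 0.5 * (fm$y - heel_ground),
        heel[, 3L] + p$foot_length * tdz + sgn * p$toe_out_offset * fmap$rz)
      hip <- pos[rows, paste0("hip_", side), ]

      # two-link inverse kinematics for the knee, bending forward
      d3 <- heel - hip
      d <- pmin(.row_norms(d3), 0.999999 * (p$thigh + p$shank))
      u <- d3 / .row_norms(d3)
      fwd <- cbind(pel$hx, 0, pel$hz)
      w <- fwd - rowSums(fwd * u) * u
      w <- w / pmax(.row_norms(w), 1e-12)
      cosa <- .clamp1((p$thigh^2 + d^2 - p$shank^2) / (2 * p$thigh * d))
      sina <- sqrt(pmax(0, 1 - cosa^2))
      knee <- hip + p$thigh * (cosa * u + sina * w)

      put(paste0("heel_", side), heel)
      put(paste0("toe_", side), toe)
      put(paste0("knee_", side), knee)
      ca <- fm$contact_arcs
      ca <- ca[ca >= 0 & ca <= v * seg_dur]
      footfalls[[length(footfalls) + 1L]] <- data.frame(
        segment = segi, side = side, arc = sort(ca))
    }
    theta0 <- theta0 + dir * (v * seg_dur) / R
  }

  out <- with_preserved_seed(p$seed, {
    noisy <- pos + rnorm(length(pos), sd = p$noise_sd)
    # re-center on the (noisy) navel: the app pins the navel at the origin
    for (d in 1:3) noisy[, , d] <- noisy[, , d] - noisy[, "center", d]
    a <- p$score_mean * p$score_kappa
    b <- (1 - p$score_mean) * p$score_kappa
    score <- matrix(rbeta(n * 24L, a, b), n, 24L, dimnames = list(NULL, kp))
    drop <- matrix(runif(n * 24L) < p$dropout, n, 24L)
    score[drop] <- runif(sum(drop), 0, 0.65)
    list(pos = noisy, score = score)
  })

  rec <- gait_recording(time = (seq_len(n) - 1L) / p$fps, pos = out$pos,
                        score = out$score, fps = p$fps,
                        direction = "unknown", subject_id = subject_id,
                        labels = labels)
  attr(rec, "params") <- p
  attr(rec, "segments") <- data.frame(
    direction = c("clockwise", "counterclockwise"),
    n_frames = c(n_seg, n_seg))
  attr(rec, "footfalls") <- do.call(rbind, footfalls)
  rec
}

#' Simulate a labeled screening cohort
#'
#' Controls are drawn from the normal preset with between-subject
#' parameter jitter (multiplicative log-normal, `jitter_sd` on the log
#' scale); cases interpolate geometrically from the normal preset toward
#' the named pathological preset with severity `effect` (0 = identical
#' to controls, 1 = the full preset) before jitter.
#'
#' @param n_cases,n_controls Cohort sizes (each `>= 1`).
#' @param feature `"shuffling"`, `"short_stepped"`, or `"wide_based"`.
#' @param effect Severity scalar in `[0, 1]` (values above 1 extrapolate).
#' @param seed Integer master seed; per-subject seeds are derived from it.
#' @param jitter_sd Between-subject log-normal jitter SD.
#' @param dir Optional directory: when given, recordings are written as
#'   keypoint CSVs plus a `manifest.csv`, and the returned manifest holds
#'   file paths instead of in-memory recordings.
#' @param ... Baseline parameter overrides applied to both presets (e.g.
#'   `laps_per_direction = 1` for shorter recordings).
#' @return A manifest data frame with columns `subject_id`,
#'   `label_shuffling`, `label_short_stepped`, `label_wide_based`, and
#'   either a `recording` list-column or a `path` column.
#' @export
simulate_cohort <- function(n_cases, n_controls,
                            feature = c("shuffling", "short_stepped", "wide_based"),
                            effect = 1, seed = 1L, jitter_sd = 0.06,
                            dir = NULL, ...) {
  feature <- match.arg(feature)
  stopifnot(n_cases >= 1, n_controls >= 1, effect >= 0)
  normal <- gait_preset("normal", ...)
  target <- gait_preset(feature, ...)
  jitter_fields <- c("step_length", "step_height", "stance_width",
                     "cadence", "trunk_sway", "foot_rotation")

  n_total <- n_cases + n_controls
  is_case <- rep(c(TRUE, FALSE), c(n_cases, n_controls))
  subjects <- sprintf("%s%02d", ifelse(is_case, "case", "ctrl"),
                      c(seq_len(n_cases), seq_len(n_controls)))
  recs <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    sub_seed <- (as.numeric(seed) * 100003 + i) %% (2^31 - 1)
    p <- unclass(normal)
    if (is_case[i]) {
      for (nm in names(p)) {
        if (is.numeric(p[[nm]]) && is.numeric(target[[nm]]) &&
            p[[nm]] > 0 && target[[nm]] != p[[nm]]) {
          p[[nm]] <- p[[nm]] * (target[[nm]] / p[[nm]])^effect
        } else if (!identical(target[[nm]], p[[nm]])) {
          p[[nm]] <- target[[nm]]
        }
      }
    }
    p <- with_preserved_seed(sub_seed, {
      for (nm in jitter_fields) {
        # truncated log-normal: keeps every subject kinematically plausible
        z <- max(-2 * jitter_sd, min(2 * jitter_sd, rnorm(1, 0, jitter_sd)))
        p[[nm]] <- p[[nm]] * exp(z)
      }
      p
    })
    p$seed <- sub_seed
    labels <- setNames(as.list(is_case[i] &
                                 c("shuffling", "short_stepped", "wide_based") == feature),
                       c("shuffling", "short_stepped", "wide_based"))
    recs[[i]] <- simulate_recording(do.call(gait_params, p[names(formals(gait_params))]),
                                    subject_id = subjects[i],
                                    labels = unlist(labels))
  }
  manifest <- data.frame(
    subject_id = subjects,
    label_shuffling = is_case & feature == "shuffling",
    label_short_stepped = is_case & feature == "short_stepped",
    label_wide_based = is_case & feature == "wide_based",
    stringsAsFactors = FALSE)
  if (is.null(dir)) {
    manifest$recording <- recs
  } else {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, paste0(subjects, ".csv"))
    for (i in seq_len(n_total)) write_recording(recs[[i]], paths[i])
    manifest$path <- paste0(subjects, ".csv")
    mpath <- file.path(dir, "manifest.csv")
    write.csv(cbind(manifest[, "subject_id", drop = FALSE],
                    path = manifest$path,
                    manifest[, grep("^label_", names(manifest))] + 0L),
              mpath, row.names = FALSE, quote = FALSE)
    manifest$path <- paths
  }
  manifest
}
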