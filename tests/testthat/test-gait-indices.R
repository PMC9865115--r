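# geometric fixtures: cross-shaped clouds give ellipses with known
# centers and axis-aligned major axes (see helper cross_cloud)

r4 <- sqrt(2 * qf(0.75, 2, 3))  # tolerance radius at n = 4

test_that("joint angle ranges reproduce hand-built geometry", {
  # hip centered at (0,0); knee ellipse centered at (1,0) with vertical
  # major-axis endpoints (1, +-1): the subtended angle is 90 degrees
  e_half <- sqrt(3 / 2) / r4  # makes the major semi-axis exactly 1
  clouds <- list(sagittal = list(
    hip_r = cross_cloud(c(0, 0), 0.01, 0.005),
    knee_r = cross_cloud(c(1, 0), 0.1, e_half),
    hip_l = cross_cloud(c(0, 0), 0.01, 0.005),
    knee_l = cross_cloud(c(1, 0), 0.1, e_half)))
  res <- hip_angle_range(tracks_from_clouds(clouds))
  expect_equal(res$value, 90, tolerance = 1e-6)
  expect_equal(unname(res$sides["l"]), unname(res$sides["r"]))

  # coincident centers: endpoints are opposite, the angle is 180
  clouds$sagittal$hip_r <- cross_cloud(c(1, 0), 0.01, 0.005)
  clouds$sagittal$hip_l <- cross_cloud(c(1, 0), 0.01, 0.005)
  expect_equal(hip_angle_range(tracks_from_clouds(clouds))$value, 180,
               tolerance = 1e-6)

  # knee angle range uses knee center and heel endpoints: (2, +-2) from
  # (0,0) is again 90 degrees
  clouds2 <- list(sagittal = list(
    knee_r = cross_cloud(c(0, 0), 0.01, 0.005),
    heel_r = cross_cloud(c(2, 0), 0.1, 2 * e_half),
    knee_l = cross_cloud(c(0, 0), 0.01, 0.005),
    heel_l = cross_cloud(c(2, 0), 0.1, 2 * e_half)))
  expect_equal(knee_angle_range(tracks_from_clouds(clouds2))$value, 90,
               tolerance = 1e-6)

  # endpoints collinear with the center on one side: angle 0
  clouds2$sagittal$knee_r <- cross_cloud(c(2, 5), 0.01, 0.005)
  clouds2$sagittal$knee_l <- cross_cloud(c(2, 5), 0.01, 0.005)
  expect_equal(knee_angle_range(tracks_from_clouds(clouds2))$value, 0,
               tolerance = 1e-6)
})

test_that("random configurations match an independent angle oracle", {
  set.seed(44)
  for (rep in 1:10) {
    clouds <- list(sagittal = list())
    for (k in c("hip_r", "hip_l", "knee_r", "knee_l"))
      clouds$sagittal[[k]] <- matrix(rnorm(40, sd = 0.3), ncol = 2) +
        rep(rnorm(2), each = 20)
    tr <- tracks_from_clouds(clouds)
    got <- hip_angle_range(tr)
    for (side in c("r", "l")) {
      hipc <- colMeans(clouds$sagittal[[paste0("hip_", side)]])
      ek <- fit_tolerance_ellipse(clouds$sagittal[[paste0("knee_", side)]], 0.75)
      ep <- major_axis_endpoints(ek)
      v1 <- ep[1, ] - hipc; v2 <- ep[2, ] - hipc
      oracle <- atan2(abs(v1[1] * v2[2] - v1[2] * v2[1]),
                      sum(v1 * v2)) * 180 / pi
      expect_equal(unname(got$sides[side]), unname(oracle),
                   tolerance = 1e-9)
    }
  }
})

test_that("degenerate distal ellipses yield a zero angle with a warning", {
  clouds <- list(sagittal = list(
    hip_r = cross_cloud(c(0, 0), 0.01, 0.005),
    knee_r = cbind(seq(0, 1, length.out = 8), 0.5),  # collinear
    hip_l = cross_cloud(c(0, 0), 0.01, 0.005),
    knee_l = cbind(seq(0, 1, length.out = 8), 0.5)))
  w <- testthat::capture_warnings(
    res <- hip_angle_range(tracks_from_clouds(clouds)))
  expect_match(w, "degenerate", all = TRUE)
  expect_gt(length(w), 0L)
  expect_equal(res$value, 0)
})

test_that("heel amplitude modes measure the vertical scatter", {
  flat <- cbind(rnorm(20), 0.3)
  clouds <- list(sagittal = list(heel_r = flat, heel_l = flat))
  expect_equal(heel_vertical_amplitude(tracks_from_clouds(clouds),
                                       mode = "raw")$value, 0)
  tall <- cross_cloud(c(0, 0), 0.1, 2)
  clouds2 <- list(sagittal = list(heel_r = tall, heel_l = tall))
  expect_equal(heel_vertical_amplitude(tracks_from_clouds(clouds2),
                                       mode = "raw")$value, 4)
  expect_equal(heel_vertical_amplitude(tracks_from_clouds(clouds2),
                                       mode = "ellipse")$value,
               2 * r4 * sqrt(8 / 3), tolerance = 1e-9)
})

test_that("foot angle reproduces constructed heel-toe vectors", {
  mk <- function(hr, tr, hl, tl) tracks_from_clouds(list(axial = list(
    heel_r = cross_cloud(hr, 0.01, 0.005), toe_r = cross_cloud(tr, 0.01, 0.005),
    heel_l = cross_cloud(hl, 0.01, 0.005), toe_l = cross_cloud(tl, 0.01, 0.005))))
  # parallel feet: both heel->toe vectors are (0, 1)
  expect_equal(foot_angle(mk(c(0.1, 0), c(0.1, 1),
                             c(-0.1, 0), c(-0.1, 1)))$value, 0,
               tolerance = 1e-6)
  # vectors (1,1) and (-1,1): 90 degrees
  expect_equal(foot_angle(mk(c(0, 0), c(1, 1), c(0, 0), c(-1, 1)))$value,
               90, tolerance = 1e-6)
  # coincident heel and toe centers: undefined
  expect_true(is.na(foot_angle(mk(c(0, 0), c(0, 0),
                                  c(0, 0), c(-1, 1)))$value))
})

test_that("outward shifts follow the construction and the exact identity", {
  mk <- function(stance) {
    half <- stance / 2
    tracks_from_clouds(list(axial = list(
      hip_r = cross_cloud(c(0.16, 0), 0.01, 0.005),
      hip_l = cross_cloud(c(-0.16, 0), 0.01, 0.005),
      heel_r = cross_cloud(c(half, 0), 0.01, 0.005),
      heel_l = cross_cloud(c(-half, 0), 0.01, 0.005),
      toe_r = cross_cloud(c(half + 0.05, 0.2), 0.01, 0.005),
      toe_l = cross_cloud(c(-half - 0.05, 0.2), 0.01, 0.005))))
  }
  # toes 0.05 outside the heels on each side, independent of stance width
  for (stance in c(0.1, 0.4)) {
    sh <- outward_shifts(mk(stance))
    expect_equal(sh$toe, 0.05, tolerance = 1e-9)
    expect_equal(sh$heel, stance / 2 - 0.16, tolerance = 1e-9)
    expect_equal(sh$leg, sh$heel + sh$toe)
  }
  # heels directly below the hips: heel shift 0
  sh0 <- outward_shifts(mk(0.32))
  expect_equal(sh0$heel, 0, tolerance = 1e-9)

  # identity holds on arbitrary random clouds, exactly
  set.seed(5)
  clouds <- list(axial = list())
  for (k in c("hip_r", "hip_l", "heel_r", "heel_l", "toe_r", "toe_l"))
    clouds$axial[[k]] <- matrix(rnorm(30), ncol = 2)
  sh <- outward_shifts(tracks_from_clouds(clouds))
  expect_identical(sh$leg, sh$heel + sh$toe)
  expect_identical(sh$sides[, "leg"],
                   sh$sides[, "heel"] + sh$sides[, "toe"])
})

test_that("cutoff flags use strict inequalities in the printed direction", {
  base <- c(hip_angle_range = 50, knee_angle_range = 60,
            heel_vertical_amplitude = 0.2, foot_angle = 20,
            heel_outward_shift = -0.2, toe_outward_shift = 0.05,
            leg_outward_shift = -0.15)
  expect_false(any(apply_cutoffs(base)))

  v <- base; v["hip_angle_range"] <- 29.9
  expect_true(apply_cutoffs(v)[["hip_angle_range"]])
  v["hip_angle_range"] <- 30.0  # boundary: no flag
  expect_false(apply_cutoffs(v)[["hip_angle_range"]])

  v <- base; v["leg_outward_shift"] <- 0.1  # boundary above-direction
  expect_false(apply_cutoffs(v)[["leg_outward_shift"]])
  v["leg_outward_shift"] <- 0.1001
  expect_true(apply_cutoffs(v)[["leg_outward_shift"]])

  # missing index: flag absent (NA), not FALSE
  v <- base; v["heel_outward_shift"] <- NA
  fl <- apply_cutoffs(v)
  expect_true(is.na(fl[["heel_outward_shift"]]))
  expect_true(is.na(apply_cutoffs(v)[["leg_outward_shift"]]) ||
                !fl[["leg_outward_shift"]])
})

test_that("a normal simulated gait raises no flags", {
  gi <- compute_gait_indices(normal_tracks())
  expect_false(any(gi$flags, na.rm = TRUE))
  expect_equal(gi$indices[["leg_outward_shift"]],
               gi$indices[["heel_outward_shift"]] +
                 gi$indices[["toe_outward_shift"]])
})

test_that("mirrored recordings swap the per-side index values", {
  rec <- cached("bf_rec", simulate_recording(
    gait_preset("normal", seed = 9, laps_per_direction = 1)))
  gi <- compute_gait_indices(project_recording(rec))
  gi_m <- compute_gait_indices(project_recording(mirror_recording(rec)))
  for (idx in rownames(gi$sides)) {
    expect_equal(unname(gi_m$sides[idx, "l"]), unname(gi$sides[idx, "r"]),
                 tolerance = 1e-6)
    expect_equal(unname(gi_m$sides[idx, "r"]), unname(gi$sides[idx, "l"]),
                 tolerance = 1e-6)
  }
  expect_equal(gi_m$indices, gi$indices, tolerance = 1e-6)
})

test_that("indices respond monotonically to their gait parameter", {
  sim_idx <- function(field, value, seed) {
    args <- list("normal", seed = seed, laps_per_direction = 1)
    args[[field]] <- value
    compute_gait_indices(project_recording(
      simulate_recording(do.call(gait_preset, args))))$indices
  }
  amp <- vapply(c(0.015, 0.075, 0.15), function(h)
    sim_idx("step_height", h, 61)[["heel_vertical_amplitude"]], 0)
  expect_true(all(diff(amp) > 0))

  knee <- vapply(c(0.24, 0.42, 0.60), function(L)
    sim_idx("step_length", L, 62)[["knee_angle_range"]], 0)
  expect_true(all(diff(knee) > 0))

  leg <- vapply(c(0.10, 0.20, 0.30), function(w)
    sim_idx("stance_width", w, 63)[["leg_outward_shift"]], 0)
  expect_true(all(diff(leg) > 0))
})

test_that("pathological presets shift their target index the stated way", {
  shuf <- compute_gait_indices(project_recording(
    simulate_recording(gait_preset("shuffling", seed = 71,
                                   laps_per_direction = 1))))$indices
  short <- compute_gait_indices(project_recording(
    simulate_recording(gait_preset("short_stepped", seed = 71,
                                   laps_per_direction = 1))))$indices
  wide <- compute_gait_indices(project_recording(
    simulate_recording(gait_preset("wide_based", seed = 71,
                                   laps_per_direction = 1))))$indices
  nrm <- compute_gait_indices(project_recording(
    simulate_recording(gait_preset("normal", seed = 71,
                                   laps_per_direction = 1))))$indices

  expect_lt(shuf[["heel_vertical_amplitude"]],
            nrm[["heel_vertical_amplitude"]])
  expect_lt(short[["knee_angle_range"]], nrm[["knee_angle_range"]])
  expect_gt(wide[["leg_outward_shift"]], nrm[["leg_outward_shift"]])
  expect_gt(wide[["leg_outward_shift"]], 0.1)
})
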