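test_that("single-plane angles satisfy their alignment contracts", {
  mk <- function(rc, lc, nb = c(0, -70, 0)) landmark_set(rc, lc, nb)

  # yaw: aligned input, derived tangent case, z-only offset
  expect_equal(compute_yaw(mk(c(-30, 0, 0), c(30, 0, 0))), 0)
  lm <- mk(c(-30, -10, 0), c(30, 10, 0))
  yaw <- compute_yaw(lm)
  expect_equal(abs(yaw), atan(20 / 60) * 180 / pi, tolerance = 1e-12)
  rot <- transform_landmarks(lm, rigid_transform(euler_to_matrix(yaw, 0, 0),
                                                 cochlear_midpoint(lm)),
                             validate = FALSE)
  expect_lt(abs(rot$left_cochlea[2] - rot$right_cochlea[2]), 1e-9)
  expect_gt(rot$left_cochlea[1], rot$right_cochlea[1])
  expect_equal(compute_yaw(mk(c(-30, 0, -5), c(30, 0, 5))), 0)

  # pitch: aligned, derived, x-only offset
  expect_equal(compute_pitch(mk(c(-30, 0, 0), c(30, 0, 0), c(0, -70, 0))), 0)
  lm2 <- mk(c(-30, 0, 0), c(30, 0, 0), c(0, -80, 25))
  pitch <- compute_pitch(lm2)
  expect_equal(abs(pitch), atan(25 / 80) * 180 / pi, tolerance = 1e-12)
  rot2 <- transform_landmarks(lm2, rigid_transform(euler_to_matrix(0, pitch, 0),
                                                   cochlear_midpoint(lm2)),
                              validate = FALSE)
  expect_lt(abs(rot2$nasal_bridge[3] - rot2$right_cochlea[3]), 1e-9)
  expect_lt(rot2$nasal_bridge[2], rot2$right_cochlea[2])
  expect_equal(compute_pitch(mk(c(-30, 0, 0), c(30, 0, 0), c(-20, -70, 0))), 0)

  # roll: aligned, derived, y-only offset
  expect_equal(compute_roll(mk(c(-30, 0, 0), c(30, 0, 0))), 0)
  lm3 <- mk(c(-30, 0, -5), c(30, 0, 5))
  roll <- compute_roll(lm3)
  expect_equal(abs(roll), atan(10 / 60) * 180 / pi, tolerance = 1e-12)
  rot3 <- transform_landmarks(lm3, rigid_transform(euler_to_matrix(0, 0, roll),
                                                   cochlear_midpoint(lm3)),
                              validate = FALSE)
  expect_lt(abs(rot3$left_cochlea[3] - rot3$right_cochlea[3]), 1e-9)
  expect_gt(rot3$left_cochlea[1], rot3$right_cochlea[1])
  expect_equal(compute_roll(mk(c(-30, -3, 0), c(30, 3, 0))), 0)
})

test_that("degenerate geometry raises informative errors", {
  lm <- landmark_set(c(-30, 10, -15), c(30, 10, -15), c(0, -60, -10))
  lm$right_cochlea <- c(0, 0, 0); lm$left_cochlea <- c(0, 0, 10)  # stacked in z
  expect_error(compute_yaw(lm), "degenerate")
  lm2 <- landmark_set(c(-30, 10, 0), c(30, 10, 0), c(0, -60, 0))
  lm2$nasal_bridge <- lm2$right_cochlea + c(10, 0, 0)
  expect_error(compute_pitch(lm2), "degenerate")
})

test_that("sequential alignment composes in order and zeroes z exactly", {
  # identity on already-aligned landmarks
  lm0 <- landmark_set(c(-30, 0, 0), c(30, 0, 0), c(0, -70, 0))
  fit0 <- compute_alignment_sequential(lm0)
  expect_equal(unname(fit0$angles), c(0, 0, 0))
  expect_equal(fit0$transform$rotation, diag(3))

  for (seed in 1:25) {
    lm <- random_landmarks(seed)
    fit <- compute_alignment_sequential(lm)
    # composite equals the ordered product of the three plane rotations
    with(as.list(fit$angles), {
      prod <- euler_to_matrix(yaw_deg, pitch_deg, roll_deg)
      expect_lt(max(abs(fit$transform$rotation - prod)), 1e-12)
    })
    al <- transform_landmarks(lm, fit$transform, validate = FALSE)
    # roll is applied last: cochlear z deviation is exactly zero
    expect_lt(abs(al$left_cochlea[3] - al$right_cochlea[3]), 1e-9)
    # nasal bridge stays anterior and left stays left
    expect_gt(al$left_cochlea[1], al$right_cochlea[1])
    expect_lt(al$nasal_bridge[2], al$right_cochlea[2])
  }
})

test_that("sequential residual y deviation follows the closed form", {
  # |y_left - y_right| after the composite equals
  # |z_left - z_right before pitch| * |sin(pitch)|; yaw does not change z,
  # so the pre-pitch z gap is the input z gap.
  for (seed in 1:50) {
    lm <- random_landmarks(seed)
    fit <- compute_alignment_sequential(lm)
    al <- transform_landmarks(lm, fit$transform, validate = FALSE)
    resid <- abs(al$left_cochlea[2] - al$right_cochlea[2])
    dz <- abs(lm$left_cochlea[3] - lm$right_cochlea[3])
    law <- dz * abs(sin(fit$angles["pitch_deg"] * pi / 180))
    expect_lt(abs(resid - unname(law)), 1e-9)
  }
})

test_that("exact alignment satisfies all three constraints on random geometry", {
  for (seed in 1:100) {
    lm <- random_landmarks(seed)
    tr <- compute_alignment_exact(lm)
    expect_lt(max(abs(crossprod(tr$rotation) - diag(3))), 1e-9)
    expect_lt(abs(det(tr$rotation) - 1), 1e-9)
    al <- transform_landmarks(lm, tr, validate = FALSE)
    expect_lt(abs(al$left_cochlea[2] - al$right_cochlea[2]), 1e-9)
    expect_lt(abs(al$left_cochlea[3] - al$right_cochlea[3]), 1e-9)
    expect_lt(abs(al$nasal_bridge[3] - al$right_cochlea[3]), 1e-9)
    expect_gt(al$left_cochlea[1], al$right_cochlea[1])
    expect_lt(al$nasal_bridge[2], al$right_cochlea[2])
  }
})

test_that("exact alignment inverts a known misalignment of aligned anatomy", {
  base <- landmark_set(c(-30, 10, -15), c(30, 10, -15), c(0, -60, -15))
  Q <- euler_to_matrix(24, -31, 17)
  tr_q <- rigid_transform(Q, cochlear_midpoint(base))
  moved <- transform_landmarks(base, tr_q, validate = FALSE)
  rec <- compute_alignment_exact(moved)
  expect_lt(max(abs(rec$rotation - t(Q))), 1e-9)
})

test_that("identity alignment on aligned landmarks is the identity rotation", {
  lm <- landmark_set(c(-28, 4, -12), c(32, 4, -12), c(2, -64, -12))
  tr <- compute_alignment_exact(lm)
  expect_lt(max(abs(tr$rotation - diag(3))), 1e-9)
})

test_that("sequential and exact rotations differ by the residual correction", {
  # The exact rotation corrects the sequential result by a yaw (fixing the
  # residual cochlear y deviation) followed by a pitch (fixing the nasal
  # bridge z residual that roll re-introduced); the geodesic gap between
  # the two rotations is bounded by the sum of those two correction
  # angles, and a second sequential pass lands exactly on the exact mode.
  for (seed in 1:40) {
    lm <- random_landmarks(seed)
    seq_tr <- compute_alignment_sequential(lm)$transform
    ex_tr <- compute_alignment_exact(lm)
    rel <- seq_tr$rotation %*% t(ex_tr$rotation)
    geodesic <- acos(min(1, max(-1, (sum(diag(rel)) - 1) / 2))) * 180 / pi

    al <- transform_landmarks(lm, seq_tr, validate = FALSE)
    fit2 <- compute_alignment_sequential(al, center = seq_tr$center)
    expect_lt(abs(fit2$angles["roll_deg"]), 1e-9)
    bound <- abs(fit2$angles["yaw_deg"]) + abs(fit2$angles["pitch_deg"])
    expect_lte(geodesic, unname(bound) + 1e-9)

    two_pass <- fit2$transform$rotation %*% seq_tr$rotation
    expect_lt(max(abs(two_pass - ex_tr$rotation)), 1e-9)
  }
})

test_that("transform_points is exact, rigid and invertible", {
  tr <- rigid_transform(euler_to_matrix(33, -12, 21), center = c(5, -4, 3))
  pts <- matrix(stats::rnorm(30), ncol = 3) * 40
  expect_points_equal(transform_points(pts, rigid_transform(diag(3), c(1, 2, 3))),
                      pts, tol = 1e-12)
  out <- transform_points(pts, tr)
  back <- transform_points(out, invert_transform(tr))
  expect_points_equal(back, pts, tol = 1e-9)
  expect_lt(max(abs(as.matrix(dist(out)) - as.matrix(dist(pts)))), 1e-9)
})

test_that("resampling through the identity changes nothing", {
  ph <- generate_phantom(coarse_spec())
  out <- apply_transform(ph$volume, rigid_transform(diag(3), c(0, 0, 0)))
  expect_lt(max(abs(out$voxels - ph$volume$voxels)), 1e-6)
})

test_that("expand_z preserves head mass through a 30-degree pitch", {
  ph <- generate_phantom(coarse_spec())
  tr <- rigid_transform(euler_to_matrix(0, 30, 0),
                        center = cochlear_midpoint(ph$landmarks))
  out <- apply_transform(ph$volume, tr, expand_z = TRUE)
  thr <- -200  # above-air tissue threshold
  n_in <- sum(ph$volume$voxels > thr)
  n_out <- sum(out$voxels > thr)
  expect_lt(abs(n_out - n_in) / n_in, 0.02)
})

test_that("one composite interpolation beats three sequential ones", {
  ph <- generate_phantom(coarse_spec())
  lab <- ph$labels$right_cochlea
  center <- cochlear_midpoint(ph$landmarks)
  set.seed(42)
  wins <- 0L; n_trials <- 10L
  for (i in seq_len(n_trials)) {
    ang <- runif(3, -40, 40)
    composite <- rigid_transform(euler_to_matrix(ang[1], ang[2], ang[3]), center)
    one <- apply_transform(lab, composite, expand_z = TRUE)
    three <- apply_transform(lab, rigid_transform(ctalign:::rot_z(ang[1]), center),
                             expand_z = TRUE)
    three <- apply_transform(three, rigid_transform(ctalign:::rot_x(ang[2]), center),
                             expand_z = TRUE)
    three <- apply_transform(three, rigid_transform(ctalign:::rot_y(ang[3]), center),
                             expand_z = TRUE)
    truth <- as.numeric(transform_points(label_center_of_mass(lab), composite))
    e1 <- sqrt(sum((label_center_of_mass(one) - truth)^2))
    e3 <- sqrt(sum((label_center_of_mass(three) - truth)^2))
    if (e1 <= e3) wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.7 * n_trials))
})

test_that("align_volume runs end-to-end in both modes", {
  spec <- coarse_spec()
  ph <- generate_phantom(spec)
  moved <- apply_misalignment(ph$volume, ph$landmarks, misalignment_spec(20, 15, 10))

  ex <- align_volume(moved$volume, moved$landmarks, mode = "exact")
  expect_lt(ex$residuals["y_dev_mm"], 1e-9)
  expect_lt(ex$residuals["z_dev_mm"], 1e-9)

  sq <- align_volume(moved$volume, moved$landmarks, mode = "sequential")
  expect_lt(sq$residuals["z_dev_mm"], 1e-9)
  dz <- abs(moved$landmarks$left_cochlea[3] - moved$landmarks$right_cochlea[3])
  bound <- dz * abs(sin(sq$angles["pitch_deg"] * pi / 180))
  expect_lte(sq$residuals["y_dev_mm"], unname(bound) + 1e-9)

  # sagittal offset tilts the final pitch without touching symmetry
  off <- align_volume(moved$volume, moved$landmarks, mode = "exact",
                      sagittal_offset_deg = 5, expand_z = FALSE)
  expect_lt(off$residuals["y_dev_mm"], 1e-6)
  expect_error(align_volume(moved$volume, moved$landmarks,
                            sagittal_offset_deg = 20), "sagittal")
})

test_that("transforms serialize to JSON and back", {
  tr <- rigid_transform(euler_to_matrix(10, -20, 5), center = c(1, -2, 3),
                        angles = c(yaw_deg = 10, pitch_deg = -20, roll_deg = 5),
                        mode = "sequential")
  f <- withr::local_tempfile(fileext = ".json")
  write_transform(tr, f)
  back <- read_transform(f)
  expect_lt(max(abs(back$rotation - tr$rotation)), 1e-12)
  expect_equal(back$center, tr$center)
  expect_identical(back$mode, "sequential")
})
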