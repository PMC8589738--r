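test_that("board model has the planar interior-corner lattice", {
  b <- board_model(5, 7, 10)
  expect_equal(nrow(b$corners), 4 * 6)
  expect_true(all(b$corners$z == 0))
  expect_error(board_model(1, 7, 10), class = "ctbiopsim_validation_error")
})

test_that("pinhole projection behaves at the principal point and under fx scaling", {
  b <- board_model(3, 3, 10)
  cam <- camera_model(fx = 1000, fy = 1000, cx = 640, cy = 360,
                      width = 1280, height = 720)
  # put corner 1 (board point (10,10,0)) on the optical axis
  pose <- rigid_transform(diag(3), c(-10, -10, 400))
  obs <- project_corners(b, cam, pose)
  expect_equal(c(obs$u[1], obs$v[1]), c(640, 360))
  cam2 <- camera_model(fx = 2000, fy = 1000, cx = 640, cy = 360,
                       width = 1280, height = 720)
  obs2 <- project_corners(b, cam2, pose)
  expect_equal(obs2$u - cam$cx, 2 * (obs$u - cam$cx), tolerance = 1e-12)
  expect_equal(obs2$v, obs$v)
})

test_that("projection matches the homogeneous-coordinates oracle", {
  set.seed(41)
  b <- board_model(6, 8, 12)
  cam <- camera_model()
  for (i in 1:20) {
    pose <- rigid_transform(
      rot_axis_angle(rnorm(3), runif(1, 0, 0.5)),
      c(runif(2, -80, 20), runif(1, 300, 800)))
    obs <- project_corners(b, cam, pose)
    uv <- project_oracle(b, cam, pose)
    expect_lt(max(abs(cbind(obs$u, obs$v) - uv)), 1e-9)
  }
})

test_that("corners behind the camera or outside the image are not visible", {
  b <- board_model(3, 3, 10)
  cam <- camera_model()
  behind <- rigid_transform(diag(3), c(0, 0, -200))
  expect_false(any(project_corners(b, cam, behind)$visible))
  off_img <- rigid_transform(diag(3), c(5000, 0, 500))
  expect_false(any(project_corners(b, cam, off_img)$visible))
})

test_that("noise-free observations recover the generating pose to 1e-6", {
  set.seed(42)
  b <- board_model(9, 9, 15)
  cam <- camera_model()
  for (i in 1:100) {
    pose <- ctbiopsim:::random_board_pose(b, cam, 500)
    obs <- simulate_observation(b, cam, pose, noise_sigma = 0)
    est <- estimate_pose(b, cam, obs)
    expect_lt(norm(est$pose$rotation - pose$rotation, "F"), 1e-6)
    expect_lt(sqrt(sum((est$pose$translation - pose$translation)^2)), 1e-6)
    expect_lt(est$rmse, 1e-6)
  }
})

test_that("too few or collinear corners raise the documented errors", {
  b <- board_model(9, 9, 15)
  cam <- camera_model()
  pose <- rigid_transform(diag(3), c(-60, -60, 500))
  obs <- project_corners(b, cam, pose)
  obs3 <- obs; obs3$visible[-(1:3)] <- FALSE
  expect_error(estimate_pose(b, cam, obs3),
               class = "ctbiopsim_insufficient_observations_error")
  # a single corner row is collinear
  col_b <- board_model(2, 8, 10)
  col_obs <- project_corners(col_b, cam, pose)
  expect_error(estimate_pose(col_b, cam, col_obs),
               class = "ctbiopsim_degenerate_configuration_error")
})

test_that("pose error degrades monotonically with corner noise", {
  b <- board_model(9, 9, 15)
  cam <- camera_model()
  errs <- vapply(c(0, 0.25, 0.5, 1.0), function(s) {
    st <- pose_error_study(b, cam, n_poses = 30, noise_sigma = s, seed = 99)
    c(st$median_rotation_error_deg, st$median_translation_error_mm)
  }, numeric(2))
  expect_true(all(diff(errs[1, ]) >= 0))
  expect_true(all(diff(errs[2, ]) >= 0))
})

test_that("Gauss-Newton refinement never degrades the reprojection RMSE", {
  set.seed(44)
  b <- board_model(7, 7, 12)
  cam <- camera_model()
  for (i in 1:25) {
    pose <- ctbiopsim:::random_board_pose(b, cam, 500)
    obs <- simulate_observation(b, cam, pose, noise_sigma = 1.0)
    vis <- obs[obs$visible, ]
    xy <- as.matrix(b$corners[match(vis$corner_id, b$corners$corner_id),
                              c("x", "y")])
    uv <- cbind(vis$u, vis$v)
    raw_pose <- ctbiopsim:::pose_from_homography(
      ctbiopsim:::dlt_homography(xy, uv), cam)
    rmse_raw <- ctbiopsim:::point_rmse(
      ctbiopsim:::reprojection_residuals(raw_pose, xy, uv, cam))
    est <- estimate_pose(b, cam, obs)
    expect_lte(est$rmse, rmse_raw + 1e-12)
  }
})

test_that("simulated observations are deterministic and occlusion counts exact", {
  b <- board_model(9, 9, 15)
  cam <- camera_model()
  pose <- rigid_transform(diag(3), c(-60, -60, 500))
  clean <- project_corners(b, cam, pose)
  o0 <- simulate_observation(b, cam, pose, noise_sigma = 0,
                             occlusion_fraction = 0, seed = 1)
  expect_equal(o0, clean)
  o5 <- simulate_observation(b, cam, pose, occlusion_fraction = 0.5, seed = 1)
  expect_equal(sum(o5$visible), 32)
  o5b <- simulate_observation(b, cam, pose, noise_sigma = 0.7,
                              occlusion_fraction = 0.5, seed = 123)
  o5c <- simulate_observation(b, cam, pose, noise_sigma = 0.7,
                              occlusion_fraction = 0.5, seed = 123)
  expect_identical(o5b, o5c)
  expect_error(simulate_observation(b, cam, pose, occlusion_fraction = 1),
               class = "ctbiopsim_validation_error")
})

test_that("needle state follows the marker through the calibration transform", {
  # identity everywhere
  st <- needle_state_from_marker(rigid_transform(),
                                 needle_model(marker_to_tip = rigid_transform()))
  expect_equal(st$tip, c(0, 0, 0))
  expect_equal(st$axis, c(0, 0, 1))
  # default: marker at the hub, tip shaft_length along -z of the tip frame
  nm <- needle_model(shaft_length = 120)
  st2 <- needle_state_from_marker(rigid_transform(), nm)
  expect_equal(st2$tip, c(0, 0, -120))
  # random composition matches the 4x4 matrix oracle
  set.seed(45)
  for (i in 1:20) {
    mp <- rand_rigid()
    cal <- rand_rigid(t_scale = 30)
    st3 <- needle_state_from_marker(mp, needle_model(marker_to_tip = cal))
    m <- homog(mp) %*% homog(cal)
    expect_equal(st3$tip, apply_homog(m, c(0, 0, 0)), tolerance = 1e-9)
    expect_equal(st3$axis, as.vector(m[1:3, 1:3] %*% c(0, 0, 1)),
                 tolerance = 1e-9)
  }
})
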