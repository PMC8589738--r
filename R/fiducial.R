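#' Planar chessboard fiducial board model
#'
#' Models the interior-corner lattice of a chessboard fiducial of
#' `squares_x` by `squares_y` squares with side `square_size` mm. The board
#' frame has its origin at the outer corner of the first square, x/y in the
#' board plane and z = 0 for every corner (planar target).
#'
#' @param squares_x,squares_y number of squares along each side.
#' @param square_size square side length in mm.
#' @return An object of class `board_model` with a `corners` data.frame
#'   (`corner_id`, `x`, `y`, `z`); there are
#'   `(squares_x - 1) * (squares_y - 1)` interior corners.
#' @export
board_model <- function(squares_x = 5, squares_y = 7, square_size = 10) {
  if (squares_x < 2 || squares_y < 2 || square_size <= 0) {
    abort_ct("validation_error", "board needs >= 2 squares per side and positive square_size")
  }
  grid <- expand.grid(ix = seq_len(squares_x - 1), iy = seq_len(squares_y - 1))
  corners <- data.frame(corner_id = seq_len(nrow(grid)),
                        x = grid$ix * square_size,
                        y = grid$iy * square_size,
                        z = 0)
  structure(list(squares_x = squares_x, squares_y = squares_y,
                 square_size = square_size, corners = corners),
            class = "board_model")
}

#' Ideal pinhole camera model
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param cx,cy principal point in pixels (inside the image).
#' @param width,height image size in pixels.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(fx = 1400, fy = 1400, cx = 960, cy = 540,
                         width = 1920, height = 1080) {
  if (fx <= 0 || fy <= 0) abort_ct("validation_error", "focal lengths must be positive")
  if (cx < 0 || cx > width || cy < 0 || cy > height) {
    abort_ct("validation_error", "principal point must lie inside the image")
  }
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = width, height = height),
            class = "camera_model")
}

camera_K <- function(camera) {
  matrix(c(camera$fx, 0, 0, 0, camera$fy, 0, camera$cx, camera$cy, 1), 3, 3)
}

#' Project board corners through a pinhole camera
#'
#' Transforms each board corner by `pose` (board frame -> camera frame) and
#' applies the pinhole projection `u = fx X/Z + cx`, `v = fy Y/Z + cy`.
#' Corners behind the camera (Z <= 0) or projecting outside the image are
#' flagged not visible (their u/v are still reported).
#'
#' @param board A [board_model()].
#' @param camera A [camera_model()].
#' @param pose board-to-camera [rigid_transform()].
#' @return data.frame with columns `corner_id`, `u`, `v`, `visible`.
#' @export
project_corners <- function(board, camera, pose) {
  pts <- as.matrix(board$corners[, c("x", "y", "z")])
  pc <- apply_transform(pose, pts)
  z <- pc[, 3]
  in_front <- z > 0
  u <- camera$fx * pc[, 1] / z + camera$cx
  v <- camera$fy * pc[, 2] / z + camera$cy
  visible <- in_front & u >= 0 & u <= camera$width & v >= 0 & v <= camera$height
  data.frame(corner_id = board$corners$corner_id, u = u, v = v,
             visible = visible)
}

#' Simulate a corner detection from the headset camera
#'
#' Stand-in for a real fiducial detector: projects the board corners under
#' the true pose, randomly occludes a fraction of the visible ones, and
#' perturbs the rest with isotropic Gaussian pixel noise. Deterministic for
#' a given seed.
#'
#' @param board A [board_model()].
#' @param camera A [camera_model()].
#' @param true_pose board-to-camera [rigid_transform()].
#' @param noise_sigma pixel-noise standard deviation (px).
#' @param occlusion_fraction fraction of visible corners dropped, in \[0, 1).
#' @param seed integer RNG seed, or `NULL` for the session RNG.
#' @return data.frame as [project_corners()], with occluded corners flagged
#'   not visible and noisy u/v on the visible ones.
#' @export
simulate_observation <- function(board, camera, true_pose, noise_sigma = 0,
                                 occlusion_fraction = 0, seed = NULL) {
  if (occlusion_fraction < 0 || occlusion_fraction >= 1) {
    abort_ct("validation_error", "occlusion_fraction must be in [0, 1)")
  }
  obs <- project_corners(board, camera, true_pose)
  with_seed(seed, {
    vis_idx <- which(obs$visible)
    n_drop <- round(occlusion_fraction * length(vis_idx))
    if (n_drop > 0) {
      obs$visible[sample(vis_idx, n_drop)] <- FALSE
    }
    still <- which(obs$visible)
    if (noise_sigma > 0 && length(still) > 0) {
      obs$u[still] <- obs$u[still] + rnorm(length(still), 0, noise_sigma)
      obs$v[still] <- obs$v[still] + rnorm(length(still), 0, noise_sigma)
    }
  })
  obs
}

# Normalized DLT homography from planar points (x,y) to image points (u,v).
dlt_homography <- function(xy, uv) {
  norm_t <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- sqrt(2) / mean(d)
    rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
  }
  t1 <- norm_t(xy); t2 <- norm_t(uv)
  ap <- cbind(xy, 1) %*% t(t1)
  bp <- cbind(uv, 1) %*% t(t2)
  n <- nrow(xy)
  a <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- ap[i, ]; u <- bp[i, 1]; v <- bp[i, 2]
    a[2 * i - 1, ] <- c(-X, 0, 0, 0, u * X)
    a[2 * i, ] <- c(0, 0, 0, -X, v * X)
  }
  h <- svd(a, nu = 0)$v[, 9]
  hmat <- matrix(h, 3, 3, byrow = TRUE)
  solve(t2) %*% hmat %*% t1
}

pose_from_homography <- function(h, camera) {
  m <- solve(camera_K(camera)) %*% h
  lam <- 2 / (sqrt(sum(m[, 1]^2)) + sqrt(sum(m[, 2]^2)))
  if (m[3, 3] < 0) lam <- -lam     # board must sit in front of the camera
  r1 <- lam * m[, 1]; r2 <- lam * m[, 2]
  r <- nearest_rotation(cbind(r1, r2, crossprod_vec(r1, r2)))
  rigid_transform(r, lam * m[, 3])
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

reprojection_residuals <- function(pose, xy, uv, camera) {
  pc <- apply_transform(pose, cbind(xy, 0))
  u <- camera$fx * pc[, 1] / pc[, 3] + camera$cx
  v <- camera$fy * pc[, 2] / pc[, 3] + camera$cy
  c(uv[, 1] - u, uv[, 2] - v)
}

#' Estimate a planar fiducial pose from corner observations
#'
#' Planar perspective-n-point: a normalized-DLT homography from board (x, y)
#' to observed image points is decomposed into an initial rotation and
#' translation (nearest-rotation orthonormalization via SVD), then refined by
#' Gauss-Newton least squares on the reprojection error (at most 50
#' iterations, stopping when the RMSE improves by less than 1e-10 px).
#'
#' @param board A [board_model()].
#' @param camera A [camera_model()].
#' @param observations data.frame as returned by [project_corners()] /
#'   [simulate_observation()]; only rows with `visible == TRUE` are used.
#' @return list with `pose` (board-to-camera [rigid_transform()]) and
#'   `rmse` (final reprojection RMSE in px).
#' @export
estimate_pose <- function(board, camera, observations) {
  obs <- observations[observations$visible, , drop = FALSE]
  if (nrow(obs) < 4) {
    abort_ct("insufficient_observations_error",
             "pose estimation needs >= 4 visible corners (got %d)", nrow(obs))
  }
  idx <- match(obs$corner_id, board$corners$corner_id)
  xy <- as.matrix(board$corners[idx, c("x", "y")])
  uv <- cbind(obs$u, obs$v)
  sv <- svd(scale(xy, scale = FALSE))$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) {
    abort_ct("degenerate_configuration_error",
             "visible corners are collinear; pose is unobservable")
  }
  pose <- pose_from_homography(dlt_homography(xy, uv), camera)
  refined <- refine_pose_gn(pose, xy, uv, camera)
  list(pose = refined$pose, rmse = refined$rmse)
}

point_rmse <- function(res) {
  n <- length(res) / 2
  sqrt(sum(res^2) / n)
}

refine_pose_gn <- function(pose, xy, uv, camera, max_iter = 50, tol = 1e-10) {
  cur <- pose
  res <- reprojection_residuals(cur, xy, uv, camera)
  rmse <- point_rmse(res)
  for (it in seq_len(max_iter)) {
    # numeric Jacobian in (rotation-delta, translation) about the current pose
    eps <- 1e-6
    jac <- matrix(0, length(res), 6)
    for (j in 1:6) {
      d <- rep(0, 6); d[j] <- eps
      p2 <- perturb_pose(cur, d)
      jac[, j] <- (reprojection_residuals(p2, xy, uv, camera) - res) / eps
    }
    step <- tryCatch(solve(crossprod(jac), crossprod(jac, -res)),
                     error = function(e) NULL)
    if (is.null(step)) break
    cand <- perturb_pose(cur, -as.vector(step))
    res2 <- reprojection_residuals(cand, xy, uv, camera)
    rmse2 <- point_rmse(res2)
    if (!is.finite(rmse2) || rmse2 > rmse) break
    improve <- rmse - rmse2
    cur <- cand; res <- res2; rmse <- rmse2
    if (improve < tol) break
  }
  list(pose = cur, rmse = rmse)
}

perturb_pose <- function(pose, delta) {
  rigid_transform(rotation_from_axis_angle(delta[1:3]) %*% pose$rotation,
                  pose$translation + delta[4:6])
}

#' Summarise pose-recovery accuracy over random poses (Monte Carlo)
#'
#' Draws random board poses in front of the camera, simulates noisy corner
#' observations, re-estimates each pose, and reports median rotation and
#' translation errors. This is the package's accuracy characterisation of the
#' tracking pipeline.
#'
#' @param board,camera board and camera models.
#' @param n_poses number of random poses.
#' @param noise_sigma corner noise in px.
#' @param occlusion_fraction fraction of corners occluded per pose.
#' @param range_mm nominal camera-to-board distance in mm.
#' @param seed integer RNG seed.
#' @return list with `median_rotation_error_deg`, `median_translation_error_mm`,
#'   `median_rmse_px`, `n_poses`, and the per-pose error vectors.
#' @export
pose_error_study <- function(board, camera, n_poses = 100, noise_sigma = 0.5,
                             occlusion_fraction = 0, range_mm = 500, seed = 1L) {
  if (n_poses < 1) abort_ct("usage_error", "n_poses must be >= 1")
  rot_err <- numeric(n_poses)
  tr_err <- numeric(n_poses)
  rmse <- numeric(n_poses)
  with_seed(seed, {
    for (i in seq_len(n_poses)) {
      true_pose <- random_board_pose(board, camera, range_mm)
      obs <- simulate_observation(board, camera, true_pose,
                                  noise_sigma = noise_sigma,
                                  occlusion_fraction = occlusion_fraction)
      est <- estimate_pose(board, camera, obs)
      rot_err[i] <- rotation_angle(est$pose$rotation, true_pose$rotation) * 180 / pi
      tr_err[i] <- sqrt(sum((est$pose$translation - true_pose$translation)^2))
      rmse[i] <- est$rmse
    }
  })
  list(median_rotation_error_deg = median(rot_err),
       median_translation_error_mm = median(tr_err),
       median_rmse_px = median(rmse),
       n_poses = n_poses,
       rotation_error_deg = rot_err,
       translation_error_mm = tr_err)
}

# Random board pose: board roughly facing the camera at the given range,
# centred near the optical axis, tilted up to ~35 degrees. Uses session RNG.
random_board_pose <- function(board, camera, range_mm = 500) {
  span <- c(board$squares_x, board$squares_y) * board$square_size
  ax <- runif(3, -1, 1); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, 35 * pi / 180)
  r <- rotation_from_axis_angle(ax * ang)
  centre_off <- c(runif(2, -30, 30), range_mm * runif(1, 0.95, 1.05))
  t <- centre_off - as.vector(r %*% c(span / 2, 0))
  rigid_transform(r, t)
}
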