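# Shared fixtures and independent oracles for the test suite.

# Independent random rotation: QR of a Gaussian matrix (sign-fixed).
rand_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rand_rigid <- function(t_scale = 100) {
  rigid_transform(rand_rotation(), rnorm(3, 0, t_scale))
}

# Rodrigues formula, written out independently of the package internals.
rot_axis_angle <- function(axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# 4x4 homogeneous matrix for a rigid transform (matrix oracle).
homog <- function(tr) {
  m <- diag(4)
  m[1:3, 1:3] <- tr$rotation
  m[1:3, 4] <- tr$translation
  m
}

apply_homog <- function(m, p) {
  as.vector(m %*% c(p, 1))[1:3]
}

# Small random volume with a random (valid) geometry.
rand_volume <- function(shape = c(8, 8, 8)) {
  ct_volume(array(sample(-1000:2000, prod(shape), replace = TRUE), shape),
            spacing = runif(3, 0.5, 4),
            origin = rnorm(3, 0, 50),
            axes = rand_rotation())
}

# A small, quick phantom used by session/scan tests (identical physics to
# the default, coarser grid).
small_phantom <- function() {
  generate_phantom(phantom_config(
    shape = c(48L, 48L, 24L), spacing = c(8, 8, 8),
    noise_sd = 0, seed = 7L))
}

# Coarse render settings so scans inside tests stay fast.
fast_scan_params <- function(volume) {
  scan_params(slice_thickness = volume$spacing[3],
              slice_spacing = volume$spacing[3],
              in_plane_pixel_size = volume$spacing[1],
              supersampling = 1)
}

extdata <- function(...) system.file("extdata", ..., package = "ctbiopsim")

# Trilinear interpolation oracle: direct 8-neighbour weighted sum.
trilinear_oracle <- function(volume, point) {
  idx <- voxel_from_world(volume, point)
  d <- dim(volume$data)
  if (any(idx < 0) || any(idx > d - 1)) return(-1024)
  i0 <- pmax(pmin(floor(idx), d - 2), 0)
  f <- idx - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
    acc <- acc + w * volume$data[i0[1] + 1 + dx, i0[2] + 1 + dy, i0[3] + 1 + dz]
  }
  acc
}

# Pinhole projection oracle via homogeneous coordinates: K [R|t].
project_oracle <- function(board, camera, pose) {
  K <- rbind(c(camera$fx, 0, camera$cx), c(0, camera$fy, camera$cy), c(0, 0, 1))
  P <- K %*% cbind(pose$rotation, pose$translation)
  pts <- t(cbind(as.matrix(board$corners[, c("x", "y", "z")]), 1))
  uvw <- t(P %*% pts)
  cbind(uvw[, 1] / uvw[, 3], uvw[, 2] / uvw[, 3])
}
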