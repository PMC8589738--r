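# A quiet uniform soft-tissue block at 1 mm voxels used by the geometry tests.
uniform_block <- function(shape = c(64, 64, 16), hu = 40L) {
  ct_volume(array(hu, shape), spacing = c(1, 1, 1), origin = c(0, 0, 0))
}

test_that("scan parameter validation", {
  expect_error(scan_params(slice_thickness = 0), class = "ctbiopsim_validation_error")
  expect_error(scan_params(needle_hu = 4000), class = "ctbiopsim_validation_error")
})

test_that("slab selection picks the nearest centre with ties toward lower index", {
  vol <- uniform_block()
  p <- scan_params(slice_thickness = 1, slice_spacing = 1,
                   in_plane_pixel_size = 1)
  tip_at <- function(z) needle_state(c(10, 10, z), c(0, 0, 1))
  expect_equal(slice_for_needle(vol, tip_at(5), p), 5L)
  expect_equal(slice_for_needle(vol, tip_at(5.5), p), 5L)   # exact tie
  expect_equal(slice_for_needle(vol, tip_at(5.51), p), 6L)
  # exhaustive argmin oracle over random tips (in and slightly out of bounds)
  set.seed(51)
  centers <- 0:15
  for (i in 1:1000) {
    z <- runif(1, -0.9, 15.9)
    k <- slice_for_needle(vol, tip_at(z), p)
    d <- abs(centers - z)
    expect_equal(k, min(which(d == min(d))) - 1L)
  }
  expect_error(slice_for_needle(vol, tip_at(30), p),
               class = "ctbiopsim_out_of_range_error")
})

test_that("slice navigation clamps at the volume ends", {
  vol <- uniform_block()
  p <- scan_params(slice_thickness = 1, slice_spacing = 1)
  expect_equal(next_slice(15, vol, p), 15L)
  expect_equal(previous_slice(0, vol, p), 0L)
  expect_equal(previous_slice(next_slice(7, vol, p), vol, p), 7L)
  expect_error(next_slice(99, vol, p), class = "ctbiopsim_out_of_range_error")
})

test_that("laser line sits at the slab centre and matches the voxel grid", {
  vol <- uniform_block()
  p <- scan_params(slice_thickness = 1, slice_spacing = 1)
  expect_equal(laser_line_z(0, vol, p), vol$origin[3])
  zs <- vapply(0:15, laser_line_z, numeric(1), volume = vol, params = p)
  expect_equal(diff(zs), rep(p$slice_spacing, 15))
  for (k in c(0, 3, 9)) {
    expect_equal(laser_line_z(k, vol, p),
                 world_from_voxel(vol, c(0, 0, k))[3])
  }
  expect_error(laser_line_z(-1, vol, p), class = "ctbiopsim_out_of_range_error")
})

test_that("a needle outside the slab leaves the rendering untouched", {
  vol <- uniform_block()
  p <- scan_params(slice_thickness = 1, slice_spacing = 1)
  plain <- render_slice(vol, 2, NULL, p)
  far_needle <- needle_state(c(30, 30, 14), c(0, 0, 1), inserted_length = 5)
  with_far <- render_slice(vol, 2, far_needle, p)
  expect_identical(with_far$image, plain$image)
  expect_false(with_far$contains_needle)
})

test_that("perpendicular needle blob centroid matches the axis-slab intersection", {
  vol <- uniform_block()
  p <- scan_params(slice_thickness = 1, slice_spacing = 1)
  tip <- c(30.3, 25.7, 14)
  nd <- needle_state(tip, c(0, 0, 1), inserted_length = 12)
  sl <- render_slice(vol, 8, nd, p)
  expect_true(sl$contains_needle)
  mask <- sl$image >= 2000
  expect_gt(sum(mask), 0)
  idx <- which(mask, arr.ind = TRUE)
  centroid <- c(mean(sl$origin_xy[1] + (idx[, 1] - 1) * sl$pixel_size),
                mean(sl$origin_xy[2] + (idx[, 2] - 1) * sl$pixel_size))
  expect_lt(sqrt(sum((centroid - tip[1:2])^2)), sl$pixel_size)
})

test_that("in-plane needle footprint matches the analytic estimate within 20%", {
  vol <- uniform_block()
  p <- scan_params(slice_thickness = 1, slice_spacing = 1)
  len <- 30
  nd <- needle_state(c(50, 32, 8), c(1, 0, 0), inserted_length = len)
  sl <- render_slice(vol, 8, nd, p)
  count <- sum(sl$image >= 2000)
  expected <- (len / p$in_plane_pixel_size) *
    ceiling(3 / p$in_plane_pixel_size)   # 3 mm default shaft diameter
  expect_gt(count, 0.8 * expected)
  expect_lt(count, 1.2 * expected)
})

test_that("compositing is confined to pixels whose samples meet the capsule", {
  vol <- uniform_block(shape = c(64, 64, 8))
  p <- scan_params(slice_thickness = 1, slice_spacing = 1)
  tip <- c(20.2, 31.6, 4); axis <- c(1, 0.3, 0.1) / sqrt(1.1)
  len <- 25
  nd <- needle_state(tip, axis, inserted_length = len)
  plain <- render_slice(vol, 4, NULL, p)
  with_nd <- render_slice(vol, 4, nd, p)
  changed <- with_nd$image != plain$image
  # geometric predicate: does any supersample point of the pixel lie in the capsule?
  a <- tip; b <- tip - len * axis; r <- 1.5
  seg_d2 <- function(pt) {
    ab <- b - a; t <- sum((pt - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    sum((pt - (a + t * ab))^2)
  }
  off <- (((0:2) + 0.5) / 3 - 0.5)
  zc <- with_nd$slab_center_z
  for (u in seq_len(nrow(changed))) for (v in seq_len(ncol(changed))) {
    if (!changed[u, v]) next
    px <- with_nd$origin_xy[1] + (u - 1) * p$in_plane_pixel_size
    py <- with_nd$origin_xy[2] + (v - 1) * p$in_plane_pixel_size
    touches <- FALSE
    for (ox in off) for (oy in off) for (oz in off) {
      pt <- c(px + ox, py + oy, zc + oz)
      if (seg_d2(pt) <= r^2) touches <- TRUE
    }
    expect_true(touches)
  }
})

test_that("partial-volume pixels on the capsule boundary are intermediate", {
  vol <- uniform_block()
  p <- scan_params(slice_thickness = 1, slice_spacing = 1)
  nd <- needle_state(c(30.3, 25.7, 14), c(0, 0, 1), inserted_length = 12)
  sl <- render_slice(vol, 8, nd, p)
  plain <- render_slice(vol, 8, NULL, p)
  mixed <- sl$image > plain$image & sl$image < p$needle_hu
  expect_gt(sum(mixed), 0)
  expect_true(all(sl$image[mixed] > 40 & sl$image[mixed] < 3071))
})

test_that("pixel values converge as supersampling is refined", {
  vol <- uniform_block(shape = c(48, 48, 8))
  nd <- needle_state(c(24.4, 20.3, 6.2), c(0.2, 0.1, 1) / sqrt(1.05),
                     inserted_length = 10)
  render_s <- function(s) {
    render_slice(vol, 4, nd, scan_params(slice_thickness = 1,
                                         slice_spacing = 1,
                                         supersampling = s))$image
  }
  r3 <- render_s(3); r6 <- render_s(6); r12 <- render_s(12)
  d36 <- max(abs(r3 - r6))
  d612 <- max(abs(r6 - r12))
  # refinement error shrinks, and a doubling from s = 6 moves no pixel by
  # more than 150 HU (at s = 3 boundary pixels can still jump by ~1 sample
  # in 27, i.e. a few hundred HU)
  expect_lt(d612, d36)
  expect_lt(d612, 150)
})

test_that("inserted length stops the shaft at the body surface", {
  # air above z = 8, tissue below; needle descends along +z
  arr <- array(-1000L, c(20, 20, 20))
  arr[, , 1:8] <- 40L
  vol <- ct_volume(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  nd <- needle_state(c(10, 10, 5), c(0, 0, -1))  # tip ~2.5 mm under the surface
  got <- ctbiopsim:::inserted_length_from_surface(vol, nd, 150)
  expect_gt(got, 1.5)
  expect_lt(got, 4.5)
  in_air <- needle_state(c(10, 10, 15), c(0, 0, -1))
  expect_equal(ctbiopsim:::inserted_length_from_surface(vol, in_air, 150), 0)
})

test_that("slice export round-trips through 16-bit PNG and 2-D NIfTI", {
  vol <- uniform_block(shape = c(24, 24, 6))
  p <- scan_params(slice_thickness = 1, slice_spacing = 1)
  nd <- needle_state(c(12, 12, 5), c(0, 0, 1), inserted_length = 4)
  sl <- render_slice(vol, 3, nd, p)
  fp <- file.path(tempdir(), "slice.png")
  write_slice_png(sl, fp)
  img <- png::readPNG(fp)
  expect_equal(dim(img), c(24, 24))
  stored <- round(img * 65535)
  expect_equal(max(stored), max(round(sl$image)) + 1024)
  fn <- file.path(tempdir(), "slice.nii.gz")
  write_slice_nifti(sl, fn)
  back <- as.array(RNifti::readNifti(fn))
  expect_equal(as.vector(back), as.vector(round(sl$image)))
})
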