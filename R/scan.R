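#' Simulated-scan acquisition parameters
#'
#' @param slice_thickness axial slab thickness in mm.
#' @param slice_spacing distance between slab centres in mm (default:
#'   contiguous, equal to thickness).
#' @param in_plane_pixel_size reconstructed pixel size in mm. Defaults to
#'   1 mm, typical of abdominal CT reconstructions, so the rendered slice can
#'   be finer than the phantom voxel grid.
#' @param needle_hu HU assigned to needle-interior sample points (metal,
#'   clamped at the 12-bit maximum 3071).
#' @param supersampling samples per axis per pixel for partial-volume
#'   averaging (>= 1).
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(slice_thickness = 3, slice_spacing = slice_thickness,
                        in_plane_pixel_size = 1, needle_hu = 3071,
                        supersampling = 3) {
  if (slice_thickness <= 0 || slice_spacing <= 0 || in_plane_pixel_size <= 0 ||
      supersampling < 1) {
    abort_ct("validation_error", "scan parameters must be positive")
  }
  if (needle_hu > HU_MAX) {
    abort_ct("validation_error", "needle_hu cannot exceed %d", HU_MAX)
  }
  structure(list(slice_thickness = slice_thickness,
                 slice_spacing = slice_spacing,
                 in_plane_pixel_size = in_plane_pixel_size,
                 needle_hu = needle_hu,
                 supersampling = as.integer(supersampling)),
            class = "scan_params")
}

#' Number of axial slabs covering a volume
#'
#' Slab 0 is centred on the first voxel plane; centres advance by
#' `slice_spacing`.
#'
#' @param volume A [ct_volume()].
#' @param params A [scan_params()].
#' @return Integer slab count.
#' @export
n_slices <- function(volume, params = scan_params()) {
  assert_axis_aligned(volume)
  extent_z <- (dim(volume$data)[3] - 1) * volume$spacing[3]
  as.integer(floor(extent_z / params$slice_spacing + 1e-9)) + 1L
}

#' World z of a slab centre (the green laser line position)
#'
#' The returned z is the plane a trainee aligns the needle with: the scan
#' location indicated by the positional laser guide of a CT scanner.
#'
#' @param slice_index 0-based slab index.
#' @param volume A [ct_volume()].
#' @param params A [scan_params()].
#' @return World z in mm.
#' @export
laser_line_z <- function(slice_index, volume, params = scan_params()) {
  ns <- n_slices(volume, params)
  if (slice_index < 0 || slice_index > ns - 1) {
    abort_ct("out_of_range_error", "slice index %s outside [0, %d]",
             slice_index, ns - 1)
  }
  volume$origin[3] + slice_index * params$slice_spacing
}

#' Slab index nearest the needle tip
#'
#' Returns the index of the slab whose centre z is closest to the needle tip
#' z; exact ties break toward the lower index. The tip may lie up to one
#' slab beyond the volume (the index is clamped); farther out is an error.
#'
#' @param volume A [ct_volume()].
#' @param needle A [needle_state()].
#' @param params A [scan_params()].
#' @return 0-based slab index.
#' @export
slice_for_needle <- function(volume, needle, params = scan_params()) {
  ns <- n_slices(volume, params)
  kc <- (needle$tip[3] - volume$origin[3]) / params$slice_spacing
  k <- ceiling(kc - 0.5)          # round to nearest, ties toward lower index
  if (k < -1 || k > ns) {
    abort_ct("out_of_range_error",
             "needle tip z = %.1f mm is more than one slab outside the volume",
             needle$tip[3])
  }
  as.integer(min(max(k, 0), ns - 1))
}

#' Next / previous slab index (clamped navigation)
#'
#' @param current current 0-based slab index.
#' @param volume A [ct_volume()].
#' @param params A [scan_params()].
#' @return Clamped neighbouring index.
#' @export
next_slice <- function(current, volume, params = scan_params()) {
  ns <- n_slices(volume, params)
  if (current < 0 || current > ns - 1) {
    abort_ct("out_of_range_error", "slice index %s outside [0, %d]", current, ns - 1)
  }
  as.integer(min(current + 1, ns - 1))
}

#' @rdname next_slice
#' @export
previous_slice <- function(current, volume, params = scan_params()) {
  ns <- n_slices(volume, params)
  if (current < 0 || current > ns - 1) {
    abort_ct("out_of_range_error", "slice index %s outside [0, %d]", current, ns - 1)
  }
  as.integer(max(current - 1, 0))
}

# Inserted length: distance from tip back along -axis to the first crossing
# from tissue (HU > -500) to air (HU <= -500), i.e. the body entry point.
# Sampled at 0.5 mm steps up to the shaft length.
inserted_length_from_surface <- function(volume, needle, shaft_length) {
  s <- seq(0, shaft_length, by = 0.5)
  pts <- outer(s, -needle$axis)
  pts <- sweep(pts, 2, needle$tip, "+")
  hu <- sample_hu(volume, pts)
  if (hu[1] <= -500) return(0)
  out <- which(hu <= -500)
  if (length(out) == 0) shaft_length else s[out[1]]
}

# Squared distance from points (n x 3) to the segment [a, b].
dist2_to_segment <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  rel <- sweep(pts, 2, a)
  t <- if (len2 < 1e-12) rep(0, nrow(pts)) else
    pmin(pmax((rel %*% ab) / len2, 0), 1)
  d <- rel - outer(as.vector(t), ab)
  rowSums(d^2)
}

#' Render a simulated CT slice, optionally containing the virtual needle
#'
#' Resamples an axial slab of the volume onto a regular pixel grid covering
#' the volume footprint. Each output pixel is the mean HU over a supersampled
#' grid of points spanning the pixel footprint and the slab thickness (slab
#' averaging / partial-volume model). Sample points falling inside the
#' needle capsule — a cylinder of the shaft diameter with a hemispherical tip
#' cap, extending from the tip back along -axis for the inserted length —
#' take the needle HU instead of the tissue HU. The result is clamped to
#' \[-1024, 3071\]. With `needle = NULL` the output is plain slab resampling.
#'
#' @param volume A [ct_volume()].
#' @param slice_index 0-based slab index.
#' @param needle A [needle_state()] or `NULL`.
#' @param params A [scan_params()].
#' @param needle_geom A [needle_model()] supplying shaft diameter/length.
#' @return An object of class `simulated_slice`: list with `image` (matrix
#'   indexed \[x, y\] in HU), `slice_index`, `slab_center_z`, `thickness`,
#'   `contains_needle`, `pixel_size`, and `origin_xy` (world x, y of pixel
#'   (0,0)'s centre).
#' @export
render_slice <- function(volume, slice_index, needle = NULL,
                         params = scan_params(), needle_geom = needle_model()) {
  zc <- laser_line_z(slice_index, volume, params)  # validates the index
  d <- dim(volume$data)
  sp <- volume$spacing
  p <- params$in_plane_pixel_size
  ext <- c(d[1] * sp[1], d[2] * sp[2])
  npx <- pmax(1L, as.integer(ceiling(ext / p - 1e-9)))
  xmin <- volume$origin[1] - sp[1] / 2
  ymin <- volume$origin[2] - sp[2] / 2
  xs <- xmin + ((0:(npx[1] - 1)) + 0.5) * p
  ys <- ymin + ((0:(npx[2] - 1)) + 0.5) * p

  capsule <- NULL
  if (!is.null(needle)) {
    len <- needle$inserted_length
    if (is.null(len)) {
      len <- inserted_length_from_surface(volume, needle, needle_geom$shaft_length)
    }
    if (len > 0) {
      capsule <- list(a = needle$tip, b = needle$tip - len * needle$axis,
                      r = needle_geom$shaft_diameter / 2)
    }
  }

  s <- params$supersampling
  off <- (((0:(s - 1)) + 0.5) / s - 0.5)
  grid_xy <- cbind(rep(xs, times = npx[2]), rep(ys, each = npx[1]))
  acc <- numeric(nrow(grid_xy))
  hit_any <- FALSE
  for (oz in off * params$slice_thickness) {
    for (oy in off * p) {
      for (ox in off * p) {
        pts <- cbind(grid_xy[, 1] + ox, grid_xy[, 2] + oy, zc + oz)
        hu <- sample_hu(volume, pts)
        if (!is.null(capsule)) {
          inside <- dist2_to_segment(pts, capsule$a, capsule$b) <= capsule$r^2
          if (any(inside)) {
            hu[inside] <- params$needle_hu
            hit_any <- TRUE
          }
        }
        acc <- acc + hu
      }
    }
  }
  img <- matrix(acc / s^3, npx[1], npx[2])
  img[img < HU_MIN] <- HU_MIN
  img[img > HU_MAX] <- HU_MAX
  structure(list(image = img, slice_index = as.integer(slice_index),
                 slab_center_z = zc, thickness = params$slice_thickness,
                 contains_needle = hit_any, pixel_size = p,
                 origin_xy = c(xs[1], ys[1])),
            class = "simulated_slice")
}

#' @export
print.simulated_slice <- function(x, ...) {
  cat(sprintf("<simulated_slice> index %d, z = %.1f mm, %d x %d px @ %.2f mm%s\n",
              x$slice_index, x$slab_center_z, nrow(x$image), ncol(x$image),
              x$pixel_size, if (x$contains_needle) ", needle visible" else ""))
  invisible(x)
}

#' Export a simulated slice as 16-bit grayscale PNG
#'
#' Stored values are HU + 1024 (so air maps to 0) in a 16-bit single-channel
#' PNG.
#'
#' @param slice A `simulated_slice`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_slice_png <- function(slice, path) {
  vals <- round(t(slice$image) + 1024)      # rows = y for conventional viewing
  vals[vals < 0] <- 0
  vals[vals > 65535] <- 65535
  write_png16(vals, path)
  invisible(path)
}

#' Export a simulated slice as a 2-D NIfTI image
#'
#' @param slice A `simulated_slice`.
#' @param path output `.nii`/`.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
write_slice_nifti <- function(slice, path) {
  img <- RNifti::asNifti(array(as.integer(round(slice$image)),
                               c(dim(slice$image), 1)),
                         pixdim = c(slice$pixel_size, slice$pixel_size,
                                    slice$thickness))
  aff <- diag(4)
  aff[1, 1] <- slice$pixel_size
  aff[2, 2] <- slice$pixel_size
  aff[3, 3] <- slice$thickness
  aff[1:3, 4] <- c(slice$origin_xy, slice$slab_center_z)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}
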