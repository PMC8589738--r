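#' CT volume with Hounsfield data, labels and voxel-to-world geometry
#'
#' A `ct_volume` couples a 3-D grid of Hounsfield units (HU) with a parallel
#' integer label grid marking target lesions, plus the affine voxel-to-world
#' mapping. The world frame is LPS in millimetres; voxel indices are 0-based;
#' `origin` is the world position of the centre of voxel (0,0,0).
#'
#' @param data 3-D numeric array of HU values; clamped to \[-1024, 3071\].
#' @param labels 3-D integer array of non-negative labels, same shape as
#'   `data` (0 = unlabeled). Defaults to all-zero.
#' @param spacing positive per-axis voxel size in mm (length 3).
#' @param origin world position (mm) of the centre of voxel (0,0,0).
#' @param axes 3x3 direction matrix with orthonormal columns.
#' @return An object of class `ct_volume`.
#' @examples
#' vol <- ct_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
#' world_from_voxel(vol, c(1, 1, 1))
#' @export
ct_volume <- function(data, labels = NULL, spacing = c(1, 1, 1),
                      origin = c(0, 0, 0), axes = diag(3)) {
  if (!is.array(data) || length(dim(data)) != 3) {
    abort_ct("validation_error", "data must be a 3-D array")
  }
  if (is.null(labels)) labels <- array(0L, dim(data))
  if (!identical(dim(labels), dim(data))) {
    abort_ct("validation_error", "labels and data must have identical shapes")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  axes <- matrix(as.numeric(axes), 3, 3)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    abort_ct("validation_error", "spacing components must be positive")
  }
  if (max(abs(crossprod(axes) - diag(3))) > 1e-9) {
    abort_ct("validation_error", "axes columns must be orthonormal")
  }
  if (any(labels < 0)) {
    abort_ct("validation_error", "labels must be non-negative")
  }
  storage.mode(data) <- "integer"
  data[data < HU_MIN] <- HU_MIN
  data[data > HU_MAX] <- HU_MAX
  storage.mode(labels) <- "integer"
  structure(list(data = data, labels = labels, spacing = spacing,
                 origin = origin, axes = axes),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels @ %s mm\n",
              d[1], d[2], d[3], paste(x$spacing, collapse = " x ")))
  cat(sprintf("  origin (mm): %s\n", paste(round(x$origin, 3), collapse = " ")))
  labs <- setdiff(sort(unique(as.vector(x$labels))), 0L)
  cat(sprintf("  HU range: [%d, %d]; labels: %s\n",
              min(x$data), max(x$data),
              if (length(labs)) paste(labs, collapse = ", ") else "none"))
  invisible(x)
}

as_point_matrix <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3)
    p
  } else {
    matrix(as.numeric(p), ncol = 3)
  }
}

#' Map voxel indices to world coordinates
#'
#' Computes `origin + axes %*% (index * spacing)` for each (possibly
#' fractional, possibly out-of-bounds) 0-based index.
#'
#' @param volume A [ct_volume()].
#' @param index length-3 continuous index, or an n x 3 matrix of indices.
#' @return World point(s) in mm, same shape as the input.
#' @export
world_from_voxel <- function(volume, index) {
  idx <- as_point_matrix(index)
  w <- sweep(sweep(idx, 2, volume$spacing, "*") %*% t(volume$axes),
             2, volume$origin, "+")
  if (is.matrix(index)) w else as.vector(w)
}

#' Map world coordinates to continuous voxel indices
#'
#' Exact inverse of [world_from_voxel()].
#'
#' @param volume A [ct_volume()].
#' @param point length-3 world point in mm, or an n x 3 matrix of points.
#' @return Continuous 0-based voxel index/indices, same shape as the input.
#' @export
voxel_from_world <- function(volume, point) {
  p <- as_point_matrix(point)
  idx <- sweep(sweep(p, 2, volume$origin, "-") %*% volume$axes,
               2, volume$spacing, "/")
  if (is.matrix(point)) idx else as.vector(idx)
}

#' Sample Hounsfield values by trilinear interpolation
#'
#' Trilinear interpolation of the HU grid at arbitrary world points. Points
#' outside the grid (beyond the outermost voxel centres) return -1024 (air).
#'
#' @param volume A [ct_volume()].
#' @param point length-3 world point in mm, or an n x 3 matrix of points.
#' @return HU value(s), length matching the number of points.
#' @export
sample_hu <- function(volume, point) {
  idx <- as_point_matrix(voxel_from_world(volume, as_point_matrix(point)))
  d <- dim(volume$data)
  inside <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
    idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
    idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  out <- rep(as.numeric(HU_MIN), nrow(idx))
  if (any(inside)) {
    ii <- idx[inside, , drop = FALSE]
    # lower corner, clamped so frac = 1 at the upper face rather than indexing
    # past the grid
    i0 <- pmin(floor(ii), matrix(rep(d - 2, each = nrow(ii)), ncol = 3))
    i0 <- pmax(i0, 0)
    f <- ii - i0
    dat <- volume$data
    gather <- function(dx, dy, dz) {
      dat[cbind(i0[, 1] + 1 + dx, i0[, 2] + 1 + dy, i0[, 3] + 1 + dz)]
    }
    v <-
      gather(0, 0, 0) * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
      gather(1, 0, 0) * f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) +
      gather(0, 1, 0) * (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) +
      gather(1, 1, 0) * f[, 1] * f[, 2] * (1 - f[, 3]) +
      gather(0, 0, 1) * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
      gather(1, 0, 1) * f[, 1] * (1 - f[, 2]) * f[, 3] +
      gather(0, 1, 1) * (1 - f[, 1]) * f[, 2] * f[, 3] +
      gather(1, 1, 1) * f[, 1] * f[, 2] * f[, 3]
    out[inside] <- v
  }
  out
}

#' Distance from a world point to a labeled lesion
#'
#' Euclidean distance (mm) from `point` to the nearest voxel centre carrying
#' `label_id`; 0 if the voxel containing the point carries it.
#'
#' @param volume A [ct_volume()].
#' @param label_id positive integer label present in `volume$labels`.
#' @param point world point in mm.
#' @return Distance in mm.
#' @export
lesion_distance <- function(volume, label_id, point) {
  vox <- which(volume$labels == label_id, arr.ind = TRUE)
  if (nrow(vox) == 0) {
    abort_ct("lookup_error", "label %s not present in volume labels", label_id)
  }
  point <- as.numeric(point)
  # containing voxel: nearest voxel centre to the point
  ci <- round(voxel_from_world(volume, point))
  d <- dim(volume$data)
  if (all(ci >= 0 & ci <= d - 1) &&
      volume$labels[ci[1] + 1, ci[2] + 1, ci[3] + 1] == label_id) {
    return(0)
  }
  centers <- world_from_voxel(volume, vox - 1)
  sqrt(min(colSums((t(centers) - point)^2)))
}

# Number of axial slabs and their world-z centres. The scan simulator assumes
# an axis-aligned volume (axial slices are planes of constant world z).
assert_axis_aligned <- function(volume) {
  if (max(abs(volume$axes - diag(3))) > 1e-9) {
    abort_ct("validation_error",
             "scan simulation requires an axis-aligned (identity-direction) volume")
  }
}

slab_centers_z <- function(volume) {
  assert_axis_aligned(volume)
  volume$origin[3] + (seq_len(dim(volume$data)[3]) - 1) * volume$spacing[3]
}
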