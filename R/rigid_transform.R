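#' Rigid transform in 3-D (rotation + translation, millimetres)
#'
#' A proper rigid transform mapping points from one frame into another:
#' `p' = R p + t`. The rotation must be orthonormal with determinant +1
#' (checked to 1e-9).
#'
#' @param rotation 3x3 orthonormal matrix, det = +1.
#' @param translation numeric length-3 translation in mm.
#' @return An object of class `rigid_transform` with fields `rotation` and
#'   `translation`.
#' @examples
#' t1 <- rigid_transform(diag(3), c(1, 0, 0))
#' apply_transform(t1, c(0, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3) {
    abort_ct("validation_error", "translation must have length 3")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    abort_ct("validation_error", "rotation matrix is not orthonormal")
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    abort_ct("validation_error", "rotation matrix must have determinant +1")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation (mm):", paste(round(x$translation, 4), collapse = " "), "\n")
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose(a, b)` applies `b` first, then `a`: the result maps `p` to
#' `a(b(p))`.
#'
#' @param a,b `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param a A `rigid_transform`.
#' @return The inverse transform, satisfying `compose(invert(a), a) == identity`.
#' @export
invert <- function(a) {
  stopifnot(inherits(a, "rigid_transform"))
  rt <- t(a$rotation)
  rigid_transform(rt, -as.vector(rt %*% a$translation))
}

#' Apply a rigid transform to points
#'
#' @param a A `rigid_transform`.
#' @param points numeric length-3 vector, or an n x 3 matrix of row points.
#' @return Transformed points in the same shape as the input.
#' @export
apply_transform <- function(a, points) {
  stopifnot(inherits(a, "rigid_transform"))
  if (is.matrix(points)) {
    sweep(points %*% t(a$rotation), 2, a$translation, "+")
  } else {
    as.vector(a$rotation %*% as.numeric(points)) + a$translation
  }
}

# Rodrigues: axis-angle vector -> rotation matrix.
rotation_from_axis_angle <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Nearest rotation (Frobenius) to an arbitrary 3x3 matrix, via SVD.
nearest_rotation <- function(m) {
  s <- svd(m)
  r <- s$u %*% t(s$v)
  if (det(r) < 0) {
    r <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  }
  r
}

# Angle (radians) of the relative rotation between two rotation matrices.
rotation_angle <- function(r1, r2 = diag(3)) {
  rel <- crossprod(r2, r1)
  c_ang <- (sum(diag(rel)) - 1) / 2
  acos(min(1, max(-1, c_ang)))
}
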