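#' Configuration for the synthetic torso phantom
#'
#' The phantom emulates a contrast-enhanced abdominal CT of a torso built
#' from geometric primitives: an elliptic-cylinder body with a subcutaneous
#' fat ring, a spine column and periodic rib shells (bone), two kidney
#' ellipsoids, a para-spinal aorta cylinder (contrast blood), and spherical
#' soft-tissue lesions carrying integer labels. The default configuration
#' contains exactly two retroperitoneal lymph-node targets: a beginner
#' pararenal node with an unobstructed anterior (vertical) needle path, and
#' an expert node directly adjacent to the aorta.
#'
#' @param shape integer length-3 grid shape (voxels).
#' @param spacing voxel size in mm (length 3).
#' @param body_semi_axes in-plane semi-axes (mm) of the body ellipse (x, y).
#' @param hu named list of tissue HU plateaus: `air`, `fat`, `soft_tissue`,
#'   `bone`, `blood`.
#' @param lesions list of lesion specs; each a list with `name`, `centroid`
#'   (world mm), `radius` (mm), `difficulty` (`"beginner"` or `"expert"`),
#'   and `hu`.
#' @param noise_sd standard deviation (HU) of additive Gaussian image noise.
#' @param seed integer seed making the noise reproducible.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(128L, 128L, 96L),
                           spacing = c(3, 3, 3),
                           body_semi_axes = c(170, 120),
                           hu = list(air = -1000, fat = -90, soft_tissue = 40,
                                     bone = 700, blood = 200),
                           lesions = default_lesions(),
                           noise_sd = 10,
                           seed = 1L) {
  cfg <- structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                        body_semi_axes = as.numeric(body_semi_axes), hu = hu,
                        lesions = lesions, noise_sd = noise_sd, seed = seed),
                   class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

default_lesions <- function() {
  list(
    list(name = "pararenal node", centroid = c(70, 20, 0), radius = 8,
         difficulty = "beginner", hu = 60),
    list(name = "para-aortic node", centroid = c(27, 35, 0), radius = 6,
         difficulty = "expert", hu = 60)
  )
}

validate_phantom_config <- function(cfg) {
  if (length(cfg$shape) != 3 || any(cfg$shape < 8)) {
    abort_ct("config_error", "phantom shape must be 3 values >= 8")
  }
  if (any(cfg$spacing <= 0)) abort_ct("config_error", "spacing must be positive")
  needed <- c("air", "fat", "soft_tissue", "bone", "blood")
  if (!all(needed %in% names(cfg$hu))) {
    abort_ct("config_error", "hu must name: %s", paste(needed, collapse = ", "))
  }
  if (cfg$noise_sd < 0) abort_ct("config_error", "noise_sd must be >= 0")
  half <- (cfg$shape - 1) * cfg$spacing / 2
  for (les in cfg$lesions) {
    if (!all(c("name", "centroid", "radius", "difficulty") %in% names(les))) {
      abort_ct("config_error", "lesion spec missing fields (name/centroid/radius/difficulty)")
    }
    if (les$radius <= 0) abort_ct("config_error", "lesion radius must be > 0")
    if (!les$difficulty %in% c("beginner", "expert")) {
      abort_ct("config_error", "lesion difficulty must be 'beginner' or 'expert'")
    }
    ctr <- as.numeric(les$centroid)
    re <- sqrt((ctr[1] / cfg$body_semi_axes[1])^2 + (ctr[2] / cfg$body_semi_axes[2])^2)
    if (re >= 1 || abs(ctr[3]) > half[3]) {
      abort_ct("config_error", "lesion '%s' lies outside the body", les$name)
    }
  }
  invisible(cfg)
}

#' A labeled biopsy target inside a CT volume
#'
#' @param label_id positive integer matching a value in the volume's labels.
#' @param name display name.
#' @param difficulty `"beginner"` or `"expert"`.
#' @param centroid world point (mm) of the lesion centre.
#' @param nominal_radius lesion radius in mm (> 0).
#' @return An object of class `target_lesion`.
#' @export
target_lesion <- function(label_id, name, difficulty, centroid, nominal_radius) {
  difficulty <- match.arg(difficulty, c("beginner", "expert"))
  if (nominal_radius <= 0) abort_ct("validation_error", "nominal_radius must be > 0")
  structure(list(label_id = as.integer(label_id), name = name,
                 difficulty = difficulty, centroid = as.numeric(centroid),
                 nominal_radius = as.numeric(nominal_radius)),
            class = "target_lesion")
}

#' Generate the synthetic labeled torso phantom
#'
#' Builds a [ct_volume()] from the geometric primitives described in
#' [phantom_config()], adds Gaussian image noise (reproducible under the
#' config seed), and returns the volume together with one [target_lesion()]
#' per configured lesion (label ids assigned 1, 2, ... in order).
#'
#' The world frame is LPS in mm, centred so that world (0,0,0) is the volume
#' centre; direction axes are identity, so axial slices are planes of
#' constant world z.
#'
#' @param config A [phantom_config()].
#' @return A list with elements `volume` ([ct_volume()]) and `targets`
#'   (list of [target_lesion()]).
#' @examples
#' ph <- generate_phantom(phantom_config(shape = c(32, 32, 16), spacing = c(6, 6, 6)))
#' ph$volume
#' @export
generate_phantom <- function(config = phantom_config()) {
  validate_phantom_config(config)
  d <- config$shape
  sp <- config$spacing
  origin <- -(d - 1) * sp / 2
  xs <- origin[1] + (0:(d[1] - 1)) * sp[1]
  ys <- origin[2] + (0:(d[2] - 1)) * sp[2]
  zs <- origin[3] + (0:(d[3] - 1)) * sp[3]
  a <- config$body_semi_axes[1]
  b <- config$body_semi_axes[2]
  hu <- config$hu

  # in-plane elliptical radius, shared by body/fat/ribs
  re2 <- outer((xs / a)^2, (ys / b)^2, "+")
  slice_hu <- matrix(hu$air, d[1], d[2])
  slice_hu[re2 <= 1] <- hu$fat
  slice_hu[re2 <= 0.9^2] <- hu$soft_tissue
  rib_band <- re2 > 0.80^2 & re2 <= 0.86^2

  # spine column (posterior midline) and aorta (anterior-left of the spine)
  spine <- outer((xs - 0)^2, (ys - 60)^2, "+") <= 18^2
  aorta <- outer((xs - 10)^2, (ys - 35)^2, "+") <= 10^2

  data <- array(hu$air, d)
  inplane_body <- re2 <= 1
  for (k in seq_len(d[3])) {
    sl <- slice_hu
    # rib shells: 6 mm bands every 30 mm along z, leaving the mid-plane clear
    zmod <- zs[k] %% 30
    if (zmod >= 12 && zmod < 18) sl[rib_band] <- hu$bone
    sl[spine & inplane_body] <- hu$bone
    sl[aorta & inplane_body] <- hu$blood
    data[, , k] <- sl
  }

  # kidney ellipsoids (soft tissue; shape only — same plateau as body interior)
  for (sx in c(-1, 1)) {
    kid <- kidney_mask(xs, ys, zs, centre = c(sx * 65, 40, 0),
                       semi = c(25, 18, 45))
    data[kid] <- hu$soft_tissue
  }

  labels <- array(0L, d)
  targets <- vector("list", length(config$lesions))
  for (i in seq_along(config$lesions)) {
    les <- config$lesions[[i]]
    m <- sphere_mask(xs, ys, zs, as.numeric(les$centroid), les$radius)
    data[m] <- les$hu
    labels[m] <- i
    targets[[i]] <- target_lesion(i, les$name, les$difficulty,
                                  les$centroid, les$radius)
  }

  if (config$noise_sd > 0) {
    noise <- with_seed(config$seed,
                       array(rnorm(prod(d), 0, config$noise_sd), d))
    data <- data + noise
  }

  vol <- ct_volume(round(data), labels = labels, spacing = sp, origin = origin)
  list(volume = vol, targets = targets)
}

sphere_mask <- function(xs, ys, zs, centre, radius) {
  dx2 <- (xs - centre[1])^2
  dy2 <- (ys - centre[2])^2
  dz2 <- (zs - centre[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
}

kidney_mask <- function(xs, ys, zs, centre, semi) {
  dx2 <- ((xs - centre[1]) / semi[1])^2
  dy2 <- ((ys - centre[2]) / semi[2])^2
  dz2 <- ((zs - centre[3]) / semi[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

#' Find the phantom target of a given difficulty
#'
#' @param targets list of [target_lesion()] objects.
#' @param difficulty `"beginner"` or `"expert"`.
#' @return The matching [target_lesion()].
#' @export
target_by_difficulty <- function(targets, difficulty) {
  difficulty <- match.arg(difficulty, c("beginner", "expert"))
  for (t in targets) if (t$difficulty == difficulty) return(t)
  abort_ct("lookup_error", "no target with difficulty '%s'", difficulty)
}
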