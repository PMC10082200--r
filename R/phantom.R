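# Synthetic CT phantoms.
#
# The clinical data the method was developed on is restricted, so training
# and evaluation run on synthetic volumes that emulate its stated structure:
# 512 x 512 axial slices, an organ whose z extent is close to 43 slices,
# contrast-enhanced organ intensities well separated from background,
# neighboring distractor structures (a bright spine-like cylinder near the
# midline, a soft-tissue sphere near the organ) and additive Gaussian noise
# over a low-frequency background texture.  Intensities are generated
# directly on the normalized [0, 1] scale.

#' Phantom specification
#'
#' Defaults describe a contrast CT-like abdomen: a right kidney (left image
#' half) and a spleen (right image half) as ellipsoids, each wrapped in a
#' dark perirenal/perisplenic fat capsule; a bright cylindrical spine
#' distractor at the midline and a large liver-like soft-tissue ellipsoid
#' adjacent to the kidney.  The multi-tissue neighborhood matters: an ROI
#' window in clinical CT always holds several intensity populations (fat,
#' parenchyma, muscle), which is what the downstream 7-cluster intensity
#' clustering is designed against.  Organ intensity must differ from the
#' background mean by at least `3 * noise_sigma` so the two classes stay
#' learnable.
#'
#' @param shape volume dimensions `(z, y, x)`.
#' @param organs list of organs, each
#'   `list(label, center = c(z, y, x), semi = c(az, ay, ax), intensity)`;
#'   centers/semi-axes in voxels (0-based), intensity in `[0, 1]`.
#' @param distractors list of unlabeled structures, each
#'   `list(type = "cylinder"|"sphere"|"ellipsoid", center, intensity)` with
#'   a `radius` (cylinder/sphere) or `semi` (ellipsoid); cylinders run
#'   along z.  Drawn in order before the organs, so an ellipsoid placed
#'   around an organ center becomes a capsule once the organ overrides its
#'   interior.
#' @param background_mean background intensity.
#' @param noise_sigma additive Gaussian noise scale.
#' @param texture_scale amplitude of the low-frequency background modulation.
#' @param seed RNG seed for texture and noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(43, 512, 512),
                         organs = list(
                           list(label = "kidney_right",
                                center = c(21, 270, 170),
                                semi = c(18, 55, 35),
                                intensity = 0.65),
                           list(label = "spleen",
                                center = c(21, 250, 370),
                                semi = c(16, 45, 30),
                                intensity = 0.60)),
                         distractors = list(
                           list(type = "cylinder", center = c(21, 340, 256),
                                radius = 28, intensity = 0.90),
                           list(type = "ellipsoid", center = c(21, 140, 140),
                                semi = c(20, 80, 80), intensity = 0.45),
                           list(type = "ellipsoid", center = c(21, 270, 170),
                                semi = c(21, 73, 49), intensity = 0.12),
                           list(type = "ellipsoid", center = c(21, 250, 370),
                                semi = c(20, 63, 44), intensity = 0.12)),
                         background_mean = 0.30,
                         noise_sigma = 0.03,
                         texture_scale = 0.05,
                         seed = 1L) {
  spec <- structure(list(shape = as.integer(shape), organs = organs,
                         distractors = distractors,
                         background_mean = background_mean,
                         noise_sigma = noise_sigma,
                         texture_scale = texture_scale,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (length(spec$shape) != 3 || any(spec$shape < 4))
    stop("phantom shape must be three dimensions of at least 4 voxels")
  for (o in spec$organs) {
    if (is.null(o$label) || is.null(o$center) || is.null(o$semi) ||
        is.null(o$intensity))
      stop("each organ needs label, center, semi, intensity")
    if (any(o$center - o$semi < 0) || any(o$center + o$semi > spec$shape - 1))
      stop("organ '", o$label, "' ellipsoid extends outside the grid")
    if (abs(o$intensity - spec$background_mean) < 3 * spec$noise_sigma)
      stop("organ '", o$label, "' intensity is within 3*noise_sigma of background")
  }
  invisible(spec)
}

# logical array of an ellipsoid on a (z,y,x) grid, evaluated only in its
# bounding box; 0-based center coordinates.
ellipsoid_mask <- function(shape, center, semi) {
  m <- array(FALSE, dim = shape)
  rng <- lapply(1:3, function(a)
    max(0, floor(center[a] - semi[a])):min(shape[a] - 1, ceiling(center[a] + semi[a])))
  dz <- ((rng[[1]] - center[1]) / semi[1])^2
  dy <- ((rng[[2]] - center[2]) / semi[2])^2
  dx <- ((rng[[3]] - center[3]) / semi[3])^2
  box <- outer(outer(dz, dy, `+`), dx, `+`) <= 1
  m[rng[[1]] + 1, rng[[2]] + 1, rng[[3]] + 1] <- box
  m
}

distractor_mask <- function(shape, d) {
  if (d$type == "cylinder") {
    dy <- ((0:(shape[2] - 1) - d$center[2]) / d$radius)^2
    dx <- ((0:(shape[3] - 1) - d$center[3]) / d$radius)^2
    disk <- outer(dy, dx, `+`) <= 1
    array(rep(disk, each = shape[1]), dim = shape)
  } else if (d$type == "sphere") {
    ellipsoid_mask(shape, d$center, pmin(rep(d$radius, 3), d$center,
                                         shape - 1 - d$center))
  } else if (d$type == "ellipsoid") {
    ellipsoid_mask(shape, d$center, pmin(d$semi, d$center,
                                         shape - 1 - d$center))
  } else stop("unknown distractor type: ", d$type)
}

#' Generate one labeled phantom volume
#'
#' Organ and distractor voxels take their specified mean intensity exactly
#' (so with `noise_sigma = 0` the in-mask mean equals the spec), background
#' voxels take `background_mean` plus a smooth random texture; Gaussian noise
#' is added everywhere and the result is clipped to `[0, 1]`.  The same seed
#' reproduces the volume bit for bit.
#'
#' @param spec a [phantom_spec()].
#' @return `list(volume = ct_volume, masks = named list of ct_mask)`, one
#'   mask per organ label.
#' @export
make_phantom <- function(spec) {
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  sh <- spec$shape
  # low-frequency 2D texture, replicated along z
  yy <- 0:(sh[2] - 1); xx <- 0:(sh[3] - 1)
  tex <- matrix(0, sh[2], sh[3])
  for (k in 1:3) {
    fy <- runif(1, 0.5, 2); fx <- runif(1, 0.5, 2); ph <- runif(1, 0, 2 * pi)
    amp <- spec$texture_scale * runif(1, 0.3, 1) / 3
    tex <- tex + amp * outer(cos(2 * pi * fy * yy / sh[2] + ph),
                             cos(2 * pi * fx * xx / sh[3]))
  }
  tex3 <- array(rep(tex, each = sh[1]), dim = sh)
  vol <- array(spec$background_mean, dim = sh) + tex3
  for (d in spec$distractors) {
    dm <- distractor_mask(sh, d)
    # distractor tissues keep the low-frequency internal texture: fat,
    # liver and muscle are not homogeneous in CT, and the clustering stage
    # relies on background intensity modes being wider than the uniformly
    # enhancing organ parenchyma
    vol[dm] <- d$intensity + tex3[dm]
  }
  masks <- list()
  for (o in spec$organs) {
    om <- ellipsoid_mask(sh, o$center, o$semi)
    vol[om] <- o$intensity
    masks[[o$label]] <- ct_mask(om, o$label)
  }
  if (spec$noise_sigma > 0)
    vol <- vol + array(rnorm(prod(sh), 0, spec$noise_sigma), dim = sh)
  vol <- pmin(pmax(vol, 0), 1)
  list(volume = ct_volume(vol, normalized = TRUE), masks = masks)
}

#' Generate a cohort of jittered phantoms
#'
#' Each case perturbs the base spec with a seeded draw: organ/distractor
#' centers move by a few voxels, semi-axes scale by ~15%, intensities shift
#' slightly.  Every organ is present in every phantom; ellipsoids are kept
#' inside the grid.
#'
#' @param n number of phantoms, `n >= 1`.
#' @param base_spec the [phantom_spec()] to jitter.
#' @param seed cohort seed (drives jitters and per-case noise seeds).
#' @return list of `n` elements, each as returned by [make_phantom()].
#' @export
make_cohort <- function(n, base_spec = phantom_spec(), seed = 1L) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max - 1L, n)
  specs <- lapply(seq_len(n), function(i) jitter_spec(base_spec, case_seeds[i]))
  lapply(specs, make_phantom)
}

# one jittered copy of a spec; jitters drawn from the current RNG stream,
# the per-case noise seed set explicitly.  Position jitter scales with the
# grid (the reference amounts, +-3 slices and +-15 px, apply at the
# canonical 43 x 512 x 512 size; a sub-sampled test grid gets
# proportionally smaller shifts).
jitter_spec <- function(spec, case_seed) {
  sh <- spec$shape
  scl <- sh / c(43, 512, 512)
  out <- spec
  out$organs <- lapply(spec$organs, function(o) {
    o$center <- o$center + c(round(runif(1, -3, 3) * scl[1]),
                             round(runif(1, -15, 15) * scl[2]),
                             round(runif(1, -15, 15) * scl[3]))
    o$semi <- o$semi * runif(3, 0.85, 1.15)
    o$intensity <- o$intensity + runif(1, -0.04, 0.04)
    # clamp so the ellipsoid stays inside the grid
    o$center <- pmin(pmax(o$center, o$semi), sh - 1 - o$semi)
    o
  })
  out$distractors <- lapply(spec$distractors, function(d) {
    d$center <- d$center + c(0, round(runif(1, -10, 10) * scl[2]),
                             round(runif(1, -10, 10) * scl[3]))
    d
  })
  out$seed <- as.integer(case_seed)
  out
}

#' Write a phantom cohort to NIfTI files
#'
#' Writes `volume_<i>.nii.gz` and `mask_<i>_<label>.nii.gz` per case.
#'
#' @param cohort result of [make_cohort()].
#' @param dir output directory (created if needed).
#' @return invisible vector of volume paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(cohort))
  for (i in seq_along(cohort)) {
    paths[i] <- file.path(dir, sprintf("volume_%03d.nii.gz", i))
    write_volume(cohort[[i]]$volume, paths[i])
    for (lb in names(cohort[[i]]$masks))
      write_volume(cohort[[i]]$masks[[lb]],
                   file.path(dir, sprintf("mask_%03d_%s.nii.gz", i, lb)))
  }
  invisible(paths)
}
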