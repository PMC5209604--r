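# Synthetic test maps with known ground truth: sums of isotropic Gaussian
# blobs evaluated exactly (no kernel truncation) at voxel centers, optional
# Cn symmetrization about the z axis through the grid center, and additive
# white Gaussian noise added in a separate, seeded step.

#' Phantom specification
#'
#' Describes a synthetic density map as a list of Gaussian blobs on a cubic
#' grid. Each blob is `weight * exp(-||r - center||^2 / (2 sigma^2))` with
#' `center` and `sigma` in Angstrom. With `symmetry_order = n > 1` the blob
#' list is replicated at rotations of `360/n` degrees about the z axis
#' through the grid center before evaluation.
#'
#' @param blobs List of blobs, each a list with elements `center` (length-3,
#'   Angstrom), `sigma` (Angstrom, > 0) and `weight` (> 0).
#' @param dims Grid size, 3 positive integers (a single integer is recycled).
#' @param voxel_size Angstrom per voxel.
#' @param symmetry_order Cn rotational symmetry order about z (>= 1;
#'   1 = none).
#' @param noise_sd Standard deviation of additive Gaussian noise (map units),
#'   applied by [add_noise()]; [make_phantom()] itself is noiseless.
#' @param seed Integer seed used when noise is added.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(blobs, dims, voxel_size, symmetry_order = 1L,
                         noise_sd = 0, seed = 1L) {
  if (length(dims) == 1L) dims <- rep(dims, 3L)
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L), voxel_size > 0,
            symmetry_order >= 1L, noise_sd >= 0)
  upper <- voxel_size * (dims - 1)
  for (b in blobs) {
    if (length(b$center) != 3L || b$sigma <= 0 || b$weight <= 0)
      stop("each blob needs a 3-vector center, sigma > 0 and weight > 0",
           call. = FALSE)
    if (any(b$center < 0) || any(b$center > upper))
      stop("blob center ", paste(b$center, collapse = ","),
           " lies outside the grid extent", call. = FALSE)
  }
  structure(list(blobs = blobs, dims = dims,
                 voxel_size = as.numeric(voxel_size),
                 symmetry_order = as.integer(symmetry_order),
                 noise_sd = as.numeric(noise_sd), seed = as.integer(seed)),
            class = "phantom_spec")
}

# Blob list after Cn replication, as matrices (centers, sigmas, weights).
expand_blobs <- function(spec) {
  centers <- do.call(rbind, lapply(spec$blobs, function(b) as.numeric(b$center)))
  sigmas <- vapply(spec$blobs, function(b) as.numeric(b$sigma), numeric(1))
  weights <- vapply(spec$blobs, function(b) as.numeric(b$weight), numeric(1))
  n_sym <- spec$symmetry_order
  if (n_sym > 1L) {
    ctr <- spec$voxel_size * (spec$dims - 1) / 2
    reps <- lapply(seq_len(n_sym) - 1L, function(k) {
      ang <- 2 * pi * k / n_sym
      rot <- matrix(c(cos(ang), sin(ang), 0,
                      -sin(ang), cos(ang), 0,
                      0, 0, 1), 3, 3)
      sweep(sweep(centers, 2, ctr) %*% t(rot), 2, ctr, "+")
    })
    centers <- do.call(rbind, reps)
    sigmas <- rep(sigmas, n_sym)
    weights <- rep(weights, n_sym)
  }
  list(centers = centers, sigmas = sigmas, weights = weights)
}

#' Generate a phantom density map
#'
#' Evaluates the blob sum exactly (no truncation) at every voxel center.
#' Deterministic; noise is a separate step ([add_noise()]).
#'
#' @param spec A [phantom_spec].
#' @return A [density_map].
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  bl <- expand_blobs(spec)
  vals <- grid_accumulate(bl$centers, bl$weights, bl$sigmas, spec$dims,
                          spec$voxel_size, c(0, 0, 0), cutoff_mult = -1)
  density_map(array(vals, dim = spec$dims), voxel_size = spec$voxel_size)
}

#' Add white Gaussian noise to a map
#'
#' @param map A [density_map].
#' @param sd Noise standard deviation (map units, >= 0).
#' @param seed Integer seed; the same seed always gives the same noise. The
#'   caller's RNG state is left untouched.
#' @return A [density_map] with i.i.d. zero-mean Gaussian noise added.
#' @export
add_noise <- function(map, sd, seed = 1L) {
  stopifnot(inherits(map, "density_map"))
  if (sd < 0) stop("`sd` must be non-negative", call. = FALSE)
  if (sd == 0) return(map)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  noisy <- map$data + array(stats::rnorm(length(map$data), sd = sd),
                            dim = map$dims)
  density_map(noisy, voxel_size = map$voxel_size, origin = map$origin)
}

#' Interpolated conformation series between two phantoms
#'
#' Blob centers are interpolated linearly from `spec_a` to `spec_b`
#' (fractions 0 to 1), so a ground-truth displacement field exists for every
#' frame; sigmas and weights come from `spec_a`. Endpoints equal
#' `make_phantom()` of the inputs.
#'
#' @param spec_a,spec_b [phantom_spec] objects with identical dims,
#'   voxel_size and blob count.
#' @param steps Number of frames (>= 2).
#' @return List of `steps` [density_map] objects.
#' @export
make_conformation_series <- function(spec_a, spec_b, steps) {
  stopifnot(inherits(spec_a, "phantom_spec"), inherits(spec_b, "phantom_spec"),
            steps >= 2L)
  if (!identical(spec_a$dims, spec_b$dims) ||
      spec_a$voxel_size != spec_b$voxel_size)
    stop("phantom specs must share dims and voxel_size", call. = FALSE)
  if (length(spec_a$blobs) != length(spec_b$blobs))
    stop("phantom specs must have the same number of blobs", call. = FALSE)
  lapply(seq_len(steps), function(s) {
    t <- (s - 1) / (steps - 1)
    blobs <- lapply(seq_along(spec_a$blobs), function(i) {
      a <- spec_a$blobs[[i]]; b <- spec_b$blobs[[i]]
      list(center = (1 - t) * a$center + t * b$center,
           sigma = a$sigma, weight = a$weight)
    })
    make_phantom(phantom_spec(blobs, spec_a$dims, spec_a$voxel_size,
                              symmetry_order = spec_a$symmetry_order))
  })
}

#' Reference phantoms used throughout the documentation and tests
#'
#' `phantom_five_blob()`: five well-separated blobs of width 3 Angstrom
#' (1.5 voxels at 2 A/voxel) and distinct weights on a 48^3 grid — the
#' canonical benchmark for the accuracy-controlled approximation.
#' `phantom_c4()`: one off-axis blob replicated with C4 symmetry, for
#' symmetry-preservation checks. `phantom_hinge_pair()`: a two-domain
#' "hinge" molecule whose distal arm is rotated by `angle_deg` degrees about
#' the z axis through the hinge point between the two returned specs; a
#' conformation series between them emulates a continuous open/close motion.
#'
#' @param dims Grid size (cubic).
#' @param voxel_size Angstrom per voxel.
#' @return A [phantom_spec] (`phantom_five_blob`, `phantom_c4`) or a list
#'   with elements `a` and `b` (`phantom_hinge_pair`).
#' @export
phantom_five_blob <- function(dims = 48L, voxel_size = 2) {
  blobs <- list(
    list(center = c(30, 32, 34), sigma = 1.5 * voxel_size, weight = 3.0),
    list(center = c(62, 34, 30), sigma = 1.5 * voxel_size, weight = 2.5),
    list(center = c(32, 60, 40), sigma = 1.5 * voxel_size, weight = 2.0),
    list(center = c(60, 62, 36), sigma = 1.5 * voxel_size, weight = 1.5),
    list(center = c(46, 46, 62), sigma = 1.5 * voxel_size, weight = 1.0))
  phantom_spec(blobs, dims = dims, voxel_size = voxel_size)
}

#' @rdname phantom_five_blob
#' @export
phantom_c4 <- function(dims = 40L, voxel_size = 2) {
  phantom_spec(list(list(center = c(54, 39, 39), sigma = 1.5 * voxel_size,
                         weight = 2.0)),
               dims = dims, voxel_size = voxel_size, symmetry_order = 4L)
}

#' @rdname phantom_five_blob
#' @param angle_deg Hinge opening angle between the two conformations.
#' @export
phantom_hinge_pair <- function(dims = 40L, voxel_size = 2, angle_deg = 30) {
  hinge <- c(40, 40, 40)
  core <- list(
    list(center = c(24, 40, 40), sigma = 3, weight = 2.0),
    list(center = c(30, 34, 40), sigma = 3, weight = 1.6),
    list(center = c(30, 46, 40), sigma = 3, weight = 1.6),
    list(center = c(36, 40, 40), sigma = 3, weight = 1.8))
  arm0 <- rbind(c(48, 40, 40), c(56, 40, 40), c(64, 40, 40))
  rot_about_hinge <- function(p, ang) {
    rot <- matrix(c(cos(ang), sin(ang), 0,
                    -sin(ang), cos(ang), 0,
                    0, 0, 1), 3, 3)
    as.numeric(rot %*% (p - hinge) + hinge)
  }
  arm_blobs <- function(ang) lapply(seq_len(nrow(arm0)), function(i)
    list(center = rot_about_hinge(arm0[i, ], ang), sigma = 3,
         weight = 1.5))
  list(a = phantom_spec(c(core, arm_blobs(0)), dims, voxel_size),
       b = phantom_spec(c(core, arm_blobs(angle_deg * pi / 180)), dims,
                        voxel_size))
}
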