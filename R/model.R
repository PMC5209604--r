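#' Pseudoatom model
#'
#' A pseudoatom model represents a density map as a weighted sum of isotropic
#' Gaussian kernels of shared standard deviation: each pseudoatom is a
#' Gaussian of amplitude 1 and standard deviation `sigma_voxels` voxels,
#' centered at `positions[i, ]` and scaled by `weights[i] > 0`. The kernel
#' width is specified in voxel units (the field's convention) and converted
#' to Angstrom through `voxel_size`.
#'
#' @param positions N x 3 numeric matrix of centers in Angstrom.
#' @param weights N positive weights.
#' @param sigma_voxels Kernel standard deviation in voxels (> 0).
#' @param voxel_size Angstrom per voxel, used to convert `sigma_voxels` to a
#'   physical width.
#' @param label Optional free-text label.
#' @return An object of class `pseudoatom_model`.
#' @examples
#' m <- pseudoatom_model(rbind(c(0, 0, 0), c(6, 0, 0)), c(1, 2),
#'                       sigma_voxels = 1.5, voxel_size = 2)
#' sigma_angstrom(m)
#' @export
pseudoatom_model <- function(positions, weights, sigma_voxels, voxel_size,
                             label = "") {
  positions <- matrix(as.numeric(positions), ncol = 3)
  weights <- as.numeric(weights)
  if (nrow(positions) < 1L) stop("model needs at least one pseudoatom",
                                 call. = FALSE)
  if (length(weights) != nrow(positions))
    stop("`weights` must match the number of positions", call. = FALSE)
  if (any(!is.finite(positions)) || any(!is.finite(weights)))
    stop("positions and weights must be finite", call. = FALSE)
  if (any(weights <= 0)) stop("all weights must be positive", call. = FALSE)
  if (sigma_voxels <= 0) stop("`sigma_voxels` must be positive", call. = FALSE)
  if (voxel_size <= 0) stop("`voxel_size` must be positive", call. = FALSE)
  structure(
    list(positions = positions, weights = weights,
         sigma_voxels = as.numeric(sigma_voxels),
         voxel_size = as.numeric(voxel_size), label = as.character(label)),
    class = "pseudoatom_model")
}

#' @rdname pseudoatom_model
#' @param model A `pseudoatom_model`.
#' @export
sigma_angstrom <- function(model) model$sigma_voxels * model$voxel_size

#' @rdname pseudoatom_model
#' @export
n_pseudoatoms <- function(model) nrow(model$positions)

#' @export
print.pseudoatom_model <- function(x, ...) {
  cat(sprintf("pseudoatom_model: %d grains, sigma = %.3g voxels (%.3g A)\n",
              n_pseudoatoms(x), x$sigma_voxels, sigma_angstrom(x)))
  cat(sprintf("  weight range: [%.4g, %.4g]\n", min(x$weights),
              max(x$weights)))
  if (nzchar(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}
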