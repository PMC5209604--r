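#' Density map container
#'
#' A `density_map` holds a 3D scalar voxel grid together with its physical
#' geometry: an isotropic voxel size (Angstrom per voxel) and the physical
#' position of the center of voxel `(0,0,0)` (0-based indexing). The physical
#' position of voxel `(i,j,k)` is `origin + voxel_size * (i,j,k)`; this
#' voxel-center convention is used by every function in the package.
#'
#' @param data 3D numeric array of density values (arbitrary units).
#' @param voxel_size Voxel edge length in Angstrom (isotropic, > 0).
#' @param origin Physical position (Angstrom, length 3) of the center of the
#'   first voxel. Defaults to `c(0, 0, 0)`.
#'
#' @return An object of class `density_map` with elements `data`,
#'   `voxel_size`, `origin` and `dims`.
#' @examples
#' m <- density_map(array(0, c(8, 8, 8)), voxel_size = 2)
#' m$dims
#' @export
density_map <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (!all(is.finite(data)))
    stop("density values must all be finite", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number", call. = FALSE)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be a finite 3-vector", call. = FALSE)
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin), dims = dim(data)),
    class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map: %d x %d x %d voxels, %.4g A/voxel\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size))
  cat(sprintf("  origin (A): %.3f %.3f %.3f\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  density range: [%.6g, %.6g]\n", min(x$data), max(x$data)))
  invisible(x)
}

# Physical coordinates (Angstrom) of all voxel centers along one axis.
axis_coords <- function(map, axis) {
  map$origin[axis] + map$voxel_size * (seq_len(map$dims[axis]) - 1)
}

# Physical extent of the grid: voxel centers span [origin, upper].
grid_extent <- function(map) {
  rbind(lower = map$origin,
        upper = map$origin + map$voxel_size * (map$dims - 1))
}

#' Pearson correlation between two maps on a common grid
#'
#' @param a,b `density_map` objects with identical dims.
#' @param mask Optional logical array restricting the comparison.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
map_correlation <- function(a, b, mask = NULL) {
  stopifnot(identical(a$dims, b$dims))
  if (is.null(mask)) {
    stats::cor(as.vector(a$data), as.vector(b$data))
  } else {
    stats::cor(a$data[mask], b$data[mask])
  }
}
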