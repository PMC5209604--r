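# Elastic 3D-to-3D fitting: displace a pseudoatom model along its low
# normal modes and adjust the amplitudes to maximize the cross-correlation
# with a reference map. Pairwise distances 1 - max(CC) over a set of maps,
# embedded by classical multidimensional scaling, give a low-dimensional
# picture of the conformational relationships among the maps.

#' Elastically fit a model to a reference map
#'
#' Maximizes the Pearson correlation between `render_map(displace_model(
#' model, a))` and the reference over a fixed mask, using a derivative-free
#' Nelder-Mead search over the amplitudes of `n_fit_modes` modes starting at
#' the first non-rigid mode. The search starts from zero amplitudes, keeps
#' the best point seen (never returning worse than its initialization),
#' stops at relative tolerance 1e-3 or 500 evaluations, and bounds each
#' amplitude by `10 sqrt(N)`.
#'
#' @param model A [pseudoatom_model].
#' @param modes A [compute_modes()] result for this model.
#' @param reference A [density_map] with the model's voxel size.
#' @param n_fit_modes Number of non-rigid modes to optimize (default 5).
#' @param mask Optional logical array; the default is the union of the
#'   voxels above 5% of the maximum in the reference and in the undisplaced
#'   render.
#' @return An object of class `fit_result`: `amplitudes`
#'   ([amplitude_vector]), `max_cc`, `distance` (= 1 - max_cc), `n_evals`.
#' @export
fit_pair <- function(model, modes, reference, n_fit_modes = 5L, mask = NULL) {
  stopifnot(inherits(model, "pseudoatom_model"),
            inherits(reference, "density_map"))
  if (abs(reference$voxel_size - model$voxel_size) >
      1e-9 * reference$voxel_size)
    stop("model and reference voxel sizes differ", call. = FALSE)
  n_avail <- ncol(modes$modes) - modes$n_zero
  if (n_fit_modes < 1L || n_fit_modes > n_avail)
    stop("`n_fit_modes` must be in 1..", n_avail, call. = FALSE)
  idx <- modes$n_zero + seq_len(n_fit_modes)

  base <- render_map(model, reference$dims, reference$voxel_size,
                     reference$origin)
  if (is.null(mask))
    mask <- reference$data > 0.05 * max(reference$data) |
      base$data > 0.05 * max(base$data)
  ref_v <- reference$data[mask]
  if (stats::sd(ref_v) == 0)
    stop("reference map is constant over the mask; correlation undefined",
         call. = FALSE)
  bound <- 10 * sqrt(n_pseudoatoms(model))

  n_evals <- 0L
  best_cc <- -Inf
  best_a <- rep(0, n_fit_modes)
  obj <- function(a) {
    if (any(abs(a) > bound)) return(2)  # outside the trust region
    n_evals <<- n_evals + 1L
    m <- displace_model(model, modes, amplitude_vector(idx, a))
    r <- render_map(m, reference$dims, reference$voxel_size, reference$origin)
    cc <- stats::cor(r$data[mask], ref_v)
    if (!is.finite(cc)) cc <- -1
    if (cc > best_cc) { best_cc <<- cc; best_a <<- a }
    1 - cc
  }
  obj(rep(0, n_fit_modes))
  suppressWarnings(stats::optim(rep(0, n_fit_modes), obj,
                                method = "Nelder-Mead",
                                control = list(maxit = 500L, reltol = 1e-3)))
  structure(list(amplitudes = amplitude_vector(idx, best_a),
                 max_cc = best_cc, distance = 1 - best_cc,
                 n_evals = n_evals),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: max CC = %.5f, distance = %.5f (%d evaluations)\n",
              x$max_cc, x$distance, x$n_evals))
  invisible(x)
}

#' Pairwise elastic distance matrix over a set of maps
#'
#' Each map is converted to pseudoatoms ([approximate_map()]) and analyzed
#' ([compute_modes()]); the entry (i, j) is the distance `1 - max(CC)` from
#' elastically fitting model i to map j. Raw distances are symmetrized by
#' averaging `(d_ij + d_ji) / 2`; the diagonal is zero.
#'
#' @param maps List of [density_map] objects on a common grid.
#' @param config [approx_config] used to convert every map.
#' @param n_fit_modes Modes optimized per fit (default 5).
#' @param cutoff ENM cutoff passed to [build_network()] (`NULL` = default).
#' @param labels Map identifiers (default `map1`, `map2`, ...).
#' @return An object of class `distance_space`: `labels`, `matrix`
#'   (symmetric, zero diagonal), `embedding` (`NULL` until
#'   [embed_space()]), and `fits` (the per-map [approximate_map()] results).
#' @export
distance_matrix <- function(maps, config = approx_config(), n_fit_modes = 5L,
                            cutoff = NULL, labels = NULL) {
  m <- length(maps)
  stopifnot(m >= 2L)
  if (is.null(labels)) labels <- paste0("map", seq_len(m))
  geo <- vapply(maps, function(x) c(x$dims, x$voxel_size), numeric(4))
  if (any(apply(geo, 1, function(r) diff(range(r))) > 1e-9))
    stop("all maps must share grid dimensions and voxel size", call. = FALSE)

  conversions <- lapply(seq_len(m), function(i) {
    res <- tryCatch(approximate_map(maps[[i]], config),
                    error = function(e) stop("conversion of ", labels[i],
                                             " failed: ",
                                             conditionMessage(e),
                                             call. = FALSE))
    list(result = res,
         modes = compute_modes(build_network(res$model, cutoff = cutoff)))
  })

  raw <- matrix(0, m, m, dimnames = list(labels, labels))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      raw[i, j] <- fit_pair(conversions[[i]]$result$model,
                            conversions[[i]]$modes, maps[[j]],
                            n_fit_modes = n_fit_modes)$distance
    }
  }
  d <- (raw + t(raw)) / 2
  diag(d) <- 0
  structure(list(labels = labels, matrix = d, embedding = NULL,
                 fits = conversions),
            class = "distance_space")
}

#' Low-dimensional embedding of a distance space
#'
#' Classical metric multidimensional scaling (double-centered squared
#' distances, top-`d` eigenvectors scaled by the square roots of their
#' eigenvalues, via [stats::cmdscale()]). Axes whose eigenvalues are not
#' positive are filled with zeros, with a warning.
#'
#' @param space A [distance_matrix()] result.
#' @param d Embedding dimension (1, 2 or 3; must be < number of maps).
#' @return `space` with `embedding` filled (M x d matrix, columns ordered
#'   by eigenvalue).
#' @export
embed_space <- function(space, d = 2L) {
  stopifnot(inherits(space, "distance_space"), d %in% 1:3)
  m <- nrow(space$matrix)
  if (d > m - 1L)
    stop("embedding dimension must be below the number of maps",
         call. = FALSE)
  if (all(space$matrix == 0)) {
    space$embedding <- matrix(0, m, d, dimnames = list(space$labels, NULL))
    return(space)
  }
  res <- stats::cmdscale(space$matrix, k = d, eig = TRUE)
  pts <- res$points
  if (ncol(pts) < d) {
    warning("only ", ncol(pts), " positive eigenvalue(s); remaining ",
            "embedding axes set to zero")
    pts <- cbind(pts, matrix(0, m, d - ncol(pts)))
  }
  dimnames(pts) <- list(space$labels, NULL)
  space$embedding <- pts
  space
}

#' @export
print.distance_space <- function(x, ...) {
  cat("distance_space over", length(x$labels), "maps\n")
  print(signif(x$matrix, 4))
  if (!is.null(x$embedding)) {
    cat("embedding:\n")
    print(signif(x$embedding, 4))
  }
  invisible(x)
}

# Circular 2D shift of a matrix by (di, dj) pixels.
circ_shift <- function(m, di, dj) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[((seq_len(n1) - 1 - di) %% n1) + 1, ((seq_len(n2) - 1 - dj) %% n2) + 1]
}

# Best circular in-plane alignment of `proj` to `img` by FFT
# cross-correlation; returns the shift (pixels, applied to proj) and the
# Pearson correlation after shifting.
align_by_cc <- function(img, proj) {
  a <- img - mean(img)
  b <- proj - mean(proj)
  r <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  peak <- arrayInd(which.max(r), dim(r)) - 1L
  n <- dim(r)
  sh <- ifelse(peak > n / 2, peak - n, peak)
  shifted <- circ_shift(proj, sh[1], sh[2])
  cc <- stats::cor(as.vector(img), as.vector(shifted))
  list(shift = as.integer(sh), cc = if (is.finite(cc)) cc else -1)
}

#' Elastic projection matching of a single image
#'
#' For every orientation in an explicit grid, optimizes the normal-mode
#' amplitudes so the model's analytic projection best matches the image;
#' the in-plane translation is solved at each evaluation by the FFT
#' cross-correlation peak (integer pixels). The image is assigned the
#' orientation, shift and amplitudes of the best match. This is a
#' single-image building block of elastic projection matching; large image
#' series, orientation refinement off the grid and CTF are out of scope.
#'
#' @param model A [pseudoatom_model].
#' @param modes A [compute_modes()] result for this model.
#' @param image A [render_projection()]-compatible `projection_image`.
#' @param orientation_grid Matrix with 3 columns of ZYZ Euler angles
#'   (degrees), one row per trial orientation.
#' @param n_fit_modes Non-rigid modes optimized per orientation (default 3).
#' @return List with `orientation` (best row), `shift` (pixels), and `fit`
#'   (a `fit_result`).
#' @export
fit_image <- function(model, modes, image, orientation_grid,
                      n_fit_modes = 3L) {
  stopifnot(inherits(image, "projection_image"))
  orientation_grid <- matrix(orientation_grid, ncol = 3)
  if (nrow(orientation_grid) == 0L)
    stop("orientation grid is empty", call. = FALSE)
  n_avail <- ncol(modes$modes) - modes$n_zero
  if (n_fit_modes < 1L || n_fit_modes > n_avail)
    stop("`n_fit_modes` must be in 1..", n_avail, call. = FALSE)
  idx <- modes$n_zero + seq_len(n_fit_modes)
  dims <- dim(image$data)
  center <- colMeans(model$positions)
  bound <- 10 * sqrt(n_pseudoatoms(model))

  best <- list(cc = -Inf)
  for (o in seq_len(nrow(orientation_grid))) {
    ori <- orientation_grid[o, ]
    n_evals <- 0L
    best_cc <- -Inf
    best_a <- rep(0, n_fit_modes)
    best_sh <- c(0L, 0L)
    obj <- function(a) {
      if (any(abs(a) > bound)) return(2)
      n_evals <<- n_evals + 1L
      m <- displace_model(model, modes, amplitude_vector(idx, a))
      pr <- render_projection(m, ori, dims, image$pixel_size, center = center)
      al <- align_by_cc(image$data, pr$data)
      if (al$cc > best_cc) {
        best_cc <<- al$cc; best_a <<- a; best_sh <<- al$shift
      }
      1 - al$cc
    }
    obj(rep(0, n_fit_modes))
    suppressWarnings(stats::optim(rep(0, n_fit_modes), obj,
                                  method = "Nelder-Mead",
                                  control = list(maxit = 200L,
                                                 reltol = 1e-3)))
    if (best_cc > best$cc)
      best <- list(cc = best_cc, a = best_a, sh = best_sh, ori = ori,
                   n_evals = n_evals)
  }
  list(orientation = best$ori, shift = best$sh,
       fit = structure(list(amplitudes = amplitude_vector(idx, best$a),
                            max_cc = best$cc, distance = 1 - best$cc,
                            n_evals = best$n_evals),
                       class = "fit_result"))
}
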