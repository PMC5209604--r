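# Accuracy-controlled approximation of a density map by pseudoatoms. The
# outer loop alternates gradient-descent refinement of positions and weights,
# pruning of light or coincident grains, and residual-driven growth, until
# the mean absolute deviation (as a percentage of the map's effective range)
# drops below the target. Refinement descends the smooth L2 objective
# J = sum_mask (f - fhat)^2; convergence is judged on the L1-type error e_N,
# whose absolute value is not differentiable.

#' Approximation configuration
#'
#' @param sigma_voxels Kernel standard deviation in voxels (typical range
#'   1-2; default 1.5).
#' @param target_error Target error `epsilon` in percent of the map's
#'   effective range (0 < epsilon < 100).
#' @param mask Optional explicit logical array (same dims as the map). When
#'   `NULL`, the mask is `f > mask_threshold * max(f)`.
#' @param mask_threshold Threshold fraction in `[0, 1)` of the maximum
#'   density; the default 0 masks to strictly positive voxels.
#' @param n_seed Initial number of pseudoatoms; default
#'   `min(300, max(1, floor(V/1000)))` for V masked voxels.
#' @param grow_fraction New grains per outer iteration as a fraction of the
#'   current N (minimum 1 grain).
#' @param min_separation Minimum center-to-center distance in voxels.
#' @param weight_floor Prune threshold as a fraction of the mean weight.
#' @param max_outer_iters Outer-iteration cap; hitting it flags
#'   non-convergence (not an error).
#' @param inner_gd_steps Gradient-descent steps per outer iteration.
#' @param gd_tolerance Relative objective decrease below which the inner
#'   loop stops early.
#' @param max_pseudoatoms Hard cap on N; growth stops at the cap while
#'   refinement continues (safety valve for unattainable targets).
#' @return An object of class `approx_config`.
#' @export
approx_config <- function(sigma_voxels = 1.5, target_error = 5, mask = NULL,
                          mask_threshold = 0, n_seed = NULL,
                          grow_fraction = 0.1, min_separation = 1.0,
                          weight_floor = 0.01, max_outer_iters = 100L,
                          inner_gd_steps = 50L, gd_tolerance = 1e-4,
                          max_pseudoatoms = 5000L) {
  stopifnot(sigma_voxels > 0, target_error > 0, target_error < 100,
            mask_threshold >= 0, mask_threshold < 1, grow_fraction > 0,
            min_separation >= 0, weight_floor >= 0, max_outer_iters >= 1,
            inner_gd_steps >= 1, gd_tolerance > 0, max_pseudoatoms >= 1)
  structure(list(sigma_voxels = sigma_voxels, target_error = target_error,
                 mask = mask, mask_threshold = mask_threshold,
                 n_seed = n_seed, grow_fraction = grow_fraction,
                 min_separation = min_separation, weight_floor = weight_floor,
                 max_outer_iters = as.integer(max_outer_iters),
                 inner_gd_steps = as.integer(inner_gd_steps),
                 gd_tolerance = gd_tolerance,
                 max_pseudoatoms = as.integer(max_pseudoatoms)),
            class = "approx_config")
}

# Logical evaluation mask for a map under a config.
resolve_mask <- function(map, config) {
  if (!is.null(config$mask)) {
    mask <- config$mask
    if (!identical(dim(mask), map$dims))
      stop("explicit mask dims do not match the map", call. = FALSE)
    return(mask)
  }
  map$data > config$mask_threshold * max(map$data)
}

#' Approximation error of a model against a map
#'
#' The error is the mean absolute voxelwise deviation over the evaluated
#' voxels, as a percentage of the effective range:
#' `e_N = 100 * mean(|f - fhat|) / (max(f) - min(f))`, all statistics taken
#' over the mask.
#'
#' @param map A [density_map].
#' @param model A [pseudoatom_model] sharing the map's voxel size.
#' @param mask Optional logical array; `NULL` evaluates every voxel.
#' @return An object of class `error_report` with `e_N` (percent),
#'   `delta_f` (effective range, map units), `v_count` (evaluated voxels)
#'   and `mask_description`.
#' @export
compute_error <- function(map, model, mask = NULL) {
  stopifnot(inherits(map, "density_map"), inherits(model, "pseudoatom_model"))
  if (abs(map$voxel_size - model$voxel_size) > 1e-9 * map$voxel_size)
    stop("map and model voxel sizes differ", call. = FALSE)
  if (is.null(mask)) {
    mask <- array(TRUE, map$dims)
    desc <- "all voxels"
  } else {
    desc <- sprintf("%d of %d voxels", sum(mask), length(mask))
  }
  v <- sum(mask)
  if (v < 1) stop("empty evaluation mask", call. = FALSE)
  f <- map$data[mask]
  delta_f <- max(f) - min(f)
  if (delta_f <= 0)
    stop("degenerate map: effective range is zero over the mask",
         call. = FALSE)
  fhat <- render_map(model, map$dims, map$voxel_size, map$origin)$data[mask]
  structure(list(e_N = 100 * mean(abs(f - fhat)) / delta_f,
                 delta_f = delta_f, v_count = v, mask_description = desc),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("error_report: e_N = %.4g%%  (delta_f = %.4g over %d voxels; %s)\n",
              x$e_N, x$delta_f, x$v_count, x$mask_description))
  invisible(x)
}

# Masked voxel centers and values, ordered by decreasing density.
masked_voxels_desc <- function(map, mask) {
  idx <- which(mask, arr.ind = TRUE)
  vals <- map$data[mask]
  ord <- order(vals, decreasing = TRUE)
  list(coords = sweep((idx[ord, , drop = FALSE] - 1) * map$voxel_size, 2,
                      map$origin, "+"),
       values = vals[ord])
}

#' Deterministic greedy seeding of an initial model
#'
#' Visits masked voxels in decreasing density order and accepts a voxel as a
#' new center when it is at least `min_separation` voxels from every
#' accepted center, stopping at `n_seed` grains. Each seed's weight is the
#' map value at its voxel. No randomness is involved.
#'
#' @param map A [density_map].
#' @param config An [approx_config].
#' @return A [pseudoatom_model].
#' @export
seed_model <- function(map, config = approx_config()) {
  mask <- resolve_mask(map, config)
  if (sum(mask) < 1) stop("empty evaluation mask", call. = FALSE)
  mv <- masked_voxels_desc(map, mask)
  pos_ok <- mv$values > 0
  if (!any(pos_ok))
    stop("degenerate map: no masked voxel has positive density",
         call. = FALSE)
  n_seed <- config$n_seed
  if (is.null(n_seed)) n_seed <- min(300L, max(1L, sum(mask) %/% 1000L))
  n_seed <- min(n_seed, config$max_pseudoatoms)
  sep <- config$min_separation * map$voxel_size
  keep <- greedy_min_sep(mv$coords[pos_ok, , drop = FALSE],
                         matrix(numeric(0), 0, 3), sep, as.integer(n_seed))
  pseudoatom_model(mv$coords[pos_ok, , drop = FALSE][keep, , drop = FALSE],
                   mv$values[pos_ok][keep],
                   sigma_voxels = config$sigma_voxels,
                   voxel_size = map$voxel_size)
}

#' Residual-driven growth step
#'
#' Computes the residual `f - fhat` over the mask and adds up to
#' `max(1, round(grow_fraction * N))` grains at the voxels of largest
#' positive residual, each at least `min_separation` voxels from all
#' existing and newly added centers; a new grain's weight is the residual
#' value at its voxel. If no residual is positive the model is returned
#' unchanged.
#'
#' @inheritParams seed_model
#' @param model Current [pseudoatom_model].
#' @return A [pseudoatom_model].
#' @export
grow_step <- function(map, model, config = approx_config()) {
  mask <- resolve_mask(map, config)
  resid <- map$data - render_map(model, map$dims, map$voxel_size,
                                 map$origin)$data
  resid[!mask] <- -Inf
  n_new <- max(1L, round(config$grow_fraction * n_pseudoatoms(model)))
  n_new <- min(n_new, config$max_pseudoatoms - n_pseudoatoms(model))
  if (n_new < 1L) return(model)
  idx <- which(resid > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(model)
  vals <- resid[resid > 0]
  ord <- order(vals, decreasing = TRUE)
  coords <- sweep((idx[ord, , drop = FALSE] - 1) * map$voxel_size, 2,
                  map$origin, "+")
  sep <- config$min_separation * map$voxel_size
  keep <- greedy_min_sep(coords, model$positions, sep, as.integer(n_new))
  if (length(keep) == 0L) return(model)
  pseudoatom_model(rbind(model$positions, coords[keep, , drop = FALSE]),
                   c(model$weights, vals[ord][keep]),
                   model$sigma_voxels, model$voxel_size, model$label)
}

#' Prune light and coincident grains
#'
#' Removes grains whose weight falls below `weight_floor * mean(weight)`,
#' then repeatedly merges any pair closer than `min_separation` voxels into
#' their weight-weighted centroid with summed weight. The heaviest grain
#' always survives.
#'
#' @param model A [pseudoatom_model].
#' @param config An [approx_config].
#' @return A [pseudoatom_model].
#' @export
prune_step <- function(model, config = approx_config()) {
  pos <- model$positions
  w <- model$weights
  keep <- w >= config$weight_floor * mean(w)
  keep[which.max(w)] <- TRUE
  pos <- pos[keep, , drop = FALSE]
  w <- w[keep]
  sep <- config$min_separation * model$voxel_size
  repeat {
    if (nrow(pos) < 2L) break
    d <- as.matrix(stats::dist(pos))
    d[!upper.tri(d)] <- Inf
    m <- which.min(d)
    if (d[m] >= sep) break
    i <- row(d)[m]; j <- col(d)[m]
    merged <- (w[i] * pos[i, ] + w[j] * pos[j, ]) / (w[i] + w[j])
    pos[i, ] <- merged
    w[i] <- w[i] + w[j]
    pos <- pos[-j, , drop = FALSE]
    w <- w[-j]
  }
  pseudoatom_model(pos, w, model$sigma_voxels, model$voxel_size, model$label)
}

#' Gradient-descent refinement of positions and weights
#'
#' Minimizes the smooth objective `J = sum_mask (f - fhat)^2` by gradient
#' descent with backtracking line search. Gradients with respect to every
#' center and weight are analytic. The descent direction is the gradient
#' scaled per block so the largest position move is one step-size times the
#' voxel size and the largest weight change one step-size times the mean
#' weight. Weights are clipped to stay positive (at 1e-12, leaving them to
#' the next prune); centers are clamped to the grid extent. J never
#' increases across accepted steps; the loop stops early when the relative
#' decrease falls below `gd_tolerance`.
#'
#' @inheritParams grow_step
#' @return A refined [pseudoatom_model].
#' @export
refine_step <- function(map, model, config = approx_config()) {
  mask <- resolve_mask(map, config)
  sig <- sigma_angstrom(model)
  dims <- as.integer(map$dims)
  ext <- grid_extent(map)
  pos <- model$positions
  w <- model$weights
  n <- nrow(pos)

  render_vals <- function(p, wt)
    grid_accumulate(p, wt, rep(sig, n), dims, map$voxel_size, map$origin,
                    KERNEL_CUTOFF_MULT)
  resid_of <- function(p, wt) {
    r <- map$data - array(render_vals(p, wt), dims)
    r[!mask] <- 0
    r
  }
  resid <- resid_of(pos, w)
  J <- sum(resid^2)
  step <- 0.5

  for (it in seq_len(config$inner_gd_steps)) {
    g <- grid_gradient(pos, w, sig, dims, map$voxel_size, map$origin,
                       as.vector(resid), KERNEL_CUTOFF_MULT)
    if (any(!is.finite(g$positions)) || any(!is.finite(g$weights)))
      stop("non-finite gradient in refine_step at inner iteration ", it,
           call. = FALSE)
    gp_max <- max(abs(g$positions))
    gw_max <- max(abs(g$weights))
    scale_ref <- max(J, 1e-300)
    if (gp_max < 1e-12 && gw_max < 1e-12) break
    dir_p <- if (gp_max > 0) g$positions / gp_max * map$voxel_size else
      g$positions * 0
    dir_w <- if (gw_max > 0) g$weights / gw_max * mean(w) else g$weights * 0

    accepted <- FALSE
    t <- step
    for (bt in seq_len(40L)) {
      p_new <- pos - t * dir_p
      p_new[, 1] <- pmin(pmax(p_new[, 1], ext[1, 1]), ext[2, 1])
      p_new[, 2] <- pmin(pmax(p_new[, 2], ext[1, 2]), ext[2, 2])
      p_new[, 3] <- pmin(pmax(p_new[, 3], ext[1, 3]), ext[2, 3])
      w_new <- pmax(w - t * dir_w, 1e-12)
      r_new <- resid_of(p_new, w_new)
      J_new <- sum(r_new^2)
      if (J_new < J) { accepted <- TRUE; break }
      t <- t / 2
    }
    if (!accepted) break
    pos <- p_new; w <- w_new; resid <- r_new
    rel <- (J - J_new) / scale_ref
    J <- J_new
    step <- min(t * 2, 4)
    if (rel < config$gd_tolerance) break
  }
  pseudoatom_model(pos, w, model$sigma_voxels, model$voxel_size, model$label)
}

#' Accuracy-controlled pseudoatom approximation of a density map
#'
#' Determines the number of pseudoatoms, their positions and weights so that
#' the approximation error `e_N` falls below the target `epsilon`. The
#' procedure seeds grains greedily at high-density voxels, then iterates:
#' refine (gradient descent on positions and weights), prune (drop light
#' grains, merge coincident ones), measure `e_N`, and — if the target is not
#' yet met — grow new grains where the residual is largest. Growing in
#' regions of large error is what lets the optimization escape poor local
#' minima of a fixed-N fit. The run is fully deterministic.
#'
#' @param map A [density_map].
#' @param config An [approx_config].
#' @return An object of class `approx_result`: `model`
#'   ([pseudoatom_model]), `report` ([compute_error] output), `converged`
#'   (`e_N < target_error`), `outer_iterations`, and `error_trace` (`e_N`
#'   per outer iteration). Non-convergence within `max_outer_iters` is
#'   flagged, not an error.
#' @examples
#' \donttest{
#' map <- make_phantom(phantom_five_blob())
#' res <- approximate_map(map, approx_config(sigma_voxels = 1.5,
#'                                           target_error = 5))
#' res$converged
#' res$report$e_N
#' }
#' @export
approximate_map <- function(map, config = approx_config()) {
  stopifnot(inherits(map, "density_map"), inherits(config, "approx_config"))
  mask <- resolve_mask(map, config)
  model <- seed_model(map, config)
  trace <- numeric(0)
  converged <- FALSE
  report <- NULL
  it <- 0L
  for (it in seq_len(config$max_outer_iters)) {
    model <- refine_step(map, model, config)
    model <- prune_step(model, config)
    report <- compute_error(map, model, mask)
    trace[it] <- report$e_N
    if (report$e_N < config$target_error) { converged <- TRUE; break }
    if (it < config$max_outer_iters)
      model <- grow_step(map, model, config)
  }
  structure(list(model = model, report = report, converged = converged,
                 outer_iterations = it, error_trace = trace,
                 config = config),
            class = "approx_result")
}

#' @export
print.approx_result <- function(x, ...) {
  cat(sprintf("approx_result: N = %d, e_N = %.4g%% (target %.4g%%), %s after %d outer iteration(s)\n",
              n_pseudoatoms(x$model), x$report$e_N, x$config$target_error,
              if (x$converged) "converged" else "NOT converged",
              x$outer_iterations))
  invisible(x)
}
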