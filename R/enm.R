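# Elastic network model on pseudoatom centers. Nodes within the interaction
# cutoff are connected by harmonic springs of uniform force constant; the
# normal modes are the eigenvectors of the 3N x 3N Hessian of the network
# potential and the frequencies the square roots of its eigenvalues. A
# connected network has exactly six zero modes (rigid translations and
# rotations). Mode vectors use the interleaved layout (x1, y1, z1, x2, ...).

#' Build an elastic network on pseudoatom centers
#'
#' Connects every pair of nodes within the cutoff distance (closed ball:
#' pairs at exactly the cutoff are connected). The default cutoff is three
#' times the mean nearest-neighbor distance, which keeps typical pseudoatom
#' clouds connected. A disconnected network triggers a warning, not an
#' error (each extra component contributes six more zero modes).
#'
#' @param model A [pseudoatom_model], or an N x 3 coordinate matrix
#'   (Angstrom).
#' @param cutoff Interaction cutoff distance in Angstrom (`NULL` for the
#'   default).
#' @param force_constant Uniform spring constant (arbitrary units).
#' @return An object of class `elastic_network`: `nodes`, `cutoff`,
#'   `force_constant`, `edges` (2-column index matrix), `n_components`.
#' @export
build_network <- function(model, cutoff = NULL, force_constant = 1) {
  nodes <- if (inherits(model, "pseudoatom_model")) model$positions else
    matrix(as.numeric(model), ncol = 3)
  n <- nrow(nodes)
  if (n < 2L) stop("an elastic network needs at least 2 nodes", call. = FALSE)
  d <- as.matrix(stats::dist(nodes))
  if (is.null(cutoff)) {
    diag(d) <- Inf
    cutoff <- 3 * mean(apply(d, 1, min))
    diag(d) <- 0
  }
  if (cutoff <= 0) stop("`cutoff` must be positive", call. = FALSE)
  pairs <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  edges <- unname(pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE])

  # connected components by breadth-first search over the edge list
  comp <- integer(n)
  nc <- 0L
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    nc <- nc + 1L
    queue <- s
    comp[s] <- nc
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[as.character(v)]]
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- nc
      queue <- c(queue, nb)
    }
  }
  if (nc > 1L)
    warning("elastic network is disconnected (", nc,
            " components); expect ", 6L * nc, " zero modes")
  structure(list(nodes = nodes, cutoff = cutoff,
                 force_constant = force_constant, edges = edges,
                 n_components = nc),
            class = "elastic_network")
}

#' Assemble the 3N x 3N elastic-network Hessian
#'
#' Standard anisotropic-network Hessian: for each spring (i, j) with unit
#' direction `u` and force constant `k`, the off-diagonal 3x3 block is
#' `-k u u^T` and the diagonal blocks accumulate the negated sum of their
#' row's off-diagonal blocks. The result is symmetric positive semidefinite
#' with the rigid-body motions in its null space.
#'
#' @param network An [build_network()] result.
#' @return A dense 3N x 3N matrix.
#' @export
assemble_hessian <- function(network) {
  stopifnot(inherits(network, "elastic_network"))
  nodes <- network$nodes
  n <- nrow(nodes)
  k <- network$force_constant
  h <- matrix(0, 3 * n, 3 * n)
  for (e in seq_len(nrow(network$edges))) {
    i <- network$edges[e, 1]; j <- network$edges[e, 2]
    dv <- nodes[j, ] - nodes[i, ]
    dn <- sqrt(sum(dv^2))
    if (dn < 1e-6)
      stop("connected nodes ", i, " and ", j, " coincide", call. = FALSE)
    u <- dv / dn
    blk <- k * tcrossprod(u)
    ii <- 3 * (i - 1) + 1:3
    jj <- 3 * (j - 1) + 1:3
    h[ii, jj] <- h[ii, jj] - blk
    h[jj, ii] <- h[jj, ii] - blk
    h[ii, ii] <- h[ii, ii] + blk
    h[jj, jj] <- h[jj, jj] + blk
  }
  h
}

#' Normal modes of an elastic network
#'
#' Full symmetric eigendecomposition of the Hessian. Eigenvalues within
#' `1e-8 * lambda_max` of zero are clamped to exactly zero and counted as
#' zero modes; for a connected network there are exactly six (rigid
#' translations and rotations), which are normally excluded from
#' deformations. Frequencies are the square roots of the (clamped)
#' eigenvalues; mode vectors are unit-norm and mutually orthogonal.
#'
#' @param network An [build_network()] result.
#' @param n_modes Number of lowest modes to keep (default: all 3N).
#' @return An object of class `mode_set`: `eigenvalues`, `frequencies`,
#'   `modes` (3N x n_modes, interleaved x,y,z per node), `n_zero`,
#'   `n_nodes`.
#' @export
compute_modes <- function(network, n_modes = NULL) {
  h <- assemble_hessian(network)
  n3 <- nrow(h)
  if (is.null(n_modes)) n_modes <- n3
  if (n_modes > n3) stop("`n_modes` cannot exceed 3N", call. = FALSE)
  ee <- tryCatch(eigen(h, symmetric = TRUE),
                 error = function(e) stop("eigendecomposition failed: ",
                                          conditionMessage(e), call. = FALSE))
  vals <- rev(ee$values)
  vecs <- ee$vectors[, rev(seq_len(n3)), drop = FALSE]
  lam_max <- max(vals, 0)
  tol <- 1e-8 * max(lam_max, .Machine$double.eps)
  vals[abs(vals) < tol] <- 0
  vals[vals < 0] <- 0
  n_zero <- sum(vals < tol)
  keep <- seq_len(n_modes)
  structure(list(eigenvalues = vals[keep], frequencies = sqrt(vals[keep]),
                 modes = vecs[, keep, drop = FALSE], n_zero = n_zero,
                 n_nodes = n3 %/% 3L),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("mode_set: %d modes of a %d-node network (%d zero/rigid-body)\n",
              ncol(x$modes), x$n_nodes, x$n_zero))
  nf <- min(10L, length(x$frequencies))
  cat("  lowest frequencies:", signif(x$frequencies[seq_len(nf)], 4), "\n")
  invisible(x)
}

#' Write a mode set as plain-text files
#'
#' One whitespace-delimited file per mode (`mode_007.txt`, N rows x 3
#' columns of Angstrom displacements) plus `frequencies.txt` (index,
#' eigenvalue, frequency).
#'
#' @param modes A [compute_modes()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_modes <- function(modes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(ncol(modes$modes))) {
    mk <- matrix(modes$modes[, k], ncol = 3, byrow = TRUE)
    utils::write.table(format(mk, digits = 12),
                       file.path(dir, sprintf("mode_%03d.txt", k)),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  utils::write.table(
    data.frame(index = seq_along(modes$eigenvalues),
               eigenvalue = modes$eigenvalues,
               frequency = modes$frequencies),
    file.path(dir, "frequencies.txt"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
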