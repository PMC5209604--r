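# Shared fixtures and small numeric helpers. Everything is generated in
# code; no data files.

# Small two-blob phantom on a 24^3 grid (voxel 2 A), blob width matched to a
# 1.5-voxel kernel.
two_blob_spec <- function() {
  phantom_spec(list(list(center = c(16, 18, 20), sigma = 3, weight = 2),
                    list(center = c(30, 28, 26), sigma = 3, weight = 1)),
               dims = 24L, voxel_size = 2)
}

# 90-degree rotation of a cubic map's values about the z axis through the
# grid center (exact index permutation; requires nx == ny).
rotate_z90 <- function(arr) {
  stopifnot(dim(arr)[1] == dim(arr)[2])
  aperm(arr, c(2, 1, 3))[, dim(arr)[1]:1, , drop = FALSE]
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

# Physical voxel-center coordinates of a map as an n_voxel x 3 matrix, in
# array (column-major) order.
voxel_coords <- function(map) {
  g <- as.matrix(expand.grid(seq_len(map$dims[1]) - 1,
                             seq_len(map$dims[2]) - 1,
                             seq_len(map$dims[3]) - 1))
  dimnames(g) <- NULL
  sweep(g * map$voxel_size, 2, map$origin, "+")
}

# Brute-force untruncated Gaussian-sum evaluation (independent of the
# package's renderer).
brute_force_render <- function(positions, weights, sigma_a, map,
                               cutoff = Inf) {
  coords <- voxel_coords(map)
  vals <- numeric(nrow(coords))
  for (i in seq_len(nrow(positions))) {
    d2 <- rowSums(sweep(coords, 2, positions[i, ])^2)
    k <- exp(-d2 / (2 * sigma_a^2))
    k[d2 > cutoff^2 * (1 + 1e-12)] <- 0
    vals <- vals + weights[i] * k
  }
  array(vals, dim = map$dims)
}

# Resample a map under a rotation about the grid center (trilinear,
# inverse mapping); used as the independent route in the
# rotate-then-render vs render-then-rotate consistency check.
resample_rotated <- function(map, rot) {
  ctr <- map$origin + map$voxel_size * (map$dims - 1) / 2
  coords <- voxel_coords(map)
  src <- sweep(sweep(coords, 2, ctr) %*% rot, 2, ctr, "+")  # inverse rotation
  g <- sweep(src, 2, map$origin) / map$voxel_size           # 0-based fractional
  out <- numeric(nrow(g))
  d <- map$dims
  f0 <- floor(g)
  fr <- g - f0
  ok <- f0[, 1] >= 0 & f0[, 1] <= d[1] - 2 & f0[, 2] >= 0 &
    f0[, 2] <= d[2] - 2 & f0[, 3] >= 0 & f0[, 3] <= d[3] - 2
  idx <- function(di, dj, dk)
    cbind(f0[ok, 1] + di + 1, f0[ok, 2] + dj + 1, f0[ok, 3] + dk + 1)
  w <- fr[ok, , drop = FALSE]
  acc <- numeric(sum(ok))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    wt <- (if (di == 1) w[, 1] else 1 - w[, 1]) *
      (if (dj == 1) w[, 2] else 1 - w[, 2]) *
      (if (dk == 1) w[, 3] else 1 - w[, 3])
    acc <- acc + wt * map$data[idx(di, dj, dk)]
  }
  out[ok] <- acc
  density_map(array(out, d), map$voxel_size, map$origin)
}
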