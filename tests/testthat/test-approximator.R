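test_that("e_N follows the mean-absolute-deviation formula", {
  # two evaluated voxels, f = (0, 1), fhat = (0, 0.5), delta_f = 1 -> 25%
  map <- density_map(array(c(0, 1), c(2, 1, 1)), voxel_size = 1)
  # a near-delta kernel puts 0.5 on voxel 2 and exactly 0 on voxel 1
  model <- pseudoatom_model(matrix(c(1, 0, 0), 1), 0.5, 0.1, 1)
  rep <- compute_error(map, model)
  expect_equal(rep$e_N, 25)
  expect_equal(rep$delta_f, 1)
  expect_identical(rep$v_count, 2L)

  # a model that renders identically to the map has zero error
  m2 <- pseudoatom_model(matrix(c(8, 8, 8), 1), 2, 1.5, 2)
  r2 <- render_map(m2, 8, 2)
  expect_equal(compute_error(r2, m2)$e_N, 0)

  # direct-formula oracle on an arbitrary map/model pair
  map3 <- make_phantom(two_blob_spec())
  m3 <- pseudoatom_model(rbind(c(16, 18, 20), c(28, 28, 28)), c(1.5, 0.8),
                         1.5, 2)
  mask <- map3$data > 0.1 * max(map3$data)
  fhat <- brute_force_render(m3$positions, m3$weights, 3, map3,
                             cutoff = 4 * 3)
  expected <- 100 * mean(abs(map3$data[mask] - fhat[mask])) /
    (max(map3$data[mask]) - min(map3$data[mask]))
  expect_equal(compute_error(map3, m3, mask)$e_N, expected, tolerance = 1e-8)

  flat <- density_map(array(1, c(2, 2, 2)), 2)
  expect_error(compute_error(flat, m2), "range")
})

test_that("seeding is a density-ordered greedy with minimum separation", {
  spec <- phantom_spec(list(list(center = c(16, 16, 16), sigma = 3,
                                 weight = 2)), 16L, 2)
  map <- make_phantom(spec)
  s1 <- seed_model(map, approx_config(1.5, 5, n_seed = 1))
  expect_identical(n_pseudoatoms(s1), 1L)
  expect_equal(s1$positions[1, ], c(16, 16, 16))   # global-maximum voxel
  expect_equal(s1$weights[1], max(map$data))

  zero <- density_map(array(0, c(4, 4, 4)), 1)
  expect_error(seed_model(zero, approx_config(1.5, 5, mask = array(TRUE, c(4, 4, 4)))),
               "degenerate")

  big <- seed_model(make_phantom(phantom_five_blob()),
                    approx_config(1.5, 5, min_separation = 2))
  d <- as.matrix(dist(big$positions))              # brute-force pair check
  diag(d) <- Inf
  expect_gte(min(d), 2 * 2)                        # 2 voxels at 2 A
})

test_that("growth adds grains at the largest positive residuals", {
  spec <- two_blob_spec()
  map <- make_phantom(spec)
  cfg <- approx_config(1.5, 5)

  # perfect first-blob grain + an unexplained second blob: the added grain
  # lands at the second blob's peak voxel
  m1 <- pseudoatom_model(matrix(c(16, 18, 20), 1), 2, 1.5, 2)
  grown <- grow_step(map, m1, cfg)
  expect_identical(n_pseudoatoms(grown), 2L)
  expect_equal(grown$positions[2, ], c(30, 28, 26))

  # a model rendering the map exactly leaves nothing to grow
  r <- render_map(m1, spec$dims, 2)
  expect_identical(grow_step(r, m1, cfg), m1)

  d <- as.matrix(dist(grown$positions))
  diag(d) <- Inf
  expect_gte(min(d), cfg$min_separation * 2)
})

test_that("pruning removes light grains and merges coincident ones", {
  cfg <- approx_config(1.5, 5)
  even <- pseudoatom_model(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)),
                           c(1, 1, 1), 1.5, 2)
  expect_equal(prune_step(even, cfg)$positions, even$positions)

  co <- pseudoatom_model(rbind(c(5, 5, 5), c(5, 5, 5)), c(2, 3), 1.5, 2)
  merged <- prune_step(co, cfg)
  expect_identical(n_pseudoatoms(merged), 1L)
  expect_equal(merged$weights, 5)
  expect_equal(merged$positions[1, ], c(5, 5, 5))

  # weights (100, 0.1), floor 1%: mean 50.05, threshold 0.5005 -> drop 2nd
  lop <- pseudoatom_model(rbind(c(0, 0, 0), c(20, 0, 0)), c(100, 0.1),
                          1.5, 2)
  pruned <- prune_step(lop, cfg)
  expect_identical(n_pseudoatoms(pruned), 1L)
  expect_equal(pruned$weights, 100)
})

test_that("the analytic refinement gradient matches finite differences", {
  vox <- 1
  dims <- rep(14L, 3)
  f <- make_phantom(phantom_spec(
    list(list(center = c(6, 7, 6), sigma = 1.6, weight = 2),
         list(center = c(8, 6, 8), sigma = 1.4, weight = 1.5)),
    dims, vox))
  pos <- rbind(c(5.6, 6.8, 6.2), c(8.3, 6.2, 7.7), c(6.9, 7.1, 7.2))
  w <- c(1.8, 1.2, 0.4)
  sig <- 1.5
  Jfun <- function(p, wt)
    sum((f$data - render_map(pseudoatom_model(p, wt, sig, vox), dims,
                             vox)$data)^2)

  # analytic gradient assembled in the test from the kernel derivatives
  resid <- f$data - render_map(pseudoatom_model(pos, w, sig, vox), dims,
                               vox)$data
  coords <- voxel_coords(f)
  rv <- as.vector(resid)
  h <- 1e-5
  for (i in 1:3) {
    d2 <- rowSums(sweep(coords, 2, pos[i, ])^2)
    K <- exp(-d2 / (2 * sig^2))
    K[d2 > (4 * sig)^2] <- 0
    gw <- -2 * sum(rv * K)
    gp <- -2 * w[i] / sig^2 * colSums(rv * K * sweep(coords, 2, pos[i, ]))
    for (k in 1:3) {
      pp <- pos; pp[i, k] <- pos[i, k] + h
      pm <- pos; pm[i, k] <- pos[i, k] - h
      fd <- (Jfun(pp, w) - Jfun(pm, w)) / (2 * h)
      expect_equal(gp[k], fd, tolerance = 1e-4)
    }
    wp <- w; wp[i] <- w[i] + h
    wm <- w; wm[i] <- w[i] - h
    expect_equal(gw, (Jfun(pos, wp) - Jfun(pos, wm)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("refinement is stationary at an exact fit and recovers an offset grain", {
  vox <- 2
  truth <- pseudoatom_model(matrix(c(24, 24, 24), 1), 2, 1.5, vox)
  map <- render_map(truth, 24, vox)
  refined <- refine_step(map, truth, approx_config(1.5, 1))
  expect_lt(max(abs(refined$positions - truth$positions)), 1e-6)
  expect_lt(abs(refined$weights - truth$weights), 1e-6)

  off <- pseudoatom_model(matrix(c(26, 24, 24), 1), 2.3, 1.5, vox)
  rec <- refine_step(map, off, approx_config(1.5, 1, inner_gd_steps = 200,
                                             gd_tolerance = 1e-12))
  expect_lt(max(abs(rec$positions - c(24, 24, 24))), 0.05 * vox)
  expect_lt(abs(rec$weights - 2) / 2, 0.01)
})

test_that("accuracy control converges with e_N below the target", {
  map <- make_phantom(phantom_five_blob())
  res <- approximate_map(map, approx_config(1.5, 5))
  expect_true(res$converged)
  expect_lt(res$report$e_N, 5)
  expect_identical(length(res$error_trace), res$outer_iterations)

  loose <- approximate_map(map, approx_config(1.5, 99.9))
  expect_true(loose$converged)
  expect_identical(loose$outer_iterations, 1L)

  # grain centers stay inside the physical grid extent
  ext <- 2 * (map$dims - 1)
  expect_true(all(res$model$positions >= 0 & res$model$positions <=
                    rep(ext, each = n_pseudoatoms(res$model))))
})

test_that("recovered model matches the generating blobs (least-squares oracle)", {
  spec <- phantom_five_blob()
  map <- make_phantom(spec)
  res <- approximate_map(map, approx_config(1.5, 1))
  truth_c <- t(sapply(spec$blobs, function(b) b$center))
  truth_w <- sapply(spec$blobs, function(b) b$weight)

  # one dominant grain within 1 voxel of each true center
  for (i in 1:5) {
    d <- sqrt(colSums((t(res$model$positions) - truth_c[i, ])^2))
    near <- which(d < 3 * map$voxel_size)
    dominant <- near[which.max(res$model$weights[near])]
    expect_lt(d[dominant], map$voxel_size)
  }

  # least squares for weights with true centers fixed, against the render
  rendered <- render_map(res$model, map$dims, map$voxel_size)
  basis <- sapply(1:5, function(i)
    as.vector(render_map(pseudoatom_model(truth_c[i, , drop = FALSE], 1,
                                          1.5, 2), map$dims, 2)$data))
  w_ls <- qr.solve(basis, as.vector(rendered$data))
  expect_lt(max(abs(w_ls - truth_w) / truth_w), 0.10)
})
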