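fit_fixture <- function(eps = 8) {
  hp <- phantom_hinge_pair()
  map <- make_phantom(hp$a)
  res <- approximate_map(map, approx_config(1.5, eps))
  modes <- suppressWarnings(compute_modes(build_network(res$model)))
  list(hp = hp, map = map, model = res$model, modes = modes)
}

test_that("self-fit returns near-perfect correlation and tiny amplitudes", {
  fx <- fit_fixture()
  ref <- render_map(fx$model, fx$map$dims, fx$map$voxel_size)
  fit <- fit_pair(fx$model, fx$modes, ref, n_fit_modes = 5)
  expect_gte(fit$max_cc, 0.999)
  expect_lte(fit$distance, 1e-3)
  expect_identical(fit$distance, 1 - fit$max_cc)
  expect_lt(sqrt(sum(fit$amplitudes$amplitudes^2)),
            0.5 * sqrt(n_pseudoatoms(fx$model)))
  expect_gte(fit$n_evals, 1L)

  flat <- density_map(array(1, fx$map$dims), fx$map$voxel_size)
  expect_error(fit_pair(fx$model, fx$modes, flat,
                        mask = array(TRUE, fx$map$dims)),
               "constant|undefined")
})

test_that("a planted mode amplitude is recovered within 10%", {
  fx <- fit_fixture()
  astar <- 3 * sqrt(n_pseudoatoms(fx$model))
  k <- fx$modes$n_zero + 1L
  disp <- displace_model(fx$model, fx$modes, amplitude_vector(k, astar))
  ref <- render_map(disp, fx$map$dims, fx$map$voxel_size)
  fit <- fit_pair(fx$model, fx$modes, ref, n_fit_modes = 3)
  expect_gte(fit$max_cc, 0.99)
  expect_lt(abs(fit$amplitudes$amplitudes[1] - astar) / astar, 0.10)

  # the optimizer never returns worse than its zero-amplitude start
  cc0 <- map_correlation(render_map(fx$model, fx$map$dims,
                                    fx$map$voxel_size), ref,
                         mask = ref$data > 0.05 * max(ref$data))
  expect_gte(fit$max_cc, cc0)
})

test_that("distance matrices are symmetric, zero-diagonal, and small for duplicates", {
  hp <- phantom_hinge_pair()
  series <- make_conformation_series(hp$a, hp$b, 3)
  maps <- list(series[[1]], series[[1]], series[[3]])  # duplicate in the set
  ds <- suppressWarnings(distance_matrix(maps, approx_config(1.5, 10),
                                         n_fit_modes = 3))
  expect_equal(ds$matrix, t(ds$matrix), tolerance = 1e-12)
  expect_identical(diag(ds$matrix), c(map1 = 0, map2 = 0, map3 = 0))
  expect_true(all(ds$matrix >= 0))
  expect_lte(ds$matrix[1, 2], 0.005)                   # identical pair
  expect_gt(ds$matrix[1, 3], ds$matrix[1, 2])
})

test_that("hinge-series distances grow with conformational separation", {
  hp <- phantom_hinge_pair()
  series <- make_conformation_series(hp$a, hp$b, 3)
  ds <- suppressWarnings(distance_matrix(series, approx_config(1.5, 10),
                                         n_fit_modes = 5))
  expect_gt(ds$matrix[1, 3], ds$matrix[1, 2])
  expect_gt(ds$matrix[1, 3], ds$matrix[2, 3])
})

test_that("classical MDS embedding reproduces Euclidean-realizable distances", {
  space <- structure(list(labels = c("a", "b", "c"),
                          matrix = rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0)),
                          embedding = NULL, fits = NULL),
                     class = "distance_space")
  out <- embed_space(space, 1)
  emb <- unname(out$embedding[, 1])
  expect_equal(abs(emb[1] - emb[2]), 1, tolerance = 1e-8)
  expect_equal(abs(emb[2] - emb[3]), 1, tolerance = 1e-8)
  expect_equal(abs(emb[1] - emb[3]), 2, tolerance = 1e-8)

  zero <- space; zero$matrix <- matrix(0, 3, 3)
  expect_true(all(embed_space(zero, 2)$embedding == 0))
  expect_error(embed_space(space, 3), "below the number")

  # eigen-truncation contracts: embedded distances never exceed the input max
  set.seed(13)
  pts <- matrix(rnorm(15), 5, 3)
  sp2 <- structure(list(labels = letters[1:5],
                        matrix = as.matrix(dist(pts)), embedding = NULL,
                        fits = NULL), class = "distance_space")
  e2 <- embed_space(sp2, 2)$embedding
  expect_lte(max(dist(e2)), max(sp2$matrix) + 1e-8)
})

test_that("elastic projection matching recovers orientation, shift and amplitude", {
  fx <- fit_fixture()
  grid <- rbind(c(0, 0, 0), c(30, 0, 0), c(0, 45, 0), c(60, 30, 15))
  ctr <- colMeans(fx$model$positions)

  img <- render_projection(fx$model, grid[3, ], 40, 2, center = ctr)
  hit <- fit_image(fx$model, fx$modes, img, grid, n_fit_modes = 3)
  expect_equal(hit$orientation, grid[3, ])
  expect_gte(hit$fit$max_cc, 0.999)
  expect_identical(hit$shift, c(0L, 0L))

  # integer-pixel circular shift of the matched image
  sh <- img
  sh$data <- img$data[c(4:40, 1:3), c(38:40, 1:37)]
  hit2 <- fit_image(fx$model, fx$modes, sh, grid, n_fit_modes = 3)
  expect_equal(hit2$orientation, grid[3, ])
  expect_equal(hit2$shift, c(-3L, 3L))

  astar <- 2 * sqrt(n_pseudoatoms(fx$model))
  k <- fx$modes$n_zero + 1L
  disp <- displace_model(fx$model, fx$modes, amplitude_vector(k, astar))
  img3 <- render_projection(disp, grid[2, ], 40, 2, center = ctr)
  hit3 <- fit_image(fx$model, fx$modes, img3, grid, n_fit_modes = 3)
  expect_equal(hit3$orientation, grid[2, ])
  expect_lt(abs(hit3$fit$amplitudes$amplitudes[1] - astar) / astar, 0.15)

  expect_error(fit_image(fx$model, fx$modes, img,
                         matrix(numeric(0), 0, 3)), "empty")
})
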