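random_nodes <- function(n, seed = 42, box = 30) {
  set.seed(seed)
  matrix(runif(3 * n, 0, box), n, 3)
}

test_that("edges are all pairs within the closed-ball cutoff", {
  two <- rbind(c(0, 0, 0), c(5, 0, 0))
  expect_identical(nrow(build_network(two, cutoff = 6)$edges), 1L)
  expect_identical(nrow(build_network(two, cutoff = 5)$edges), 1L)  # boundary
  expect_identical(nrow(suppressWarnings(build_network(two, cutoff = 4.999))$edges), 0L)
  expect_error(build_network(matrix(c(0, 0, 0), 1)), "2 nodes")

  nodes <- random_nodes(20)
  net <- suppressWarnings(build_network(nodes, cutoff = 12))
  expected <- NULL                       # brute-force O(N^2) enumeration
  for (i in 1:19) for (j in (i + 1):20)
    if (sqrt(sum((nodes[i, ] - nodes[j, ])^2)) <= 12)
      expected <- rbind(expected, c(i, j))
  expect_equal(net$edges, expected)
})

test_that("the Hessian is symmetric, PSD, and annihilates rigid motions", {
  net <- build_network(random_nodes(12, seed = 3), cutoff = 15)
  h <- assemble_hessian(net)
  expect_equal(h, t(h))
  n <- nrow(net$nodes)
  for (ax in 1:3) {
    t_vec <- rep(diag(3)[ax, ], n)
    expect_lt(max(abs(h %*% t_vec)), 1e-10)
  }
  ev <- eigen(h, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
})

test_that("the dimer spectrum is five zeros and one stretching eigenvalue 2k", {
  for (k in c(1, 2.5)) {
    net <- build_network(rbind(c(0, 0, 0), c(5, 0, 0)), cutoff = 6,
                         force_constant = k)
    ms <- compute_modes(net)
    expect_identical(ms$n_zero, 5L)
    expect_equal(sort(ms$eigenvalues), c(0, 0, 0, 0, 0, 2 * k))
    expect_equal(ms$frequencies, sqrt(ms$eigenvalues))
  }
})

test_that("the Hessian matches finite differences of the spring energy", {
  nodes <- random_nodes(4, seed = 9, box = 10)
  net <- build_network(nodes, cutoff = 20, force_constant = 1.5)
  h <- assemble_hessian(net)
  d0 <- as.matrix(dist(nodes))
  energy <- function(x) {
    p <- matrix(x, ncol = 3, byrow = TRUE)
    e <- 0
    for (r in seq_len(nrow(net$edges))) {
      i <- net$edges[r, 1]; j <- net$edges[r, 2]
      e <- e + 0.5 * 1.5 * (sqrt(sum((p[i, ] - p[j, ])^2)) - d0[i, j])^2
    }
    e
  }
  x0 <- as.vector(t(nodes))
  eps <- 1e-4
  for (a in seq_along(x0)) for (b in seq_len(a)) {
    xpp <- x0; xpp[a] <- xpp[a] + eps; xpp[b] <- xpp[b] + eps
    xpm <- x0; xpm[a] <- xpm[a] + eps; xpm[b] <- xpm[b] - eps
    xmp <- x0; xmp[a] <- xmp[a] - eps; xmp[b] <- xmp[b] + eps
    xmm <- x0; xmm[a] <- xmm[a] - eps; xmm[b] <- xmm[b] - eps
    fd <- (energy(xpp) - energy(xpm) - energy(xmp) + energy(xmm)) /
      (4 * eps^2)
    expect_equal(h[a, b], fd, tolerance = 1e-5)
  }
})

test_that("a connected network has six orthonormal zero modes spanning rigid motions", {
  nodes <- random_nodes(20)
  ms <- compute_modes(build_network(nodes))
  expect_identical(ms$n_zero, 6L)
  expect_lt(max(abs(crossprod(ms$modes) - diag(ncol(ms$modes)))), 1e-8)
  expect_equal(ms$frequencies, sqrt(ms$eigenvalues))

  # infinitesimal rotations about the centroid lie in the zero-mode span
  ctr <- colMeans(nodes)
  z <- ms$modes[, seq_len(6)]
  for (ax in 1:3) {
    gen <- matrix(0, 3, 3)
    gen[(ax %% 3) + 1, ((ax + 1) %% 3) + 1] <- 1
    gen[((ax + 1) %% 3) + 1, (ax %% 3) + 1] <- -1
    v <- as.vector(t(sweep(nodes, 2, ctr) %*% t(gen)))
    v <- v / sqrt(sum(v^2))
    resid <- v - z %*% crossprod(z, v)
    expect_lt(max(abs(resid)), 1e-6)
  }
})

test_that("two far-apart clusters give twelve zero modes", {
  a <- random_nodes(8, seed = 1, box = 10)
  b <- sweep(random_nodes(8, seed = 2, box = 10), 2, c(200, 0, 0), "+")
  expect_warning(net <- build_network(rbind(a, b), cutoff = 15),
                 "disconnected")
  expect_identical(compute_modes(net)$n_zero, 12L)
})

test_that("the spectrum is invariant under rigid rotation of the nodes", {
  nodes <- random_nodes(15, seed = 8)
  ang <- 0.7
  rot <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
                3, 3)
  e1 <- compute_modes(suppressWarnings(build_network(nodes, cutoff = 14)))$eigenvalues
  e2 <- compute_modes(suppressWarnings(build_network(nodes %*% t(rot),
                                                   cutoff = 14)))$eigenvalues
  expect_equal(e1, e2, tolerance = 1e-8)
})

test_that("mode files round-trip through the plain-text export", {
  ms <- compute_modes(build_network(random_nodes(6, seed = 5), cutoff = 20),
                      n_modes = 10)
  dir <- withr::local_tempdir()
  write_modes(ms, dir)
  expect_length(list.files(dir, pattern = "^mode_"), 10L)
  m7 <- as.matrix(read.table(file.path(dir, "mode_007.txt")))
  expect_equal(unname(m7), matrix(ms$modes[, 7], ncol = 3, byrow = TRUE),
               tolerance = 1e-10)
  freqs <- read.table(file.path(dir, "frequencies.txt"), header = TRUE)
  expect_equal(freqs$frequency, ms$frequencies, tolerance = 1e-10)
})
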