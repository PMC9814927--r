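# Descriptor featurization, REMatch kernel, clustering utilities.

desc_structure <- function(shift = c(0, 0, 0), quat = c(1, 0, 0, 0)) {
  m <- rigid_molecule(c("C", "O"), rbind(c(-0.6, 0, 0), c(0.6, 0, 0)),
                      name = "CO")
  crystal_structure(lattice(6, 7, 8, 90, 100, 90), list(CO = m),
                    list(placement("CO", c(0.1, 0.2, 0.3) + shift, quat)))
}

test_that("descriptors are deterministic and periodic-invariant", {
  cfgs <- list(descriptor_config("acsf", elements = c("C", "O")),
               descriptor_config("soap", elements = c("C", "O")))
  for (cfg in cfgs) {
    f <- featurize(list(desc_structure(), desc_structure(),
                        desc_structure(shift = c(2, -1, 3))), cfg)
    expect_equal(f[1, ], f[2, ], tolerance = 1e-12)
    expect_lt(max(abs(f[1, ] - f[3, ])), 1e-8) # lattice-vector translation
  }
})

test_that("descriptors are invariant under whole-cell rotation and atom order", {
  # atom permutation within element classes: swap the two placements of a
  # two-molecule cell
  m <- rigid_molecule(c("C", "O"), rbind(c(-0.6, 0, 0), c(0.6, 0, 0)),
                      name = "CO")
  mk <- function(order) {
    pls <- list(placement("CO", c(0.1, 0.2, 0.3)),
                placement("CO", c(0.6, 0.7, 0.8)))
    crystal_structure(lattice(6, 7, 8), list(CO = m), pls[order])
  }
  cfg <- descriptor_config("acsf", elements = c("C", "O"))
  f <- featurize(list(mk(1:2), mk(2:1)), cfg)
  expect_lt(max(abs(f[1, ] - f[2, ])), 1e-10)
  # rigid rotation of the whole cell: re-describe via transform with a
  # rotated canonical frame (90-degree axis permutation of a cubic cell)
  s <- crystal_structure(lattice(7, 7, 7), list(CO = m),
                         list(placement("CO", c(0.1, 0.2, 0.3))))
  sr <- transform_cell(s, matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3))
  f2 <- featurize(list(s, sr), cfg)
  expect_lt(max(abs(f2[1, ] - f2[2, ])), 1e-8)
})

test_that("an isolated atom beyond every cutoff has zero-valued channels", {
  g <- rigid_molecule("C", matrix(0, 1, 3), name = "C1")
  s <- crystal_structure(lattice(30, 30, 30), list(C1 = g),
                         list(placement("C1", c(0.5, 0.5, 0.5))))
  cfg <- descriptor_config("acsf", elements = "C")
  f <- featurize(list(s), cfg)
  expect_true(all(abs(f) < 1e-12))
})

test_that("elements missing from the descriptor config raise an error", {
  cfg <- descriptor_config("acsf", elements = "C")
  expect_error(featurize(list(desc_structure()), cfg), "absent")
})

test_that("REMatch has the documented limits and unit self-similarity", {
  set.seed(4)
  mkenv <- function(n, d) {
    m <- matrix(rnorm(n * d), n, d)
    m / sqrt(rowSums(m^2))
  }
  e1 <- mkenv(4, 6); e2 <- mkenv(4, 6)
  K <- e1 %*% t(e2)
  # gamma -> Inf: mean of the environment-kernel matrix
  expect_lt(abs(rematch_similarity(e1, e2, gamma = 1000, normalize = FALSE) -
                  mean(K)), 1e-3)
  # gamma -> 0: best-match (assignment) kernel, enumerated exactly on 4x4
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  assign_best <- max(vapply(perms(1:4), function(p) mean(K[cbind(1:4, p)]), 0))
  got <- rematch_similarity(e1, e2, gamma = 0.02, normalize = FALSE,
                            max_iter = 50000, tol = 1e-8)
  expect_lt(abs(got - assign_best), 0.005)
  expect_lte(got, assign_best + 1e-9) # regularized value approaches from below
  # self-similarity is exactly 1 after normalization
  expect_equal(rematch_similarity(e1, e1, gamma = 0.1), 1, tolerance = 1e-8)
  # non-convergence is reported with the iteration count
  expect_error(rematch_similarity(e1, e2, gamma = 1e-4, max_iter = 5),
               "did not converge")
})

test_that("the REMatch kernel over structures is symmetric PSD with unit diagonal", {
  fx <- fx_pocket()
  set.seed(6)
  structs <- lapply(1:5, function(i) {
    s <- fx$minima[[1 + i %% 2]]$structure
    s$placements[[2]]$frac <- s$placements[[2]]$frac + runif(3, -0.02, 0.02)
    s
  })
  cfg <- descriptor_config("soap", elements = c("C", "N", "H", "O"),
                           gamma = 0.1)
  K <- rematch_kernel(structs, cfg)
  expect_equal(K, t(K), tolerance = 1e-9)
  expect_equal(diag(K), rep(1, 5), tolerance = 1e-9)
  expect_gte(min(eigen(K, symmetric = TRUE)$values), -1e-8)
})

test_that("PCA + HDBSCAN* separate constructed blobs (ARI = 1)", {
  set.seed(8)
  X <- rbind(matrix(rnorm(60, 0, 0.3), ncol = 3),
             matrix(rnorm(60, 6, 0.3), ncol = 3))
  lab <- rep(c("I", "II"), each = 20)
  res <- project_and_cluster(X, lab, min_cluster_sizes = c(4, 6))
  expect_true(all(res$ari == 1))
  expect_equal(dim(res$projection), c(40, 2))
  expect_gt(res$eigenvalues[1], res$eigenvalues[3])
  # ARI is invariant under label permutation
  cl <- res$clusterings[["4"]]$labels
  expect_equal(adjusted_rand_index(cl, lab),
               adjusted_rand_index(cl, c("II", "I")[match(lab, c("I", "II"))]))
  # degenerate input is flagged
  expect_warning(project_and_cluster(matrix(1, 10, 3), rep("I", 10),
                                     min_cluster_sizes = 3), "degenerate")
})

test_that("distance distributions separate blobs but not duplicated labels", {
  set.seed(9)
  X <- rbind(matrix(rnorm(40, 0, 0.3), ncol = 2),
             matrix(rnorm(40, 5, 0.3), ncol = 2))
  D <- as.matrix(dist(X))
  expect_equal(D, t(D), tolerance = 1e-12)
  lab <- rep(c("I", "II"), each = 20)
  r <- basin_distance_distributions(D, lab)
  expect_gt(r$overlap, 0.99) # between-distances dominate within-distances
  # a single cloud split arbitrarily into two labels: indistinguishable
  lab2 <- rep(c("I", "II"), 20)[1:40]
  X2 <- matrix(rnorm(80, 0, 1), ncol = 2)
  r2 <- basin_distance_distributions(as.matrix(dist(X2)), lab2)
  expect_lt(abs(r2$overlap - 0.5), 0.1)
  expect_error(basin_distance_distributions(D, rep("I", 40)), "2 structures|basin")
})

test_that("own ARI implementation agrees with mclust on random partitions", {
  skip_if_not_installed("mclust")
  set.seed(10)
  for (rep in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})
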