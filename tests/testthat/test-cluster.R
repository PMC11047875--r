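test_that("region query returns the closed eps-ball including the point", {
  pts <- rbind(c(0, 0), c(0, 1), c(3, 3))
  expect_equal(region_query(pts, 1, 1), c(1L, 2L))
  expect_equal(region_query(pts, 1, 0.5), 1L)
  expect_equal(region_query(pts, 1, 100), 1:3)
  expect_error(region_query(pts, 5, 1), "out of range")
  expect_error(region_query(pts, 1, 0), "positive")
})

test_that("dbscan reproduces the hand-worked 1-D example and limits", {
  pts <- matrix(c(0, 0.5, 1.0, 10), ncol = 1)
  r <- dbscan(pts, eps = 0.6, min_pts = 3)
  expect_equal(r$labels, c(0L, 0L, 0L, -1L))
  expect_equal(r$n_clusters, 1L)

  ## huge eps, min_pts 1: one cluster of everything
  r2 <- dbscan(pts, eps = 100, min_pts = 1)
  expect_equal(r2$labels, rep(0L, 4))

  ## identical points collapse into one cluster without noise
  r3 <- dbscan(matrix(1, 5, 2), eps = 0.1, min_pts = 3)
  expect_equal(r3$labels, rep(0L, 5))
  expect_error(dbscan(matrix(numeric(0), 0, 2), 1, 1), "empty")
})

test_that("dbscan agrees with the density-reachability oracle on random data", {
  skip_if_not_installed("igraph")
  withr::with_seed(42, {
    for (rep in 1:60) {
      n <- sample(10:60, 1)
      pts <- matrix(runif(n * 2, 0, 10), n, 2)
      eps <- runif(1, 0.3, 3)
      mp <- sample(2:6, 1)
      mine <- dbscan(pts, eps, mp)$labels
      oracle <- dbscan_oracle(pts, eps, mp)
      expect_true(same_partition(mine, oracle),
                  info = sprintf("rep %d n=%d eps=%.3f mp=%d", rep, n, eps, mp))
    }
  })
})

test_that("dbscan partition is invariant to input order", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      n <- 40
      pts <- matrix(rnorm(n * 2, sd = 2), n, 2)
      perm <- sample(n)
      a <- dbscan(pts, eps = 1, min_pts = 4)$labels
      b <- dbscan(pts[perm, ], eps = 1, min_pts = 4)$labels
      expect_true(same_partition(a[perm], b))
    }
  })
})

test_that("clustering fitness matches hand values and penalizes degeneracy", {
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(clustering_fitness(pts, c(0L, 0L, 1L, 1L)), 0.89975,
               tolerance = 1e-4)
  expect_equal(clustering_fitness(pts, rep(-1L, 4)), -1)
  expect_equal(clustering_fitness(pts, rep(0L, 4)), -1)
  ## with no noise it equals the silhouette coefficient
  expect_equal(clustering_fitness(pts, c(0L, 0L, 1L, 1L)),
               silhouette_coefficient(pts, c(0L, 0L, 1L, 1L)),
               tolerance = 1e-12)
  ## noise discounts the fitness by the clustered fraction
  labs <- c(0L, 0L, 1L, 1L, -1L)
  pts5 <- matrix(c(0, 1, 10, 11, 100), ncol = 1)
  expect_equal(clustering_fitness(pts5, labs),
               silhouette_coefficient(pts5[1:4, , drop = FALSE],
                                      labs[1:4]) * 4 / 5,
               tolerance = 1e-12)
})

test_that("sparrow search minimizes the sphere function reliably", {
  ok <- 0
  for (s in 1:10) {
    res <- ssa_optimize(function(x) sum(x^2), c(-5, -5), c(5, 5),
                        ssa_params(itermax = 100, pop = 20, seed = s))
    if (res$value <= 1e-3) ok <- ok + 1
    expect_true(all(diff(res$trace) <= 0))
    expect_true(all(res$best >= -5 & res$best <= 5))
  }
  expect_gte(ok, 9)
})

test_that("sparrow search is seeded and degrades gracefully", {
  f <- function(x) (x[1] - 1)^2 + (x[2] + 2)^2
  a <- ssa_optimize(f, c(-5, -5), c(5, 5), ssa_params(itermax = 30, seed = 2))
  b <- ssa_optimize(f, c(-5, -5), c(5, 5), ssa_params(itermax = 30, seed = 2))
  expect_identical(a$best, b$best)
  ## single-sparrow population still works
  one <- ssa_optimize(f, c(-5, -5), c(5, 5),
                      ssa_params(itermax = 20, pop = 1, explorer_count = 1,
                                 seed = 0))
  expect_length(one$best, 2)
  expect_true(is.finite(one$value))
  ## non-finite objective values are treated as worst
  nf <- ssa_optimize(function(x) if (x[1] > 0) NaN else sum(x^2),
                     c(-5, -5), c(5, 5), ssa_params(itermax = 30, seed = 1))
  expect_true(is.finite(nf$value))
  expect_lte(nf$best[1], 0)
})

test_that("ssa_dbscan recovers blob structure and beats random draws", {
  ctr <- rbind(c(0, 0), c(5, 5), c(10, 0))
  bl <- blob_points(ctr, n_each = 50, sd = 0.3, seed = 0)
  cl <- ssa_dbscan(bl$points, params = ssa_params(itermax = 50, pop = 20,
                                                  seed = 1))
  expect_equal(cl$n_clusters, 3L)
  expect_gte(cl$fitness, 0.8)
  expect_true(all(diff(cl$trace) >= 0))       # best fitness non-decreasing
  ## labels match the generating blobs
  expect_true(same_partition(cl$labels, bl$labels))

  ## two blobs give two clusters
  bl2 <- blob_points(rbind(c(0, 0), c(6, 6)), n_each = 40, sd = 0.3,
                     seed = 1)
  cl2 <- ssa_dbscan(bl2$points, params = ssa_params(itermax = 40, pop = 15,
                                                    seed = 2))
  expect_equal(cl2$n_clusters, 2L)
  expect_error(ssa_dbscan(matrix(rnorm(8), 4, 2)), "at least 5")

  ## optimized fitness at least matches random parameter draws
  D <- as.matrix(dist(bl$points))
  bounds <- eegcluster:::default_bounds(D, nrow(bl$points))
  wins <- 0
  withr::with_seed(5, {
    for (trial in 1:5) {
      draws <- replicate(20, {
        eps <- runif(1, bounds$eps_range[1], bounds$eps_range[2])
        mp <- round(runif(1, bounds$minpts_range[1], bounds$minpts_range[2]))
        dbscan(bl$points, eps, mp)$fitness
      })
      if (cl$fitness >= max(draws)) wins <- wins + 1
    }
  })
  expect_gte(wins, 5 * 0.95 - 1)  # >= 95% of trials up to integer rounding
})
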