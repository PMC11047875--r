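test_that("indices reproduce the hand-worked two-cluster example", {
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  labs <- c("A", "A", "B", "B")
  expect_equal(silhouette_coefficient(pts, labs), 0.89975, tolerance = 1e-4)
  expect_equal(calinski_harabasz(pts, labs), 200, tolerance = 1e-6)
  expect_equal(davies_bouldin(pts, labs), 0.1, tolerance = 1e-9)
})

test_that("index limits and invariances hold", {
  ## coincident clusters: silhouette <= 0, CH ~ 0
  pts <- matrix(rep(c(0, 1, 2, 3), 2), ncol = 1)
  labs <- rep(c(0, 1), each = 4)
  expect_lte(silhouette_coefficient(pts, labs), 0)
  expect_equal(calinski_harabasz(pts, labs), 0)
  expect_identical(davies_bouldin(pts, labs), Inf)

  ## extreme separation drives silhouette to 1
  far <- blob_points(rbind(c(0, 0), c(500, 500)), n_each = 20, sd = 1,
                     seed = 0)
  expect_gte(silhouette_coefficient(far$points, far$labels), 0.99)

  ## DBI is scale invariant
  bl <- blob_points(rbind(c(0, 0), c(4, 4), c(8, 0)), n_each = 15, sd = 0.5,
                    seed = 1)
  expect_equal(davies_bouldin(bl$points, bl$labels),
               davies_bouldin(bl$points * 13, bl$labels), tolerance = 1e-9)

  ## tighter clusters lower DBI; true labels beat permuted ones on CH
  tight <- blob_points(rbind(c(0, 0), c(4, 4), c(8, 0)), n_each = 15,
                       sd = 0.25, seed = 1)
  expect_lt(davies_bouldin(tight$points, tight$labels),
            davies_bouldin(bl$points, bl$labels))
  perm <- withr::with_seed(0, sample(bl$labels))
  expect_gt(calinski_harabasz(bl$points, bl$labels),
            calinski_harabasz(bl$points, perm))
  expect_error(silhouette_coefficient(bl$points, rep(0, 45)), "2 clusters")
})

test_that("indices agree with independent implementations on random data", {
  skip_if_not_installed("cluster")
  withr::with_seed(1, {
    for (rep in 1:50) {
      n <- sample(10:40, 1)
      k <- sample(2:4, 1)
      pts <- matrix(rnorm(n * 2), n, 2)
      labs <- sample(0:(k - 1), n, replace = TRUE)
      if (length(unique(labs)) < 2) next
      ## reference silhouette
      ref <- mean(cluster::silhouette(labs + 1, dist(pts))[, "sil_width"])
      expect_equal(silhouette_coefficient(pts, labs), ref, tolerance = 1e-9)
      ## brute-force CH and DBI
      grand <- colMeans(pts)
      uq <- sort(unique(labs))
      trB <- 0; trW <- 0
      for (u in uq) {
        g <- pts[labs == u, , drop = FALSE]
        trB <- trB + nrow(g) * sum((colMeans(g) - grand)^2)
        trW <- trW + sum(sweep(g, 2, colMeans(g))^2)
      }
      ch_ref <- (trB / (length(uq) - 1)) / (trW / (n - length(uq)))
      expect_equal(calinski_harabasz(pts, labs), ch_ref, tolerance = 1e-9)
      cen <- t(sapply(uq, function(u) colMeans(pts[labs == u, , drop = FALSE])))
      Sm <- sapply(uq, function(u) {
        g <- pts[labs == u, , drop = FALSE]
        mean(sqrt(rowSums(sweep(g, 2, colMeans(g))^2)))
      })
      dbi_ref <- mean(sapply(seq_along(uq), function(i)
        max(sapply(setdiff(seq_along(uq), i), function(j)
          (Sm[i] + Sm[j]) / sqrt(sum((cen[i, ] - cen[j, ])^2))))))
      expect_equal(davies_bouldin(pts, labs), dbi_ref, tolerance = 1e-9)
    }
  })
})

test_that("CV composite weights are a distribution and respect symmetry", {
  tab <- metric_table(matrix(c(1, 2, 3, 4, 2, 1, 5, 3), 4, 2),
                      sprintf("alg%d", 1:4), c("i1", "i2"),
                      c("positive", "negative"))
  for (norm in c("vector", "minmax", "max", "sum")) {
    cv <- cv_composite(tab, normalization = norm)
    expect_equal(sum(cv$weights), 1, tolerance = 1e-12)
  }
  ## identical rows score identically (zero dispersion -> uniform weights)
  same <- metric_table(matrix(c(2, 2, 2, 5, 5, 5), 3, 2),
                       sprintf("a%d", 1:3), c("x", "y"),
                       c("positive", "positive"))
  sc0 <- cv_composite(same)$scores
  expect_equal(unname(sc0), rep(sc0[[1]], 3), tolerance = 1e-12)
  mixed <- metric_table(rbind(c(1, 4), c(1, 4), c(2, 8)),
                        c("a", "b", "c"), c("x", "y"),
                        c("positive", "positive"))
  sc <- cv_composite(mixed)$scores
  expect_equal(sc[["a"]], sc[["b"]], tolerance = 1e-12)
})

test_that("CV ranking is invariant to rescaling an indicator column", {
  vals <- rbind(c(0.58, 2242, 0.82), c(0.65, 3032, 0.76), c(0.63, 3863, 0.71),
                c(0.61, 3432, 0.72), c(0.63, 4227, 0.62), c(0.68, 4615, 0.53))
  tab1 <- metric_table(vals, sprintf("m%d", 1:6), c("SC", "CH", "DBI"),
                       c("positive", "positive", "negative"))
  vals2 <- vals; vals2[, 2] <- vals2[, 2] * 1000
  tab2 <- metric_table(vals2, sprintf("m%d", 1:6), c("SC", "CH", "DBI"),
                       c("positive", "positive", "negative"))
  expect_identical(cv_composite(tab1)$ranking, cv_composite(tab2)$ranking)
  ## scaling the negative column too
  vals3 <- vals; vals3[, 3] <- vals3[, 3] * 7
  tab3 <- metric_table(vals3, sprintf("m%d", 1:6), c("SC", "CH", "DBI"),
                       c("positive", "positive", "negative"))
  expect_equal(cv_composite(tab1)$scores, cv_composite(tab3)$scores,
               tolerance = 1e-9)
})

test_that("the bundled benchmark table ranks the adaptive method first", {
  path <- system.file("extdata", "clustering_benchmark_indices.csv",
                      package = "eegcluster")
  tab <- read_metric_table_csv(path)
  expect_equal(dim(tab$values), c(6L, 3L))
  cv <- cv_composite(tab)
  expect_equal(cv$ranking[1], "SSA-DBSCAN")
  expect_equal(cv$ranking[2], "DBSCAN")
  expect_equal(unname(cv$scores["SSA-DBSCAN"]), 0.67969, tolerance = 5e-4)
  expect_equal(unname(cv$scores["DBSCAN"]), 0.50883, tolerance = 5e-4)
})

test_that("metric tables survive a CSV round trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- metric_table(matrix(c(1, 2, 3, 6, 5, 4), 3, 2), c("a", "b", "c"),
                      c("up", "down"), c("positive", "negative"))
  write_metric_table_csv(tab, path)
  back <- read_metric_table_csv(path)
  expect_equal(back$values, tab$values, ignore_attr = TRUE)
  expect_equal(back$polarity, tab$polarity)
  expect_equal(back$object_names, tab$object_names)
})
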