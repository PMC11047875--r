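## DBSCAN with adaptive parameter selection by the sparrow search algorithm
## (SSA), using the silhouette coefficient of the labeling as fitness.

#' Eps-neighborhood query
#'
#' Indices of all points (the query point included) within Euclidean
#' distance `eps` of point `index`.
#'
#' @param points numeric `n x d` matrix.
#' @param index query point index (1-based).
#' @param eps positive radius.
#' @return integer index vector.
#' @export
region_query <- function(points, index, eps) {
  points <- as.matrix(points)
  if (eps <= 0) stop("eps must be positive", call. = FALSE)
  if (index < 1 || index > nrow(points))
    stop("index out of range", call. = FALSE)
  d <- sqrt(colSums((t(points) - points[index, ])^2))
  which(d <= eps)
}

## Core DBSCAN on a precomputed distance matrix. Clusters are connected
## components of the core-point graph at radius eps; border points join the
## cluster of their nearest core point, which makes the partition
## independent of input order. Noise is -1; clusters are numbered from 0 in
## order of their smallest member distance ranking (first occurrence).
dbscan_from_dist <- function(D, eps, min_pts) {
  n <- nrow(D)
  adj <- D <= eps
  n_nb <- rowSums(adj)                 # self-inclusive neighborhood size
  core <- n_nb >= min_pts
  labels <- rep(-1L, n)
  cl <- 0L
  if (any(core)) {
    core_idx <- which(core)
    comp <- rep(NA_integer_, n)
    for (s in core_idx) {
      if (!is.na(comp[s])) next
      ## BFS over core points only
      queue <- s
      comp[s] <- cl
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        nb <- which(adj[p, ] & core & is.na(comp))
        comp[nb] <- cl
        queue <- c(queue, nb)
      }
      cl <- cl + 1L
    }
    labels[core_idx] <- comp[core_idx]
    ## border points: nearest core within eps
    border <- which(!core)
    for (b in border) {
      cores_near <- core_idx[adj[b, core_idx]]
      if (length(cores_near) > 0)
        labels[b] <- comp[cores_near[which.min(D[b, cores_near])]]
    }
  }
  ## renumber clusters consecutively from 0 by first occurrence
  seen <- unique(labels[labels >= 0])
  if (length(seen) > 0)
    labels[labels >= 0] <- match(labels[labels >= 0], seen) - 1L
  labels
}

#' DBSCAN clustering
#'
#' Density-based clustering: points with at least `min_pts` neighbors within
#' `eps` (self included) are core points; clusters are the
#' density-reachability closures of core points; non-core points within
#' `eps` of a core join the nearest core's cluster, everything else is noise
#' (-1). Border assignment to the *nearest* core makes the partition
#' independent of input order.
#'
#' @param points numeric `n x d` matrix.
#' @param eps positive neighborhood radius.
#' @param min_pts minimum self-inclusive neighborhood size of a core point.
#' @return a `cluster_result`: `labels` (0-based, noise -1), `eps`,
#'   `min_pts`, `fitness` (silhouette of the labeling, see
#'   [clustering_fitness()]) and `n_clusters`.
#' @export
dbscan <- function(points, eps, min_pts) {
  points <- as.matrix(points)
  if (nrow(points) < 1) stop("empty input", call. = FALSE)
  if (eps <= 0) stop("eps must be positive", call. = FALSE)
  if (min_pts < 1) stop("min_pts must be >= 1", call. = FALSE)
  D <- as.matrix(stats::dist(points))
  labels <- dbscan_from_dist(D, eps, as.integer(round(min_pts)))
  new_cluster_result(labels, eps, as.integer(round(min_pts)),
                     fitness_from_dist(D, labels))
}

new_cluster_result <- function(labels, eps, min_pts, fitness,
                               trace = NULL, no_valid = FALSE) {
  structure(list(labels = labels, eps = eps, min_pts = min_pts,
                 fitness = fitness,
                 n_clusters = length(unique(labels[labels >= 0])),
                 trace = trace, no_valid_clustering = no_valid),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d clusters (+%d noise) | eps=%.4g minPts=%d | silhouette=%.4f\n",
              x$n_clusters, sum(x$labels == -1), x$eps, x$min_pts, x$fitness))
  if (isTRUE(x$no_valid_clustering))
    cat("  note: no valid clustering found anywhere in the search space\n")
  invisible(x)
}

## Silhouette over non-noise points from a distance matrix; the penalty
## value -1 covers degenerate labelings (fewer than 2 clusters or fewer
## than 3 clustered points). Singleton-cluster points contribute 0.
silhouette_from_dist <- function(D, labels) {
  keep <- labels >= 0
  if (sum(keep) < 3) return(-1)
  labs <- labels[keep]
  uniq <- unique(labs)
  if (length(uniq) < 2) return(-1)
  Dk <- D[keep, keep, drop = FALSE]
  m <- length(labs)
  sizes <- table(factor(labs, levels = uniq))
  ## mean distance of every point to every cluster
  member <- outer(labs, uniq, "==")
  sums <- Dk %*% member                        # m x k total distance per cluster
  s <- numeric(m)
  for (i in seq_len(m)) {
    ci <- match(labs[i], uniq)
    ni <- sizes[ci]
    if (ni == 1) { s[i] <- 0; next }
    a <- sums[i, ci] / (ni - 1)
    b <- min(sums[i, -ci] / sizes[-ci])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

## Optimization fitness: silhouette over the clustered points, weighted by
## the fraction of points that were clustered at all. Without the coverage
## weight the landscape is degenerate — a handful of near-coincident points
## kept as tiny clusters while everything else is declared noise scores an
## almost perfect silhouette, and the optimizer reliably finds such optima.
fitness_from_dist <- function(D, labels) {
  s <- silhouette_from_dist(D, labels)
  if (s <= -1) return(-1)
  s * sum(labels >= 0) / length(labels)
}

#' Silhouette fitness of a DBSCAN labeling
#'
#' Mean silhouette over the non-noise points, weighted by the fraction of
#' points assigned to clusters, so labelings that discard most points as
#' noise cannot dominate honest ones. For a labeling without noise this is
#' exactly the silhouette coefficient. Degenerate labelings (fewer than 2
#' clusters, or fewer than 3 clustered points) receive the penalty value -1
#' so the optimizer ranks them below any valid clustering.
#'
#' @param points numeric `n x d` matrix.
#' @param labels integer labels with noise marked -1.
#' @return scalar in `[-1, 1]`.
#' @export
clustering_fitness <- function(points, labels) {
  D <- as.matrix(stats::dist(as.matrix(points)))
  fitness_from_dist(D, labels)
}

#' Sparrow search algorithm parameters
#'
#' @param itermax maximum iterations.
#' @param pop population size.
#' @param ST safety (warning) threshold in `(0.5, 1]`.
#' @param explorer_count number of explorers (best-ranked sparrows); default
#'   20% of the population.
#' @param alarm_fraction fraction of the population updated by the
#'   anti-predation rule each iteration.
#' @param seed integer seed.
#' @return an `ssa_params` list.
#' @export
ssa_params <- function(itermax = 50L, pop = 30L, ST = 0.8,
                       explorer_count = NULL, alarm_fraction = 0.2,
                       seed = 0L) {
  if (is.null(explorer_count)) explorer_count <- ceiling(0.2 * pop)
  if (explorer_count >= pop && pop > 1)
    stop("explorer_count must be smaller than pop", call. = FALSE)
  if (ST <= 0.5 || ST > 1) stop("ST must lie in (0.5, 1]", call. = FALSE)
  if (itermax < 1) stop("itermax must be >= 1", call. = FALSE)
  structure(list(itermax = as.integer(itermax), pop = as.integer(pop),
                 ST = ST, explorer_count = as.integer(explorer_count),
                 alarm_fraction = alarm_fraction, seed = as.integer(seed)),
            class = "ssa_params")
}

#' Sparrow search optimization
#'
#' Population metaheuristic with three update rules per iteration on the
#' fitness-ranked population: explorers (best-ranked) either contract
#' multiplicatively (`x * exp(-i / (alpha * itermax))`, `alpha` uniform) when
#' the warning value `R2` is below the safety threshold or take a Gaussian
#' step otherwise; followers either jump with a worst-relative exponential
#' move (lower half) or move to the best position plus an averaged
#' random-sign share of their distance to it; finally a random alarm subset
#' is pulled toward the best position (or repelled from the worst when it
#' *is* the best). Positions are clamped to bounds after every update; the
#' objective is evaluated once per iteration per sparrow and non-finite
#' values are treated as `+Inf`.
#'
#' @param objective function mapping a position vector to a scalar to
#'   MINIMIZE.
#' @param lower,upper numeric bound vectors (equal length = dimensionality).
#' @param params an [ssa_params()].
#' @return list with `best` (position), `value`, and `trace` (best-so-far
#'   objective value per iteration, non-increasing).
#' @export
ssa_optimize <- function(objective, lower, upper, params = ssa_params()) {
  Dd <- length(lower)
  if (length(upper) != Dd || any(upper <= lower))
    stop("invalid bounds", call. = FALSE)
  n <- params$pop
  PN <- min(params$explorer_count, n)
  eval_safe <- function(x) {
    v <- objective(x)
    if (!is.finite(v)) Inf else v
  }
  clamp <- function(X) {
    X <- pmax(X, matrix(lower, nrow(X), Dd, byrow = TRUE))
    pmin(X, matrix(upper, nrow(X), Dd, byrow = TRUE))
  }
  with_seed(params$seed, {
    X <- matrix(stats::runif(n * Dd, rep(lower, each = n), rep(upper, each = n)),
                n, Dd)
    f <- apply(X, 1, eval_safe)
    best_i <- which.min(f)
    best_x <- X[best_i, ]; best_f <- f[best_i]
    trace <- numeric(params$itermax)
    for (t in seq_len(params$itermax)) {
      ord <- order(f)                 # ascending: best first
      xb <- X[ord[1], ]; xw <- X[ord[n], ]
      fg <- f[ord[1]]; fw <- f[ord[n]]
      Xn <- X
      ## explorers: ranks 1..PN
      R2 <- stats::runif(1)
      for (r in seq_len(PN)) {
        i <- ord[r]
        if (R2 < params$ST) {
          alpha <- stats::runif(1)
          Xn[i, ] <- X[i, ] * exp(-r / (alpha * params$itermax))
        } else {
          Xn[i, ] <- X[i, ] + stats::rnorm(Dd)
        }
      }
      ## followers: ranks PN+1..n
      if (n > PN) for (r in (PN + 1):n) {
        i <- ord[r]
        if (r > n / 2) {
          alpha <- stats::runif(1)
          Xn[i, ] <- stats::rnorm(Dd) * exp((xw - X[i, ]) / (alpha * params$itermax))
        } else {
          step <- mean(sample(c(-1, 1), Dd, replace = TRUE) * abs(xb - X[i, ]))
          Xn[i, ] <- xb + step
        }
      }
      ## anti-predation: random alarm subset
      n_alarm <- max(1L, round(params$alarm_fraction * n))
      for (i in sample.int(n, n_alarm)) {
        if (f[i] != fg) {
          Xn[i, ] <- xb + stats::rnorm(1) * abs(Xn[i, ] - xb)
        } else {
          K <- stats::runif(1, -1, 1)
          Xn[i, ] <- Xn[i, ] + K * (abs(Xn[i, ] - xw) / (f[i] - fw + 1e-50))
        }
      }
      X <- clamp(Xn)
      f <- apply(X, 1, eval_safe)
      it_best <- which.min(f)
      if (f[it_best] < best_f) { best_f <- f[it_best]; best_x <- X[it_best, ] }
      trace[t] <- best_f
    }
    list(best = best_x, value = best_f, trace = trace)
  })
}

#' Search bounds for SSA-DBSCAN
#'
#' @param eps_range numeric `c(low, high)` for the neighborhood radius.
#' @param minpts_range integer `c(low, high)` for the core-point density.
#' @return a `search_bounds` list.
#' @export
search_bounds <- function(eps_range, minpts_range) {
  if (eps_range[1] <= 0 || eps_range[2] <= eps_range[1])
    stop("invalid eps_range", call. = FALSE)
  if (minpts_range[1] < 1 || minpts_range[2] <= minpts_range[1])
    stop("invalid minpts_range", call. = FALSE)
  structure(list(eps_range = as.numeric(eps_range),
                 minpts_range = as.numeric(minpts_range)),
            class = "search_bounds")
}

## Data-driven default bounds: eps between the 1st and 99th percentile of
## the pairwise distances, minPts between 2 and min(50, n/3).
default_bounds <- function(D, n) {
  dv <- D[upper.tri(D)]
  q <- stats::quantile(dv[dv > 0], c(0.01, 0.99), names = FALSE)
  search_bounds(c(max(q[1], 1e-8), q[2]), c(2, max(3, min(50, floor(n / 3)))))
}

#' Adaptive DBSCAN: parameter selection by sparrow search
#'
#' Runs [ssa_optimize()] over the 2-D `(eps, minPts)` space (minPts rounded
#' to the nearest integer when decoded), minimizing the negative silhouette
#' fitness of the DBSCAN labeling. Labels of every evaluated candidate are
#' cached so the returned result is the actual best labeling encountered,
#' not a re-run.
#'
#' @param points numeric `n x d` matrix (n >= 5), typically embedding
#'   coordinates.
#' @param bounds a [search_bounds()]; `NULL` selects data-driven defaults
#'   (eps between the 1st and 99th pairwise-distance percentiles, minPts in
#'   `[2, min(50, n/3)]`).
#' @param params an [ssa_params()].
#' @return a `cluster_result` with the winning `eps`, `min_pts`, `labels`,
#'   `fitness`, `n_clusters` and the SSA best-fitness `trace`; the
#'   `no_valid_clustering` flag is set when every candidate was degenerate.
#' @export
ssa_dbscan <- function(points, bounds = NULL, params = ssa_params()) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 5) stop("need at least 5 points", call. = FALSE)
  D <- as.matrix(stats::dist(points))
  if (is.null(bounds)) bounds <- default_bounds(D, n)

  best <- list(fitness = -Inf, labels = NULL, eps = NA, min_pts = NA)
  objective <- function(pos) {
    eps <- pos[1]
    min_pts <- as.integer(round(pos[2]))
    labels <- dbscan_from_dist(D, eps, min_pts)
    fit <- fitness_from_dist(D, labels)
    if (fit > best$fitness) {
      best <<- list(fitness = fit, labels = labels, eps = eps,
                    min_pts = min_pts)
    }
    -fit
  }
  opt <- ssa_optimize(objective,
                      lower = c(bounds$eps_range[1], bounds$minpts_range[1]),
                      upper = c(bounds$eps_range[2], bounds$minpts_range[2]),
                      params)
  new_cluster_result(best$labels, best$eps, best$min_pts, best$fitness,
                     trace = -opt$trace,
                     no_valid = best$fitness <= -1)
}

#' @export
plot.cluster_result <- function(x, points = NULL, ...) {
  if (!is.null(points)) {
    points <- as.matrix(points)
    col <- ifelse(x$labels < 0, "grey60", x$labels + 2)
    graphics::plot(points[, 1], points[, 2], col = col, pch = 19,
                   xlab = "dim 1", ylab = "dim 2", ...)
  } else if (!is.null(x$trace)) {
    graphics::plot(seq_along(x$trace), x$trace, type = "l",
                   xlab = "iteration", ylab = "best silhouette", ...)
  }
  invisible(x)
}

#' Write cluster labels as CSV (id, label)
#' @param result a `cluster_result`.
#' @param path output CSV path.
#' @param ids optional id column.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(result, path, ids = NULL) {
  df <- data.frame(id = if (is.null(ids)) seq_along(result$labels) else ids,
                   label = result$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
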