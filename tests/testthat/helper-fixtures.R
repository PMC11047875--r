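## Shared fixtures, all generated in code.

tone <- function(freq, fs = 200, n = 1024, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (seq_len(n) - 1) / fs + phase)
}

## three Gaussian blobs in d dimensions with given centers and spread
blob_points <- function(centers, n_each, sd, seed) {
  withr::with_seed(seed, {
    k <- nrow(centers)
    pts <- centers[rep(seq_len(k), each = n_each), , drop = FALSE] +
      matrix(stats::rnorm(k * n_each * ncol(centers), sd = sd),
             k * n_each, ncol(centers))
    list(points = pts, labels = rep(seq_len(k) - 1L, each = n_each))
  })
}

## brute-force DBSCAN oracle: density-reachability closure via igraph
## components on the core-point graph; border points to the nearest core.
dbscan_oracle <- function(points, eps, min_pts) {
  D <- as.matrix(stats::dist(points))
  n <- nrow(D)
  core <- which(rowSums(D <= eps) >= min_pts)
  labels <- rep(-1L, n)
  if (length(core) > 0) {
    sub <- D[core, core, drop = FALSE] <= eps
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership - 1L
    labels[core] <- comp
    for (b in setdiff(seq_len(n), core)) {
      near <- core[D[b, core] <= eps]
      if (length(near) > 0)
        labels[b] <- labels[near[which.min(D[b, near])]]
    }
  }
  labels
}

## compare two labelings up to relabeling (noise must match exactly)
same_partition <- function(a, b) {
  if (!identical(a == -1L, b == -1L)) return(FALSE)
  keep <- a != -1L
  if (!any(keep)) return(TRUE)
  ta <- table(a[keep], b[keep])
  sum(ta > 0) == length(unique(a[keep])) &&
    length(unique(a[keep])) == length(unique(b[keep]))
}
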