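## Clustering quality indices and the coefficient-of-variation composite
## score for comparing algorithms across several indicators at once.

check_labels <- function(points, labels) {
  points <- as.matrix(points)
  if (length(labels) != nrow(points))
    stop("labels length must match the number of points", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("need at least 2 clusters", call. = FALSE)
  points
}

#' Silhouette coefficient
#'
#' Mean over samples of `(b - a) / max(a, b)`, where `a` is the mean
#' distance to the sample's own cluster (excluding itself) and `b` the
#' smallest mean distance to any other cluster. Samples in singleton
#' clusters contribute 0. Result in `[-1, 1]`; higher is better.
#'
#' @param points numeric `n x d` matrix (n >= 3).
#' @param labels cluster labels (at least 2 distinct values; no noise
#'   convention here — filter noise before calling).
#' @return scalar silhouette coefficient.
#' @export
silhouette_coefficient <- function(points, labels) {
  points <- check_labels(points, labels)
  if (nrow(points) < 3) stop("need at least 3 points", call. = FALSE)
  D <- as.matrix(stats::dist(points))
  s <- silhouette_from_dist(D, rep_len(match(labels, unique(labels)) - 1L,
                                       length(labels)))
  s
}

cluster_split <- function(points, labels) {
  split.data.frame(as.data.frame(points), labels)
}

#' Calinski-Harabasz score
#'
#' Ratio of between-cluster to within-cluster scatter,
#' `[tr(B)/(k - 1)] / [tr(W)/(n - k)]`; higher is better. Zero
#' within-cluster scatter yields `Inf`.
#'
#' @inheritParams silhouette_coefficient
#' @return nonnegative scalar (possibly `Inf`).
#' @export
calinski_harabasz <- function(points, labels) {
  points <- check_labels(points, labels)
  n <- nrow(points)
  groups <- cluster_split(points, labels)
  k <- length(groups)
  grand <- colMeans(points)
  trB <- 0; trW <- 0
  for (g in groups) {
    g <- as.matrix(g)
    cen <- colMeans(g)
    trB <- trB + nrow(g) * sum((cen - grand)^2)
    trW <- trW + sum(sweep(g, 2, cen)^2)
  }
  if (trW == 0) return(Inf)
  (trB / (k - 1)) / (trW / (n - k))
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-case ratio
#' `(S_i + S_j) / ||w_i - w_j||`, with `S_i` the mean Euclidean distance of
#' cluster i's samples to their centroid `w_i`. Lower is better; coincident
#' centroids yield `Inf`.
#'
#' @inheritParams silhouette_coefficient
#' @return positive scalar (possibly `Inf`).
#' @export
davies_bouldin <- function(points, labels) {
  points <- check_labels(points, labels)
  groups <- cluster_split(points, labels)
  k <- length(groups)
  cen <- matrix(vapply(groups, function(g) colMeans(as.matrix(g)),
                       numeric(ncol(points))),
                nrow = k, ncol = ncol(points), byrow = TRUE)
  S <- vapply(seq_len(k), function(i) {
    g <- as.matrix(groups[[i]])
    mean(sqrt(rowSums(sweep(g, 2, cen[i, ])^2)))
  }, numeric(1))
  vals <- numeric(k)
  for (i in seq_len(k)) {
    r <- -Inf
    for (j in seq_len(k)) {
      if (j == i) next
      gap <- sqrt(sum((cen[i, ] - cen[j, ])^2))
      r <- max(r, if (gap == 0) Inf else (S[i] + S[j]) / gap)
    }
    vals[i] <- r
  }
  mean(vals)
}

#' Build a metric table for composite scoring
#'
#' @param values numeric `m x J` matrix: m evaluated objects (algorithms) by
#'   J quality indicators.
#' @param object_names length-m character vector.
#' @param indicator_names length-J character vector.
#' @param polarity per-indicator `"positive"` (higher is better) or
#'   `"negative"` (lower is better).
#' @return a `metric_table`.
#' @export
metric_table <- function(values, object_names, indicator_names, polarity) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  if (nrow(values) < 2 || ncol(values) < 1)
    stop("need at least 2 objects and 1 indicator", call. = FALSE)
  polarity <- match.arg(polarity, c("positive", "negative"),
                        several.ok = TRUE)
  if (length(polarity) != ncol(values))
    stop("one polarity per indicator is required", call. = FALSE)
  structure(list(values = values, object_names = object_names,
                 indicator_names = indicator_names, polarity = polarity),
            class = "metric_table")
}

invert_negative <- function(col, how) {
  switch(how,
         reverse = max(col) - col,
         reciprocal = 1 / col,
         revminmax = max(col) + min(col) - col)
}

normalize_col <- function(col, how) {
  switch(how,
         vector = col / sqrt(sum(col^2)),
         minmax = (col - min(col)) / (max(col) - min(col)),
         max = col / max(col),
         sum = col / sum(col),
         none = col)
}

#' Coefficient-of-variation composite score
#'
#' Weights each quality indicator by its relative dispersion across the
#' evaluated objects and scores each object by the weighted sum of its
#' normalized indicator values: negative indicators are first made positive
#' (default `"reverse"`: `max - x`; `"reciprocal"` and `"revminmax"`
#' available), every indicator column is normalized (default `"vector"`:
#' division by the column L2 norm), then per indicator the mean `A_j`,
#' standard deviation `S_j` (population form by default), coefficient of
#' variation `V_j = S_j / A_j` and weight `W_j = V_j / sum(V)` are computed,
#' and object i scores `sum_j W_j * r_ij`. The default reverse + vector
#' dialect is the one that reproduces published worked examples of this
#' scoring scheme; because both steps are positively homogeneous the ranking
#' is invariant to rescaling any indicator.
#'
#' @param table a [metric_table()].
#' @param inversion how negative indicators are made positive.
#' @param normalization column normalization dialect.
#' @param sd_type `"population"` (divide by m) or `"sample"` (m - 1).
#' @return a `cv_score` list: `weights` (sum to 1), `scores` (per object),
#'   `normalized` matrix, `ranking` (object names, best first).
#' @export
cv_composite <- function(table,
                         inversion = c("reverse", "reciprocal", "revminmax"),
                         normalization = c("vector", "minmax", "max", "sum",
                                           "none"),
                         sd_type = c("population", "sample")) {
  inversion <- match.arg(inversion)
  normalization <- match.arg(normalization)
  sd_type <- match.arg(sd_type)
  V <- table$values
  m <- nrow(V)
  for (j in seq_len(ncol(V))) {
    col <- V[, j]
    if (table$polarity[j] == "negative") col <- invert_negative(col, inversion)
    V[, j] <- normalize_col(col, normalization)
  }
  A <- colMeans(V)
  if (any(A == 0))
    stop(sprintf("indicator '%s' has zero mean after normalization",
                 table$indicator_names[which(A == 0)[1]]), call. = FALSE)
  div <- if (sd_type == "population") m else m - 1
  S <- sqrt(colSums(sweep(V, 2, A)^2) / div)
  cv <- S / A
  ## zero dispersion everywhere (all objects identical): uniform weights,
  ## so every object scores the same, as symmetry requires
  W <- if (sum(cv) == 0) rep(1 / length(cv), length(cv)) else cv / sum(cv)
  scores <- drop(V %*% W)
  names(scores) <- table$object_names
  names(W) <- table$indicator_names
  structure(list(weights = W, scores = scores, normalized = V,
                 ranking = table$object_names[order(scores,
                                                    decreasing = TRUE)]),
            class = "cv_score")
}

#' @export
print.cv_score <- function(x, ...) {
  cat("Coefficient-of-variation composite scores\n")
  cat("  weights:", paste(sprintf("%s=%.4f", names(x$weights), x$weights),
                          collapse = "  "), "\n")
  ord <- order(x$scores, decreasing = TRUE)
  for (i in ord)
    cat(sprintf("  %-12s %.5f\n", names(x$scores)[i], x$scores[i]))
  invisible(x)
}

#' Read a metric table CSV with a polarity header row
#'
#' Expected layout: first column object names; first data row holds the
#' per-indicator polarity (`positive`/`negative`); remaining rows the
#' numeric values.
#'
#' @param path CSV path.
#' @return a `metric_table`.
#' @export
read_metric_table_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  pol <- as.character(df[1, -1])
  vals <- as.matrix(sapply(df[-1, -1, drop = FALSE], as.numeric))
  metric_table(vals, object_names = df[[1]][-1],
               indicator_names = names(df)[-1], polarity = pol)
}

#' Write a metric table in the layout read by [read_metric_table_csv()]
#' @param table a `metric_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_table_csv <- function(table, path) {
  df <- rbind(data.frame(object = "polarity",
                         t(table$polarity), check.names = FALSE),
              data.frame(object = table$object_names, table$values,
                         check.names = FALSE))
  names(df) <- c("object", table$indicator_names)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
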