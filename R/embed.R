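## Exact t-SNE: per-point Gaussian affinity calibration to a target
## perplexity by bisection, then gradient descent on the KL divergence with
## the heavy-tailed Student-t low-dimensional kernel, momentum, adaptive
## gains and early exaggeration. Exact (quadratic) gradients — intended for
## the few hundred segments a desk-scale recording session yields.

#' Calibrate Gaussian affinities to a target perplexity
#'
#' For each row of the distance matrix a Gaussian bandwidth is found by
#' bisection so the row's entropy `H` satisfies `2^H = perplexity` (within
#' `tol`). Rows are normalized to sum to 1 with a zero diagonal.
#'
#' @param distances symmetric nonnegative `n x n` matrix of Euclidean
#'   distances with zero diagonal.
#' @param perplexity target perplexity in `(1, n)`.
#' @param tol absolute tolerance on the achieved perplexity.
#' @return row-stochastic affinity matrix `P` with zero diagonal.
#' @export
perplexity_calibration <- function(distances, perplexity, tol = 1e-4) {
  n <- nrow(distances)
  if (perplexity <= 1 || perplexity >= n)
    stop("perplexity must lie in (1, n)", call. = FALSE)
  D2 <- distances^2
  P <- matrix(0, n, n)
  log_u <- log2(perplexity)
  for (i in seq_len(n)) {
    d2 <- D2[i, -i]
    beta <- 1; beta_lo <- -Inf; beta_hi <- Inf
    for (iter in 1:100) {
      w <- exp(-d2 * beta)
      sw <- sum(w)
      if (sw == 0) { p <- rep(1 / length(d2), length(d2)); break }
      p <- w / sw
      h <- -sum(p[p > 0] * log2(p[p > 0]))   # entropy in bits
      if (abs(2^h - perplexity) < tol) break
      if (h > log_u) {               # too spread out -> sharpen
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P
}

#' t-SNE embedding of a feature matrix
#'
#' Symmetrized calibrated affinities, Student-t similarities
#' `1 / (1 + ||y_i - y_j||^2)` in the embedding, gradient descent on the KL
#' divergence with momentum (0.5 during the exaggerated phase, then 0.8),
#' adaptive per-coordinate gains, early exaggeration (x12 for the first 250
#' iterations, or the first half of short runs) and a small random Gaussian
#' initialization. Deterministic given `seed`. The perplexity is clamped to
#' `(n - 1) / 3` when the sample is small.
#'
#' @param features a `feature_matrix` or plain numeric matrix (rows =
#'   segments).
#' @param d embedding dimensionality, 2 or 3.
#' @param perplexity target perplexity.
#' @param iters gradient-descent iterations.
#' @param seed integer seed for the initialization.
#' @param learning_rate gradient step size.
#' @param Y_init optional `n x d` initialization matrix overriding the
#'   random one (used e.g. by equivariance checks).
#' @return an `embedding`: list with `coords` (`n x d`), `kl_trace`
#'   (per-iteration KL divergence against the non-exaggerated target) and
#'   `seed`.
#' @export
tsne_embed <- function(features, d = 2L, perplexity = 30, iters = 1000L,
                       seed = 0L, learning_rate = 100, Y_init = NULL) {
  X <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  if (!d %in% c(2L, 3L)) stop("d must be 2 or 3", call. = FALSE)
  n <- nrow(X)
  if (n < 5) stop("need at least 5 points", call. = FALSE)
  perplexity <- min(perplexity, (n - 1) / 3)

  D <- as.matrix(stats::dist(X))
  P <- perplexity_calibration(D, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  diag(P) <- 0

  exagg_iters <- min(250L, max(1L, round(iters / 2)))
  Y <- if (!is.null(Y_init)) {
    stopifnot(nrow(Y_init) == n, ncol(Y_init) == d)
    as.matrix(Y_init)
  } else {
    with_seed(seed, matrix(stats::rnorm(n * d, sd = 1e-4), n, d))
  }
  inc <- matrix(0, n, d)
  gains <- matrix(1, n, d)
  kl_trace <- numeric(iters)

  for (it in seq_len(iters)) {
    Pe <- if (it <= exagg_iters) P * 12 else P
    ## pairwise student-t similarities
    sq <- rowSums(Y^2)
    num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q <- pmax(Q, 1e-12)
    ## gradient: 4 * sum_j (p - q) num (y_i - y_j)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    momentum <- if (it < exagg_iters) 0.5 else 0.8
    inc <- momentum * inc - learning_rate * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
    pos <- P > 0
    kl_trace[it] <- sum(P[pos] * log(P[pos] / Q[pos]))
  }
  structure(list(coords = Y, kl_trace = kl_trace, seed = seed,
                 perplexity = perplexity, d = d),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> %d points in %d-D | perplexity %.1f | final KL %.4f\n",
              nrow(x$coords), x$d, x$perplexity,
              x$kl_trace[length(x$kl_trace)]))
  invisible(x)
}

#' @export
plot.embedding <- function(x, labels = NULL, ...) {
  col <- if (is.null(labels)) 1 else as.integer(factor(labels))
  graphics::plot(x$coords[, 1], x$coords[, 2], col = col, pch = 19,
                 xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  invisible(x)
}

#' Write an embedding as CSV (id, x, y[, z])
#' @param embedding an `embedding`.
#' @param path output CSV path.
#' @param ids optional id column values.
#' @return `path`, invisibly.
#' @export
write_embedding_csv <- function(embedding, path, ids = NULL) {
  co <- embedding$coords
  df <- data.frame(id = if (is.null(ids)) seq_len(nrow(co)) else ids)
  df$x <- co[, 1]; df$y <- co[, 2]
  if (ncol(co) == 3) df$z <- co[, 3]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an embedding written by [write_embedding_csv()]
#' @param path CSV path.
#' @return an `embedding` (with empty `kl_trace`).
#' @export
read_embedding_csv <- function(path) {
  df <- utils::read.csv(path)
  cols <- intersect(c("x", "y", "z"), names(df))
  structure(list(coords = as.matrix(df[cols]), kl_trace = numeric(0),
                 seed = NA_integer_, perplexity = NA_real_,
                 d = length(cols), ids = df$id),
            class = "embedding")
}
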