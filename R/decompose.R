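## Empirical mode decomposition family: EMD, ensemble EMD, and CEEMDAN
## (complete ensemble EMD with adaptive noise).
##
## Sifting follows the classic recipe: cubic-spline envelopes through local
## extrema (mirrored boundary extension), mean-envelope subtraction, Cauchy
## stopping rule. CEEMDAN adds, at every stage, the matching EMD mode of
## fixed white-noise realizations to the current residue and takes the
## ensemble mean of the first sifted mode, with a geometrically decaying
## noise amplitude; the stage-wise residue update makes reconstruction exact
## by construction.

#' Sifting configuration for the EMD family
#'
#' @param max_imfs maximum number of modes to extract.
#' @param max_sift_iters sift iteration cap per mode.
#' @param stop_threshold Cauchy stopping value: sifting of a mode stops when
#'   the normalized squared difference between successive sift iterates falls
#'   below this.
#' @param boundary extremum extension policy; only `"mirror"` (reflect two
#'   extrema per side) is implemented.
#' @return a `sift_config` list.
#' @export
sift_config <- function(max_imfs = 10L, max_sift_iters = 50L,
                        stop_threshold = 0.2, boundary = "mirror") {
  if (max_imfs < 1) stop("max_imfs must be >= 1", call. = FALSE)
  if (stop_threshold <= 0) stop("stop_threshold must be > 0", call. = FALSE)
  boundary <- match.arg(boundary, "mirror")
  structure(list(max_imfs = as.integer(max_imfs),
                 max_sift_iters = as.integer(max_sift_iters),
                 stop_threshold = stop_threshold, boundary = boundary),
            class = "sift_config")
}

## Local extrema; flat runs are collapsed by carrying the last nonzero slope.
find_extrema <- function(x) {
  d <- sign(diff(x))
  nz <- d != 0
  if (!any(nz)) return(list(maxima = integer(0), minima = integer(0)))
  ## propagate previous nonzero sign into zero slots
  idx <- cumsum(nz)
  filled <- c(NA_real_, d[nz])[idx + 1]
  keep <- !is.na(filled)
  ds <- diff(filled[keep])
  pos <- which(keep)[-1][ds != 0]
  types <- ds[ds != 0]
  list(maxima = pos[types < 0], minima = pos[types > 0])
}

## Cubic-spline envelope through extrema with two extrema mirrored per side.
spline_envelope <- function(t, v, n) {
  k <- min(2L, length(t))
  tl <- 2 - rev(t[seq_len(k)]);      vl <- rev(v[seq_len(k)])
  tr <- 2 * n - rev(rev(t)[seq_len(k)]); vr <- rev(rev(v)[seq_len(k)])
  tt <- c(tl, t, tr); vv <- c(vl, v, vr)
  ok <- !duplicated(tt)
  stats::splinefun(tt[ok], vv[ok], method = "fmm")(seq_len(n))
}

## One full sift: extract the next mode from r, or NULL if r has too few
## extrema to define envelopes (then r is the residue).
sift_mode <- function(r, cfg) {
  n <- length(r)
  h <- r
  for (it in seq_len(cfg$max_sift_iters)) {
    ex <- find_extrema(h)
    if (length(ex$maxima) < 2 || length(ex$minima) < 2)
      return(if (it == 1) NULL else h)
    upper <- spline_envelope(ex$maxima, h[ex$maxima], n)
    lower <- spline_envelope(ex$minima, h[ex$minima], n)
    m <- (upper + lower) / 2
    denom <- sum(h^2)
    if (denom == 0) return(h)
    if (sum(m^2) / denom < cfg$stop_threshold) return(h - m)
    h <- h - m
  }
  h
}

new_imfset <- function(imfs, residue, fs = NA_real_, id = NA_character_) {
  structure(list(imfs = imfs, residue = residue,
                 source_length = length(residue), fs = fs, id = id),
            class = "imfset")
}

#' @export
print.imfset <- function(x, ...) {
  cat(sprintf("<imfset> %d IMFs + residue, n=%d\n", nrow(x$imfs),
              x$source_length))
  invisible(x)
}

#' Empirical mode decomposition
#'
#' Iteratively sifts intrinsic mode functions (IMFs) out of a signal until
#' the residue has too few extrema to continue or `max_imfs` is reached.
#' The residue is defined as the exact remainder, so
#' `colSums(imfs) + residue` reproduces the input to machine precision.
#'
#' @param signal a [signal_segment()] or finite numeric vector, non-constant.
#' @param cfg a [sift_config()].
#' @return an `imfset`: `imfs` (K x N matrix, ordered high to low frequency),
#'   `residue` (length N), `source_length`.
#' @export
emd <- function(signal, cfg = sift_config()) {
  x <- as_samples(signal)
  fs <- if (inherits(signal, "signal_segment")) signal$fs else NA_real_
  id <- if (inherits(signal, "signal_segment")) signal$id else NA_character_
  ex <- find_extrema(x)
  if (length(ex$maxima) < 2 || length(ex$minima) < 2)
    stop("signal has too few extrema to decompose (constant or monotone?)",
         call. = FALSE)
  r <- x
  imfs <- list()
  for (k in seq_len(cfg$max_imfs)) {
    mode <- sift_mode(r, cfg)
    if (is.null(mode)) break
    imfs[[k]] <- mode
    r <- r - mode
    ex <- find_extrema(r)
    if (length(ex$maxima) < 2 || length(ex$minima) < 2) break
  }
  if (length(imfs) == 0)
    stop("decomposition failed: no mode could be extracted", call. = FALSE)
  new_imfset(do.call(rbind, imfs), r, fs, id)
}

#' Ensemble empirical mode decomposition (EEMD)
#'
#' Decomposes `ensemble_size` white-noise-perturbed copies of the signal and
#' averages the IMFs mode-by-mode (zero-padding shorter decompositions).
#' The averaged decomposition is deterministic given `seed`.
#'
#' @inheritParams emd
#' @param ensemble_size number of noise realizations (>= 1).
#' @param noise_ratio noise standard deviation as a fraction of the signal's.
#' @param seed integer root seed; realization i uses `derive_seed(seed, i)`.
#' @return an `imfset` of ensemble-averaged modes.
#' @export
eemd <- function(signal, ensemble_size = 100L, noise_ratio = 0.2, seed = 0L,
                 cfg = sift_config()) {
  x <- as_samples(signal)
  if (ensemble_size < 1) stop("ensemble_size must be >= 1", call. = FALSE)
  if (noise_ratio < 0) stop("noise_ratio must be >= 0", call. = FALSE)
  sigma <- stats::sd(x)
  n <- length(x)
  acc <- list(); res_acc <- numeric(n); maxk <- 0L
  all_imfs <- vector("list", ensemble_size)
  for (i in seq_len(ensemble_size)) {
    w <- if (noise_ratio > 0)
      with_seed(derive_seed(seed, i), stats::rnorm(n, sd = noise_ratio * sigma))
    else numeric(n)
    dec <- emd(x + w, cfg)
    all_imfs[[i]] <- dec
    maxk <- max(maxk, nrow(dec$imfs))
  }
  imfs <- matrix(0, maxk, n)
  for (i in seq_len(ensemble_size)) {
    m <- all_imfs[[i]]$imfs
    imfs[seq_len(nrow(m)), ] <- imfs[seq_len(nrow(m)), , drop = FALSE] + m
    res_acc <- res_acc + all_imfs[[i]]$residue
  }
  fs <- if (inherits(signal, "signal_segment")) signal$fs else NA_real_
  id <- if (inherits(signal, "signal_segment")) signal$id else NA_character_
  new_imfset(imfs / ensemble_size, res_acc / ensemble_size, fs, id)
}

#' CEEMDAN: complete ensemble EMD with adaptive noise
#'
#' Stage-wise noise-assisted decomposition: at stage k the k-th EMD mode of
#' each fixed white-noise realization, scaled by a geometrically decaying
#' amplitude, is added to the current residue; the ensemble mean of the first
#' sifted mode becomes IMF k and is subtracted from the residue. Because the
#' residue update is exact, `colSums(imfs) + residue` equals the input to
#' machine precision, unlike plain EEMD. With `noise_ratio = 0` the procedure
#' collapses to plain EMD.
#'
#' @inheritParams eemd
#' @param decay per-stage geometric decay factor of the added-noise amplitude.
#' @return an `imfset`.
#' @export
ceemdan <- function(signal, ensemble_size = 100L, noise_ratio = 0.2,
                    seed = 0L, cfg = sift_config(), decay = 0.9) {
  x <- as_samples(signal)
  fs <- if (inherits(signal, "signal_segment")) signal$fs else NA_real_
  id <- if (inherits(signal, "signal_segment")) signal$id else NA_character_
  if (ensemble_size < 1) stop("ensemble_size must be >= 1", call. = FALSE)
  if (noise_ratio < 0) stop("noise_ratio must be >= 0", call. = FALSE)
  if (noise_ratio == 0) {
    out <- emd(signal, cfg)
    return(out)
  }
  n <- length(x)
  eps0 <- noise_ratio * stats::sd(x)
  ## fixed noise realizations, each fully decomposed once
  noise_modes <- vector("list", ensemble_size)
  for (i in seq_len(ensemble_size)) {
    w <- with_seed(derive_seed(seed, i), stats::rnorm(n))
    noise_modes[[i]] <- emd(w, cfg)$imfs
  }
  r <- x
  imfs <- list()
  for (k in seq_len(cfg$max_imfs)) {
    eps_k <- eps0 * decay^(k - 1)
    acc <- numeric(n)
    used <- 0L
    for (i in seq_len(ensemble_size)) {
      nm <- noise_modes[[i]]
      perturbed <- if (k <= nrow(nm)) r + eps_k * nm[k, ] else r
      mode <- sift_mode(perturbed, cfg)
      if (is.null(mode)) next
      acc <- acc + mode
      used <- used + 1L
    }
    if (used == 0) break
    mode_k <- acc / used
    imfs[[k]] <- mode_k
    r <- r - mode_k
    ex <- find_extrema(r)
    if (length(ex$maxima) < 2 || length(ex$minima) < 2) break
  }
  if (length(imfs) == 0)
    stop("decomposition failed: no mode could be extracted", call. = FALSE)
  new_imfset(do.call(rbind, imfs), r, fs, id)
}

## Mean zero-crossing rate, used to check high-to-low mode ordering.
zero_crossing_rate <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0)
  sum(diff(s) != 0) / length(x)
}

#' Write an IMF set as CSV (columns IMF1..IMFK, residue)
#' @param imfset an `imfset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_imfset_csv <- function(imfset, path) {
  k <- nrow(imfset$imfs)
  df <- as.data.frame(t(imfset$imfs))
  names(df) <- paste0("IMF", seq_len(k))
  df$residue <- imfset$residue
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an IMF set written by [write_imfset_csv()]
#' @param path CSV path.
#' @return an `imfset`.
#' @export
read_imfset_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"residue" %in% names(df)) stop("no residue column in ", path, call. = FALSE)
  imf_cols <- grep("^IMF", names(df), value = TRUE)
  new_imfset(t(as.matrix(df[imf_cols])), df$residue)
}
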