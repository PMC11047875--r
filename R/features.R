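## Multivariate feature extraction: twelve time, frequency, time-frequency
## and nonlinear descriptors per segment.

#' Basic statistics: mean, RMS, skewness
#'
#' @param segment numeric vector (or [signal_segment()]), length >= 3.
#' @return named numeric vector `c(mean, rms, skewness)`; skewness is the
#'   third standardized sample moment, 0 with a warning for zero variance.
#' @export
basic_stats <- function(segment) {
  x <- as_samples(segment)
  if (length(x) < 3) stop("need at least 3 samples", call. = FALSE)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  skew <- if (s == 0) {
    warning("zero variance; skewness set to 0")
    0
  } else mean((x - m)^3) / s^3
  c(mean = m, rms = sqrt(mean(x^2)), skewness = skew)
}

#' Hjorth parameters
#'
#' Activity is the signal variance; mobility the standard-deviation ratio of
#' the first difference to the signal; complexity the mobility of the first
#' difference relative to the signal's mobility. All three are 0 with a
#' warning for a constant input.
#'
#' @inheritParams basic_stats
#' @return named numeric vector `c(activity, mobility, complexity)`.
#' @export
hjorth <- function(segment) {
  x <- as_samples(segment)
  if (length(x) < 3) stop("need at least 3 samples", call. = FALSE)
  v0 <- stats::var(x)
  if (v0 == 0) {
    warning("zero variance; Hjorth parameters set to 0")
    return(c(activity = 0, mobility = 0, complexity = 0))
  }
  d1 <- diff(x)
  d2 <- diff(d1)
  v1 <- stats::var(d1)
  v2 <- stats::var(d2)
  mob <- sqrt(v1 / v0)
  comp <- if (v1 == 0) 0 else sqrt(v2 / v1) / mob
  c(activity = v0, mobility = mob, complexity = comp)
}

#' Histogram Shannon entropy
#'
#' Entropy (nats) of the empirical distribution over `bins` equal-width bins
#' spanning the sample range. A constant segment has zero entropy.
#'
#' @inheritParams basic_stats
#' @param bins number of histogram bins, >= 2.
#' @return entropy in nats, bounded by `log(bins)`.
#' @export
shannon_entropy <- function(segment, bins = 16L) {
  x <- as_samples(segment)
  if (bins < 2) stop("bins must be >= 2", call. = FALSE)
  if (max(x) == min(x)) return(0)
  cuts <- seq(min(x), max(x), length.out = bins + 1)
  counts <- tabulate(findInterval(x, cuts, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  p <- counts[counts > 0] / length(x)
  -sum(p * log(p))
}

#' Mean Teager energy
#'
#' Average of the Teager-Kaiser operator
#' `psi(n) = x(n)^2 - x(n-1) * x(n+1)`, an instantaneous amplitude-frequency
#' energy estimate.
#'
#' @inheritParams basic_stats
#' @return mean Teager energy.
#' @export
mean_teager_energy <- function(segment) {
  x <- as_samples(segment)
  n <- length(x)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  mean(x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n])
}

#' Fluctuation index
#'
#' Mean absolute first difference, a simple roughness measure.
#'
#' @inheritParams basic_stats
#' @return nonnegative scalar.
#' @export
fluctuation_index <- function(segment) {
  x <- as_samples(segment)
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  mean(abs(diff(x)))
}

#' Spectral band powers and peak frequency
#'
#' Periodogram-based relative power in each requested band (normalized by
#' total power over `(0, fs/2)`) plus the frequency of the periodogram peak.
#'
#' @inheritParams basic_stats
#' @param fs sampling rate in Hz (taken from a [signal_segment()] input).
#' @param bands list of `c(low, high)` Hz intervals inside `(0, fs/2)`.
#' @return named vector: one relative power per band, then `peak_freq`.
#' @export
spectral_features <- function(segment, fs = NULL,
                              bands = list(c(4, 13), c(13, 45))) {
  x <- as_samples(segment)
  if (is.null(fs)) {
    if (!inherits(segment, "signal_segment"))
      stop("fs is required for a bare numeric input", call. = FALSE)
    fs <- segment$fs
  }
  for (b in bands)
    if (b[1] <= 0 || b[2] >= fs / 2 || b[2] <= b[1])
      stop("bands must be increasing intervals inside (0, fs/2)", call. = FALSE)
  n <- length(x)
  xc <- x - mean(x)
  spec <- Mod(stats::fft(xc))^2
  half <- 2:floor((n + 1) / 2)         # (0, fs/2) open: no DC, no Nyquist
  freqs <- (half - 1) * fs / n
  pw <- spec[half]
  total <- sum(pw)
  out <- numeric(length(bands))
  if (total == 0) {
    warning("degenerate (constant) signal; band powers set to 0")
    peak <- 0
  } else {
    for (i in seq_along(bands))
      out[i] <- sum(pw[freqs >= bands[[i]][1] & freqs <= bands[[i]][2]]) / total
    peak <- freqs[which.max(pw)]
  }
  names(out) <- vapply(bands, function(b) sprintf("bp_%g_%g", b[1], b[2]),
                       character(1))
  c(out, peak_freq = peak)
}

#' Wavelet sub-band energies and energy entropy
#'
#' Relative energy of each decomposition level (details from fine to coarse,
#' then the final approximation) and the wavelet energy entropy
#' `-sum(e * log(e))` over those relative energies.
#'
#' @inheritParams basic_stats
#' @param spec a [wavelet_spec()].
#' @return named vector of `levels + 1` relative energies plus
#'   `energy_entropy`.
#' @export
wavelet_subband_features <- function(segment, spec = wavelet_spec()) {
  x <- as_samples(segment)
  dec <- dwt_periodic(x, spec$name, spec$levels)
  e <- c(vapply(dec$details, function(d) sum(d^2), numeric(1)),
         sum(dec$approx^2))
  names(e) <- c(paste0("d", seq_along(dec$details)), "approx")
  total <- sum(e)
  rel <- if (total == 0) e else e / total
  ent <- {
    p <- rel[rel > 0]
    if (length(p) == 0) 0 else -sum(p * log(p))
  }
  c(rel, energy_entropy = ent)
}

#' Extract the default twelve-feature matrix
#'
#' Columns: mean, rms, skewness, fluctuation index, Hjorth activity /
#' mobility / complexity, Shannon entropy, mean Teager energy, two relative
#' band powers (theta+alpha 4-13 Hz, beta+gamma 13-45 Hz) and wavelet energy
#' entropy. Columns are z-score standardized by default (mixed physical
#' units otherwise dominate any distance-based embedding).
#'
#' @param segments list of [signal_segment()] (>= 2) or a `labeled_dataset`.
#' @param bands two-band list for the spectral features.
#' @param wavelet a [wavelet_spec()] for the energy entropy.
#' @param bins histogram bins for the Shannon entropy.
#' @param standardize z-score each column.
#' @return a `feature_matrix`: list with `values` (segments x features),
#'   `feature_names`, `segment_ids`, `standardized`.
#' @export
extract_feature_matrix <- function(segments, bands = list(c(4, 13), c(13, 45)),
                                   wavelet = wavelet_spec(), bins = 16L,
                                   standardize = TRUE) {
  if (inherits(segments, "labeled_dataset")) segments <- segments$segments
  if (length(segments) < 2) stop("need at least 2 segments", call. = FALSE)
  feature_names <- c("mean", "rms", "skewness", "fluctuation",
                     "hjorth_activity", "hjorth_mobility", "hjorth_complexity",
                     "shannon_entropy", "teager_energy",
                     sprintf("bp_%g_%g", bands[[1]][1], bands[[1]][2]),
                     sprintf("bp_%g_%g", bands[[2]][1], bands[[2]][2]),
                     "wavelet_energy_entropy")
  vals <- matrix(NA_real_, length(segments), length(feature_names),
                 dimnames = list(NULL, feature_names))
  ids <- character(length(segments))
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    ids[i] <- if (inherits(seg, "signal_segment")) seg$id else sprintf("seg_%03d", i)
    bs <- basic_stats(seg)
    hj <- hjorth(seg)
    sp <- spectral_features(seg, bands = bands)
    wl <- wavelet_subband_features(seg, wavelet)
    vals[i, ] <- c(bs["mean"], bs["rms"], bs["skewness"],
                   fluctuation_index(seg),
                   hj, shannon_entropy(seg, bins), mean_teager_energy(seg),
                   sp[1], sp[2], wl["energy_entropy"])
  }
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite feature '%s' for segment '%s'",
                 feature_names[bad[1, 2]], ids[bad[1, 1]]), call. = FALSE)
  if (standardize) {
    mu <- colMeans(vals)
    sd <- apply(vals, 2, stats::sd)
    if (any(sd == 0))
      stop(sprintf("feature '%s' is constant across segments; cannot standardize",
                   feature_names[which(sd == 0)[1]]), call. = FALSE)
    vals <- sweep(sweep(vals, 2, mu), 2, sd, "/")
  }
  structure(list(values = vals, feature_names = feature_names,
                 segment_ids = ids, standardized = standardize),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d segments x %d features%s\n",
              nrow(x$values), ncol(x$values),
              if (x$standardized) " (standardized)" else ""))
  invisible(x)
}

#' Write a feature matrix as CSV (id column + one column per feature)
#' @param fm a `feature_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(fm, path) {
  df <- data.frame(id = fm$segment_ids, fm$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_csv()]
#' @param path CSV path.
#' @param standardized whether the stored columns were standardized.
#' @return a `feature_matrix`.
#' @export
read_feature_csv <- function(path, standardized = TRUE) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"id" %in% names(df)) stop("no id column in ", path, call. = FALSE)
  vals <- as.matrix(df[setdiff(names(df), "id")])
  structure(list(values = vals, feature_names = colnames(vals),
                 segment_ids = as.character(df$id),
                 standardized = standardized),
            class = "feature_matrix")
}
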