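## Synthetic EEG-like segment generator.
##
## Emulates the geometry of segmented clinical recordings (fixed sampling
## rate, fixed duration, a few latent stages) without claiming clinical
## fidelity: each class is band-limited colored noise in a characteristic
## rhythm band plus class-specific transients.

#' Specification of one synthetic segment class
#'
#' @param band numeric length-2, rhythm band in Hz (must lie below Nyquist).
#' @param amplitude amplitude scale of the band-limited component
#'   (microvolt-like arbitrary units).
#' @param spike_rate expected transient spikes per second (Poisson rate); 0
#'   disables transients.
#' @param spike_amplitude peak amplitude of each transient relative to
#'   `amplitude`.
#' @param name label used in manifests.
#' @return a `synth_class` list.
#' @export
synth_class <- function(band, amplitude = 1, spike_rate = 0,
                        spike_amplitude = 4, name = "class") {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1])
    stop("band must be an increasing positive frequency interval", call. = FALSE)
  structure(list(band = as.numeric(band), amplitude = amplitude,
                 spike_rate = spike_rate, spike_amplitude = spike_amplitude,
                 name = name),
            class = "synth_class")
}

#' Configuration of the synthetic dataset generator
#'
#' Defaults mirror a segmented three-stage epileptic EEG recording: 50
#' segments per stage, 200 Hz sampling, 5.12 s per segment (1024 samples),
#' with a background class (alpha-band 8-13 Hz noise), an interictal-like
#' class (background plus sparse sharp transients) and an ictal-like class
#' (high-amplitude ~3 Hz rhythmic activity with spike-wave transients).
#'
#' @param n_per_class segments per class.
#' @param fs sampling rate in Hz.
#' @param duration_s segment duration in seconds; `fs * duration_s` must be a
#'   whole number of samples, at least 64.
#' @param classes list of [synth_class()] specifications (at least 2).
#' @param seed integer root seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_per_class = 50, fs = 200, duration_s = 5.12,
                         classes = NULL, seed = 0L) {
  if (is.null(classes)) {
    classes <- list(
      synth_class(c(8, 13), amplitude = 1, spike_rate = 0,
                  name = "background"),
      synth_class(c(8, 13), amplitude = 1, spike_rate = 1,
                  spike_amplitude = 5, name = "interictal"),
      synth_class(c(2.5, 4), amplitude = 3, spike_rate = 3,
                  spike_amplitude = 2, name = "ictal"))
  }
  n <- fs * duration_s
  if (abs(n - round(n)) > 1e-9 || round(n) < 64)
    stop("fs * duration_s must be an integer sample count >= 64", call. = FALSE)
  if (length(classes) < 2)
    stop("at least 2 classes are required", call. = FALSE)
  for (cl in classes) {
    if (!inherits(cl, "synth_class")) stop("classes must be synth_class objects",
                                           call. = FALSE)
    if (cl$band[2] >= fs / 2)
      stop(sprintf("class '%s' band reaches the Nyquist frequency %g Hz",
                   cl$name, fs / 2), call. = FALSE)
  }
  structure(list(n_per_class = as.integer(n_per_class), fs = fs,
                 duration_s = duration_s, n_samples = as.integer(round(n)),
                 classes = classes, seed = as.integer(seed)),
            class = "synth_config")
}

## Band-limited Gaussian noise by Fourier masking: white noise -> FFT ->
## zero bins outside [f1, f2] -> inverse FFT -> rescale to unit RMS.
band_limited_noise <- function(n, fs, band) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)      # two-sided spectrum folding
  keep <- freqs >= band[1] & freqs <= band[2]
  W[!keep] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  r <- sqrt(mean(x^2))
  if (r == 0) x else x / r
}

## Mexican-hat (Ricker) pulse, peak-normalized to 1.
ricker_pulse <- function(half_width) {
  t <- seq(-4, 4, length.out = 2 * half_width + 1)
  (1 - t^2) * exp(-t^2 / 2)
}

synth_segment <- function(cls, n, fs, seed) {
  with_seed(seed, {
    x <- cls$amplitude * band_limited_noise(n, fs, cls$band)
    if (cls$spike_rate > 0) {
      n_spikes <- stats::rpois(1, cls$spike_rate * n / fs)
      if (n_spikes > 0) {
        pulse <- ricker_pulse(round(0.04 * fs))   # ~80 ms sharp transient
        hw <- (length(pulse) - 1) / 2
        centers <- sample.int(n, n_spikes, replace = TRUE)
        for (c0 in centers) {
          idx <- (c0 - hw):(c0 + hw)
          ok <- idx >= 1 & idx <= n
          x[idx[ok]] <- x[idx[ok]] +
            cls$spike_amplitude * cls$amplitude * pulse[ok]
        }
      }
    }
    x
  })
}

#' Generate a labeled synthetic EEG-like dataset
#'
#' Each class contributes `n_per_class` segments of band-limited colored
#' noise in the class rhythm band plus class-specific transient pulses at
#' Poisson times. Fully deterministic given `cfg$seed`: every segment draws
#' from its own derived stream, so the dataset is reproducible
#' segment-by-segment.
#'
#' @param cfg a [synth_config()].
#' @return a `labeled_dataset`: list with `segments` (list of
#'   [signal_segment()]) and `labels` (integer vector, classes numbered from
#'   0 in the order of `cfg$classes`).
#' @export
generate_dataset <- function(cfg) {
  if (!inherits(cfg, "synth_config")) stop("cfg must be a synth_config",
                                           call. = FALSE)
  segments <- vector("list", cfg$n_per_class * length(cfg$classes))
  labels <- integer(length(segments))
  i <- 0L
  for (k in seq_along(cfg$classes)) {
    cls <- cfg$classes[[k]]
    for (j in seq_len(cfg$n_per_class)) {
      i <- i + 1L
      x <- synth_segment(cls, cfg$n_samples, cfg$fs, derive_seed(cfg$seed, i))
      segments[[i]] <- signal_segment(x, cfg$fs,
                                      id = sprintf("%s_%03d", cls$name, j),
                                      stage_label = k - 1L)
      labels[i] <- k - 1L
    }
  }
  structure(list(segments = segments, labels = labels, config = cfg),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d segments, %d classes, fs=%g Hz, %d samples each\n",
              length(x$segments), length(unique(x$labels)),
              x$config$fs, x$config$n_samples))
  invisible(x)
}

#' Add white Gaussian noise at an exact signal-to-noise ratio
#'
#' The noise realization is scaled so that
#' `10 * log10(sum(x^2) / sum(e^2))` equals `snr_db` exactly (up to floating
#' point). An infinite `snr_db` returns the signal unchanged.
#'
#' @param signal finite numeric vector (or [signal_segment()]) with nonzero
#'   power.
#' @param snr_db requested SNR in dB; `Inf` means no noise.
#' @param seed integer seed for the noise realization.
#' @return numeric vector `signal + noise`.
#' @export
add_noise <- function(signal, snr_db, seed = 0L) {
  x <- as_samples(signal)
  if (sum(x^2) == 0) stop("signal has zero power", call. = FALSE)
  if (is.infinite(snr_db) && snr_db > 0) return(x)
  w <- with_seed(seed, stats::rnorm(length(x)))
  scale <- sqrt(sum(x^2) / (sum(w^2) * 10^(snr_db / 10)))
  x + scale * w
}

## Dataset writers ------------------------------------------------------------

#' Write a labeled dataset as per-segment CSV files plus a manifest
#'
#' Each segment goes to `<id>.csv` (single column `value`); the manifest
#' (`manifest.txt`) has one row per segment: id, class label, file name, fs.
#'
#' @param dataset a `labeled_dataset`.
#' @param dir output directory, created if missing.
#' @return the manifest path, invisibly.
#' @export
write_dataset_csv <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- character(length(dataset$segments))
  for (i in seq_along(dataset$segments)) {
    seg <- dataset$segments[[i]]
    file <- paste0(seg$id, ".csv")
    utils::write.csv(data.frame(value = seg$samples),
                     file.path(dir, file), row.names = FALSE)
    rows[i] <- sprintf("%s\t%d\t%s\t%g", seg$id, dataset$labels[i], file, seg$fs)
  }
  manifest <- file.path(dir, "manifest.txt")
  writeLines(c("id\tclass\tfile\tfs", rows), manifest)
  invisible(manifest)
}

#' Read a labeled dataset written by [write_dataset_csv()]
#'
#' @param dir directory containing `manifest.txt` and the per-segment CSVs.
#' @return a `labeled_dataset`.
#' @export
read_dataset_csv <- function(dir) {
  manifest <- file.path(dir, "manifest.txt")
  if (!file.exists(manifest)) stop("no manifest.txt in ", dir, call. = FALSE)
  tab <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  segments <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    vals <- utils::read.csv(file.path(dir, tab$file[i]))$value
    segments[[i]] <- signal_segment(vals, tab$fs[i], id = tab$id[i],
                                    stage_label = tab$class[i])
  }
  structure(list(segments = segments, labels = as.integer(tab$class),
                 config = NULL),
            class = "labeled_dataset")
}
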