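#' @keywords internal
"_PACKAGE"

## Seed plumbing -------------------------------------------------------------

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a deterministic sub-seed from a root seed
#'
#' Mixes a root seed with a stream index through a Lehmer-style multiplicative
#' step so each stochastic stage or ensemble member has its own reproducible
#' stream. All arithmetic stays below 2^53 so it is exact in doubles; the
#' result is always a valid 32-bit seed.
#'
#' @param seed integer root seed.
#' @param k nonnegative integer stream index.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, k = 0L) {
  m <- 2147483647  # 2^31 - 1
  s <- (abs(as.numeric(seed)) %% m)
  s <- (s * 48271 + 11 + as.numeric(k) * 1299709) %% m
  as.integer(s)
}

## Argument checks ------------------------------------------------------------

stop_if_not_finite <- function(x, what = "input") {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(sprintf("%s must be a finite numeric vector", what), call. = FALSE)
  invisible(x)
}

## Relative L2 error, used by reconstruction-identity checks everywhere.
rel_l2 <- function(x, y) {
  dx <- sqrt(sum((x - y)^2))
  sx <- sqrt(sum(x^2))
  if (sx == 0) return(dx)
  dx / sx
}

## Signal segments ------------------------------------------------------------

#' Construct a fixed-rate EEG signal segment
#'
#' The elementary unit of the pipeline: one single-channel time series with a
#' sampling rate, an identifier and an optional stage label. Values are in
#' arbitrary microvolt-like units.
#'
#' @param samples finite numeric vector, length at least 64.
#' @param fs sampling rate in Hz, positive.
#' @param id character identifier.
#' @param stage_label optional integer class/stage label.
#' @return an object of class `signal_segment`.
#' @export
signal_segment <- function(samples, fs, id = "seg", stage_label = NULL) {
  stop_if_not_finite(samples, "samples")
  if (length(samples) < 64)
    stop("signal segment must contain at least 64 samples", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a positive scalar (Hz)", call. = FALSE)
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         id = as.character(id),
         stage_label = if (is.null(stage_label)) NULL else as.integer(stage_label)),
    class = "signal_segment")
}

#' @export
print.signal_segment <- function(x, ...) {
  cat(sprintf("<signal_segment> id=%s  n=%d  fs=%g Hz  duration=%.3f s%s\n",
              x$id, length(x$samples), x$fs, length(x$samples) / x$fs,
              if (is.null(x$stage_label)) ""
              else sprintf("  stage=%d", x$stage_label)))
  invisible(x)
}

## Accept either a signal_segment or a bare numeric vector.
as_samples <- function(x) {
  if (inherits(x, "signal_segment")) x$samples else {
    stop_if_not_finite(x, "signal")
    as.numeric(x)
  }
}
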