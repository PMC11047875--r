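## Minimal EDF (European Data Format) support.
##
## EDF is the de-facto exchange format for clinical EEG: a 256-byte ASCII
## header, one 256-byte ASCII header per signal, then data records of 16-bit
## little-endian integers with linear physical scaling. This implementation
## covers the plain-EDF subset needed here: one data record holding every
## signal, one signal per segment. Values survive a round trip to within the
## per-signal quantization step (physical range / 2^15).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

edf_num <- function(x, width = 8) {
  s <- formatC(x, digits = 6, width = 1, format = "g")
  if (nchar(s) > width) s <- formatC(x, digits = 4, width = 1, format = "g")
  edf_pad(s, width)
}

#' Write signal segments to an EDF file
#'
#' All segments must share a sampling rate and length; each becomes one EDF
#' signal (channel) whose label carries the segment id and stage label. One
#' data record spanning the whole segment duration is written.
#'
#' @param dataset a `labeled_dataset` or list of [signal_segment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(dataset, path) {
  segments <- if (inherits(dataset, "labeled_dataset")) dataset$segments else dataset
  ns <- length(segments)
  if (ns == 0) stop("no segments to write", call. = FALSE)
  n <- length(segments[[1]]$samples)
  fs <- segments[[1]]$fs
  for (s in segments)
    if (length(s$samples) != n || s$fs != fs)
      stop("all segments must share length and sampling rate for EDF output",
           call. = FALSE)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("synthetic", 80),
    edf_pad("eegcluster export", 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8),
    edf_pad("", 44),
    edf_pad(1, 8),
    edf_num(n / fs, 8),
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)

  ## EDF signal labels are 16 ASCII chars; the stage goes first so it
  ## survives truncation of long segment ids
  labels <- vapply(segments, function(s) {
    lab <- if (is.null(s$stage_label)) s$id
           else sprintf("c%d %s", s$stage_label, s$id)
    edf_pad(lab, 16)
  }, character(1))
  pmaxs <- vapply(segments, function(s) max(abs(s$samples), 1e-6), numeric(1))
  ## symmetric physical range, printed at full 8-char precision
  pm_str <- vapply(pmaxs, edf_num, character(1))
  pmaxs <- as.numeric(pm_str)               # use the printed value for scaling

  field <- function(f, w) writeChar(paste(vapply(seq_len(ns), f, character(1)),
                                          collapse = ""), con, eos = NULL)
  field(function(i) labels[i], 16)
  field(function(i) edf_pad("", 80), 80)
  field(function(i) edf_pad("uV", 8), 8)
  field(function(i) edf_pad(paste0("-", trimws(pm_str[i])), 8), 8)
  field(function(i) pm_str[i], 8)
  field(function(i) edf_pad(-32768, 8), 8)
  field(function(i) edf_pad(32767, 8), 8)
  field(function(i) edf_pad("", 80), 80)
  field(function(i) edf_pad(n, 8), 8)
  field(function(i) edf_pad("", 32), 32)

  for (i in seq_len(ns)) {
    x <- segments[[i]]$samples
    ## same linear calibration the reader applies: phys range
    ## [-pmax, pmax] onto digital [-32768, 32767]
    dig <- as.integer(round((x + pmaxs[i]) / (2 * pmaxs[i]) * 65535 - 32768))
    dig <- pmax(pmin(dig, 32767L), -32768L)
    writeBin(dig, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into signal segments
#'
#' Plain-EDF reader for continuous recordings: concatenates all data records
#' per signal and applies the physical calibration from the header. The
#' sampling rate is samples-per-record / record-duration.
#'
#' @param path EDF file path.
#' @return list of [signal_segment()], one per EDF signal.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  ver <- rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header in ", path, call. = FALSE)
  sig_field <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- sig_field(16); sig_field(80); sig_field(8)
  pmin <- as.numeric(sig_field(8)); pmax <- as.numeric(sig_field(8))
  dmin <- as.numeric(sig_field(8)); dmax <- as.numeric(sig_field(8))
  sig_field(80)
  spr <- as.integer(sig_field(8)); sig_field(32)

  seek(con, hdr_bytes)
  raw <- vector("list", ns)
  for (i in seq_len(ns)) raw[[i]] <- numeric(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2, endian = "little")
      raw[[i]] <- c(raw[[i]], dig)
    }
  }
  lapply(seq_len(ns), function(i) {
    phys <- pmin[i] + (raw[[i]] - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    lab <- labels[i]
    stage <- NULL
    m <- regmatches(lab, regexec("^c(\\d+) ", lab))[[1]]
    if (length(m) == 2) {
      stage <- as.integer(m[2])
      lab <- sub("^c\\d+ ", "", lab)
    }
    signal_segment(phys, spr[i] / rec_dur, id = lab, stage_label = stage)
  })
}
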