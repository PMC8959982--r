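# Minimal EDF (European Data Format) reader/writer.
#
# EDF stores an ASCII header (256 bytes + 256 per signal) followed by data
# records of 16-bit little-endian integers, mapped linearly between each
# signal's digital and physical ranges. The writer emits one data record per
# second when the duration is a whole number of seconds, otherwise a single
# record spanning the recording.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  sprintf("%-*s", width, s)
}

#' Write an EEG recording to an EDF file
#'
#' The subject id is stored in the patient-identification field and the group
#' label in the recording-identification field, so a round trip preserves
#' both. Samples are quantized to the 16-bit digital range spanning each
#' channel's physical min/max.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  nc <- nrow(rec$data); n <- ncol(rec$data)
  whole_seconds <- abs(n / rec$fs - round(n / rec$fs)) < 1e-9 &&
    abs(rec$fs - round(rec$fs)) < 1e-9
  if (whole_seconds) {
    rec_dur <- 1
    spr <- as.integer(round(rec$fs))
    n_rec <- as.integer(round(n / rec$fs))
  } else {
    rec_dur <- n / rec$fs
    spr <- n
    n_rec <- 1L
  }
  pmin <- apply(rec$data, 1L, min)
  pmax <- apply(rec$data, 1L, max)
  flat <- pmax - pmin < 1e-12
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32767L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(rec$subject_id, 80),
    pad_field(paste0("group=", rec$group), 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (nc + 1), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(format(rec_dur, digits = 8), 8),
    pad_field(nc, 4))
  sig_hdr <- paste0(
    paste(vapply(rec$channel_labels, pad_field, "", width = 16), collapse = ""),
    paste(rep(pad_field("", 80), nc), collapse = ""),
    paste(rep(pad_field("uV", 8), nc), collapse = ""),
    paste(vapply(pmin, function(v) pad_field(signif(v, 7), 8), ""), collapse = ""),
    paste(vapply(pmax, function(v) pad_field(signif(v, 7), 8), ""), collapse = ""),
    paste(rep(pad_field(dmin, 8), nc), collapse = ""),
    paste(rep(pad_field(dmax, 8), nc), collapse = ""),
    paste(rep(pad_field("", 80), nc), collapse = ""),
    paste(rep(pad_field(spr, 8), nc), collapse = ""),
    paste(rep(pad_field("", 32), nc), collapse = ""))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  # header stores signif(pmin/pmax, 7); quantize against the stored values
  pmin_s <- as.numeric(signif(pmin, 7)); pmax_s <- as.numeric(signif(pmax, 7))
  scale <- (dmax - dmin) / (pmax_s - pmin_s)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ci in seq_len(nc)) {
      dig <- as.integer(round((rec$data[ci, idx] - pmin_s[ci]) * scale[ci]) + dmin)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf_field <- function(raw, offset, width, name, numeric = FALSE) {
  s <- trimws(rawToChar(raw[(offset + 1L):(offset + width)]))
  if (numeric) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v))
      stop("malformed EDF header: field '", name, "' is not numeric (got '",
           s, "')")
    return(v)
  }
  s
}

#' Read an EDF file into an EEG recording
#'
#' @param path EDF file path.
#' @param channels optional channel labels to keep (in the given order); an
#'   error lists any configured label missing from the file.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, channels = NULL) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 256) stop("malformed EDF header: file shorter than 256 bytes")
  n_rec <- read_edf_field(raw, 236, 8, "number of data records", numeric = TRUE)
  rec_dur <- read_edf_field(raw, 244, 8, "data record duration", numeric = TRUE)
  ns <- read_edf_field(raw, 252, 4, "number of signals", numeric = TRUE)
  if (ns < 1) stop("malformed EDF header: number of signals must be >= 1")
  hdr_bytes <- 256L + 256L * ns
  if (length(raw) < hdr_bytes) stop("malformed EDF header: truncated signal headers")
  subject_id <- read_edf_field(raw, 8, 80, "patient id")
  rec_id <- read_edf_field(raw, 88, 80, "recording id")
  group <- if (startsWith(rec_id, "group=")) sub("^group=", "", rec_id) else NA_character_

  off <- 256L
  fld <- function(width, name, numeric = FALSE) {
    out <- vapply(seq_len(ns), function(i)
      read_edf_field(raw, off + (i - 1L) * width, width,
                     paste0(name, "[", i, "]"), numeric = FALSE), "")
    off <<- off + ns * width
    if (numeric) {
      v <- suppressWarnings(as.numeric(out))
      if (any(is.na(v)))
        stop("malformed EDF header: field '", name, "' is not numeric")
      return(v)
    }
    out
  }
  labels <- fld(16, "label")
  fld(80, "transducer"); fld(8, "physical dimension")
  pmin <- fld(8, "physical minimum", numeric = TRUE)
  pmax <- fld(8, "physical maximum", numeric = TRUE)
  dmin <- fld(8, "digital minimum", numeric = TRUE)
  dmax <- fld(8, "digital maximum", numeric = TRUE)
  fld(80, "prefiltering")
  spr <- fld(8, "samples per record", numeric = TRUE)
  if (length(unique(spr)) != 1L)
    stop("EDF files with per-signal sampling rates are not supported")
  spr <- spr[1]
  fs <- spr / rec_dur

  dat <- readBin(raw[(hdr_bytes + 1L):length(raw)], "integer",
                 n = n_rec * ns * spr, size = 2L, signed = TRUE,
                 endian = "little")
  x <- matrix(0, ns, n_rec * spr)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (ci in seq_len(ns)) {
      seg <- dat[(pos + 1L):(pos + spr)]
      pos <- pos + as.integer(spr)
      phys <- (seg - dmin[ci]) * (pmax[ci] - pmin[ci]) / (dmax[ci] - dmin[ci]) +
        pmin[ci]
      x[ci, ((r - 1L) * spr + 1L):(r * spr)] <- phys
    }
  }
  rec <- eeg_recording(x, fs, labels, subject_id = subject_id, group = group)
  if (!is.null(channels)) rec <- select_channels(rec, channels)
  rec
}
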