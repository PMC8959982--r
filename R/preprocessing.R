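#' Preprocess a raw EEG recording
#'
#' Applies, in order: common average reference (each sample has the
#' across-channel mean subtracted), selection of the contiguous
#' `window_seconds` window with the highest signal-to-noise proxy, zero-phase
#' 0.1--30 Hz band-pass filtering, and per-channel z-scoring.
#'
#' The SNR proxy for window selection is the ratio of 0.5--30 Hz band power
#' to total power, evaluated on sliding windows with a 1 s stride;
#' artifact-heavy stretches carry broadband/DC energy and score low. Window
#' selection happens before the band-pass (after filtering the proxy would be
#' constant), and z-scoring comes last so retained channels have mean 0, SD 1.
#'
#' @param rec an [eeg_recording()].
#' @param window_seconds retained window length in seconds (default 80).
#' @param lo,hi band-pass edges in Hz.
#' @return The preprocessed [eeg_recording()] of length `window_seconds`.
#' @export
preprocess <- function(rec, window_seconds = 80, lo = 0.1, hi = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$data)
  win <- round(window_seconds * rec$fs)
  if (n < win)
    stop("recording is ", sprintf("%.1f", n / rec$fs), " s but ",
         window_seconds, " s are required")
  x <- average_reference(rec$data)
  if (n > win) {
    stride <- max(1L, round(rec$fs))
    starts <- unique(c(seq(1L, n - win + 1L, by = stride), n - win + 1L))
    snr <- vapply(starts, function(s) {
      w <- x[, s:(s + win - 1L), drop = FALSE]
      inband <- fft_bandpass_rows(w, rec$fs, 0.5, 30)
      sum(inband^2) / max(sum(w^2), .Machine$double.eps)
    }, 0)
    s <- starts[which.max(snr)]
    x <- x[, s:(s + win - 1L), drop = FALSE]
  }
  x <- fft_bandpass_rows(x, rec$fs, lo, hi)
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  sdv[sdv < .Machine$double.eps] <- 1
  x <- (x - mu) / sdv
  eeg_recording(x, rec$fs, rec$channel_labels, rec$subject_id, rec$group)
}

# Common average reference: subtract the across-channel mean at every sample.
average_reference <- function(x) sweep(x, 2L, colMeans(x))

#' Split a recording into equal contiguous segments
#'
#' Trailing samples that do not fill a complete segment are dropped.
#'
#' @param rec an [eeg_recording()].
#' @param n_segments number of segments (default 4).
#' @return list of `eeg_segment` objects, in temporal order, with
#'   `segment_index` running 1..`n_segments`.
#' @export
split_segments <- function(rec, n_segments = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(is.numeric(n_segments) && n_segments >= 1))
    stop("n_segments must be >= 1")
  n_segments <- as.integer(n_segments)
  len <- ncol(rec$data) %/% n_segments
  if (len < 1) stop("recording too short for ", n_segments, " segments")
  lapply(seq_len(n_segments), function(k) {
    idx <- ((k - 1L) * len + 1L):(k * len)
    new_segment(rec$data[, idx, drop = FALSE], rec$fs, k,
                rec$subject_id, rec$group)
  })
}

#' Select and reorder channels
#'
#' @param rec an [eeg_recording()].
#' @param labels channel labels to keep, in the desired order.
#' @return An [eeg_recording()] with exactly those channels.
#' @export
select_channels <- function(rec, labels) {
  stopifnot(inherits(rec, "eeg_recording"))
  miss <- setdiff(labels, rec$channel_labels)
  if (length(miss) > 0)
    stop("channel label(s) not present in recording: ",
         paste(miss, collapse = ", "))
  idx <- match(labels, rec$channel_labels)
  eeg_recording(rec$data[idx, , drop = FALSE], rec$fs, labels,
                rec$subject_id, rec$group)
}

#' Band-pass filter a segment to one frequency band
#'
#' Zero-phase filtering; the returned segment carries the band tag.
#'
#' @param seg an `eeg_segment`.
#' @param band a band name or [band_def()] row.
#' @return The filtered, band-tagged `eeg_segment`.
#' @export
bandpass_band <- function(seg, band) {
  stopifnot(inherits(seg, "eeg_segment"))
  band <- resolve_band(band)
  if (seg$fs <= 2 * band$hi)
    stop("band ", band$name, " (hi = ", band$hi,
         " Hz) violates Nyquist at fs = ", seg$fs, " Hz")
  out <- seg
  out$data <- fft_bandpass_rows(seg$data, seg$fs, band$lo, band$hi)
  out$band <- band
  out
}
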