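#' Construct an EEG recording object
#'
#' The basic container for one subject's multichannel time series.
#'
#' @param data channels x samples numeric matrix, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per row of `data`.
#' @param subject_id subject identifier.
#' @param group group label (e.g. `"SCZ"` / `"HC"`), or `NA` if unknown.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels, subject_id = NA_character_,
                          group = NA_character_) {
  data <- as.matrix(data)
  if (nrow(data) != length(channel_labels))
    stop("data has ", nrow(data), " rows but ", length(channel_labels),
         " channel labels were given")
  if (!all(is.finite(data)))
    stop("recording contains non-finite samples")
  if (!(is.numeric(fs) && length(fs) == 1L && fs > 0))
    stop("fs must be a positive scalar (Hz)")
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = as.character(channel_labels),
         subject_id = as.character(subject_id), group = as.character(group)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> subject %s (group %s): %d channels x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$group, nrow(x$data), ncol(x$data), x$fs,
    ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

# One of the equal-length pieces of a recording (optionally band-filtered).
new_segment <- function(data, fs, segment_index, subject_id, group,
                        band = NULL) {
  structure(
    list(data = data, fs = fs, band = band,
         segment_index = as.integer(segment_index),
         subject_id = subject_id, group = group),
    class = "eeg_segment"
  )
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf(
    "<eeg_segment> subject %s segment %d: %d channels x %d samples @ %g Hz%s\n",
    x$subject_id, x$segment_index, nrow(x$data), ncol(x$data), x$fs,
    if (is.null(x$band)) "" else paste0(" [", x$band$name, " band]")))
  invisible(x)
}

#' Duration of a recording or segment in seconds
#' @param x an `eeg_recording` or `eeg_segment`.
#' @return duration in seconds.
#' @export
duration_s <- function(x) ncol(x$data) / x$fs
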