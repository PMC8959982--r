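#' Canonical EEG frequency bands
#'
#' The five clinical bands used throughout the pipeline: delta 0.5--4 Hz,
#' theta 4--8 Hz, alpha 8--13 Hz, beta1 13--20 Hz, beta2 20--30 Hz.
#'
#' @param names optional character vector selecting a subset (in the given
#'   order); defaults to all five bands.
#' @return A data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
#' @examples
#' eeg_bands()
#' eeg_bands(c("alpha", "beta1", "beta2"))
eeg_bands <- function(names = NULL) {
  tab <- data.frame(
    name = c("delta", "theta", "alpha", "beta1", "beta2"),
    lo   = c(0.5, 4, 8, 13, 20),
    hi   = c(4, 8, 13, 20, 30),
    stringsAsFactors = FALSE
  )
  if (is.null(names)) return(tab)
  miss <- setdiff(names, tab$name)
  if (length(miss) > 0)
    stop("unknown band(s): ", paste(miss, collapse = ", "),
         "; valid bands are ", paste(tab$name, collapse = ", "))
  tab[match(names, tab$name), , drop = FALSE]
}

#' Define a frequency band
#'
#' @param name band label.
#' @param lo,hi band edges in Hz, `0 < lo < hi <= 30`.
#' @return A one-row band data.frame as in [eeg_bands()].
#' @export
band_def <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(is.numeric(lo) && is.numeric(hi) && lo > 0 && lo < hi && hi <= 30))
    stop("band edges must satisfy 0 < lo < hi <= 30 Hz (got lo=", lo,
         ", hi=", hi, ")")
  data.frame(name = name, lo = lo, hi = hi, stringsAsFactors = FALSE)
}

# Resolve a band argument (name or one-row band data.frame) to a one-row band.
resolve_band <- function(band) {
  if (is.character(band)) return(eeg_bands(band))
  stopifnot(is.data.frame(band), nrow(band) == 1L,
            all(c("name", "lo", "hi") %in% names(band)))
  band
}

# Band center frequency, the wavelet analysis frequency for that band.
band_center <- function(band) {
  band <- resolve_band(band)
  (band$lo + band$hi) / 2
}
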