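# Zero-phase band-pass filtering, done in the frequency domain.
#
# A real FFT gain profile is exactly zero-phase, is unconditionally stable,
# and keeps its shape at very low normalized edges (0.1 Hz at fs = 1000 Hz),
# where cascaded IIR designs lose double precision. Transition bands are
# raised-cosine ramps so the impulse response decays quickly.

# Gain profile over the (two-sided) FFT frequency grid.
fft_band_gain <- function(n, fs, lo, hi, transition) {
  f <- c(seq.int(0L, floor(n / 2)), seq.int(-(ceiling(n / 2) - 1L), -1L)) * fs / n
  af <- abs(f)
  g <- as.numeric(af >= lo & af <= hi)
  if (lo > 0) {
    tw <- min(transition, lo)  # ramp cannot cross 0 Hz
    ramp <- af > lo - tw & af < lo
    g[ramp] <- 0.5 * (1 + cos(pi * (lo - af[ramp]) / tw))
  }
  tw <- transition
  ramp <- af > hi & af < hi + tw
  g[ramp] <- 0.5 * (1 + cos(pi * (af[ramp] - hi) / tw))
  g
}

# Band-pass one channel. `transition` is the half-power transition width in Hz.
fft_bandpass <- function(x, fs, lo, hi, transition = 0.5) {
  n <- length(x)
  if (hi >= fs / 2)
    stop("band upper edge ", hi, " Hz violates Nyquist (fs/2 = ", fs / 2, " Hz)")
  g <- fft_band_gain(n, fs, lo, hi, transition)
  Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
}

# Band-pass each row of a channels x samples matrix.
fft_bandpass_rows <- function(x, fs, lo, hi, transition = 0.5) {
  t(apply(x, 1L, fft_bandpass, fs = fs, lo = lo, hi = hi,
          transition = transition))
}
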