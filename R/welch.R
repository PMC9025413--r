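#' Welch power spectral density estimate
#'
#' Averaged modified periodograms: the signal is cut into overlapping
#' segments, each segment is mean-detrended, tapered, and its periodogram
#' computed; the periodograms are averaged and scaled to a one-sided density
#' (units input^2 per Hz). The zero-frequency bin is dropped: after
#' detrending its estimate can be zero or negative, and the log target of
#' band discovery is undefined there.
#'
#' @param samples Numeric vector of time-series samples, all finite.
#' @param fs Sampling rate in Hz.
#' @param segment_length Samples per segment (default 1028). The returned
#'   grid has spacing `fs / segment_length`.
#' @param window Taper name: `"hann"` (default, periodic), `"hamming"`, or
#'   `"boxcar"`.
#' @param overlap Fraction of segment overlap in `[0, 1)`; default 0.5.
#' @return A [power_spectrum()] on the one-sided Welch grid (DC dropped,
#'   Nyquist kept when `segment_length` is even).
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 10, by = 1 / 250))
#' s <- welch_psd(x, fs = 250, segment_length = 512)
#' s$frequencies[which.max(s$psd)]  # ~10 Hz
welch_psd <- function(samples, fs, segment_length = 1028L,
                      window = c("hann", "hamming", "boxcar"),
                      overlap = 0.5) {
  window <- match.arg(window)
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("`samples` must be finite")
  }
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be > 0")
  segment_length <- as.integer(segment_length)
  if (segment_length < 2L) stop("`segment_length` must be >= 2")
  if (length(samples) < segment_length) {
    stop("signal shorter than one segment (", length(samples), " < ",
         segment_length, " samples)")
  }
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)")

  w <- taper_window(window, segment_length)
  step <- max(1L, as.integer(round(segment_length * (1 - overlap))))
  starts <- seq.int(1L, length(samples) - segment_length + 1L, by = step)
  half <- segment_length %/% 2L
  nbins <- half + 1L

  # average of |FFT|^2 of mean-detrended, tapered segments
  acc <- numeric(nbins)
  for (s0 in starts) {
    seg <- samples[s0:(s0 + segment_length - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nbins)]
    acc <- acc + Re(X)^2 + Im(X)^2
  }
  pxx <- acc / length(starts) / (fs * sum(w^2))
  # one-sided: double everything except DC and (even-length) Nyquist
  dbl <- seq.int(2L, nbins - if (segment_length %% 2L == 0L) 1L else 0L)
  pxx[dbl] <- 2 * pxx[dbl]

  freqs <- (seq_len(nbins) - 1L) * fs / segment_length
  power_spectrum(freqs[-1L], pxx[-1L])
}

# taper of length n; hann/hamming are periodic (DFT-even), the spectral
# convention
taper_window <- function(window, n) {
  i <- 0:(n - 1L)
  switch(window,
         hann = 0.5 - 0.5 * cos(2 * pi * i / n),
         hamming = 0.54 - 0.46 * cos(2 * pi * i / n),
         boxcar = rep(1, n))
}
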