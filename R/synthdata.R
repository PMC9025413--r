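# run `expr` under a seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate the artificial 1/f power spectrum
#'
#' Synthesises the broadband EEG-like test spectrum: power values
#' `P_i = 1/f_i + U_i` on an evenly spaced frequency grid, with `U_i`
#' independent Uniform[0, `noise_high`) draws. The defaults (150 frequencies
#' on 0.2-30 Hz, noise amplitude 0.4) define the artificial case-study
#' conditions used throughout the package's tests.
#'
#' @param n_freqs Number of grid frequencies (default 150).
#' @param fmin,fmax Grid range in Hz (defaults 0.2 and 30; the lower edge is
#'   kept above zero so 1/f stays finite).
#' @param noise_high Upper limit of the uniform noise (default 0.4; 0 gives
#'   the exact 1/f curve).
#' @param seed Optional integer seed; the same seed reproduces the spectrum
#'   bit-for-bit without touching the caller's RNG state.
#' @return A [power_spectrum()] with `n_freqs` frequencies.
#' @export
#' @examples
#' s <- generate_artificial_spectrum(seed = 42)
#' n_freq(s)  # 150
generate_artificial_spectrum <- function(n_freqs = 150L, fmin = 0.2,
                                         fmax = 30, noise_high = 0.4,
                                         seed = NULL) {
  n_freqs <- as.integer(n_freqs)
  if (n_freqs < 2L) stop("`n_freqs` must be >= 2")
  if (!(fmin > 0 && fmin < fmax)) stop("need 0 < fmin < fmax")
  if (noise_high < 0) stop("`noise_high` must be >= 0")
  f <- seq(fmin, fmax, length.out = n_freqs)
  noise <- .with_seed(seed, stats::runif(n_freqs, 0, noise_high))
  if (noise_high == 0) noise <- numeric(n_freqs)
  power_spectrum(f, 1 / f + noise)
}

#' Generate an EEG-like test signal with an alpha peak
#'
#' A sinusoid at `alpha_freq` plus white Gaussian noise: a minimal stand-in
#' for an occipital EEG recording whose spectrum shows a single alpha-rhythm
#' peak over a flat noise floor. Used to exercise the full Welch-to-discovery
#' pipeline end to end with a known spectral feature.
#'
#' @param fs Sampling rate in Hz; must exceed `2 * alpha_freq`.
#' @param duration Signal length in seconds (default 60).
#' @param alpha_freq Peak frequency in Hz (default 10).
#' @param alpha_amp Sinusoid amplitude (default 2).
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (default 1).
#' @param seed Optional integer seed (see [generate_artificial_spectrum()]).
#' @return Numeric vector of `fs * duration` samples.
#' @export
generate_eeg_like_signal <- function(fs = 500, duration = 60,
                                     alpha_freq = 10, alpha_amp = 2,
                                     noise_sd = 1, seed = NULL) {
  if (fs <= 2 * alpha_freq) {
    stop("`fs` must exceed 2 * alpha_freq (", 2 * alpha_freq,
         " Hz) to avoid aliasing")
  }
  if (duration <= 0 || noise_sd < 0 || alpha_amp < 0) {
    stop("`duration` must be > 0 and amplitudes >= 0")
  }
  n <- round(fs * duration)
  t <- seq_len(n) / fs
  noise <- .with_seed(seed, stats::rnorm(n, 0, noise_sd))
  if (noise_sd == 0) noise <- numeric(n)
  alpha_amp * sin(2 * pi * alpha_freq * t) + noise
}
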