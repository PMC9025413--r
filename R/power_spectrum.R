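#' Construct a power spectrum
#'
#' A `power_spectrum` is the sole input to band discovery: a strictly
#' increasing frequency grid paired with strictly positive power spectral
#' density values. Positivity is required because the regression target of the
#' band-discovery model is the natural logarithm of the PSD.
#'
#' @param frequencies Numeric vector of frequencies in Hz, strictly
#'   increasing, length at least 2.
#' @param psd Numeric vector of power spectral density values, finite and
#'   strictly positive, same length as `frequencies`. Units are
#'   input-squared per Hz for Welch estimates, or arbitrary for synthetic
#'   spectra; all band-discovery arithmetic is unit-free.
#'
#' @return An object of class `power_spectrum`: a list with elements
#'   `frequencies` and `psd`.
#' @export
#' @examples
#' s <- power_spectrum(1:10, 1 / (1:10))
#' n_freq(s)
power_spectrum <- function(frequencies, psd) {
  frequencies <- as.numeric(frequencies)
  psd <- as.numeric(psd)
  if (length(frequencies) != length(psd)) {
    stop("`frequencies` and `psd` must have the same length (",
         length(frequencies), " vs ", length(psd), ")")
  }
  if (length(frequencies) < 2L) {
    stop("a power spectrum needs at least 2 frequencies")
  }
  if (anyNA(frequencies) || any(!is.finite(frequencies))) {
    stop("`frequencies` must be finite")
  }
  if (any(diff(frequencies) <= 0)) {
    stop("`frequencies` must be strictly increasing with no duplicates")
  }
  if (anyNA(psd) || any(!is.finite(psd))) {
    stop("`psd` must be finite")
  }
  if (any(psd <= 0)) {
    bad <- frequencies[which(psd <= 0)[1L]]
    stop("`psd` must be strictly positive everywhere (log target undefined); ",
         "first offending frequency: ", format(bad), " Hz")
  }
  structure(list(frequencies = frequencies, psd = psd),
            class = "power_spectrum")
}

#' Number of frequencies in a spectrum
#'
#' @param spectrum A [power_spectrum()].
#' @return Integer count of (unique) frequency grid points; this is the `N`
#'   of the quality score and the maximum possible band count.
#' @export
n_freq <- function(spectrum) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  length(spectrum$frequencies)
}

#' Natural-log PSD regression target
#'
#' Returns the element-wise natural logarithm of the PSD, the target variable
#' of the band-discovery regression (one value per grid frequency).
#'
#' @param spectrum A [power_spectrum()].
#' @return Numeric vector, `ln psd`, same length as the frequency grid.
#' @export
#' @examples
#' log_power(power_spectrum(1:3, exp(0:2)))  # 0 1 2
log_power <- function(spectrum) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (any(spectrum$psd <= 0)) {
    bad <- spectrum$frequencies[which(spectrum$psd <= 0)[1L]]
    stop("psd must be > 0 to take the log; offending frequency: ",
         format(bad), " Hz")
  }
  log(spectrum$psd)
}

#' Restrict a spectrum to a frequency range
#'
#' Keeps grid points with `fmin <= f <= fmax`, preserving order. Errors if
#' fewer than two frequencies survive.
#'
#' @param spectrum A [power_spectrum()].
#' @param fmin,fmax Range limits in Hz, `fmin < fmax`.
#' @return A `power_spectrum` on the surviving sub-grid.
#' @export
restrict_spectrum <- function(spectrum, fmin, fmax) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (!is.numeric(fmin) || !is.numeric(fmax) || fmin >= fmax) {
    stop("need fmin < fmax")
  }
  keep <- spectrum$frequencies >= fmin & spectrum$frequencies <= fmax
  if (sum(keep) < 2L) {
    stop("fewer than 2 frequencies in [", fmin, ", ", fmax, "] Hz")
  }
  power_spectrum(spectrum$frequencies[keep], spectrum$psd[keep])
}

#' Average multiple channels into one signal
#'
#' Point-wise arithmetic mean of equal-length time series, e.g. averaging the
#' occipital electrodes O1 and O2 into a single aggregated signal before
#' spectral estimation.
#'
#' @param signals A list of equal-length numeric vectors, or a numeric matrix
#'   with one column per channel.
#' @return Numeric vector, the point-wise mean.
#' @export
aggregate_channels <- function(signals) {
  if (is.matrix(signals)) {
    signals <- lapply(seq_len(ncol(signals)), function(j) signals[, j])
  }
  if (!is.list(signals) || length(signals) < 1L) {
    stop("`signals` must be a non-empty list of numeric vectors or a matrix")
  }
  lens <- lengths(signals)
  if (length(unique(lens)) != 1L) {
    stop("all channels must have the same length (got lengths ",
         paste(unique(lens), collapse = ", "), ")")
  }
  Reduce(`+`, lapply(signals, as.numeric)) / length(signals)
}

#' @export
print.power_spectrum <- function(x, ...) {
  f <- x$frequencies
  cat(sprintf("power_spectrum: %d frequencies, %.4g-%.4g Hz\n",
              length(f), f[1L], f[length(f)]))
  cat(sprintf("  psd range: [%.4g, %.4g]\n", min(x$psd), max(x$psd)))
  invisible(x)
}

#' @export
as.data.frame.power_spectrum <- function(x, ...) {
  data.frame(frequency_hz = x$frequencies, psd = x$psd)
}

#' Plot a power spectrum
#'
#' @param x A [power_spectrum()].
#' @param log Logical; plot natural-log PSD (default) or raw PSD.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.power_spectrum <- function(x, log = TRUE, ...) {
  y <- if (log) log_power(x) else x$psd
  graphics::plot(x$frequencies, y, type = "l", xlab = "frequency (Hz)",
                 ylab = if (log) "ln PSD" else "PSD", ...)
  invisible(x)
}
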