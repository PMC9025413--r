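#' Read and write the CSV spectrum format
#'
#' Two columns, `frequency_hz,psd`, header required, one row per frequency
#' in ascending order.
#'
#' @param path File path.
#' @return `read_spectrum_csv()` returns a [power_spectrum()];
#'   `write_spectrum_csv()` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("frequency_hz", "psd")
  if (!all(need %in% names(df))) {
    stop("spectrum CSV must have columns `frequency_hz` and `psd` (found: ",
         paste(names(df), collapse = ", "), ")")
  }
  power_spectrum(df$frequency_hz, df$psd)
}

#' @rdname read_spectrum_csv
#' @param spectrum A [power_spectrum()].
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  utils::write.csv(as.data.frame(spectrum), path, row.names = FALSE)
  invisible(path)
}

#' Read and write band sets as JSON
#'
#' Schema: `{"names": [...], "edges_hz": [...]}`.
#'
#' @param path File path.
#' @return `read_band_set()` returns a [band_set()]; the writer returns
#'   `path` invisibly.
#' @export
read_band_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$names) || is.null(obj$edges_hz)) {
    stop("band-set JSON must have fields `names` and `edges_hz`")
  }
  band_set(obj$names, obj$edges_hz)
}

#' @rdname read_band_set
#' @param bandset A [band_set()].
#' @export
write_band_set <- function(bandset, path) {
  stopifnot(inherits(bandset, "band_set"))
  jsonlite::write_json(list(names = bandset$names, edges_hz = bandset$edges),
                       path, auto_unbox = FALSE, digits = I(12), pretty = TRUE)
  invisible(path)
}

#' Write a band report as JSON
#'
#' Self-contained record of a partition: band count, interior boundaries,
#' per-band mean targets, fit statistics and the spectrum size, so that QS
#' can be recomputed from the report alone. Keys are emitted in a fixed
#' order and floats with 12 significant digits, so identical partitions give
#' byte-identical files.
#'
#' @param partition A `band_partition`.
#' @param path File path.
#' @return `path`, invisibly; `read_band_report()` returns the parsed list.
#' @export
write_band_report <- function(partition, path) {
  stopifnot(inherits(partition, "band_partition"))
  qs <- partition$qs
  if (is.null(qs)) qs <- quality_score(partition$r2, partition$k, partition$n)
  report <- list(
    k = partition$k,
    boundaries_hz = as.numeric(partition$boundaries),
    band_means_ln_psd = as.numeric(partition$band_means),
    r2 = partition$r2,
    sse = partition$sse,
    qs = qs,
    n = partition$n
  )
  if (!is.null(partition$band_names)) report$band_names <- partition$band_names
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = I(12),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_band_report
#' @export
read_band_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a quality curve as CSV
#'
#' Columns `k,r2,qs`, one row per evaluated band count.
#'
#' @param curve A `quality_curve` from [select_band_count()].
#' @param path File path.
#' @return `path`, invisibly; `read_quality_curve()` returns a data frame.
#' @export
write_quality_curve <- function(curve, path) {
  stopifnot(inherits(curve, "quality_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_quality_curve
#' @export
read_quality_curve <- function(path) {
  utils::read.csv(path)
}

#' Read selected channels from an EDF recording
#'
#' Loads one or more channels from a European Data Format file by
#' case-insensitive label match (e.g. `c("O1", "O2")`). Requires the
#' optional `edfReader` package.
#'
#' @param path EDF file path.
#' @param channels Character vector of channel labels.
#' @return A list with `signals` (list of numeric vectors, one per requested
#'   channel) and `fs` (sampling rate in Hz).
#' @export
read_edf_channels <- function(path, channels) {
  if (!requireNamespace("edfReader", quietly = TRUE)) {
    stop("reading EDF files requires the optional `edfReader` package; ",
         "alternatively supply a CSV spectrum (see read_spectrum_csv)")
  }
  hdr <- edfReader::readEdfHeader(path)
  sig <- edfReader::readEdfSignals(hdr)
  labels <- vapply(sig, function(s) s$label, character(1))
  idx <- match(tolower(channels), tolower(trimws(labels)))
  if (anyNA(idx)) {
    stop("channel(s) not found: ",
         paste(channels[is.na(idx)], collapse = ", "),
         "; available: ", paste(trimws(labels), collapse = ", "))
  }
  fs <- unique(vapply(sig[idx], function(s) s$sRate, numeric(1)))
  if (length(fs) != 1L) stop("requested channels have differing sample rates")
  list(signals = lapply(sig[idx], function(s) as.numeric(s$signal)), fs = fs)
}
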