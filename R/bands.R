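#' Construct a named band set
#'
#' A fixed set of named, contiguous frequency bands: `length(names) + 1`
#' strictly increasing edge frequencies, band `i` spanning
#' `[edges[i], edges[i+1])` (the last band closed). Used to evaluate
#' conventional band definitions (delta/theta/alpha/beta) against a spectrum
#' with the same r2/QS machinery as discovered partitions.
#'
#' @param names Character vector of band labels.
#' @param edges Numeric vector of boundary frequencies in Hz, strictly
#'   increasing, one longer than `names`.
#' @return An object of class `band_set`.
#' @export
#' @examples
#' band_set(c("low", "high"), c(1, 10, 30))
band_set <- function(names, edges) {
  names <- as.character(names)
  edges <- as.numeric(edges)
  if (length(edges) != length(names) + 1L) {
    stop("`edges` must have exactly length(names) + 1 = ",
         length(names) + 1L, " values (got ", length(edges), ")")
  }
  if (anyNA(edges) || any(!is.finite(edges))) stop("`edges` must be finite")
  if (any(diff(edges) <= 0)) stop("`edges` must be strictly increasing")
  if (anyNA(names) || any(names == "")) stop("band names must be non-empty")
  structure(list(names = names, edges = edges), class = "band_set")
}

#' Canonical delta/theta/alpha/beta band set
#'
#' The conventional four EEG bands with the widely used boundaries
#' delta [1, 4), theta [4, 8), alpha [8, 12), beta [12, 30) Hz. These are a
#' configurable default: reported boundaries vary by about +/- 1 Hz across
#' the literature.
#'
#' @return A [band_set()] with 4 names and 5 edges.
#' @export
default_standard_bands <- function() {
  band_set(c("delta", "theta", "alpha", "beta"), c(1, 4, 8, 12, 30))
}

#' Evaluate a fixed band set against a spectrum
#'
#' Assigns every grid frequency to a band and computes the same per-band
#' mean / SSE / r2 statistics as [grow_partition()], plus the quality score
#' with `k` equal to the number of *named* bands. Three conventions handle
#' frequencies outside `[min(edges), max(edges)]`:
#'
#' * `"stretch"` (default): the outermost edges are extended to the
#'   spectrum's range, so out-of-range frequencies join the first/last named
#'   band. Gives a whole-spectrum comparison with exactly k groups.
#' * `"drop"`: out-of-range frequencies are excluded from the evaluation
#'   (SSE, SST and `n` all refer to the covered sub-grid).
#' * `"group"`: out-of-range frequencies below the first edge (and above the
#'   last) form their own flanking residual group(s). They are predicted by
#'   their own mean and counted in SSE/SST/`n`, but `k` in the QS still
#'   counts only the named bands. This is the convention a
#'   digitize-into-edges implementation produces, and the one that
#'   reproduces the reported discovered-versus-standard comparisons.
#'
#' @inheritParams grow_partition
#' @param bandset A [band_set()].
#' @param uncovered How to treat frequencies outside the outermost edges;
#'   see Details.
#' @return A `band_partition` with additional fields `band_names`, `qs`, and
#'   `uncovered`; `boundaries` holds the interior edges actually used.
#' @export
#' @examples
#' s <- generate_artificial_spectrum(seed = 1)
#' evaluate_fixed_bands(s, default_standard_bands(), log = FALSE)
evaluate_fixed_bands <- function(spectrum, bandset, log = TRUE,
                                 uncovered = c("stretch", "drop", "group")) {
  stopifnot(inherits(spectrum, "power_spectrum"),
            inherits(bandset, "band_set"))
  uncovered <- match.arg(uncovered)
  f <- spectrum$frequencies
  y <- .target(spectrum, log)
  edges <- bandset$edges
  k_named <- length(bandset$names)
  labels <- bandset$names

  if (uncovered == "stretch") {
    edges[1L] <- min(edges[1L], f[1L])
    edges[length(edges)] <- max(edges[length(edges)], f[length(f)])
  } else if (uncovered == "drop") {
    keep <- f >= edges[1L] & f <= edges[length(edges)]
    if (sum(keep) < 2L) stop("fewer than 2 frequencies covered by the band set")
    f <- f[keep]
    y <- y[keep]
  }

  # interior boundaries define the groups; flanking groups 0 and k+1 can
  # only be non-empty in "group" mode
  interior <- edges[-c(1L, length(edges))]
  groups <- findInterval(f, edges[-length(edges)], left.open = FALSE)
  groups[f > edges[length(edges)]] <- k_named + 1L
  if (uncovered != "group" && (any(groups == 0L) || any(groups > k_named))) {
    # stretch/drop have already forced coverage; guard against edge cases
    groups <- pmin(pmax(groups, 1L), k_named)
  }

  counts <- tabulate(groups + 1L, nbins = k_named + 2L)  # offset for group 0
  empty <- which(counts[2:(k_named + 1L)] == 0L)
  if (length(empty)) {
    stop("empty band(s) after assignment: ",
         paste(labels[empty], collapse = ", "))
  }

  st <- .group_stats(y, groups)
  sse <- sum(st$sses)
  sst <- .sse_total(y)
  r2 <- if (sst == 0) {
    if (sse == 0) 0 else NA_real_
  } else 1 - sse / sst
  n <- length(y)
  qs <- quality_score(r2, k_named, n)

  structure(list(k = k_named,
                 boundaries = interior,
                 band_means = st$means,
                 band_sizes = st$sizes,
                 band_names = labels,
                 sse = sse,
                 r2 = r2,
                 qs = qs,
                 n = n,
                 uncovered = uncovered),
            class = "band_partition")
}

#' Convert a discovered partition to a named band set
#'
#' Wraps a partition's interior boundaries with the spectrum's range so the
#' partition can be re-evaluated, serialised, or applied to another spectrum
#' as a fixed band set. Band names are `band_1..band_k`.
#'
#' @param partition A `band_partition`.
#' @param spectrum The [power_spectrum()] the partition was grown on (its
#'   range supplies the outer edges).
#' @return A [band_set()].
#' @export
partition_as_bandset <- function(partition, spectrum) {
  stopifnot(inherits(partition, "band_partition"),
            inherits(spectrum, "power_spectrum"))
  f <- spectrum$frequencies
  band_set(paste0("band_", seq_len(partition$k)),
           c(f[1L], partition$boundaries, f[length(f)]))
}

#' @export
print.band_set <- function(x, ...) {
  cat("band_set:", length(x$names), "bands\n")
  for (i in seq_along(x$names)) {
    cat(sprintf("  %-8s [%g, %g) Hz\n", x$names[i], x$edges[i], x$edges[i + 1L]))
  }
  invisible(x)
}
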