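#' AIC-inspired quality score of a band partition
#'
#' `QS = -ln(r2) + 2 k / n`, where `r2` is the coefficient of determination
#' of the k-band piecewise-mean fit and `n` is the total number of observed
#' frequency values (equivalently the maximum band count). Like AIC, smaller
#' is better: the first term rewards fit (it is 0 at r2 = 1, about 2 at
#' r2 = exp(-2) ~= 0.135), the second penalises band count and ranges over
#' (0, 2]. A partition no better than the global-mean model (r2 <= 0) gets
#' `QS = +Inf` and is never selected.
#'
#' @param r2 Coefficient(s) of determination, <= 1.
#' @param k Band count(s), >= 1.
#' @param n Total number of frequency values, `n >= k`.
#' @return Numeric QS value(s); vectorised over `r2` and `k`.
#' @export
#' @examples
#' quality_score(0.94, 6, 150)   # ~0.14
#' quality_score(1, 10, 150)     # exactly 2*10/150
quality_score <- function(r2, k, n) {
  if (any(k < 1)) stop("`k` must be >= 1")
  if (any(n < k)) stop("`n` must be >= `k`")
  ifelse(r2 > 0, -log(r2) + 2 * k / n, Inf)
}

#' Select the band count by quality-score minimisation
#'
#' Runs one nested greedy growth over `k = kmin..kmax`, scores every k with
#' [quality_score()], and returns the partition at the QS-minimising band
#' count together with the full quality curve. Ties on the minimum go to the
#' smallest k (parsimony).
#'
#' @inheritParams grow_partition
#' @param kmin Smallest band count considered; default 2 (a single band has
#'   r2 = 0 and infinite QS, so it is excluded by default; pass `kmin = 1`
#'   to include it).
#' @param kmax Largest band count; default `n_freq(spectrum)`.
#' @return A list with elements `partition` (the `band_partition` at the best
#'   k, with its `qs` attached) and `curve` (a `quality_curve`: `ks`, `r2s`,
#'   `qss`, `best_k`, `n`).
#' @export
#' @examples
#' s <- generate_artificial_spectrum(seed = 1)
#' fit <- select_band_count(s, log = FALSE)
#' fit$curve$best_k
select_band_count <- function(spectrum, kmin = 2L, kmax = NULL, log = TRUE) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  n <- n_freq(spectrum)
  if (is.null(kmax)) kmax <- n
  kmin <- as.integer(kmin)
  kmax <- as.integer(kmax)
  if (kmin < 1L || kmin > kmax || kmax > n) {
    stop("need 1 <= kmin <= kmax <= ", n)
  }
  parts <- grow_nested(spectrum, kmax, log = log)
  ks <- kmin:kmax
  r2s <- vapply(parts[ks], `[[`, numeric(1), "r2")
  qss <- quality_score(r2s, ks, n)
  best_i <- which.min(qss)  # first minimum = smallest k on ties
  best_k <- ks[best_i]
  curve <- structure(list(ks = ks, r2s = r2s, qss = qss,
                          best_k = best_k, n = n),
                     class = "quality_curve")
  part <- parts[[best_k]]
  part$qs <- qss[best_i]
  list(partition = part, curve = curve)
}

#' @export
print.quality_curve <- function(x, ...) {
  cat(sprintf("quality_curve: k = %d..%d (n = %d)\n",
              min(x$ks), max(x$ks), x$n))
  i <- which(x$ks == x$best_k)
  cat(sprintf("  best k = %d  (r2 = %.4f, QS = %.4f)\n",
              x$best_k, x$r2s[i], x$qss[i]))
  invisible(x)
}

#' @export
as.data.frame.quality_curve <- function(x, ...) {
  data.frame(k = x$ks, r2 = x$r2s, qs = x$qss)
}

#' Plot a quality curve
#'
#' QS against band count, with the fitness term (`-ln r2`) and penalty term
#' (`2k/n`) overlaid and the minimum marked.
#'
#' @param x A `quality_curve` from [select_band_count()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.quality_curve <- function(x, ...) {
  fit_term <- ifelse(x$r2s > 0, -log(x$r2s), NA_real_)
  pen_term <- 2 * x$ks / x$n
  ylim <- range(c(x$qss[is.finite(x$qss)], fit_term, pen_term), na.rm = TRUE)
  graphics::plot(x$ks, x$qss, type = "l", xlab = "number of bands",
                 ylab = "quality score", ylim = ylim, ...)
  graphics::lines(x$ks, fit_term, lty = 2, col = "blue")
  graphics::lines(x$ks, pen_term, lty = 2, col = "orange")
  i <- which(x$ks == x$best_k)
  graphics::points(x$best_k, x$qss[i], pch = 8, col = "red", cex = 1.5)
  graphics::legend("top", c("QS", "-ln r2", "2k/N"), lty = c(1, 2, 2),
                   col = c("black", "blue", "orange"), bty = "n")
  invisible(x)
}
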