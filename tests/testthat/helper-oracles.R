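# Independent brute-force oracles for the segmentation code. These stay
# deliberately naive (explicit loops, no prefix sums) so they share no code
# path with the implementation they check.

sse_of <- function(v) sum((v - mean(v))^2)

# exhaustive best binary split: try every cut, recompute both SSEs directly
brute_best_split <- function(y) {
  n <- length(y)
  tot <- vapply(seq_len(n - 1L), function(i) {
    sse_of(y[1:i]) + sse_of(y[(i + 1):n])
  }, numeric(1))
  i <- which.min(tot)
  list(split_index = i, sse_decrease = sse_of(y) - tot[i])
}

# exhaustive optimal k-segmentation: enumerate all placements of k-1 cut
# positions and take the SSE-minimal one
brute_kseg_sse <- function(y, k) {
  n <- length(y)
  if (k == 1L) return(sse_of(y))
  best <- Inf
  for (cut in utils::combn(2:n, k - 1L, simplify = FALSE)) {
    groups <- findInterval(seq_len(n), c(1L, cut))
    sse <- sum(vapply(split(y, groups), sse_of, numeric(1)))
    if (sse < best) best <- sse
  }
  best
}

# Welch estimate written directly from the definition: explicit segment
# loop, periodogram of each mean-removed tapered segment, plain average
oracle_welch <- function(x, fs, seg, overlap = 0.5) {
  w <- 0.5 * (1 - cos(2 * pi * (0:(seg - 1)) / seg))
  step <- round(seg * (1 - overlap))
  periodograms <- list()
  s <- 1
  while (s + seg - 1 <= length(x)) {
    xi <- x[s:(s + seg - 1)]
    xi <- (xi - mean(xi)) * w
    pg <- abs(fft(xi))^2 / (fs * sum(w^2))
    periodograms[[length(periodograms) + 1]] <- pg[1:(seg / 2 + 1)]
    s <- s + step
  }
  p <- Reduce(`+`, periodograms) / length(periodograms)
  one_sided <- 2 * p
  one_sided[1] <- p[1]
  one_sided[seg / 2 + 1] <- p[seg / 2 + 1]
  list(f = (0:(seg / 2)) * fs / seg, p = one_sided)
}

# small random spectrum for property tests
random_spectrum <- function(n, seed) {
  set.seed(seed)
  f <- sort(runif(n, 0.5, 40))
  while (any(diff(f) == 0)) f <- sort(runif(n, 0.5, 40))
  power_spectrum(f, exp(rnorm(n)))
}

band_edges_of <- function(partition, spectrum) {
  f <- spectrum$frequencies
  c(f[1], partition$boundaries, f[length(f)])
}
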