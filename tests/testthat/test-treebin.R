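test_that("best_split minimises the summed within-group SSE", {
  # two-level step: cutting at the step removes all residual variance
  res <- best_split(c(0, 0, 0, 5, 5))
  expect_equal(res$split_index, 3L)
  expect_equal(res$sse_decrease, 30)  # SSE about the mean 2: 3*4 + 2*9

  # constant input: every cut ties at zero decrease; first index wins
  res <- best_split(rep(2.5, 8))
  expect_equal(res$split_index, 1L)
  expect_equal(res$sse_decrease, 0)

  expect_error(best_split(3), "fewer than 2")
})

test_that("best_split agrees with exhaustive enumeration", {
  for (seed in 1:25) {
    set.seed(seed)
    y <- rnorm(sample(2:12, 1))
    got <- best_split(y)
    want <- brute_best_split(y)
    expect_equal(got$split_index, want$split_index)
    expect_equal(got$sse_decrease, want$sse_decrease, tolerance = 1e-9)
  }
})

test_that("the first split matches an independent CART implementation", {
  # a depth-1 rpart stump uses the same squared-error criterion and reports
  # the split as the midpoint of the flanking predictor values
  for (seed in c(31, 32, 33, 34, 35)) {
    s <- random_spectrum(sample(5:40, 1), seed = seed)
    y <- log_power(s)
    p <- grow_partition(s, 2)
    stump <- rpart::rpart(y ~ f, data.frame(f = s$frequencies, y = y),
                          control = rpart::rpart.control(
                            maxdepth = 1, minsplit = 2, minbucket = 1,
                            cp = 0, xval = 0))
    expect_equal(unname(stump$splits[1, "index"]), p$boundaries)
  }
})

test_that("grow_partition handles the null and saturated models", {
  s <- random_spectrum(20, seed = 3)
  y <- log_power(s)

  p1 <- grow_partition(s, 1)
  expect_equal(p1$k, 1L)
  expect_length(p1$boundaries, 0)
  expect_equal(p1$band_means, mean(y))
  expect_equal(p1$r2, 0)

  pn <- grow_partition(s, n_freq(s))
  expect_equal(pn$sse, 0)
  expect_equal(pn$r2, 1)
  expect_equal(pn$band_means, y)
  expect_equal(sort(pn$boundaries),
               (s$frequencies[-1] + s$frequencies[-20]) / 2)

  expect_error(grow_partition(s, 0), "must be in")
  expect_error(grow_partition(s, 21), "must be in")
})

test_that("a single greedy split is exactly optimal (k = 2 matches DP)", {
  for (seed in 1:10) {
    s <- random_spectrum(sample(5:40, 1), seed = 100 + seed)
    g <- grow_partition(s, 2)
    d <- dp_optimal_partition(s, 2)
    expect_equal(g$sse, d$sse, tolerance = 1e-12)
    expect_equal(g$boundaries, d$boundaries)
  }
})

test_that("boundaries are midpoints of the flanking grid frequencies", {
  s <- power_spectrum(c(1, 2, 4, 8, 16), c(10, 10, 1, 1, 1))
  p <- grow_partition(s, 2)
  expect_equal(p$boundaries, 3)  # cut between 2 and 4 Hz
  expect_equal(p$band_means, c(log(10), log(1)))
  expect_equal(p$sse, 0)
  expect_equal(p$r2, 1)
})

test_that("grow_nested emits nested partitions with monotone fit", {
  for (seed in 1:15) {
    n <- sample(5:40, 1)
    s <- random_spectrum(n, seed = 200 + seed)
    parts <- grow_nested(s, n)
    r2s <- vapply(parts, `[[`, numeric(1), "r2")
    sses <- vapply(parts, `[[`, numeric(1), "sse")
    expect_true(all(diff(r2s) >= -1e-12))
    expect_true(all(diff(sses) <= 1e-12))
    for (k in seq_len(n - 1)) {
      expect_true(all(parts[[k]]$boundaries %in% parts[[k + 1]]$boundaries))
    }
    # final element equals the one-shot growth to the same k
    one_shot <- grow_partition(s, n)
    expect_equal(parts[[n]]$boundaries, one_shot$boundaries)
    expect_equal(parts[[n]]$sse, one_shot$sse)
  }
})

test_that("greedy SSE is bounded below by the DP optimum", {
  for (seed in 1:10) {
    n <- sample(6:30, 1)
    s <- random_spectrum(n, seed = 300 + seed)
    parts <- grow_nested(s, n)
    for (k in c(1, 2, sample(3:(n - 1), 2), n)) {
      d <- dp_optimal_partition(s, k)
      expect_lte(d$sse, parts[[k]]$sse + 1e-9)
      if (k %in% c(1, 2, n)) {
        expect_equal(d$sse, parts[[k]]$sse, tolerance = 1e-9)
      }
    }
  }
})

test_that("DP agrees with brute-force enumeration on small spectra", {
  for (seed in 1:8) {
    n <- sample(4:10, 1)
    s <- random_spectrum(n, seed = 400 + seed)
    y <- log_power(s)
    for (k in 1:n) {
      expect_equal(dp_optimal_partition(s, k)$sse, brute_kseg_sse(y, k),
                   tolerance = 1e-9)
    }
  }
})

test_that("stored SSE matches reconstruction from band means", {
  for (seed in 1:10) {
    n <- sample(8:40, 1)
    s <- random_spectrum(n, seed = 500 + seed)
    k <- sample(2:(n - 1), 1)
    p <- grow_partition(s, k)
    y <- log_power(s)
    groups <- findInterval(s$frequencies, p$boundaries) + 1
    pred <- p$band_means[groups]
    expect_equal(sum((y - pred)^2), p$sse, tolerance = 1e-9 * max(1, p$sse))
    expect_true(all(tabulate(groups, p$k) >= 1))  # no empty band
    expect_equal(p$r2, r_squared(p, s))
  }
})

test_that("permuting psd values within a band leaves sse unchanged", {
  set.seed(6)
  s <- random_spectrum(30, seed = 6)
  p <- grow_partition(s, 4)
  groups <- findInterval(s$frequencies, p$boundaries) + 1
  psd2 <- s$psd
  for (g in unique(groups)) {
    i <- which(groups == g)
    psd2[i] <- psd2[i[sample.int(length(i))]]
  }
  s2 <- power_spectrum(s$frequencies, psd2)
  expect_equal(r_squared(p, s2), p$r2, tolerance = 1e-12)
})

test_that("raw-target growth fits the psd values directly", {
  s <- power_spectrum(1:6, c(10, 10, 10, 2, 2, 2))
  p <- grow_partition(s, 2, log = FALSE)
  expect_equal(p$boundaries, 3.5)
  expect_equal(p$band_means, c(10, 2))
  expect_equal(p$sse, 0)
})

test_that("r_squared handles saturated, single-band and step partitions", {
  s <- random_spectrum(12, seed = 9)
  expect_equal(grow_partition(s, 12)$r2, 1)
  expect_equal(grow_partition(s, 1)$r2, 0)
  step <- power_spectrum(1:10, c(rep(5, 4), rep(1, 6)))
  expect_equal(grow_partition(step, 2)$r2, 1)
})
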