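test_that("a single Gaussian population is recovered", {
  set.seed(11)
  x <- rnorm(500, 0.5, 0.05)
  pk <- fit_peaks(x, seed = 1, zero_component = FALSE)
  expect_equal(nrow(pk$peaks), 1)
  expect_equal(pk$peaks$mean, 0.5, tolerance = 0.01)
  expect_equal(pk$peaks$sd, 0.05, tolerance = 0.015)
})

test_that("three well-separated components are recovered at n = 1000", {
  set.seed(12)
  x <- c(rnorm(300, 0.3, 0.04), rnorm(400, 0.55, 0.04),
         rnorm(300, 0.8, 0.04))
  pk <- fit_peaks(x, seed = 2, zero_component = FALSE)
  expect_equal(nrow(pk$peaks), 3)
  expect_equal(pk$peaks$mean, c(0.3, 0.55, 0.8), tolerance = 0.02)
  expect_equal(pk$peaks$weight, c(0.3, 0.4, 0.3), tolerance = 0.05)
})

test_that("mixture weights normalize and SEM follows the component size", {
  set.seed(13)
  x <- c(rep(0, 100), abs(rnorm(150, 0, 0.03)), rnorm(400, 0.6, 0.05))
  pk <- fit_peaks(x, seed = 1)
  total <- sum(pk$peaks$weight) + pk$zero_peak$weight
  expect_equal(total, 1, tolerance = 1e-6)
  expect_equal(pk$peaks$sem, pk$peaks$sd / sqrt(pk$peaks$n),
               tolerance = 1e-12)
})

test_that("fitting is invariant to the event order", {
  set.seed(14)
  x <- c(rnorm(300, 0.35, 0.05), rnorm(300, 0.7, 0.05))
  pk1 <- fit_peaks(x, seed = 5, zero_component = FALSE)
  pk2 <- fit_peaks(sample(x), seed = 5, zero_component = FALSE)
  expect_equal(pk1$peaks$mean, pk2$peaks$mean, tolerance = 1e-6)
  expect_equal(pk1$peaks$weight, pk2$peaks$weight, tolerance = 1e-6)
})

test_that("the donor-only population is absorbed by the zero peak", {
  # clipped zero pile with two noise scales plus one real peak
  set.seed(15)
  donor_only <- pmax(rnorm(600, 0, 0.04), 0)
  x <- c(donor_only, rnorm(400, 0.5, 0.05))
  pk <- fit_peaks(x, seed = 1)
  expect_equal(nrow(pk$peaks), 1)
  expect_equal(pk$peaks$mean, 0.5, tolerance = 0.02)
  expect_equal(pk$zero_peak$weight, 0.6, tolerance = 0.06)
})

test_that("peak recovery bias stays below 0.01 for 4-sigma separations", {
  # property check over seeds: separations >= 4 pooled SDs, n >= 1000
  for (s in 1:5) {
    set.seed(100 + s)
    x <- c(rnorm(500, 0.4, 0.04), rnorm(500, 0.6, 0.04))
    pk <- fit_peaks(x, seed = s, zero_component = FALSE)
    expect_equal(nrow(pk$peaks), 2)
    expect_lt(abs(pk$peaks$mean[1] - 0.4), 0.01)
    expect_lt(abs(pk$peaks$mean[2] - 0.6), 0.01)
  }
})

test_that("too few events is an error", {
  expect_error(fit_peaks(rnorm(10, 0.5, 0.05)), "20")
})

test_that("degenerate expansions enumerate compositions of the edge count", {
  # no degeneracy: all six peaks resolved
  e6 <- degenerate_expansions(6, 4)
  expect_length(e6, 1)
  expect_equal(e6[[1]], rep(1L, 6))
  # stars and bars: compositions of 6 into 4 positive parts = C(5,3) = 10,
  # cross-checked by brute force
  e4 <- degenerate_expansions(4, 4)
  expect_length(e4, 10)
  brute <- expand.grid(m1 = 1:3, m2 = 1:3, m3 = 1:3, m4 = 1:3)
  brute <- brute[rowSums(brute) == 6, ]
  expect_equal(length(e4), nrow(brute))
  expect_true(all(vapply(e4, sum, numeric(1)) == 6))
  # D2-symmetric tetramer: three doubly degenerate peaks
  e3 <- degenerate_expansions(3, 4)
  expect_true(any(vapply(e3, function(m) all(m == c(2, 2, 2)), logical(1))))
  # lexicographic deterministic order
  expect_equal(e3[[1]], c(1L, 1L, 4L))
  expect_error(degenerate_expansions(7, 4), "edges")
})

test_that("expansions are complete against brute force for 3 sites", {
  e <- degenerate_expansions(2, 3)
  brute <- expand.grid(m1 = 1:2, m2 = 1:2)
  brute <- brute[rowSums(brute) == 3, ]
  expect_equal(length(e), nrow(brute))
})

test_that("peak sets convert to distances with propagated uncertainty", {
  pk <- peak_set(data.frame(mean = c(0.3, 0.6), sd = c(0.05, 0.05),
                            weight = c(0.4, 0.4), sem = c(0.01, 0.01),
                            n = c(25, 25)),
                 zero_peak = list(weight = 0.2, sd = 0.03))
  fm <- forster_model(5.4)
  ds <- peaks_to_distances(pk, fm)
  expect_equal(ds$d, fret_to_distance(c(0.3, 0.6), fm))
  expect_equal(ds$m, 2)
  expect_true(all(ds$sd > 0))
  expect_true(ds$sd[1] > ds$sd[2])  # flat end of the transform is noisier
})

test_that("peak sets round-trip through JSON", {
  pk <- peak_set(data.frame(mean = 0.42, sd = 0.05, weight = 0.7,
                            sem = 0.004, n = 150),
                 zero_peak = list(weight = 0.3, sd = 0.02))
  path <- tempfile(fileext = ".json")
  write_peaks(pk, path)
  back <- read_peaks(path)
  expect_equal(back$peaks$mean, pk$peaks$mean, tolerance = 1e-12)
  expect_equal(back$zero_peak$weight, pk$zero_peak$weight,
               tolerance = 1e-12)
  unlink(path)
})
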