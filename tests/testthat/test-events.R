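test_that("per-event efficiency averages the per-frame ratio", {
  expect_equal(event_fret(c(100, 100), c(0, 0)), 0)
  expect_equal(event_fret(c(50, 50), c(50, 50)), 0.5)
  # hand arithmetic: mean of {20/100, 40/100} = 0.3
  expect_equal(event_fret(c(80, 60), c(20, 40)), 0.3)
})

test_that("frames with non-positive total intensity are excluded", {
  expect_equal(event_fret(c(80, -10, 60), c(20, 5, 40)), 0.3)
  expect_true(is.na(event_fret(c(-5, 0), c(0, 0))))
})

test_that("the averaged efficiency is clipped to the unit interval", {
  expect_equal(event_fret(c(-20, -20), c(30, 30)), 1)
  expect_equal(event_fret(c(120, 120), c(-20, -20)), 0)
})

test_that("a flat baseline-only trace yields no events", {
  tr <- intensity_trace("m", seq(0, 9.9, 0.1),
                        I_D = rep(0, 100), I_A = rep(0, 100))
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 0)
  set.seed(1)
  tr2 <- intensity_trace("m", seq(0, 9.9, 0.1),
                         I_D = rnorm(100, 0, 30), I_A = rnorm(100, 0, 30))
  expect_equal(nrow(detect_events(tr2)), 0)
})

test_that("an injected bound segment is recovered with exact boundaries", {
  set.seed(7)
  n <- 300
  I_D <- rnorm(n, 0, 20)
  I_A <- rnorm(n, 0, 20)
  idx <- 101:110                      # frames 100..109, 0-based
  I_D[idx] <- 700 + rnorm(10, 0, 20)  # 5x the baseline SD and beyond
  I_A[idx] <- 300 + rnorm(10, 0, 20)
  tr <- intensity_trace("m", (0:(n - 1)) * 0.1, I_D, I_A)
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_frame, 100)
  expect_equal(ev$end_frame, 109)
  expect_equal(ev$n_frames, 10)
  expect_equal(ev$E_app, mean(I_A[idx] / (I_A[idx] + I_D[idx])),
               tolerance = 1e-12)
})

test_that("detection is invariant to a common channel offset", {
  set.seed(8)
  n <- 400
  I_D <- rnorm(n, 0, 15)
  I_A <- rnorm(n, 0, 15)
  I_D[51:70] <- I_D[51:70] + 500
  I_A[51:70] <- I_A[51:70] + 500
  tr1 <- detect_events(intensity_trace("m", (0:(n - 1)) * 0.1, I_D, I_A))
  tr2 <- detect_events(intensity_trace("m", (0:(n - 1)) * 0.1,
                                       I_D + 250, I_A + 250))
  expect_equal(tr1$start_frame, tr2$start_frame)
  expect_equal(tr1$end_frame, tr2$end_frame)
})

test_that("short runs are dropped and near-adjacent runs merged", {
  n <- 200
  I_D <- rep(0, n)
  I_D[21:22] <- 1000                   # 2 frames < min_frames
  I_D[51:60] <- 1000
  I_D[62:70] <- 1000                   # 1-frame gap: merged
  tr <- intensity_trace("m", (0:(n - 1)) * 0.1, I_D, rep(0, n))
  ev <- detect_events(tr, event_params(k = 3, min_frames = 3,
                                       gap_frames = 1))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_frame, 50)
  expect_equal(ev$end_frame, 69)
})

test_that("runs with an efficiency step are split into pure events", {
  n <- 200
  I_D <- rep(0, n); I_A <- rep(0, n)
  I_D[101:110] <- 1000                 # donor-only episode
  I_D[111:120] <- 400                  # acceptor joins: E steps to 0.6
  I_A[111:120] <- 600
  tr <- intensity_trace("m", (0:(n - 1)) * 0.1, I_D, I_A)
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$E_app, c(0, 0.6), tolerance = 1e-12)
})

test_that("noiseless synthetic events recover the generating efficiencies", {
  truth <- triangle_truth(c(0.67, 0.34, 0.49))
  des <- sparse_design(3, duration = 240)
  tr <- synthesize_traces(des, truth, n_molecules = 1,
                          noise = noise_model(0, 0, 1000), seed = 13)[[1]]
  ev <- suppressWarnings(detect_events(tr))
  expect_gt(nrow(ev), 3)
  pure <- ev[ev$internal_sd < 1e-12, ]
  allowed <- c(0, 0.34, 0.49, 0.67)
  for (E in pure$E_app) {
    expect_lt(min(abs(E - allowed)), 1e-9)
  }
})

test_that("donor-only event share falls as acceptor excess rises", {
  truth <- triangle_truth(c(0.67, 0.34, 0.49))
  donor_only_share <- function(ca, tau_a, seed) {
    des <- assay_design(3, list(imager_species("donor", 50, 1.0),
                                imager_species("acceptor", ca, tau_a)),
                        duration = 240)
    ev <- synthetic_events(des, truth, n_molecules = 15, seed = seed)
    mean(ev$E_app < 0.1)
  }
  lo <- donor_only_share(2, 8, seed = 21)
  hi <- donor_only_share(20, 8, seed = 21)
  expect_gt(lo, hi)
})

test_that("event tables round-trip through TSV", {
  truth <- triangle_truth(c(0.6, 0.45, 0.3))
  ev <- synthetic_events(sparse_design(3, duration = 60), truth,
                         n_molecules = 3, seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(back$E_app, ev$E_app, tolerance = 1e-12)
  expect_equal(back$start_frame, ev$start_frame)
  unlink(path)
})
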