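test_that("per-site occupancy matches the competitive-binding steady state", {
  # closed form derived from the per-site Markov chain:
  # p_s = kon*c_s*tau_s / (1 + sum kon*c*tau), computed here independently
  kon <- 1e-3
  cd <- 100; td <- 1.0
  ca <- 400; ta <- 1.5
  load <- kon * c(cd, ca) * c(td, ta)
  p_expect <- load / (1 + sum(load))
  des <- assay_design(3, list(imager_species("donor", cd, td, kon),
                              imager_species("acceptor", ca, ta, kon)),
                      frame_time = 0.1, duration = 100)
  # replicate simulations give an honest Monte Carlo SE (frames within one
  # run are autocorrelated on the dwell-time scale)
  reps <- vapply(1:20, function(r) {
    occ <- simulate_occupancy(des, seed = 100 + r)
    c(mean(occ == 1L), mean(occ == 2L))
  }, numeric(2))
  pd <- rowMeans(reps)
  se <- apply(reps, 1, stats::sd) / sqrt(ncol(reps))
  expect_lt(abs(pd[1] - p_expect[1]), 3 * se[1] + 1e-12)
  expect_lt(abs(pd[2] - p_expect[2]), 3 * se[2] + 1e-12)
  # and the closed-form helper agrees with the hand formula
  ss <- occupancy_steady_state(des)
  expect_equal(unname(ss[1:2]), unname(p_expect), tolerance = 1e-12)
})

test_that("zero acceptor concentration leaves no acceptor-bound frame", {
  des <- assay_design(2, list(imager_species("donor", 100, 1.0),
                              imager_species("acceptor", 0, 1.0)),
                      duration = 60)
  occ <- simulate_occupancy(des, seed = 1)
  expect_false(any(occ == 2L))
})

test_that("all-zero concentrations warn and give an empty trace", {
  des <- assay_design(2, list(imager_species("donor", 0, 1.0),
                              imager_species("acceptor", 0, 1.0)),
                      duration = 10)
  expect_warning(occ <- simulate_occupancy(des, seed = 1), "zero")
  expect_true(all(occ == 0L))
  expect_equal(single_pair_fraction(occ), 0)
})

test_that("occupancy simulation is reproducible for a fixed seed", {
  des <- sparse_design(3, duration = 30)
  o1 <- simulate_occupancy(des, seed = 42)
  o2 <- simulate_occupancy(des, seed = 42)
  expect_identical(unclass(o1)[, ], unclass(o2)[, ])
  o3 <- simulate_occupancy(des, seed = 43)
  expect_false(identical(unclass(o1)[, ], unclass(o3)[, ]))
})

test_that("rate rescaling (2x concentration, dwell/2) preserves occupancy", {
  base <- assay_design(2, list(imager_species("donor", 50, 1.0),
                               imager_species("acceptor", 200, 2.0)),
                       duration = 50)
  scaled <- assay_design(2, list(imager_species("donor", 100, 0.5),
                                 imager_species("acceptor", 400, 1.0)),
                         duration = 50)
  expect_equal(occupancy_steady_state(base), occupancy_steady_state(scaled))
})

test_that("single-pair fraction matches the two-site binomial expansion", {
  # with 2 iid sites, P(exactly one donor AND one acceptor bound)
  # = 2 * p_D * p_A, from expanding over the 9 site-state combinations
  kon <- 1e-3
  des <- assay_design(2, list(imager_species("donor", 150, 1.0, kon),
                              imager_species("acceptor", 300, 1.5, kon)),
                      frame_time = 0.1, duration = 100)
  load <- kon * c(150, 300) * c(1.0, 1.5)
  p <- load / (1 + sum(load))
  expected <- 2 * p[1] * p[2]
  reps <- vapply(1:20, function(r) {
    single_pair_fraction(simulate_occupancy(des, seed = 500 + r))
  }, numeric(1))
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - expected), 3 * se + 1e-12)
})

test_that("single-pair fraction is invariant under site relabeling", {
  des <- sparse_design(4, duration = 60)
  occ <- simulate_occupancy(des, seed = 9)
  f0 <- single_pair_fraction(occ)
  perm <- c(3L, 1L, 4L, 2L)
  occ2 <- structure(unclass(occ)[, perm], class = "occupancy_trace",
                    design = attr(occ, "design"),
                    frame_time = attr(occ, "frame_time"), seed = 9L)
  expect_equal(single_pair_fraction(occ2), f0)
})

test_that("a single site cannot host a FRET pair", {
  # pigeonhole: one site holds one imager at a time
  des <- assay_design(2, list(imager_species("donor", 100, 1),
                              imager_species("acceptor", 100, 1)),
                      duration = 50)
  occ <- simulate_occupancy(des, seed = 3)
  one_site <- structure(unclass(occ)[, 1L, drop = FALSE],
                        class = "occupancy_trace",
                        design = attr(occ, "design"),
                        frame_time = 0.1, seed = 3L)
  expect_equal(single_pair_fraction(one_site), 0)
})

test_that("acceptor excess with longer dwell raises the single-pair yield", {
  # at sparse experimental occupancy, a 10:1 acceptor excess with a longer
  # acceptor dwell outperforms the unoptimized 1:1 short-dwell design at
  # the same total imager concentration. Closed form first: with 3 iid
  # sites, P(one donor, one acceptor, one empty) = 6 pD pA pE
  kon <- 1e-3
  spf_theory <- function(cd, ca, td, ta) {
    l <- kon * c(cd, ca) * c(td, ta)
    p <- l / (1 + sum(l))
    pe <- 1 - sum(p)
    6 * p[1] * p[2] * pe
  }
  even_th <- spf_theory(10, 10, 1, 1)
  excess_th <- spf_theory(1.8, 18.2, 1, 5)
  expect_gt(excess_th, even_th)
  # and the simulator reproduces the ordering
  f <- function(cd, ca, ta) {
    des <- assay_design(3, list(imager_species("donor", cd, 1.0, kon),
                                imager_species("acceptor", ca, ta, kon)),
                        duration = 3000)
    mean(vapply(1:6, function(r) {
      single_pair_fraction(simulate_occupancy(des, seed = 700 + r))
    }, numeric(1)))
  }
  expect_gt(f(1.8, 18.2, 5.0), f(10, 10, 1.0))
})

test_that("synthesized single-pair frames carry the exact pair efficiency", {
  truth <- triangle_truth(c(0.67, 0.34, 0.49))
  des <- sparse_design(3, duration = 120)
  tr <- synthesize_traces(des, truth, n_molecules = 1,
                          noise = noise_model(0, 0, 1000), seed = 5)[[1]]
  occ <- attr(tr, "occupancy")
  E_pair <- fretshape:::pair_fret_matrix(truth)
  nd <- rowSums(unclass(occ) == 1L)
  na <- rowSums(unclass(occ) == 2L)
  sp <- which(nd == 1L & na == 1L)
  expect_gt(length(sp), 0)
  for (f in sp) {
    di <- which(unclass(occ)[f, ] == 1L)
    ai <- which(unclass(occ)[f, ] == 2L)
    expect_equal(tr$I_A[f] / (tr$I_A[f] + tr$I_D[f]), E_pair[di, ai],
                 tolerance = 1e-12)
  }
  # donor-only frames emit at zero efficiency
  don <- which(nd >= 1L & na == 0L)
  expect_true(all(tr$I_A[don] == 0))
})

test_that("a two-site truth at exactly R0 emits at efficiency one half", {
  truth <- ground_truth_geometry(rbind(c(0, 0, 0), c(5.4, 0, 0)), 5.4)
  des <- sparse_design(2, duration = 600)
  tr <- synthesize_traces(des, truth, n_molecules = 1,
                          noise = noise_model(0, 0, 1000), seed = 8)[[1]]
  occ <- attr(tr, "occupancy")
  sp <- which(rowSums(unclass(occ) == 1L) == 1L &
                rowSums(unclass(occ) == 2L) == 1L)
  expect_gt(length(sp), 0)
  expect_equal(tr$I_A[sp] / (tr$I_A[sp] + tr$I_D[sp]), rep(0.5, length(sp)))
})

test_that("trace synthesis validates the coordinate count and reproduces", {
  des <- sparse_design(3, duration = 30)
  truth4 <- ground_truth_geometry(d2_tetrad(), 5.4)
  expect_error(synthesize_traces(des, truth4), "sites")
  truth <- triangle_truth(c(0.6, 0.4, 0.5))
  t1 <- synthesize_traces(des, truth, n_molecules = 2, seed = 10)
  t2 <- synthesize_traces(des, truth, n_molecules = 2, seed = 10)
  expect_identical(t1[[2]]$I_A, t2[[2]]$I_A)
})
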