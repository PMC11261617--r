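test_that("classic triangles embed exactly in the canonical frame", {
  tri <- reconstruct_triangle(3, 4, 5)
  expect_equal(tri$residual, 0)
  expect_equal(unname(tri$coords),
               rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)))
  eq <- reconstruct_triangle(1, 1, 1)
  expect_equal(unname(eq$coords[3, ]), c(0.5, sqrt(3) / 2, 0))
  expect_error(reconstruct_triangle(1, -1, 1))
})

test_that("violated triangle inequality gives the least-change collinear layout", {
  tri <- reconstruct_triangle(1, 1, 3)
  # analytic optimum: stretch the short edges and shrink the long one by
  # t = (3 - 2)/3, so the residual is exactly 1/3
  expect_equal(tri$residual, 1 / 3, tolerance = 1e-12)
  expect_true(all(abs(tri$coords[, 2:3]) < 1e-9))  # collinear
  # realized edges match the projected lengths 4/3, 4/3, 8/3
  d <- as.numeric(dist(tri$coords))
  expect_equal(sort(d), c(4 / 3, 4 / 3, 8 / 3), tolerance = 1e-9)
  # grid-search oracle over perturbed feasible triples
  grid <- expand.grid(a = seq(0.8, 1.8, 0.02), b = seq(0.8, 1.8, 0.02),
                      cc = seq(2.2, 3.0, 0.02))
  feas <- grid[grid$a + grid$b >= grid$cc, ]
  rms <- sqrt(((feas$a - 1)^2 + (feas$b - 1)^2 + (feas$cc - 3)^2) / 3)
  expect_equal(tri$residual, min(rms), tolerance = 0.02)
})

test_that("six distinct lengths give exactly 30 dissimilar quadrangles", {
  asn <- enumerate_assignments(c(1, 2, 3, 4, 5, 6))
  expect_length(asn, 30)
  # deduplication under all 24 vertex permutations, against brute force
  expect_length(enumerate_assignments(rep(2, 6)), 1)
  expect_error(enumerate_assignments(1:5))
})

test_that("assignment counts match brute-force orbit counting for repeats", {
  brute_count <- function(lengths) {
    perms <- fretshape:::permutations_of(6L)
    cand <- unique(matrix(lengths[perms], nrow = nrow(perms)))
    canon <- apply(cand, 1, function(a) {
      paste(fretshape:::canonical_assignment(a), collapse = ",")
    })
    length(unique(canon))
  }
  for (lengths in list(c(1, 1, 2, 2, 3, 3), c(1, 1, 1, 2, 2, 3),
                       c(1, 1, 1, 1, 2, 2), c(1, 2, 3, 4, 5, 6))) {
    expect_length(enumerate_assignments(lengths), brute_count(lengths))
  }
})

test_that("a regular tetrahedron embeds with zero violation", {
  a <- stats::setNames(rep(1, 6), c("d12", "d13", "d14", "d23", "d24", "d34"))
  sh <- embed_assignment(a)
  expect_lt(sh$residual, 1e-9)
  expect_equal(as.numeric(dist(sh$coords)), rep(1, 6), tolerance = 1e-9)
})

test_that("the D2 tetrad with hand-computed distances is reproduced", {
  # vertices (1,2,3), (-1,-2,3), (-1,2,-3), (1,-2,-3): pairwise squared
  # distances 20, 40, 52, each twice
  X <- rbind(c(1, 2, 3), c(-1, -2, 3), c(-1, 2, -3), c(1, -2, -3))
  d2 <- sort(round(as.numeric(dist(X))^2, 9))
  expect_equal(d2, c(20, 20, 40, 40, 52, 52))
  a <- stats::setNames(as.numeric(dist(X)),
                       c("d12", "d13", "d14", "d23", "d24", "d34"))
  sh <- embed_assignment(a)
  expect_lt(sh$residual, 1e-9)
  expect_lt(fit_to_reference(sh, X)$rmsd, 1e-6)
})

test_that("embedding is self-consistent on random configurations", {
  for (s in 1:10) {
    X <- random_quad(1000 + s)
    a <- stats::setNames(as.numeric(dist(X)),
                         c("d12", "d13", "d14", "d23", "d24", "d34"))
    sh <- embed_assignment(a, seed = s)
    expect_lt(sh$residual, 1e-9)
    expect_lt(fit_to_reference(sh, X)$rmsd, 1e-6 * max(dist(X)))
  }
})

test_that("unrealizable distances embed by stress minimization", {
  # a flat square with both diagonals forced equal to the side cannot be
  # realized; the optimizer must return a finite positive residual
  a <- stats::setNames(c(1, 1, 1, 1, 1, 1.9),
                       c("d12", "d13", "d14", "d23", "d24", "d34"))
  sh <- embed_assignment(a, n_restarts = 5, seed = 2)
  expect_true(is.finite(sh$residual))
  expect_gt(sh$residual, 1e-4)
})

test_that("the canonical frame is idempotent and fixes the gauge", {
  X <- random_quad(77)
  C1 <- canonical_frame(X)
  C2 <- canonical_frame(C1)
  expect_equal(C1, C2, tolerance = 1e-12)
  expect_equal(C1[1, ], c(0, 0, 0))
  expect_equal(C1[2, 2:3], c(0, 0))
  expect_equal(C1[3, 3], 0)
  expect_gte(C1[3, 2], 0)
  expect_gte(C1[4, 3], 0)
})

test_that("distance data cannot resolve chirality", {
  X <- random_quad(31)
  a <- stats::setNames(as.numeric(dist(X)),
                       c("d12", "d13", "d14", "d23", "d24", "d34"))
  sh <- embed_assignment(a)
  mir <- shape_mirror(sh)
  expect_equal(fretshape:::edge_residual(mir$coords, as.numeric(a)),
               fretshape:::edge_residual(sh$coords, as.numeric(a)),
               tolerance = 1e-9)
  # the mirror canonicalizes back to the same representative
  expect_equal(canonical_frame(mir$coords), sh$coords, tolerance = 1e-6)
})

test_that("three distances reconstruct a unique triangle", {
  rec <- reconstruct_best(distance_set(c(3, 4, 5)))
  expect_length(rec$ties, 1)
  expect_equal(rec$shape$residual, 0)
  expect_equal(nrow(rec$shape$coords), 3)
})

test_that("reconstruction searches degenerate expansions when peaks < edges", {
  # D2 tetrad: three distances, each doubled
  X <- d2_tetrad()
  dists <- sort(unique(round(as.numeric(dist(X)), 9)))
  expect_length(dists, 3)
  rec <- reconstruct_best(distance_set(dists), n_sites = 4, seed = 1)
  expect_lt(rec$shape$residual, 1e-9)
  expect_true("2,2,2" %in% rec$candidates$expansion)
  # the all-double expansion attains (one of) the best residuals
  r222 <- min(rec$candidates$residual[rec$candidates$expansion == "2,2,2"])
  expect_lt(r222, 1e-9)
  expect_lt(best_tie_rmsd(rec, X), 1e-6)
})

test_that("reconstruction errors on empty or non-triangular input", {
  expect_error(reconstruct_best(distance_set(c(1, 2))), "triangular")
  expect_error(distance_set(numeric(0)))
})

test_that("distance sets validate their invariants", {
  expect_error(distance_set(c(1, -2)))
  expect_error(distance_set(1:3, multiplicity = c(1, 1)))
  ds <- distance_set(c(2, 3), multiplicity = c(2, 4))
  expect_equal(ds$m, 6)
})
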