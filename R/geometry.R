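#' Distance set derived from FRET peaks
#'
#' A set of labeled distances with integer multiplicities. The total edge
#' count m = sum of multiplicities must be a triangular number (1, 3 or 6)
#' before a shape can be reconstructed; when fewer peaks than edges are
#' observed, degenerate-peak expansions are enumerated by
#' [degenerate_expansions()].
#'
#' @param d Positive distances in nm.
#' @param multiplicity Positive integer multiplicity per distance
#'   (default all 1).
#' @param sd Optional per-distance uncertainty in nm (reporting only).
#' @return An object of class `distance_set`.
#' @seealso [peaks_to_distances()], [reconstruct_best()]
#' @export
distance_set <- function(d, multiplicity = rep(1L, length(d)), sd = NULL) {
  stopifnot(is.numeric(d), length(d) >= 1L, all(is.finite(d)), all(d > 0),
            length(multiplicity) == length(d),
            all(multiplicity >= 1), all(multiplicity == round(multiplicity)))
  if (!is.null(sd)) stopifnot(length(sd) == length(d), all(sd >= 0))
  structure(list(d = as.numeric(d), multiplicity = as.integer(multiplicity),
                 sd = sd, m = sum(as.integer(multiplicity))),
            class = "distance_set")
}

#' @export
print.distance_set <- function(x, ...) {
  cat(sprintf("Distance set: %d distances, total edge count m = %d\n",
              length(x$d), x$m))
  df <- data.frame(d_nm = x$d, multiplicity = x$multiplicity)
  if (!is.null(x$sd)) df$sd_nm <- x$sd
  print(df)
  invisible(x)
}

#' Convert a fitted peak set to a distance set
#'
#' Applies the inverse Förster relation to each non-zero peak mean and
#' propagates the peak SEM to a distance uncertainty by the delta method.
#' The donor-only zero peak carries no distance and is ignored.
#'
#' @param peakset A [peak_set()] from [fit_peaks()].
#' @param model A [forster_model()].
#' @param multiplicity Optional multiplicities (default all 1).
#' @return A [distance_set()].
#' @export
peaks_to_distances <- function(peakset, model = forster_model(),
                               multiplicity = NULL) {
  stopifnot(inherits(peakset, "peak_set"))
  E <- peakset$peaks$mean
  if (length(E) == 0L) stop("peak set has no non-zero peaks", call. = FALSE)
  if (is.null(multiplicity)) multiplicity <- rep(1L, length(E))
  d <- fret_to_distance(E, model)
  sd <- fret_distance_sd(E, peakset$peaks$sem, model)
  distance_set(d, multiplicity, sd)
}

#' Reconstruct a triangle from its three edge lengths
#'
#' Up to rotation, translation and reflection, three edge lengths determine
#' at most one triangle. When the triangle inequality holds the planar
#' coordinates are exact and the violation residual is zero; otherwise the
#' least-violation layout is collinear, obtained in closed form by shrinking
#' the longest edge and stretching the other two by a common amount t =
#' (c - a - b)/3, giving residual |t|.
#'
#' @param d12,d13,d23 Positive edge lengths in nm.
#' @return A [reconstructed_shape()] with 3 vertices (z = 0).
#' @export
#' @examples
#' reconstruct_triangle(3, 4, 5)   # right triangle, residual 0
#' reconstruct_triangle(1, 1, 3)   # violated inequality, collinear layout
reconstruct_triangle <- function(d12, d13, d23) {
  d <- c(d12, d13, d23)
  stopifnot(is.numeric(d), length(d) == 3L, all(is.finite(d)), all(d > 0))
  if (triangle_feasible(d12, d13, d23)) {
    x3 <- (d12^2 + d13^2 - d23^2) / (2 * d12)
    y3 <- sqrt(max(d13^2 - x3^2, 0))
    coords <- rbind(c(0, 0, 0), c(d12, 0, 0), c(x3, y3, 0))
    return(reconstructed_shape(coords, residual = 0,
                               assignment = stats::setNames(d, edge_names(3L))))
  }
  # violated inequality: longest edge c > a + b. Optimal embedding is
  # collinear with the middle vertex between the endpoints of c; least-squares
  # adjustment is a' = a + t, b' = b + t, c' = c - t with t = (c - a - b)/3.
  k <- which.max(d)
  c_len <- d[k]; ab <- d[-k]
  t <- (c_len - sum(ab)) / 3
  a_adj <- ab[1L] + t
  # vertices: edge k joins the two outer vertices; the vertex not on edge k
  # sits between them. Edge order (12, 13, 23): vertex not on edge k is
  # 3, 2, 1 for k = 1, 2, 3.
  mid <- c(3L, 2L, 1L)[k]
  outer_v <- setdiff(1:3, mid)
  coords <- matrix(0, 3L, 3L)
  # adjusted length of the edge joining the first outer vertex to the middle
  e <- edge_pairs(3L)
  fe <- sort(c(outer_v[1L], mid))
  len_first <- d[e[, 1L] == fe[1L] & e[, 2L] == fe[2L]] + t
  coords[outer_v[1L], ] <- c(0, 0, 0)
  coords[mid, ] <- c(len_first, 0, 0)
  coords[outer_v[2L], ] <- c(c_len - t, 0, 0)
  reconstructed_shape(coords, residual = abs(t),
                      assignment = stats::setNames(d, edge_names(3L)))
}

triangle_feasible <- function(a, b, c) {
  a + b >= c && a + c >= b && b + c >= a
}

#' Enumerate dissimilar edge assignments of six lengths to a quadrangle
#'
#' Assigns a multiset of six lengths to the six edges of the complete graph
#' on four vertices and deduplicates assignments related by one of the 24
#' vertex permutations. With six distinct lengths this yields 6!/24 = 30
#' equivalence classes, i.e. 30 dissimilar quadrangles; repeated lengths
#' reduce the count by symmetry.
#'
#' @param lengths Numeric vector of exactly six positive lengths
#'   (repetitions allowed).
#' @return A list of named length-6 vectors (`d12`, `d13`, `d14`, `d23`,
#'   `d24`, `d34`), one per equivalence class, each the lexicographically
#'   smallest member of its class, in deterministic sorted order.
#' @export
#' @examples
#' length(enumerate_assignments(1:6))   # 30
#' length(enumerate_assignments(rep(1, 6)))  # 1
enumerate_assignments <- function(lengths) {
  stopifnot(is.numeric(lengths), all(is.finite(lengths)), all(lengths > 0))
  if (length(lengths) != 6L) {
    stop("exactly six edge lengths are required for a quadrangle",
         call. = FALSE)
  }
  perms <- permutations_of(6L)
  cand <- matrix(lengths[perms], nrow = nrow(perms))
  cand <- unique(cand)
  canon <- canonical_assignment_rows(cand)
  canon <- unique(canon)
  ord <- do.call(order, as.data.frame(canon))
  canon <- canon[ord, , drop = FALSE]
  nm <- edge_names(4L)
  lapply(seq_len(nrow(canon)), function(i) stats::setNames(canon[i, ], nm))
}

# lexicographically smallest relabeling of an edge-length vector under the
# vertex permutation group of K4
canonical_assignment <- function(a, maps = k4_edge_permutations()) {
  canonical_assignment_rows(matrix(a, nrow = 1L))[1L, ]
}

# row-wise canonicalization: each row of `cand` is an edge-length vector;
# the relabeling by map m is the column permutation cand[, inverse(m)]
canonical_assignment_rows <- function(cand) {
  maps <- k4_edge_permutations()
  best <- cand
  for (m in maps) {
    minv <- order(m)
    B <- cand[, minv, drop = FALSE]
    less <- rep(FALSE, nrow(cand))
    eq <- rep(TRUE, nrow(cand))
    for (j in seq_len(ncol(cand))) {
      less <- less | (eq & B[, j] < best[, j])
      eq <- eq & B[, j] == best[, j]
    }
    if (any(less)) best[less, ] <- B[less, , drop = FALSE]
  }
  best
}

# For each of the 24 vertex permutations pi, the edge index map m with
# m[k] = position of edge (pi(i), pi(j)) where (i, j) is the k-th edge.
k4_edge_permutations <- function() {
  if (!is.null(.geom_cache$k4maps)) return(.geom_cache$k4maps)
  pairs <- edge_pairs(4L)
  pos <- matrix(0L, 4L, 4L)
  for (k in seq_len(nrow(pairs))) {
    pos[pairs[k, 1L], pairs[k, 2L]] <- k
    pos[pairs[k, 2L], pairs[k, 1L]] <- k
  }
  vperms <- permutations_of(4L)
  maps <- lapply(seq_len(nrow(vperms)), function(p) {
    pi <- vperms[p, ]
    vapply(seq_len(6L), function(k) {
      pos[pi[pairs[k, 1L]], pi[pairs[k, 2L]]]
    }, integer(1))
  })
  .geom_cache$k4maps <- maps
  maps
}

.geom_cache <- new.env(parent = emptyenv())

# all permutations of 1:n as a matrix (n! rows), deterministic order
permutations_of <- function(n) {
  key <- paste0("perm", n)
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- permutations_build(n)
  .geom_cache[[key]] <- out
  out
}

permutations_build <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_build(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' Embed one edge assignment in 3D
#'
#' Attempts an exact embedding by sequential trilateration (placing vertices
#' 1-4 from the assigned edge lengths, with Cayley-Menger-style feasibility
#' checks on the squared offsets). If the distances are not realizable in 3D,
#' minimizes the squared edge-length violation over coordinates, starting
#' from classical multidimensional scaling plus seeded random restarts.
#'
#' @param assignment Named length-6 vector of edge lengths in the `d12` ...
#'   `d34` order (as produced by [enumerate_assignments()]), or a length-3
#'   vector for a triangle.
#' @param n_restarts Number of random restarts for the stress minimization
#'   used on infeasible assignments.
#' @param seed Integer seed for the restarts.
#' @return A [reconstructed_shape()]; `residual` is the RMS difference
#'   between realized and requested edge lengths (0 for realizable input).
#' @export
embed_assignment <- function(assignment, n_restarts = 10L, seed = 1L) {
  a <- as.numeric(assignment)
  if (length(a) == 3L) {
    return(reconstruct_triangle(a[1L], a[2L], a[3L]))
  }
  stopifnot(length(a) == 6L, all(is.finite(a)), all(a > 0))
  nm <- edge_names(4L)
  target <- stats::setNames(a, nm)
  D <- assignment_to_matrix(a)
  scale <- mean(a)
  tri <- trilaterate4(D, tol = 1e-9 * scale^2)
  if (!is.null(tri)) {
    res <- edge_residual(tri, a)
    if (res <= 1e-9 * scale) {
      return(reconstructed_shape(tri, residual = res, assignment = target))
    }
  }
  best <- stress_embed(D, a, n_restarts = n_restarts, seed = seed,
                       extra_start = tri)
  if (is.null(best)) {
    sh <- reconstructed_shape(matrix(0, 4L, 3L), residual = 0,
                              assignment = target, canonicalize = FALSE)
    sh$residual <- Inf
    return(sh)
  }
  reconstructed_shape(best$coords, residual = best$residual,
                      assignment = target)
}

# exact embedding attempt only: shape if trilateration realizes the
# assignment to within tol, else NULL
exact_embed <- function(a, tol_factor = 1e-9) {
  a <- as.numeric(a)
  scale <- mean(a)
  D <- assignment_to_matrix(a)
  tri <- trilaterate4(D, tol = tol_factor * scale^2)
  if (is.null(tri)) return(NULL)
  res <- edge_residual(tri, a)
  if (res > tol_factor * scale) return(NULL)
  reconstructed_shape(tri, residual = res,
                      assignment = stats::setNames(a, edge_names(4L)))
}

# cheap embedding: classical-scaling coordinates without optimization;
# the residual is an upper bound on the attainable minimum
mds_embed <- function(a) {
  a <- as.numeric(a)
  D <- assignment_to_matrix(a)
  X <- mds_start(D)
  reconstructed_shape(X, residual = edge_residual(X, a),
                      assignment = stats::setNames(a, edge_names(4L)))
}

assignment_to_matrix <- function(a) {
  D <- matrix(0, 4L, 4L)
  pairs <- edge_pairs(4L)
  for (k in seq_len(6L)) {
    D[pairs[k, 1L], pairs[k, 2L]] <- a[k]
    D[pairs[k, 2L], pairs[k, 1L]] <- a[k]
  }
  D
}

# sequential trilateration of 4 points from a full distance matrix;
# returns NULL when a squared offset goes negative beyond tolerance
trilaterate4 <- function(D, tol) {
  d12 <- D[1L, 2L]
  if (d12 <= 0) return(NULL)
  x3 <- (d12^2 + D[1L, 3L]^2 - D[2L, 3L]^2) / (2 * d12)
  y3sq <- D[1L, 3L]^2 - x3^2
  if (y3sq < -tol) return(NULL)
  y3 <- sqrt(max(y3sq, 0))
  x4 <- (d12^2 + D[1L, 4L]^2 - D[2L, 4L]^2) / (2 * d12)
  if (y3 < sqrt(tol)) return(NULL)   # degenerate base triangle
  y4 <- (D[1L, 3L]^2 + D[1L, 4L]^2 - D[3L, 4L]^2 - 2 * x3 * x4) / (2 * y3)
  z4sq <- D[1L, 4L]^2 - x4^2 - y4^2
  if (z4sq < -tol) return(NULL)
  z4 <- sqrt(max(z4sq, 0))
  rbind(c(0, 0, 0), c(d12, 0, 0), c(x3, y3, 0), c(x4, y4, z4))
}

# least-squares embedding of a (possibly unrealizable) distance matrix:
# minimize sum over edges of (|xi - xj| - dij)^2
stress_embed <- function(D, target, n_restarts, seed, extra_start = NULL) {
  idx <- edge_pairs(4L)
  obj <- function(x) {
    X <- matrix(x, 4L, 3L)
    dd <- X[idx[, 1L], ] - X[idx[, 2L], ]
    r <- sqrt(rowSums(dd^2))
    sum((r - target)^2)
  }
  grad <- function(x) {
    X <- matrix(x, 4L, 3L)
    G <- matrix(0, 4L, 3L)
    dd <- X[idx[, 1L], ] - X[idx[, 2L], ]
    r <- sqrt(rowSums(dd^2))
    r[r < 1e-12] <- 1e-12
    w <- 2 * (r - target) / r
    for (k in seq_len(nrow(idx))) {
      g <- w[k] * dd[k, ]
      G[idx[k, 1L], ] <- G[idx[k, 1L], ] + g
      G[idx[k, 2L], ] <- G[idx[k, 2L], ] - g
    }
    as.numeric(G)
  }
  starts <- list(mds_start(D))
  if (!is.null(extra_start)) starts <- c(starts, list(extra_start))
  best <- NULL
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  scale <- mean(target)
  while (length(starts) < n_restarts) {
    starts <- c(starts, list(starts[[1L]] +
                               matrix(stats::rnorm(12L, sd = 0.3 * scale),
                                      4L, 3L)))
  }
  for (s in starts) {
    fit <- try(stats::optim(as.numeric(s), obj, grad, method = "BFGS",
                            control = list(maxit = 200L, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < (1e-10 * scale)^2) break
  }
  if (is.null(best)) return(NULL)
  X <- matrix(best$par, 4L, 3L)
  list(coords = X, residual = sqrt(best$value / nrow(idx)))
}

# classical scaling start (double centering; top 3 eigenvectors)
mds_start <- function(D) {
  n <- nrow(D)
  D2 <- D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  e <- eigen(B, symmetric = TRUE)
  k <- 3L
  lam <- pmax(e$values[seq_len(k)], 0)
  X <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
  X
}
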