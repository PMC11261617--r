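#' Rigid-body superposition of two point sets
#'
#' Least-squares (Kabsch) superposition of `X` onto `Y` by translation and
#' rotation, optionally allowing an improper rotation (reflection). Rows are
#' corresponding points.
#'
#' @param X,Y n x 3 coordinate matrices with corresponding rows.
#' @param allow_reflection Permit an improper rotation.
#' @return List with `coords` (X transformed onto Y), `R` (the 3x3
#'   orthogonal matrix applied on the right of centered coordinates),
#'   `rmsd`.
#' @export
superpose <- function(X, Y, allow_reflection = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(all(dim(X) == dim(Y)), ncol(X) == 3L)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  C <- t(Xc) %*% Yc
  sv <- svd(C)
  R <- sv$u %*% t(sv$v)
  if (!allow_reflection && det(R) < 0) {
    u <- sv$u
    u[, 3L] <- -u[, 3L]
    R <- u %*% t(sv$v)
  }
  fitted <- Xc %*% R
  fitted <- sweep(fitted, 2, cy, `+`)
  list(coords = fitted, R = R,
       rmsd = sqrt(mean(rowSums((fitted - Y)^2))))
}

#' Align and average a collection of shapes
#'
#' Generalized Procrustes analysis without scaling: every shape is aligned
#' to the current mean by translation and rotation (reflection allowed by
#' default, since FRET distances cannot resolve chirality), the mean is
#' recomputed, and the procedure is iterated to convergence.
#'
#' @param shapes List of [reconstructed_shape()] objects or coordinate
#'   matrices with equal vertex counts and consistent labels.
#' @param allow_reflection Allow improper rotations during alignment.
#' @param max_iter,tol Iteration controls on the mean-shape movement (nm).
#' @return List with `mean_shape` (a [reconstructed_shape()] in canonical
#'   frame), `rmsd` (per-shape RMSD to the mean), and `aligned` (the list of
#'   aligned coordinate matrices).
#' @export
align_and_average <- function(shapes, allow_reflection = TRUE,
                              max_iter = 100L, tol = 1e-10) {
  stopifnot(is.list(shapes), length(shapes) >= 1L)
  coords <- lapply(shapes, function(s) {
    if (inherits(s, "reconstructed_shape")) s$coords else as.matrix(s)
  })
  n <- nrow(coords[[1L]])
  if (!all(vapply(coords, nrow, integer(1)) == n)) {
    stop("all shapes must have the same vertex count", call. = FALSE)
  }
  coords <- lapply(coords, function(X) sweep(X, 2, colMeans(X)))
  mean_c <- coords[[1L]]
  for (it in seq_len(max_iter)) {
    coords <- lapply(coords, function(X) {
      superpose(X, mean_c, allow_reflection)$coords
    })
    new_mean <- Reduce(`+`, coords) / length(coords)
    delta <- sqrt(mean((new_mean - mean_c)^2))
    mean_c <- new_mean
    if (delta < tol) break
  }
  rmsds <- vapply(coords, function(X) {
    sqrt(mean(rowSums((X - mean_c)^2)))
  }, numeric(1))
  rownames(mean_c) <- rownames(coords[[1L]])
  list(mean_shape = reconstructed_shape(mean_c, residual = 0),
       rmsd = rmsds, aligned = coords)
}

#' Bootstrap positional uncertainty of the average shape
#'
#' Resamples molecules with replacement `B` times; each replicate's
#' per-molecule shapes (reconstructed once and cached) are aligned and
#' averaged, the replicate means are brought into a common frame, and the
#' spread of each vertex across replicates is reported.
#'
#' @param distance_sets List with one [distance_set()] (or numeric distance
#'   vector) per molecule.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the resampling.
#' @param n_sites Passed to [reconstruct_best()].
#' @param ... Further arguments to [reconstruct_best()].
#' @return List with `mean_shape`, `vertex_sd` (per-vertex positional SD in
#'   nm, the square root of the summed coordinate variances), `coord_sd` (n x 3 matrix of
#'   per-coordinate SDs), and `replicate_means`.
#' @export
bootstrap_shape <- function(distance_sets, B = 1000L, seed = 1L,
                            n_sites = NULL, ...) {
  stopifnot(is.list(distance_sets), length(distance_sets) >= 2L)
  if (B < 1L) stop("B must be at least 1", call. = FALSE)
  shapes <- lapply(distance_sets, function(ds) {
    reconstruct_best(ds, n_sites = n_sites, ...)$shape
  })
  n_mol <- length(shapes)
  overall <- align_and_average(shapes)
  reps <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      idx <- sample.int(n_mol, n_mol, replace = TRUE)
      align_and_average(shapes[idx])$mean_shape$coords
    })
  })
  # common frame for the replicate means
  ref <- overall$mean_shape$coords
  reps <- lapply(reps, function(X) {
    superpose(sweep(X, 2, colMeans(X)), ref)$coords
  })
  n <- nrow(ref)
  arr <- array(unlist(reps), dim = c(n, 3L, B))
  coord_sd <- apply(arr, c(1L, 2L), stats::sd)
  if (B == 1L) coord_sd[] <- 0
  vertex_sd <- sqrt(rowMeans(coord_sd^2) * 3)
  list(mean_shape = overall$mean_shape, vertex_sd = vertex_sd,
       coord_sd = coord_sd, replicate_means = reps)
}

#' Fit a reconstructed shape to a reference structure
#'
#' Expands each reference point radially outward from the reference
#' centroid by the dye linker length (modeling where the dyes sit relative
#' to the labeled positions), then superposes the shape onto the expanded
#' reference by a rigid-body transform with optional reflection. When the
#' correspondence between shape vertices and reference points is unknown,
#' all vertex permutations are searched and the best is returned.
#'
#' @param shape A [reconstructed_shape()] or coordinate matrix (nm).
#' @param reference n x 3 reference coordinates in nm (e.g. from
#'   [read_reference_pdb()]).
#' @param linker_length Dye linker length in nm.
#' @param allow_reflection Permit an improper rotation.
#' @param search_permutations Search vertex correspondences.
#' @return List with `rmsd`, `permutation` (shape vertex order used),
#'   `coords` (the fitted shape coordinates), and `reference_expanded`.
#' @export
fit_to_reference <- function(shape, reference, linker_length = 0,
                             allow_reflection = TRUE,
                             search_permutations = TRUE) {
  X <- if (inherits(shape, "reconstructed_shape")) shape$coords
       else as.matrix(shape)
  reference <- as.matrix(reference)
  if (nrow(X) != nrow(reference)) {
    stop("shape and reference must have the same vertex count",
         call. = FALSE)
  }
  ref_exp <- linker_expand(reference, linker_length)
  perms <- if (search_permutations) permutations_of(nrow(X))
           else matrix(seq_len(nrow(X)), 1L)
  best <- NULL
  for (p in seq_len(nrow(perms))) {
    fit <- superpose(X[perms[p, ], , drop = FALSE], ref_exp,
                     allow_reflection)
    if (is.null(best) || fit$rmsd < best$rmsd) {
      best <- fit
      best$permutation <- perms[p, ]
    }
  }
  list(rmsd = best$rmsd, permutation = best$permutation,
       coords = best$coords, reference_expanded = ref_exp)
}
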