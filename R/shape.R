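#' Reconstructed shape object
#'
#' A labeled set of 3D coordinates (nm) in the canonical frame together with
#' the violation residual: the root-mean-square change in edge length needed
#' to embed the requested distances in 3D.
#'
#' The canonical frame places vertex 1 at the origin, vertex 2 on the +x axis,
#' vertex 3 in the xy half-plane with y >= 0, and (for quadrangles) vertex 4
#' at z >= 0. Because distances cannot determine chirality, a shape and its
#' mirror image share one canonical representative.
#'
#' @param coords Numeric n x 3 matrix of coordinates in nm (n = 3 or 4).
#' @param residual Non-negative violation residual in nm.
#' @param assignment Optional named vector of target edge lengths
#'   (`d12`, `d13`, ...) that produced the shape.
#' @param canonicalize Transform `coords` into the canonical frame (default).
#' @return An object of class `reconstructed_shape` with elements `coords`,
#'   `residual`, `assignment`.
#' @export
reconstructed_shape <- function(coords, residual = 0, assignment = NULL,
                                canonicalize = TRUE) {
  coords <- as.matrix(coords)
  stopifnot(is.numeric(coords), ncol(coords) == 3L,
            nrow(coords) >= 2L, nrow(coords) <= 4L,
            is.numeric(residual), length(residual) == 1L, residual >= -1e-12)
  if (is.null(rownames(coords))) {
    rownames(coords) <- paste0("v", seq_len(nrow(coords)))
  }
  if (canonicalize) coords <- canonical_frame(coords)
  structure(list(coords = coords, residual = max(residual, 0),
                 assignment = assignment),
            class = "reconstructed_shape")
}

#' @export
print.reconstructed_shape <- function(x, ...) {
  cat(sprintf("Reconstructed shape: %d vertices, violation residual %.3g nm\n",
              nrow(x$coords), x$residual))
  print(round(x$coords, 4))
  invisible(x)
}

#' Transform coordinates into the canonical frame
#'
#' Rigid motion (plus a z-reflection, which distance data cannot resolve)
#' bringing vertex 1 to the origin, vertex 2 onto the +x axis, vertex 3 into
#' the y >= 0 half of the xy plane, and vertex 4 to z >= 0. Idempotent.
#'
#' @param coords Numeric n x 3 coordinate matrix.
#' @return The transformed matrix, same dimnames.
#' @export
canonical_frame <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L)
  n <- nrow(coords)
  X <- sweep(coords, 2, coords[1L, ])
  # rotate vertex 2 onto +x
  v <- X[2L, ]
  nv <- sqrt(sum(v^2))
  if (nv > 1e-12) {
    u <- v / nv
    b <- pick_orthogonal(u)
    w <- cross3(u, b)
    R <- rbind(u, b, w)            # orthonormal rows, det +1; R %*% u = e1
    X <- X %*% t(R)
  }
  # roll about x so the reference vertex lands in the xy plane with y >= 0
  ref <- if (n >= 3L && sqrt(X[3L, 2L]^2 + X[3L, 3L]^2) > 1e-9) 3L
         else if (n >= 4L && sqrt(X[4L, 2L]^2 + X[4L, 3L]^2) > 1e-9) 4L
         else 0L
  if (ref > 0L) {
    a <- atan2(X[ref, 3L], X[ref, 2L])
    ca <- cos(a); sa <- sin(a)
    # rotate rows (y, z) by -a: y' = y cos a + z sin a, z' = z cos a - y sin a
    yz <- X[, 2:3, drop = FALSE] %*% matrix(c(ca, sa, -sa, ca), 2L, 2L)
    X[, 2L] <- yz[, 1L]
    X[, 3L] <- yz[, 2L]
  }
  # mirror ambiguity: put vertex 4 (when present and off-plane) at z >= 0
  if (n >= 4L && X[4L, 3L] < 0) X[, 3L] <- -X[, 3L]
  X[abs(X) < 1e-12] <- 0
  dimnames(X) <- dimnames(coords)
  X
}

# unit vector orthogonal to u
pick_orthogonal <- function(u) {
  a <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b <- a - sum(a * u) * u
  b / sqrt(sum(b^2))
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Mirror image of a shape
#'
#' Reflects the coordinates through the xy plane without re-canonicalizing,
#' giving the enantiomer. Useful for checking that distance data cannot
#' distinguish a shape from its mirror image.
#'
#' @param shape A [reconstructed_shape()].
#' @return A `reconstructed_shape` with reflected raw coordinates.
#' @export
shape_mirror <- function(shape) {
  stopifnot(inherits(shape, "reconstructed_shape"))
  coords <- shape$coords
  coords[, 3L] <- -coords[, 3L]
  structure(list(coords = coords, residual = shape$residual,
                 assignment = shape$assignment),
            class = "reconstructed_shape")
}

# pairwise distances of a coordinate matrix, as the full symmetric matrix
coord_dist <- function(coords) as.matrix(stats::dist(coords))

# RMS difference between realized and target edge lengths
edge_residual <- function(coords, target) {
  n <- nrow(coords)
  idx <- edge_index(n)
  d <- coord_dist(coords)
  realized <- d[idx]
  sqrt(mean((realized - target)^2))
}

# linear indices of the upper-triangle edges in canonical order
# (12, 13, 14, 23, 24, 34) for n = 4; (12, 13, 23) for n = 3
edge_index <- function(n) {
  pairs <- edge_pairs(n)
  cbind(pairs[, 1L], pairs[, 2L])
}

edge_pairs <- function(n) {
  out <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) out <- rbind(out, c(i, j))
  out
}

edge_names <- function(n) {
  p <- edge_pairs(n)
  paste0("d", p[, 1L], p[, 2L])
}

# diameter (largest pairwise distance) of a configuration
coord_diameter <- function(coords) max(stats::dist(coords))
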