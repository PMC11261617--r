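#' Reconstruct the best-fitting shape from a distance set
#'
#' Enumerates every dissimilar edge assignment of the distances (expanded by
#' their multiplicities) to the complete graph on 3 or 4 vertices, embeds
#' each in 3D, and returns the shape whose edge lengths had to change the
#' least — the minimum RMS edge-length violation. When fewer distinct
#' distances than edges are supplied without multiplicities, all
#' degenerate-peak expansions to the triangular edge count are searched
#' (see [degenerate_expansions()]).
#'
#' Three distances determine at most one dissimilar triangle, so the search
#' is trivial there; six distinct distances generate 30 dissimilar
#' quadrangles. Candidates are screened with a single embedding start and
#' the best few are refined with the full restart budget.
#'
#' @param ds A [distance_set()], or a bare numeric vector of distances.
#' @param n_sites Number of labeled sites (3 or 4). Defaults to the value
#'   implied by the total edge count when that count is already triangular.
#' @param n_restarts Restart budget for refining infeasible embeddings.
#' @param refine_top How many screened candidates to refine fully.
#' @param tie_tol Residual difference (nm) under which candidates tie.
#' @param seed Integer seed for embedding restarts.
#' @return An object of class `reconstruction`: list with `shape` (the best
#'   [reconstructed_shape()]), `ties` (all shapes within `tie_tol` of the
#'   best, lexicographically smallest canonical form first), and
#'   `candidates` (a data frame ranking every expansion x assignment by
#'   residual).
#' @export
#' @examples
#' reconstruct_best(distance_set(c(3, 4, 5)))
reconstruct_best <- function(ds, n_sites = NULL, n_restarts = 10L,
                             refine_top = 5L, tie_tol = 1e-6, seed = 1L) {
  if (!inherits(ds, "distance_set")) ds <- distance_set(ds)
  if (length(ds$d) == 0L) stop("empty distance set", call. = FALSE)
  if (is.null(n_sites)) {
    n_sites <- switch(as.character(ds$m), "3" = 3L, "6" = 4L,
                      stop("total edge count ", ds$m, " is not triangular; ",
                           "supply n_sites to search degenerate expansions",
                           call. = FALSE))
  }
  stopifnot(n_sites %in% c(3L, 4L))
  m <- n_sites * (n_sites - 1L) / 2L
  if (ds$m == m) {
    expansions <- list(ds$multiplicity)
  } else {
    if (!all(ds$multiplicity == 1L)) {
      stop("multiplicities are set but do not sum to ", m, call. = FALSE)
    }
    expansions <- degenerate_expansions(length(ds$d), n_sites)
  }

  cand <- list()
  for (ei in seq_along(expansions)) {
    mu <- expansions[[ei]]
    lengths <- rep(ds$d, mu)
    if (n_sites == 3L) {
      sh <- reconstruct_triangle(lengths[1L], lengths[2L], lengths[3L])
      cand[[length(cand) + 1L]] <- list(shape = sh, expansion = mu,
                                        residual = sh$residual)
    } else {
      asn <- enumerate_assignments(lengths)
      exact <- lapply(asn, exact_embed)
      any_exact <- any(!vapply(exact, is.null, logical(1)))
      for (ai in seq_along(asn)) {
        sh <- exact[[ai]]
        if (is.null(sh)) {
          # when an exact fit exists, unrealizable assignments cannot win:
          # rank them by the cheap classical-scaling upper bound instead of
          # running the full stress minimization
          sh <- if (any_exact) mds_embed(asn[[ai]])
                else embed_assignment(asn[[ai]], n_restarts = 1L,
                                      seed = seed + ai)
        }
        cand[[length(cand) + 1L]] <- list(shape = sh, expansion = mu,
                                          residual = sh$residual)
      }
    }
  }

  res <- vapply(cand, `[[`, numeric(1), "residual")
  # refine the most promising infeasible candidates with the full budget
  # (pointless when an exactly realizable assignment already won)
  if (n_sites == 4L && n_restarts > 1L && min(res) > tie_tol) {
    ord <- order(res)
    for (i in ord[seq_len(min(refine_top, length(ord)))]) {
      if (cand[[i]]$residual > tie_tol) {
        sh <- embed_assignment(cand[[i]]$shape$assignment,
                               n_restarts = n_restarts, seed = seed + 1000L + i)
        if (sh$residual < cand[[i]]$residual) {
          cand[[i]]$shape <- sh
          cand[[i]]$residual <- sh$residual
        }
      }
    }
    res <- vapply(cand, `[[`, numeric(1), "residual")
  }

  ord <- order(res)
  cand <- cand[ord]
  res <- res[ord]
  tied <- which(res <= res[1L] + tie_tol)
  tie_shapes <- lapply(cand[tied], `[[`, "shape")
  # deterministic tie order: lexicographically smallest canonical coords
  if (length(tie_shapes) > 1L) {
    keys <- vapply(tie_shapes, function(s) {
      paste(sprintf("%.9f", as.numeric(t(s$coords))), collapse = ",")
    }, character(1))
    o <- order(keys)
    tie_shapes <- tie_shapes[o]
  }
  candidates <- data.frame(
    rank = seq_along(cand),
    residual = res,
    expansion = vapply(cand, function(x)
      paste(x$expansion, collapse = ","), character(1)),
    assignment = vapply(cand, function(x)
      paste(signif(x$shape$assignment, 8), collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  structure(list(shape = tie_shapes[[1L]], ties = tie_shapes,
                 candidates = candidates, n_sites = n_sites),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("Reconstruction over %d candidate(s); best residual %.3g nm",
              nrow(x$candidates), x$shape$residual))
  if (length(x$ties) > 1L) cat(sprintf(" (%d tied)", length(x$ties)))
  cat("\n")
  print(x$shape)
  invisible(x)
}
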