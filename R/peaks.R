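#' Fitted peak set of a FRET-event histogram
#'
#' Container for the components of a Gaussian-mixture fit of per-event
#' apparent FRET efficiencies: the non-zero peaks (mean, SD, weight, SEM of
#' the mean, responsibility-weighted event count) plus, optionally, the
#' donor-only peak anchored at E = 0. Peaks are sorted by mean and all
#' weights (including the zero peak) sum to 1.
#'
#' @param peaks Data frame with columns `mean`, `sd`, `weight`, `sem`, `n`.
#' @param zero_peak `NULL`, or a list with elements `weight` and `sd`.
#' @return An object of class `peak_set`.
#' @seealso [fit_peaks()]
#' @export
peak_set <- function(peaks, zero_peak = NULL) {
  stopifnot(is.data.frame(peaks),
            all(c("mean", "sd", "weight", "sem", "n") %in% names(peaks)))
  if (nrow(peaks) > 0L) {
    stopifnot(all(peaks$mean > 0), all(peaks$mean < 1), all(peaks$sd > 0),
              all(peaks$weight >= 0))
  }
  w <- sum(peaks$weight) + if (is.null(zero_peak)) 0 else zero_peak$weight
  if (abs(w - 1) > 1e-6) {
    stop("mixture weights must sum to 1 (got ", signif(w, 8), ")",
         call. = FALSE)
  }
  peaks <- peaks[order(peaks$mean), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(peaks = peaks, zero_peak = zero_peak), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("Peak set: %d non-zero peak(s)", nrow(x$peaks)))
  if (!is.null(x$zero_peak)) {
    cat(sprintf("; donor-only zero peak weight %.3f", x$zero_peak$weight))
  }
  cat("\n")
  if (nrow(x$peaks) > 0L) print(transform(x$peaks,
                                          mean = round(mean, 4),
                                          sd = round(sd, 4),
                                          weight = round(weight, 4),
                                          sem = signif(sem, 3),
                                          n = round(n, 1)))
  invisible(x)
}

#' Fit the FRET-event histogram as a Gaussian mixture
#'
#' Fits per-event apparent FRET efficiencies with an EM-estimated Gaussian
#' mixture of k = 1..`k_max` free components, optionally plus a component
#' whose mean is fixed at 0 to absorb donor-only binding events (the
#' dominant population in an unoptimized probe design). The number of free
#' components is chosen by BIC. Per-peak SEM is SD/sqrt(n) with n the
#' responsibility-weighted event count of the component.
#'
#' Initialization is deterministic (responsibility-free quantile split), so
#' refitting with permuted event order gives identical peaks; seeded jitter
#' restarts guard against poor local optima.
#'
#' @param events An event table from [detect_events()], or a numeric vector
#'   of per-event efficiencies.
#' @param k_max Maximum number of non-zero components to consider.
#' @param seed Integer seed for restart jitter.
#' @param zero_component Include the mean-0 donor-only component.
#' @param n_restarts EM restarts per k (first start is deterministic).
#' @param sd_floor Lower bound on component SD, in E units.
#' @param min_peak_E When a zero component is fitted, free components whose
#'   mean falls below this are counted as part of the donor-only population
#'   rather than reported as distance peaks: below it the Förster transform
#'   leaves the usable distance range and such components are
#'   indistinguishable from the tail of the zero pile.
#' @param min_weight Fitted components carrying less than this fraction of
#'   the non-zero mixture weight are discarded as splinters (too few events
#'   to constitute a distance peak).
#' @param merge_sep Components whose means are closer than `merge_sep`
#'   times their average SD are merged into one peak: they describe a
#'   single distance population that EM happened to model with two noise
#'   scales.
#' @return A [peak_set()].
#' @export
fit_peaks <- function(events, k_max = 6L, seed = 1L, zero_component = TRUE,
                      n_restarts = 3L, sd_floor = 5e-3, min_peak_E = 0.1,
                      min_weight = 0.02, merge_sep = 1) {
  x <- if (is.data.frame(events)) events$E_app else as.numeric(events)
  x <- x[is.finite(x)]
  if (length(x) < 20L) {
    stop("at least 20 events are required to fit peaks", call. = FALSE)
  }
  n <- length(x)
  best <- NULL
  for (k in seq_len(k_max)) {
    npar <- 3L * k - 1L + if (zero_component) 4L else 0L
    if (npar + 1L >= n) break
    fit <- em_best_of(x, k, zero_component, seed, n_restarts, sd_floor)
    if (is.null(fit)) next
    bic <- -2 * fit$loglik + npar * log(n)
    if (is.null(best) || bic < best$bic) {
      best <- fit
      best$bic <- bic
    }
  }
  if (is.null(best)) {
    stop("EM failed to converge for every candidate model", call. = FALSE)
  }
  as_peak_set(best, x, if (zero_component) min_peak_E else 0, min_weight,
              merge_sep)
}

as_peak_set <- function(fit, x, min_peak_E = 0, min_weight = 0,
                        merge_sep = 0) {
  nz <- fit$n_zero
  free <- setdiff(seq_along(fit$mean), seq_len(nz))
  low <- free[fit$mean[free] <= max(min_peak_E, 1e-6)]
  keep <- free[fit$mean[free] > max(min_peak_E, 1e-6) &
                 fit$mean[free] < 1 - 1e-6]
  if (length(keep) > 0L && min_weight > 0) {
    rel <- fit$weight[keep] / sum(fit$weight[keep])
    keep <- keep[rel >= min_weight]
  }
  comp <- data.frame(mean = fit$mean[keep], sd = fit$sd[keep],
                     weight = fit$weight[keep], n = fit$n_eff[keep])
  if (merge_sep > 0) comp <- merge_components(comp, merge_sep)
  peaks <- data.frame(mean = comp$mean, sd = comp$sd,
                      weight = comp$weight,
                      sem = comp$sd / sqrt(pmax(comp$n, 1)),
                      n = comp$n)
  zero <- NULL
  if (nz > 0L) {
    idx <- c(seq_len(nz), low)     # anchor scales + sub-range components
    wz <- fit$weight[idx]
    sz <- fit$sd[idx]
    # the zero anchor may use several noise scales; report it as one peak
    zero <- list(weight = sum(wz),
                 sd = if (sum(wz) > 0) sqrt(sum(wz * sz^2) / sum(wz))
                      else sz[1L])
  }
  # renormalize tiny numerical drift
  tot <- sum(peaks$weight) + if (is.null(zero)) 0 else zero$weight
  peaks$weight <- peaks$weight / tot
  if (!is.null(zero)) zero$weight <- zero$weight / tot
  peak_set(peaks, zero)
}

em_best_of <- function(x, k, zero_component, seed, n_restarts, sd_floor) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- em_init(x, k, zero_component, seed, jitter = r - 1L)
    fit <- try(em_gauss(x, init, sd_floor), silent = TRUE)
    if (inherits(fit, "try-error") || !fit$converged) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

# deterministic quantile-based init; restarts > 1 add seeded jitter.
# The zero anchor gets two half-normal scales because the event-averaged
# efficiency noise depends on the event length (SD ~ 1/sqrt(n_frames)).
em_init <- function(x, k, zero_component, seed, jitter = 0L) {
  xf <- x[x > 0.02]
  if (length(xf) < k) xf <- x
  qs <- stats::quantile(xf, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  s <- rep(max(stats::sd(xf) / k, 0.02), k)
  if (jitter > 0L) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()), add = TRUE)
    set.seed(seed + 7919L * jitter)
    qs <- qs + stats::rnorm(k, sd = 0.03)
  }
  n_zero <- if (zero_component) 2L else 0L
  mu <- c(rep(0, n_zero), qs)
  sd0 <- c(if (zero_component) c(0.01, 0.05) else NULL, s)
  w <- rep(1 / length(mu), length(mu))
  list(mean = mu, sd = sd0, weight = w, n_zero = n_zero)
}

em_gauss <- function(x, init, sd_floor, max_iter = 500L, tol = 1e-8,
                     zero_sd_cap = 0.12) {
  mu <- init$mean; sd <- init$sd; w <- init$weight
  n_zero <- init$n_zero
  n <- length(x)
  K <- length(mu)
  ll_old <- -Inf
  converged <- FALSE
  is_zero <- seq_len(K) <= n_zero
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(j) {
      if (is_zero[j]) {
        # donor-only anchor: event efficiencies are clipped at 0, so the
        # population is half-normal (mass at 0 plus a folded tail)
        w[j] * 2 * stats::dnorm(x, 0, sd[j])
      } else {
        w[j] * stats::dnorm(x, mu[j], sd[j])
      }
    }, numeric(n))
    rowsum_ <- rowSums(dens)
    rowsum_[rowsum_ < 1e-300] <- 1e-300
    ll <- sum(log(rowsum_))
    resp <- dens / rowsum_
    nk <- colSums(resp)
    w <- nk / n
    for (j in seq_len(K)) {
      if (nk[j] < 1e-8) next
      if (!is_zero[j]) {
        mu[j] <- sum(resp[, j] * x) / nk[j]
      }
      sd[j] <- sqrt(sum(resp[, j] * (x - mu[j])^2) / nk[j])
      sd[j] <- max(sd[j], sd_floor)
      if (is_zero[j]) sd[j] <- min(sd[j], zero_sd_cap)
    }
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  # canonical order: zero components first, free components by mean
  free <- which(!is_zero)
  o <- c(which(is_zero), free[order(mu[free])])
  list(mean = mu[o], sd = sd[o], weight = w[o], n_eff = nk[o],
       loglik = ll, converged = converged, n_zero = n_zero)
}

# iteratively merge the closest pair of components whose mean separation
# is below merge_sep x their average SD; the merged component carries the
# mixture mean and variance
merge_components <- function(comp, merge_sep) {
  while (nrow(comp) > 1L) {
    comp <- comp[order(comp$mean), , drop = FALSE]
    sep <- diff(comp$mean)
    lim <- merge_sep * (comp$sd[-nrow(comp)] + comp$sd[-1L]) / 2
    cand <- which(sep < lim)
    if (length(cand) == 0L) break
    i <- cand[which.min(sep[cand] / lim[cand])]
    w <- comp$weight[i:(i + 1L)]
    mu <- comp$mean[i:(i + 1L)]
    s <- comp$sd[i:(i + 1L)]
    wm <- sum(w * mu) / sum(w)
    vm <- sum(w * (s^2 + (mu - wm)^2)) / sum(w)
    comp$mean[i] <- wm
    comp$sd[i] <- sqrt(vm)
    comp$weight[i] <- sum(w)
    comp$n[i] <- sum(comp$n[i:(i + 1L)])
    comp <- comp[-(i + 1L), , drop = FALSE]
  }
  comp
}

#' Histogram of per-event FRET efficiencies
#'
#' @param events Event table or numeric vector of efficiencies.
#' @param bin_width Histogram bin width in E units.
#' @return Data frame with `bin_left` and `count`.
#' @export
fret_histogram <- function(events, bin_width = 0.02) {
  x <- if (is.data.frame(events)) events$E_app else as.numeric(events)
  breaks <- seq(0, 1 + bin_width, by = bin_width)
  h <- graphics::hist(pmin(pmax(x, 0), 1), breaks = breaks, plot = FALSE)
  data.frame(bin_left = h$breaks[-length(h$breaks)], count = h$counts)
}

#' Enumerate degenerate-peak multiplicity assignments
#'
#' When the number of resolved histogram peaks p is smaller than the
#' triangular number m = n(n-1)/2 expected for n sites, some peaks must be
#' degenerate: several underlying distances of equal value. This enumerates
#' every assignment of positive integer multiplicities (mu_1, ..., mu_p)
#' summing to m, in deterministic lexicographic order — the candidate
#' expansions to try during reconstruction.
#'
#' @param p_peaks Number of resolved peaks (1 <= p_peaks <= m).
#' @param n_sites Number of labeled sites (2-4).
#' @return List of integer vectors of length `p_peaks`, each summing to m.
#' @export
#' @examples
#' degenerate_expansions(3, 4)  # includes c(2, 2, 2), the D2-symmetric case
degenerate_expansions <- function(p_peaks, n_sites) {
  stopifnot(n_sites %in% 2:4, p_peaks >= 1L)
  m <- n_sites * (n_sites - 1L) / 2L
  if (p_peaks > m) {
    stop("more peaks (", p_peaks, ") than edges (", m, ")", call. = FALSE)
  }
  compositions_of(m, p_peaks)
}

# all compositions of m into p positive parts, lexicographic order
compositions_of <- function(m, p) {
  if (p == 1L) return(list(as.integer(m)))
  out <- list()
  for (first in seq_len(m - p + 1L)) {
    for (rest in compositions_of(m - first, p - 1L)) {
      out[[length(out) + 1L]] <- c(as.integer(first), rest)
    }
  }
  out
}
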