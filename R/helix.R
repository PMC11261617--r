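#' B-DNA helix model
#'
#' Idealized double-helix geometry used to model where docking strands (and
#' hence dyes) sit along a dsDNA edge. Defaults are standard B-DNA values:
#' 0.34 nm rise per base pair, 10.5 bp per turn, 1.0 nm helix radius.
#'
#' @param rise_per_bp Axial rise per base pair in nm.
#' @param bp_per_turn Base pairs per helical turn.
#' @param helix_radius Helix radius in nm.
#' @param phase Attachment phase offset in radians.
#' @return An object of class `helix_model`.
#' @export
helix_model <- function(rise_per_bp = 0.34, bp_per_turn = 10.5,
                        helix_radius = 1.0, phase = 0) {
  stopifnot(rise_per_bp > 0, bp_per_turn > 0, helix_radius > 0)
  structure(list(rise_per_bp = rise_per_bp, bp_per_turn = bp_per_turn,
                 helix_radius = helix_radius, phase = phase),
            class = "helix_model")
}

#' Dye positions on the helix
#'
#' Places the dye attached at base pair b at
#' ((r + L) cos theta_b, (r + L) sin theta_b, rise x b) with
#' theta_b = 2 pi b / bp_per_turn + phase: the attachment point on the
#' helix surface pushed radially outward by the linker length L.
#'
#' @param helix A [helix_model()].
#' @param bp Integer (or numeric) base-pair indices.
#' @param linker_length Radial linker length L in nm.
#' @return length(bp) x 3 coordinate matrix in nm.
#' @export
helix_dye_positions <- function(helix, bp, linker_length = 0) {
  stopifnot(inherits(helix, "helix_model"), linker_length >= 0)
  theta <- 2 * pi * bp / helix$bp_per_turn + helix$phase
  r <- helix$helix_radius + linker_length
  cbind(x = r * cos(theta), y = r * sin(theta),
        z = helix$rise_per_bp * bp)
}

#' Calibrate the Förster radius and linker length against the helix model
#'
#' Given sets of docking positions with known base-pair indices and their
#' measured pair efficiencies, jointly fits the Förster radius R0, the dye
#' linker length L and (optionally) the attachment phase by least squares
#' between the helix-model pair distances and the FRET-derived distances
#' R0 (1/E - 1)^(1/6).
#'
#' With every position on a single helix, the phase is a pure rotation of
#' the whole point set and does not affect distances; it is therefore held
#' fixed by default and only fitted when `fit_phase = TRUE` (for designs
#' where it is identifiable).
#'
#' @param sets List of measurement sets; each is a list with elements `bp`
#'   (base-pair indices of the docking positions) and `E` (the measured
#'   pair efficiencies in the pair order of [edge_pairs()], i.e. 12, 13,
#'   23, ... for the positions in `bp` order).
#' @param helix A [helix_model()].
#' @param init A [forster_model()] providing starting values.
#' @param fit_phase Also fit the attachment phase.
#' @param fix_linker If non-`NULL`, hold the linker length fixed at this
#'   value (nm) and fit only the remaining parameters.
#' @return List with `model` (the fitted [forster_model()]), `phase`,
#'   `set_rms` (per-set RMS distance residual in nm), `residuals` (all
#'   distance residuals), and the `nls.lm` fit object.
#' @export
helix_calibrate <- function(sets, helix = helix_model(),
                            init = forster_model(), fit_phase = FALSE,
                            fix_linker = NULL) {
  stopifnot(is.list(sets), length(sets) >= 1L,
            inherits(helix, "helix_model"), inherits(init, "forster_model"))
  if (length(sets) < 2L) {
    # a single triangle gives 3 distances for 2-3 parameters; demand more
    stop("at least 2 measurement sets are required for calibration",
         call. = FALSE)
  }
  n_res <- sum(vapply(sets, function(s) {
    n <- length(s$bp)
    stopifnot(n >= 2L, length(s$E) == n * (n - 1L) / 2L,
              all(s$E > 0), all(s$E < 1))
    n * (n - 1L) / 2L
  }, numeric(1)))
  free_linker <- is.null(fix_linker)
  n_par <- 1L + as.integer(free_linker) + as.integer(fit_phase)
  if (n_res <= n_par) {
    stop("under-determined calibration: ", n_res, " distances for ",
         n_par, " free parameters", call. = FALSE)
  }
  resid_fun <- function(par) {
    R0 <- par[["R0"]]
    L <- if (free_linker) par[["L"]] else fix_linker
    ph <- if (fit_phase) par[["phase"]] else helix$phase
    h <- helix_model(helix$rise_per_bp, helix$bp_per_turn,
                     helix$helix_radius, ph)
    unlist(lapply(sets, function(s) {
      P <- helix_dye_positions(h, s$bp, linker_length = L)
      model_d <- as.numeric(stats::dist(P))  # dist order == edge_pairs order
      meas_d <- R0 * (1 / s$E - 1)^(1 / 6)
      model_d - meas_d
    }))
  }
  par0 <- c(R0 = init$R0)
  lower <- 1e-3
  upper <- Inf
  if (free_linker) {
    par0 <- c(par0, L = init$linker_length)
    lower <- c(lower, 0)
    upper <- c(upper, Inf)
  }
  if (fit_phase) {
    par0 <- c(par0, phase = helix$phase)
    lower <- c(lower, -pi)
    upper <- c(upper, pi)
  }
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200L, ftol = 1e-14, ptol = 1e-14))
  par <- fit$par
  res <- resid_fun(par)
  sizes <- vapply(sets, function(s) {
    n <- length(s$bp); n * (n - 1L) / 2L
  }, numeric(1))
  grp <- rep(seq_along(sets), sizes)
  set_rms <- vapply(split(res, grp), function(r) sqrt(mean(r^2)),
                    numeric(1))
  list(model = forster_model(R0 = par[["R0"]],
                             linker_length = if (free_linker) par[["L"]]
                                             else fix_linker),
       phase = if (fit_phase) par[["phase"]] else helix$phase,
       set_rms = unname(set_rms), residuals = res, fit = fit)
}
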