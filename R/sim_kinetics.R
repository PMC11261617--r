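#' Imager species description
#'
#' One dye-labeled imager strand species competing for the docking sites:
#' its dye role, solution concentration, mean bound dwell time, and
#' association rate constant. An 8 nt imager dwells about 1.0 s; acceptor
#' imagers are typically used in ~10-fold excess (and/or with longer dwell)
#' to suppress donor-only events.
#'
#' @param label `"donor"` or `"acceptor"`.
#' @param concentration Concentration in nM (>= 0).
#' @param dwell_time Mean bound time tau in s (> 0).
#' @param k_on Association rate constant in /nM/s; default 1e-3, the scale
#'   typical of short-oligo hybridization.
#' @return An object of class `imager_species`.
#' @export
imager_species <- function(label = c("donor", "acceptor"),
                           concentration, dwell_time = 1.0, k_on = 1e-3) {
  label <- match.arg(label)
  stopifnot(is.numeric(concentration), concentration >= 0,
            is.numeric(dwell_time), dwell_time > 0,
            is.numeric(k_on), k_on > 0)
  structure(list(label = label, concentration = concentration,
                 dwell_time = dwell_time, k_on = k_on),
            class = "imager_species")
}

#' Probe-exchange assay design
#'
#' Describes the measurement: how many docking sites the molecule carries
#' (2-4), which imager species are in solution, and the recording frame time
#' and duration. The default 0.1 s frame time resolves a 1.0 s dwell over
#' about ten frames.
#'
#' @param n_sites Number of docking sites (2, 3 or 4).
#' @param species List of [imager_species()]; must contain at least one
#'   donor and one acceptor.
#' @param frame_time Camera frame time in s.
#' @param duration Total recording duration in s (>= `frame_time`).
#' @return An object of class `assay_design`.
#' @export
assay_design <- function(n_sites, species, frame_time = 0.1,
                         duration = 120) {
  stopifnot(n_sites %in% 2:4, is.list(species), length(species) >= 2L,
            all(vapply(species, inherits, logical(1), "imager_species")),
            frame_time > 0, duration >= frame_time)
  labels <- vapply(species, `[[`, character(1), "label")
  if (!("donor" %in% labels) || !("acceptor" %in% labels)) {
    stop("design needs at least one donor and one acceptor species",
         call. = FALSE)
  }
  structure(list(n_sites = as.integer(n_sites), species = species,
                 frame_time = frame_time, duration = duration),
            class = "assay_design")
}

#' Ground-truth geometry for trace synthesis
#'
#' Site coordinates in nm, the Förster radius and an optional dye linker
#' length. The effective dye positions are the site coordinates pushed
#' radially outward from their centroid by `linker_length`.
#'
#' @param site_coords n x 3 numeric matrix of docking-site coordinates (nm).
#' @param forster_radius Förster radius R0 in nm.
#' @param linker_length Dye linker length in nm (default 0: dyes at the
#'   sites).
#' @return An object of class `ground_truth_geometry`.
#' @export
ground_truth_geometry <- function(site_coords, forster_radius = 5.4,
                                  linker_length = 0) {
  site_coords <- as.matrix(site_coords)
  stopifnot(ncol(site_coords) == 3L, nrow(site_coords) >= 2L,
            forster_radius > 0, linker_length >= 0)
  if (min(stats::dist(site_coords)) <= 0) {
    stop("all pairwise site distances must be positive", call. = FALSE)
  }
  structure(list(site_coords = site_coords,
                 forster_radius = forster_radius,
                 linker_length = linker_length),
            class = "ground_truth_geometry")
}

#' Push points radially outward from their centroid
#'
#' Models the mean dye position given a flexible linker of length `L`
#' attached at each site, oriented away from the body of the molecule.
#'
#' @param coords n x 3 coordinate matrix (nm).
#' @param L Linker length in nm.
#' @return The expanded coordinate matrix.
#' @export
linker_expand <- function(coords, L) {
  coords <- as.matrix(coords)
  if (L == 0) return(coords)
  ctr <- colMeans(coords)
  out <- coords
  for (i in seq_len(nrow(coords))) {
    v <- coords[i, ] - ctr
    nv <- sqrt(sum(v^2))
    if (nv > 1e-12) out[i, ] <- coords[i, ] + v / nv * L
  }
  out
}

# matrix of pairwise FRET efficiencies between effective dye positions
pair_fret_matrix <- function(truth) {
  stopifnot(inherits(truth, "ground_truth_geometry"))
  dye <- linker_expand(truth$site_coords, truth$linker_length)
  D <- as.matrix(stats::dist(dye))
  E <- 1 / (1 + (D / truth$forster_radius)^6)
  diag(E) <- 0
  E
}

#' Simulate site occupancy under competitive imager exchange
#'
#' Each docking site is an independent continuous-time Markov chain:
#' empty -> bound(species s) at rate k_on(s) x concentration(s), and
#' bound(s) -> empty at rate 1/dwell_time(s). Event times are drawn exactly
#' (Gillespie); the per-frame state is the species occupying the majority of
#' the frame. Reproducible for a given seed.
#'
#' @param design An [assay_design()].
#' @param seed Integer seed.
#' @return An object of class `occupancy_trace`: an n_frames x n_sites
#'   integer matrix (0 = empty, j = bound by species j) with attributes
#'   `design`, `frame_time`, `seed`.
#' @export
simulate_occupancy <- function(design, seed = 1L) {
  stopifnot(inherits(design, "assay_design"))
  n_frames <- floor(design$duration / design$frame_time)
  if (n_frames < 1L) stop("design duration shorter than one frame",
                          call. = FALSE)
  conc <- vapply(design$species, `[[`, numeric(1), "concentration")
  kon <- vapply(design$species, `[[`, numeric(1), "k_on")
  tau <- vapply(design$species, `[[`, numeric(1), "dwell_time")
  lambda <- kon * conc
  if (sum(lambda) == 0) {
    warning("all imager concentrations are zero; trace is empty")
  }
  occ <- matrix(0L, n_frames, design$n_sites)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()), add = TRUE)
  set.seed(seed)
  for (s in seq_len(design$n_sites)) {
    occ[, s] <- simulate_site(lambda, tau, design$frame_time, n_frames)
  }
  structure(occ, class = "occupancy_trace", design = design,
            frame_time = design$frame_time, seed = seed)
}

# Gillespie simulation of one site, discretized to frames by majority time
simulate_site <- function(lambda, tau, frame_time, n_frames) {
  duration <- n_frames * frame_time
  R <- sum(lambda)
  n_states <- length(lambda) + 1L     # 0 = empty
  acc <- matrix(0, n_frames, n_states) # occupancy time per frame per state
  t <- 0
  state <- 0L
  while (t < duration) {
    if (state == 0L) {
      if (R == 0) {
        dt <- duration - t
        next_state <- 0L
      } else {
        dt <- stats::rexp(1L, R)
        next_state <- sample.int(length(lambda), 1L, prob = lambda)
      }
    } else {
      dt <- stats::rexp(1L, 1 / tau[state])
      next_state <- 0L
    }
    t1 <- min(t + dt, duration)
    # distribute the time in [t, t1) over the frames it overlaps
    if (t1 > t) {
      f0 <- floor(t / frame_time) + 1L
      f1 <- min(ceiling(t1 / frame_time), n_frames)
      col <- state + 1L
      for (f in f0:f1) {
        lo <- (f - 1L) * frame_time
        hi <- f * frame_time
        acc[f, col] <- acc[f, col] + max(0, min(t1, hi) - max(t, lo))
      }
    }
    t <- t + dt
    state <- next_state
  }
  max.col(acc, ties.method = "first") - 1L
}

#' Closed-form steady-state occupancy probabilities
#'
#' For the per-site competitive-binding Markov chain, the long-run
#' probability that a site is bound by species s is
#' p_s = k_on(s) c(s) tau(s) / (1 + sum_s' k_on(s') c(s') tau(s')).
#'
#' @param design An [assay_design()].
#' @return Named numeric vector: one probability per species, plus `empty`.
#' @export
occupancy_steady_state <- function(design) {
  stopifnot(inherits(design, "assay_design"))
  conc <- vapply(design$species, `[[`, numeric(1), "concentration")
  kon <- vapply(design$species, `[[`, numeric(1), "k_on")
  tau <- vapply(design$species, `[[`, numeric(1), "dwell_time")
  load <- kon * conc * tau
  p <- load / (1 + sum(load))
  names(p) <- paste0("species", seq_along(p))
  c(p, empty = 1 - sum(p))
}

#' Fraction of frames with exactly one donor and one acceptor bound
#'
#' The useful fraction of the recording: frames in which exactly one site is
#' occupied by a donor imager and exactly one site by an acceptor imager, so
#' that a single unambiguous FRET pair is observed. Maximized by acceptor
#' excess and longer acceptor dwell times.
#'
#' @param occ An [simulate_occupancy()] result.
#' @return Fraction in [0, 1].
#' @export
single_pair_fraction <- function(occ) {
  stopifnot(inherits(occ, "occupancy_trace"))
  if (nrow(occ) == 0L) stop("empty occupancy trace", call. = FALSE)
  design <- attr(occ, "design")
  labels <- vapply(design$species, `[[`, character(1), "label")
  donor_ids <- which(labels == "donor")
  acceptor_ids <- which(labels == "acceptor")
  nd <- rowSums(matrix(occ %in% donor_ids, nrow(occ)))
  na <- rowSums(matrix(occ %in% acceptor_ids, nrow(occ)))
  mean(nd == 1L & na == 1L)
}

#' Noise model for synthetic traces
#'
#' Additive per-channel Gaussian noise on a constant total emission while a
#' donor is excited, plus background noise when dark. No photobleaching,
#' blinking, or spectral crosstalk is modeled; the apparent efficiency is
#' the modeled quantity. Defaults give an event-averaged efficiency SD of
#' about 0.05 for ~1 s events at a 0.1 s frame time.
#'
#' @param channel_sd SD of the additive noise per channel while emitting
#'   (a.u.).
#' @param background_sd SD of the background in dark frames (a.u.).
#' @param I_total Mean total intensity while a donor is bound (a.u.).
#' @return A named list.
#' @export
noise_model <- function(channel_sd = 110, background_sd = 30,
                        I_total = 1000) {
  stopifnot(channel_sd >= 0, background_sd >= 0, I_total > 0)
  list(channel_sd = channel_sd, background_sd = background_sd,
       I_total = I_total)
}

#' Synthesize two-color intensity traces from a ground-truth geometry
#'
#' Runs the occupancy simulation for each molecule and converts per-frame
#' binding states into donor/acceptor intensities. Frames with exactly one
#' donor at site i and one acceptor at site j emit at the pair efficiency
#' E_ij of the Förster model applied to the effective dye distance;
#' donor-bound frames without an acceptor emit at E = 0 (the donor-only
#' population); frames without a bound donor carry only background, since
#' the acceptor is not directly excited.
#'
#' @param design An [assay_design()].
#' @param truth A [ground_truth_geometry()] with
#'   `nrow(site_coords) == design$n_sites`.
#' @param n_molecules Number of molecules (traces) to generate.
#' @param noise A [noise_model()].
#' @param seed Integer seed; per-molecule seeds are derived from it.
#' @return List of [intensity_trace()] objects; each carries its occupancy
#'   matrix as attribute `occupancy`.
#' @export
synthesize_traces <- function(design, truth, n_molecules = 1L,
                              noise = noise_model(), seed = 1L) {
  stopifnot(inherits(design, "assay_design"),
            inherits(truth, "ground_truth_geometry"))
  if (nrow(truth$site_coords) != design$n_sites) {
    stop("geometry has ", nrow(truth$site_coords), " sites but the design ",
         "expects ", design$n_sites, call. = FALSE)
  }
  E_pair <- pair_fret_matrix(truth)
  labels <- vapply(design$species, `[[`, character(1), "label")
  donor_ids <- which(labels == "donor")
  acceptor_ids <- which(labels == "acceptor")
  dye <- linker_expand(truth$site_coords, truth$linker_length)
  Dmat <- as.matrix(stats::dist(dye))
  lapply(seq_len(n_molecules), function(i) {
    mseed <- derive_seed(seed, i)
    occ <- simulate_occupancy(design, seed = mseed)
    n_frames <- nrow(occ)
    E <- frame_efficiency(occ, donor_ids, acceptor_ids, E_pair, Dmat,
                          truth$forster_radius)
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()), add = TRUE)
    set.seed(derive_seed(mseed, 1L))
    emitting <- !is.na(E)
    I_D <- stats::rnorm(n_frames, 0, noise$background_sd)
    I_A <- stats::rnorm(n_frames, 0, noise$background_sd)
    if (any(emitting)) {
      ne <- sum(emitting)
      I_A[emitting] <- E[emitting] * noise$I_total +
        stats::rnorm(ne, 0, noise$channel_sd)
      I_D[emitting] <- (1 - E[emitting]) * noise$I_total +
        stats::rnorm(ne, 0, noise$channel_sd)
    }
    tr <- intensity_trace(sprintf("mol_%04d", i),
                          time = (seq_len(n_frames) - 1L) * design$frame_time,
                          I_D = I_D, I_A = I_A)
    attr(tr, "occupancy") <- occ
    tr
  })
}

# per-frame apparent efficiency; NA = dark frame (no donor bound)
frame_efficiency <- function(occ, donor_ids, acceptor_ids, E_pair, Dmat,
                             R0) {
  n_frames <- nrow(occ)
  E <- rep(NA_real_, n_frames)
  donor_bound <- matrix(occ %in% donor_ids, n_frames)
  acceptor_bound <- matrix(occ %in% acceptor_ids, n_frames)
  nd <- rowSums(donor_bound)
  na_ <- rowSums(acceptor_bound)
  # donor-only frames
  E[nd >= 1L & na_ == 0L] <- 0
  # single-pair frames: the dominant informative case, vectorized
  sp <- which(nd == 1L & na_ == 1L)
  if (length(sp) > 0L) {
    di <- max.col(donor_bound[sp, , drop = FALSE], ties.method = "first")
    ai <- max.col(acceptor_bound[sp, , drop = FALSE], ties.method = "first")
    E[sp] <- E_pair[cbind(di, ai)]
  }
  # rare multi-imager frames: each donor transfers to all bound acceptors,
  # E averaged over donors
  multi <- which(nd >= 1L & na_ >= 1L & !(nd == 1L & na_ == 1L))
  for (f in multi) {
    ds <- which(donor_bound[f, ])
    as_ <- which(acceptor_bound[f, ])
    Ed <- vapply(ds, function(i) {
      kk <- sum((R0 / Dmat[i, as_])^6)
      kk / (1 + kk)
    }, numeric(1))
    E[f] <- mean(Ed)
  }
  E
}
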