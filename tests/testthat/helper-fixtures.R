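# Shared fixtures: generated in code, sized for fast default runs.

# triangle ground truth whose pair efficiencies are exactly `Es`
# (order: d12, d13, d23) at the given Forster radius
triangle_truth <- function(Es, R0 = 5.4) {
  fm <- forster_model(R0, 0)
  d <- fret_to_distance(Es, fm)
  ground_truth_geometry(reconstruct_triangle(d[1], d[2], d[3])$coords, R0)
}

# D2-symmetric tetrad from half-diagonals (a, b, c): opposite edges equal,
# three distinct pairwise distances of multiplicity two
d2_tetrad <- function(a = 0.8, b = 1.6, c = 2.6) {
  rbind(c(a, b, c), c(-a, -b, c), c(-a, b, -c), c(a, -b, -c))
}

# probe-exchange design used in the synthetic experiments: donor-limited
# binding with acceptor excess and a long acceptor dwell
sparse_design <- function(n_sites, duration = 360, tau_a = 8) {
  assay_design(n_sites,
               list(imager_species("donor", 50, 1.0),
                    imager_species("acceptor", 10, tau_a)),
               frame_time = 0.1, duration = duration)
}

# pooled event table from a synthetic experiment
synthetic_events <- function(design, truth, n_molecules, seed,
                             params = event_params()) {
  traces <- synthesize_traces(design, truth, n_molecules = n_molecules,
                              seed = seed)
  ev <- suppressWarnings(
    do.call(rbind, lapply(traces, detect_events, params = params)))
  class(ev) <- c("event_table", "data.frame")
  ev
}

# random 4-point configuration with a given seed
random_quad <- function(seed, sd = 3) {
  with_seed(seed, matrix(stats::rnorm(12, sd = sd), 4, 3))
}

# smallest RMSD between any tied reconstruction and the generating
# coordinates (vertex correspondence searched)
best_tie_rmsd <- function(rec, X) {
  min(vapply(rec$ties, function(s) fit_to_reference(s, X)$rmsd, numeric(1)))
}

with_seed <- fretshape:::with_seed
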