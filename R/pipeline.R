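#' Build a run configuration
#'
#' Assembles the configuration driving [run_pipeline()]. Every stochastic
#' stage receives a seed derived deterministically from the global seed, so
#' a run is fully reproducible.
#'
#' @param design An [assay_design()].
#' @param truth A [ground_truth_geometry()] (for synthetic runs), or `NULL`
#'   when `traces_file` is given.
#' @param traces_file Optional TSV of measured traces (see
#'   [read_traces()]); used instead of synthesis when `truth` is `NULL`.
#' @param n_molecules Number of molecules to synthesize.
#' @param noise A [noise_model()].
#' @param forster A [forster_model()] for the distance conversion.
#' @param event_params Parameters from [event_params()].
#' @param k_max Maximum non-zero peak count for [fit_peaks()].
#' @param multiplicity Optional distance multiplicities for reconstruction
#'   (e.g. `c(2, 2, 2)` for a D2-symmetric tetramer); `NULL` searches all
#'   degenerate expansions when needed.
#' @param bootstrap_B Bootstrap replicates over molecules (0 disables).
#' @param out_dir Output directory for artifacts (`NULL`: no files
#'   written).
#' @param seed Global integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(design, truth = NULL, traces_file = NULL,
                       n_molecules = 50L, noise = noise_model(),
                       forster = forster_model(),
                       event_params = fretshape::event_params(),
                       k_max = 6L, multiplicity = NULL, bootstrap_B = 0L,
                       out_dir = NULL, seed = 1L) {
  stopifnot(inherits(design, "assay_design"))
  if (is.null(truth) && is.null(traces_file)) {
    stop("either a ground-truth geometry (synthesis) or a traces file ",
         "must be supplied", call. = FALSE)
  }
  structure(list(design = design, truth = truth, traces_file = traces_file,
                 n_molecules = as.integer(n_molecules), noise = noise,
                 forster = forster, event_params = event_params,
                 k_max = as.integer(k_max), multiplicity = multiplicity,
                 bootstrap_B = as.integer(bootstrap_B), out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Synthesis (or trace loading) -> event detection -> histogram peak
#' fitting -> distance conversion -> 3D reconstruction -> bootstrap, in
#' one reproducible pass. With two docking sites the pipeline stops at the
#' single distance (no 3D reconstruction is defined). Any stage failure
#' aborts with a stage-named error; artifacts written before the failure
#' are preserved.
#'
#' @param config A [run_config()].
#' @return A result bundle: list with `traces`, `events`, `peaks`,
#'   `distances`, `reconstruction` (`NULL` for 2 sites), `bootstrap`
#'   (`NULL` unless requested), and `info` (seeds, parameters, versions).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  info <- list(seed = config$seed,
               package_version = as.character(utils::packageVersion("fretshape")),
               r_version = R.version.string,
               n_sites = config$design$n_sites)
  emit <- function(name, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, name))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  traces <- stage("synthesize", {
    if (!is.null(config$truth)) {
      synthesize_traces(config$design, config$truth,
                        n_molecules = config$n_molecules,
                        noise = config$noise,
                        seed = derive_seed(config$seed, 1L))
    } else {
      read_traces(config$traces_file)
    }
  })
  emit("traces.tsv", function(p) write_traces(traces, p))

  events <- stage("detect_events", {
    ev <- do.call(rbind, lapply(traces, detect_events,
                                params = config$event_params))
    class(ev) <- c("event_table", "data.frame")
    ev
  })
  if (nrow(events) == 0L) {
    stop("stage 'detect_events' failed: no events detected", call. = FALSE)
  }
  emit("events.tsv", function(p) write_events(events, p))
  emit("histogram.tsv", function(p) {
    utils::write.table(fret_histogram(events), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  peaks <- stage("fit_peaks", {
    fit_peaks(events, k_max = config$k_max,
              seed = derive_seed(config$seed, 2L))
  })
  emit("peaks.json", function(p) write_peaks(peaks, p))

  distances <- stage("distances", {
    peaks_to_distances(peaks, config$forster,
                       multiplicity = config$multiplicity)
  })

  reconstruction <- NULL
  boot <- NULL
  if (config$design$n_sites >= 3L) {
    reconstruction <- stage("reconstruct", {
      reconstruct_best(distances, n_sites = config$design$n_sites,
                       seed = derive_seed(config$seed, 3L))
    })
    emit("shape.csv", function(p) write_shape_csv(reconstruction$shape, p))
    emit("shape.pdb", function(p) write_shape_pdb(reconstruction$shape, p))
    if (config$bootstrap_B > 0L) {
      boot <- stage("bootstrap", {
        mol_sets <- molecule_distance_sets(events, peaks, config$forster,
                                           config$multiplicity)
        if (length(mol_sets) < 2L) {
          stop("fewer than 2 molecules carry all peaks")
        }
        bootstrap_shape(mol_sets, B = config$bootstrap_B,
                        seed = derive_seed(config$seed, 4L),
                        n_sites = config$design$n_sites)
      })
      emit("bootstrap.json", function(p) {
        jsonlite::write_json(list(vertex_sd = boot$vertex_sd,
                                  mean_coords = boot$mean_shape$coords),
                             p, auto_unbox = TRUE, digits = NA,
                             matrix = "rowmajor")
      })
    }
  }
  info$n_events <- nrow(events)
  info$n_molecules <- length(traces)
  emit("run_info.json", function(p) {
    jsonlite::write_json(info, p, auto_unbox = TRUE, digits = NA)
  })
  list(traces = traces, events = events, peaks = peaks,
       distances = distances, reconstruction = reconstruction,
       bootstrap = boot, info = info)
}

#' Per-molecule distance sets from pooled peaks
#'
#' Assigns each molecule's events to the pooled mixture components by
#' maximum responsibility, averages the efficiencies per component and
#' molecule, and converts to per-molecule distance sets. Molecules missing
#' any non-zero component are dropped (they cannot constrain the full
#' shape).
#'
#' @param events Pooled `event_table` with a `molecule_id` column.
#' @param peakset A [peak_set()] from the pooled fit.
#' @param model A [forster_model()].
#' @param multiplicity Optional multiplicities applied to every molecule.
#' @return Named list of [distance_set()] objects.
#' @export
molecule_distance_sets <- function(events, peakset,
                                   model = forster_model(),
                                   multiplicity = NULL) {
  stopifnot(inherits(peakset, "peak_set"), is.data.frame(events))
  pk <- peakset$peaks
  comp_mean <- c(if (!is.null(peakset$zero_peak)) 0 else NULL, pk$mean)
  comp_sd <- c(if (!is.null(peakset$zero_peak)) peakset$zero_peak$sd
               else NULL, pk$sd)
  comp_w <- c(if (!is.null(peakset$zero_peak)) peakset$zero_peak$weight
              else NULL, pk$weight)
  has_zero <- !is.null(peakset$zero_peak)
  assign_comp <- function(E) {
    dens <- vapply(seq_along(comp_mean), function(j) {
      comp_w[j] * stats::dnorm(E, comp_mean[j], comp_sd[j])
    }, numeric(length(E)))
    if (length(E) == 1L) dens <- matrix(dens, nrow = 1L)
    max.col(dens, ties.method = "first")
  }
  out <- list()
  for (mol in unique(events$molecule_id)) {
    E <- events$E_app[events$molecule_id == mol]
    comp <- assign_comp(E)
    if (has_zero) {
      keep <- comp > 1L
      comp <- comp[keep] - 1L
      E <- E[keep]
    }
    if (length(E) == 0L || length(unique(comp)) < nrow(pk)) next
    Ebar <- vapply(seq_len(nrow(pk)), function(j) mean(E[comp == j]),
                   numeric(1))
    Ebar <- pmin(pmax(Ebar, 1e-4), 1 - 1e-4)
    out[[as.character(mol)]] <-
      distance_set(fret_to_distance(Ebar, model),
                   multiplicity = if (is.null(multiplicity))
                     rep(1L, length(Ebar)) else multiplicity)
  }
  out
}
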