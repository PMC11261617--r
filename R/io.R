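#' Write intensity traces to a TSV file
#'
#' One row per frame with columns `molecule_id`, `frame`, `time_s`, `I_D`,
#' `I_A`; multiple molecules are concatenated.
#'
#' @param traces A single [intensity_trace()] or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "intensity_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read intensity traces from a TSV file
#'
#' @param path File written by [write_traces()] (or any TSV with the same
#'   columns).
#' @return List of [intensity_trace()] objects, one per molecule.
#' @export
read_traces <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("molecule_id", "frame", "time_s", "I_D", "I_A")
  if (!all(need %in% names(df))) {
    stop("trace file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(df, df$molecule_id), function(d) {
    d <- d[order(d$frame), ]
    intensity_trace(d$molecule_id[1L], d$time_s, d$I_D, d$I_A)
  })
}

#' Write an event table to TSV
#'
#' @param events An `event_table` (possibly rbind-ed over molecules).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event table from TSV
#'
#' @param path File written by [write_events()].
#' @return An `event_table` data frame.
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("event_table", "data.frame")
  df
}

#' Write a peak set to JSON
#'
#' @param peakset A [peak_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peakset, path) {
  stopifnot(inherits(peakset, "peak_set"))
  jsonlite::write_json(list(peaks = peakset$peaks,
                            zero_peak = peakset$zero_peak),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a peak set from JSON
#'
#' @param path File written by [write_peaks()].
#' @return A [peak_set()].
#' @export
read_peaks <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  zp <- if (is.null(x$zero_peak) || length(x$zero_peak) == 0L) NULL
        else as.list(x$zero_peak)
  peak_set(as.data.frame(x$peaks), zp)
}

#' Write shape coordinates to CSV
#'
#' Columns `vertex`, `x_nm`, `y_nm`, `z_nm`, `residual`.
#'
#' @param shape A [reconstructed_shape()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_shape_csv <- function(shape, path) {
  stopifnot(inherits(shape, "reconstructed_shape"))
  df <- data.frame(vertex = rownames(shape$coords),
                   x_nm = shape$coords[, 1L], y_nm = shape$coords[, 2L],
                   z_nm = shape$coords[, 3L], residual = shape$residual)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write shape coordinates as PDB pseudo-atoms
#'
#' One HETATM carbon pseudo-atom per vertex, coordinates converted from nm
#' to Angstrom, for visualization in standard structure viewers.
#'
#' @param shape A [reconstructed_shape()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_shape_pdb <- function(shape, path) {
  stopifnot(inherits(shape, "reconstructed_shape"))
  n <- nrow(shape$coords)
  xyz <- as.numeric(t(shape$coords * 10))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("HETATM", n),
                   resno = seq_len(n), resid = rep("DYE", n),
                   elety = rep("C", n), chain = rep("A", n))
  invisible(path)
}

#' Read reference coordinates from a PDB file
#'
#' Extracts atom coordinates (optionally restricted to a chain, element
#' type, or residue numbers) and converts Angstrom to nm.
#'
#' @param path PDB file path.
#' @param chain Optional chain identifier(s).
#' @param elety Optional atom name(s), e.g. `"CA"`.
#' @param resno Optional residue numbers.
#' @return n x 3 coordinate matrix in nm.
#' @export
read_reference_pdb <- function(path, chain = NULL, elety = NULL,
                               resno = NULL) {
  pdb <- bio3d::read.pdb(path)
  args <- list(pdb, verbose = FALSE)
  if (!is.null(chain)) args$chain <- chain
  if (!is.null(elety)) args$elety <- elety
  if (!is.null(resno)) args$resno <- resno
  sel <- do.call(bio3d::atom.select, args)
  xyz <- matrix(pdb$xyz[sel$xyz], ncol = 3L, byrow = TRUE)
  xyz / 10
}
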