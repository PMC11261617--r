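#' Förster model for efficiency-distance conversion
#'
#' Bundles the Förster radius `R0` (the donor-acceptor distance at which the
#' transfer efficiency is 0.5) with the mean dye linker length used when
#' comparing reconstructed dye positions against attachment-point coordinates.
#'
#' Defaults are a typical Cy3-Cy5 radius of 5.4 nm and a 1.8 nm linker; both
#' can be re-estimated from dsDNA calibration constructs with
#' [helix_calibrate()].
#'
#' @param R0 Förster radius in nm. Must be positive.
#' @param linker_length Mean dye linker length in nm. Must be non-negative.
#' @return An object of class `forster_model`.
#' @seealso [fret_to_distance()], [distance_to_fret()], [helix_calibrate()]
#' @export
#' @examples
#' fm <- forster_model(R0 = 5.4)
#' fret_to_distance(0.5, fm)  # equals R0
forster_model <- function(R0 = 5.4, linker_length = 1.8) {
  stopifnot(is.numeric(R0), length(R0) == 1L, R0 > 0,
            is.numeric(linker_length), length(linker_length) == 1L,
            linker_length >= 0)
  structure(list(R0 = R0, linker_length = linker_length),
            class = "forster_model")
}

#' @export
print.forster_model <- function(x, ...) {
  cat(sprintf("Forster model: R0 = %.3f nm, linker length = %.3f nm\n",
              x$R0, x$linker_length))
  invisible(x)
}

#' Convert apparent FRET efficiency to distance
#'
#' Inverts the Förster relation \eqn{E = 1/(1 + (r/R_0)^6)} to
#' \eqn{r = R_0 (1/E - 1)^{1/6}}.
#'
#' @param E Apparent FRET efficiency, strictly between 0 and 1 (vectorised).
#' @param model A [forster_model()].
#' @return Distances in nm.
#' @export
fret_to_distance <- function(E, model = forster_model()) {
  stopifnot(inherits(model, "forster_model"), is.numeric(E))
  if (any(!is.finite(E)) || any(E <= 0) || any(E >= 1)) {
    stop("FRET efficiency must lie strictly in (0, 1); the distance is ",
         "undefined at the endpoints", call. = FALSE)
  }
  model$R0 * (1 / E - 1)^(1 / 6)
}

#' Convert distance to FRET efficiency
#'
#' The forward Förster relation \eqn{E = 1/(1 + (r/R_0)^6)}.
#'
#' @param r Distance in nm, positive (vectorised).
#' @param model A [forster_model()].
#' @return Efficiencies in (0, 1).
#' @export
distance_to_fret <- function(r, model = forster_model()) {
  stopifnot(inherits(model, "forster_model"), is.numeric(r))
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("distance must be positive and finite", call. = FALSE)
  }
  1 / (1 + (r / model$R0)^6)
}

# Delta-method SD of the derived distance given the SEM of a peak mean.
# dr/dE = -R0/6 * (1/E - 1)^(-5/6) / E^2; reported magnitude only.
fret_distance_sd <- function(E, sem, model = forster_model()) {
  abs(model$R0 / 6 * (1 / E - 1)^(-5 / 6) / E^2) * sem
}
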