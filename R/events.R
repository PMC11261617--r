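#' Two-channel intensity trace for one immobilized molecule
#'
#' @param molecule_id Identifier for the molecule.
#' @param time Frame times in seconds, strictly increasing with constant
#'   step.
#' @param I_D,I_A Donor and acceptor channel intensities (arbitrary units),
#'   same length as `time`.
#' @return An object of class `intensity_trace` (a data frame with columns
#'   `molecule_id`, `frame`, `time_s`, `I_D`, `I_A`; frames are 0-based).
#' @export
intensity_trace <- function(molecule_id, time, I_D, I_A) {
  stopifnot(length(time) == length(I_D), length(I_D) == length(I_A),
            length(time) >= 1L)
  dt <- diff(time)
  if (length(dt) > 0L) {
    stopifnot(all(dt > 0))
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
      stop("frame times must have a constant step", call. = FALSE)
    }
  }
  out <- data.frame(molecule_id = molecule_id,
                    frame = seq_along(time) - 1L,
                    time_s = time, I_D = I_D, I_A = I_A)
  class(out) <- c("intensity_trace", "data.frame")
  out
}

#' Default event-detection parameters
#'
#' The baseline is the `baseline_quantile` quantile of the total intensity
#' (the median by default — a robust background center while bound frames
#' are the minority) and the noise SD is the MAD of the whole trace; frames
#' exceeding baseline + `k` x SD are considered bound. Runs shorter than `min_frames`
#' are dropped and runs separated by gaps of at most `gap_frames` frames are
#' merged.
#'
#' @param k Threshold in baseline SDs.
#' @param min_frames Minimum event length in frames.
#' @param gap_frames Maximum gap (frames) across which two runs are merged.
#' @param baseline_quantile Quantile of total intensity used as the
#'   baseline level.
#' @param max_internal_sd Events whose per-frame efficiency SD exceeds this
#'   are discarded — standard quality control against events in which the
#'   bound probe pair changed mid-event (the efficiency is then an average
#'   of two states and belongs to no peak). `Inf` disables the filter.
#' @param split_delta Minimum per-frame efficiency step at which an
#'   above-threshold run is split into separate events (recursive binary
#'   segmentation). A run during which the bound pair changes — e.g. an
#'   acceptor joining a bound donor mid-dwell — shows a step in the frame
#'   efficiency; splitting recovers the pure-state episodes. `Inf`
#'   disables splitting.
#' @return A named list of parameters.
#' @export
event_params <- function(k = 3, min_frames = 3L, gap_frames = 1L,
                         baseline_quantile = 0.5, max_internal_sd = 0.2,
                         split_delta = 0.2) {
  stopifnot(k > 0, min_frames >= 1L, gap_frames >= 0L,
            baseline_quantile > 0, baseline_quantile < 1,
            max_internal_sd > 0, split_delta > 0)
  list(k = k, min_frames = as.integer(min_frames),
       gap_frames = as.integer(gap_frames),
       baseline_quantile = baseline_quantile,
       max_internal_sd = max_internal_sd,
       split_delta = split_delta)
}

#' Detect binding events in a two-channel trace
#'
#' Thresholds the total intensity I_D + I_A against a baseline estimated
#' from the dimmest frames (noise SD from the robust MAD of the whole
#' trace) and returns contiguous above-threshold runs as
#' binding events, each with its averaged apparent FRET efficiency from
#' [event_fret()]. Detection is invariant to adding a constant offset to
#' both channels because the baseline is re-estimated from the shifted
#' trace.
#'
#' @param trace An [intensity_trace()] (or data frame with `I_D`, `I_A`).
#' @param params Parameters from [event_params()].
#' @return Data frame of class `event_table` with columns `molecule_id`,
#'   `start_frame`, `end_frame` (inclusive, 0-based), `n_frames`, `E_app`,
#'   `internal_sd` (SD of the per-frame efficiency within the event),
#'   `mean_I_D`, `mean_I_A`. Zero rows when nothing exceeds the threshold.
#'   Events failing the `max_internal_sd` quality filter are silently
#'   dropped.
#' @export
detect_events <- function(trace, params = event_params()) {
  stopifnot(is.data.frame(trace), all(c("I_D", "I_A") %in% names(trace)))
  if (nrow(trace) < 2L) stop("trace needs at least 2 frames", call. = FALSE)
  mol <- if ("molecule_id" %in% names(trace)) trace$molecule_id[1L] else NA
  total <- trace$I_D + trace$I_A
  # robust background statistics: bound frames are the minority, so the
  # baseline_quantile of the total intensity sits in the background and the
  # MAD is barely inflated. Estimating both from the dimmest frames alone
  # would be truncation-biased and set the threshold far too low.
  baseline <- stats::quantile(total, params$baseline_quantile,
                              names = FALSE)
  noise_sd <- stats::mad(total)
  if (!is.finite(noise_sd)) noise_sd <- 0
  threshold <- baseline + params$k * noise_sd
  bound <- total > threshold
  runs <- bound_runs(bound, params$gap_frames)
  if (nrow(runs) > 0L) {
    runs <- runs[runs$end - runs$start + 1L >= params$min_frames, ,
                 drop = FALSE]
  }
  # split runs in which the bound pair changed (efficiency step)
  if (is.finite(params$split_delta) && nrow(runs) > 0L) {
    Ef <- trace$I_A / pmax(total, .Machine$double.eps)
    split_list <- list()
    for (i in seq_len(nrow(runs))) {
      segs <- split_run(Ef, runs$start[i], runs$end[i],
                        params$split_delta, params$min_frames)
      split_list[[i]] <- segs
    }
    runs <- do.call(rbind, split_list)
    runs <- runs[runs$end - runs$start + 1L >= params$min_frames, ,
                 drop = FALSE]
  }

  out <- empty_event_table()
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]; e <- runs$end[i]
    Ed <- trace$I_D[s:e]; Ea <- trace$I_A[s:e]
    E <- event_fret(Ed, Ea)
    if (is.na(E)) {
      warning("event at frames ", s - 1L, "-", e - 1L,
              " dropped: no frame with positive total intensity")
      next
    }
    tot <- Ed + Ea
    ok <- tot > 0
    isd <- if (sum(ok) > 1L) stats::sd(Ea[ok] / tot[ok]) else 0
    if (is.finite(params$max_internal_sd) && isd > params$max_internal_sd) {
      next
    }
    out <- rbind(out, data.frame(molecule_id = mol,
                                 start_frame = s - 1L, end_frame = e - 1L,
                                 n_frames = e - s + 1L, E_app = E,
                                 internal_sd = isd,
                                 mean_I_D = mean(Ed), mean_I_A = mean(Ea)))
  }
  class(out) <- c("event_table", "data.frame")
  attr(out, "params") <- params
  out
}

empty_event_table <- function() {
  data.frame(molecule_id = character(0), start_frame = integer(0),
             end_frame = integer(0), n_frames = integer(0),
             E_app = numeric(0), internal_sd = numeric(0),
             mean_I_D = numeric(0), mean_I_A = numeric(0))
}

# recursive binary segmentation of one run on the per-frame efficiency:
# split at the boundary maximizing the mean difference between the two
# sides (each side at least min_frames), if that difference exceeds delta
split_run <- function(Ef, s, e, delta, min_frames) {
  n <- e - s + 1L
  if (n < 2L * min_frames) return(data.frame(start = s, end = e))
  x <- Ef[s:e]
  cum <- cumsum(x)
  best_diff <- 0
  best_cut <- 0L
  for (cut in min_frames:(n - min_frames)) {
    ml <- cum[cut] / cut
    mr <- (cum[n] - cum[cut]) / (n - cut)
    d <- abs(ml - mr)
    if (d > best_diff) {
      best_diff <- d
      best_cut <- cut
    }
  }
  if (best_diff <= delta) return(data.frame(start = s, end = e))
  rbind(split_run(Ef, s, s + best_cut - 1L, delta, min_frames),
        split_run(Ef, s + best_cut, e, delta, min_frames))
}

# contiguous TRUE runs, merging gaps of <= gap frames; 1-based start/end
bound_runs <- function(bound, gap) {
  r <- rle(bound)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) <= 1L || gap < 1L) return(runs)
  merged <- runs[1L, , drop = FALSE]
  for (i in 2L:nrow(runs)) {
    if (runs$start[i] - merged$end[nrow(merged)] - 1L <= gap) {
      merged$end[nrow(merged)] <- runs$end[i]
    } else {
      merged <- rbind(merged, runs[i, ])
    }
  }
  merged
}

#' Averaged apparent FRET efficiency of one event
#'
#' The per-frame apparent efficiency I_A/(I_A + I_D) averaged over the event
#' frames, then clipped to [0, 1]. Frames with non-positive total intensity
#' are excluded; the per-frame average (rather than the ratio of channel
#' means) matches per-event FRET histogramming and differs from the
#' ratio-of-means estimator under noise.
#'
#' @param I_D,I_A Donor and acceptor intensities over the event frames.
#' @return The averaged efficiency in [0, 1], or `NA` if every frame was
#'   excluded.
#' @export
#' @examples
#' event_fret(c(80, 60), c(20, 40))  # mean of 0.2 and 0.4 = 0.3
event_fret <- function(I_D, I_A) {
  stopifnot(length(I_D) == length(I_A), length(I_D) >= 1L)
  total <- I_D + I_A
  ok <- is.finite(total) & total > 0
  if (!any(ok)) return(NA_real_)
  E <- mean(I_A[ok] / total[ok])
  min(max(E, 0), 1)
}
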