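#' String-method burst detection
#'
#' Scans a spike train for maximal runs of consecutive spikes whose
#' inter-spike intervals are all at most `max_isi_ms` and that contain at
#' least `min_spikes` spikes. Runs are maximal by construction, so bursts
#' are non-overlapping, ordered in time, and every spike belongs to at most
#' one burst. Burst duration is measured first spike to last spike.
#'
#' @param train a [spike_train()].
#' @param min_spikes minimum number of spikes in a burst (default 5).
#' @param max_isi_ms maximum intra-burst inter-spike interval in ms
#'   (default 100).
#' @return Data frame with one row per burst: `electrode_id`, `start`, `end`
#'   (s), `n_spikes`, `duration_ms`, and the spike index range
#'   `first_spike`/`last_spike`.
#' @export
detect_bursts <- function(train, min_spikes = 5L, max_isi_ms = 100) {
  stopifnot(min_spikes >= 2, max_isi_ms > 0)
  t <- train$times
  empty <- data.frame(electrode_id = character(0), start = numeric(0),
                      end = numeric(0), n_spikes = integer(0),
                      duration_ms = numeric(0), first_spike = integer(0),
                      last_spike = integer(0), stringsAsFactors = FALSE)
  n <- length(t)
  if (n < min_spikes) return(empty)
  ok <- diff(t) <= max_isi_ms / 1000
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_spikes - 1L)
  if (!length(runs)) return(empty)
  i0 <- starts[runs]          # index into ISI vector -> spike index
  i1 <- ends[runs] + 1L
  data.frame(
    electrode_id = train$electrode_id,
    start = t[i0], end = t[i1],
    n_spikes = i1 - i0 + 1L,
    duration_ms = (t[i1] - t[i0]) * 1000,
    first_spike = i0, last_spike = i1,
    stringsAsFactors = FALSE
  )
}

#' Mean firing rate of a spike train
#'
#' @param train a [spike_train()].
#' @return Spike count divided by the observation window, in spikes/s.
#' @export
mean_firing_rate <- function(train) {
  w <- train$t_stop - train$t_start
  if (w <= 0) stop("mean_firing_rate: zero-length window", call. = FALSE)
  length(train$times) / w
}

#' Bursting rate and burst durations
#'
#' @param bursts data frame from [detect_bursts()].
#' @param window_s observation window in seconds.
#' @return List with `mbr` (bursts/min, `60 * n_bursts / window_s`) and
#'   `durations_ms`.
#' @export
burst_rate_and_durations <- function(bursts, window_s) {
  stopifnot(window_s > 0)
  list(mbr = 60 * nrow(bursts) / window_s, durations_ms = bursts$duration_ms)
}

#' Per-electrode spontaneous activity metrics
#'
#' Computes, for every electrode of a recording and over an explicit time
#' window (by default the spontaneous phase preceding the first stimulation
#' session), the mean firing rate (MFR, spikes/s), the mean bursting rate
#' (MBR, bursts/min), the mean burst duration (BD, ms) and the
#' active-electrode flag. An electrode counts as active when its MFR is not
#' lower than `active_threshold` (strictly-lower values are flagged
#' inactive).
#'
#' @param rec an `mea_recording`.
#' @param window numeric `c(start, stop)` in seconds; default `[0, first
#'   stimulus)` or the full duration when there are no sessions.
#' @param min_spikes,max_isi_ms burst-detection parameters, see
#'   [detect_bursts()].
#' @param active_threshold MFR activity threshold in spikes/s (default 0.1).
#' @return Data frame with one row per electrode: `electrode_id`, `mfr`,
#'   `mbr`, `n_bursts`, `mean_bd_ms`, `is_active`.
#' @export
spontaneous_metrics <- function(rec, window = NULL, min_spikes = 5L,
                                max_isi_ms = 100, active_threshold = 0.1) {
  if (is.null(window)) {
    first_stim <- suppressWarnings(
      min(vapply(rec$sessions, function(s) s$stimulus_times[1], 0)))
    window <- c(0, if (is.finite(first_stim)) first_stim else rec$duration)
  }
  stopifnot(length(window) == 2, window[2] > window[1])
  rows <- lapply(rec$trains, function(tr) {
    times <- tr$times[tr$times >= window[1] & tr$times < window[2]]
    sub <- spike_train(tr$electrode_id, times, window[1], window[2])
    b <- detect_bursts(sub, min_spikes, max_isi_ms)
    mfr <- mean_firing_rate(sub)
    rd <- burst_rate_and_durations(b, window[2] - window[1])
    data.frame(electrode_id = tr$electrode_id, mfr = mfr, mbr = rd$mbr,
               n_bursts = nrow(b),
               mean_bd_ms = if (nrow(b)) mean(rd$durations_ms) else NA_real_,
               is_active = mfr >= active_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "window") <- window
  out
}

#' Split activity metrics into active and inactive electrodes
#'
#' Electrodes whose MFR is strictly lower than the threshold are discarded
#' from downstream statistics; an MFR exactly at the threshold keeps the
#' electrode.
#'
#' @param metrics data frame from [spontaneous_metrics()] (needs `mfr`).
#' @param threshold activity threshold in spikes/s (default 0.1).
#' @return List with elements `active` and `inactive` (data frames).
#' @export
filter_active <- function(metrics, threshold = 0.1) {
  keep <- metrics$mfr >= threshold
  list(active = metrics[keep, , drop = FALSE],
       inactive = metrics[!keep, , drop = FALSE])
}
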