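#' Spike train of one electrode
#'
#' @param electrode_id electrode identifier.
#' @param times spike times in seconds, strictly increasing.
#' @param t_start,t_stop observation window in seconds.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(electrode_id, times = numeric(0), t_start = 0, t_stop) {
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times))) {
    stop("spike_train: non-finite spike times on ", electrode_id, call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("spike_train: spike times not strictly increasing on ", electrode_id,
         call. = FALSE)
  }
  if (t_stop <= t_start) stop("spike_train: t_stop must exceed t_start", call. = FALSE)
  if (length(times) && (times[1] < t_start || times[length(times)] > t_stop)) {
    stop("spike_train: spike times outside [t_start, t_stop] on ",
         electrode_id, call. = FALSE)
  }
  structure(list(electrode_id = as.character(electrode_id), times = times,
                 t_start = t_start, t_stop = t_stop),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d spikes in [%g, %g] s\n",
              x$electrode_id, length(x$times), x$t_start, x$t_stop))
  invisible(x)
}

#' Raw extracellular voltage trace of one electrode
#'
#' @param electrode_id electrode identifier.
#' @param samples voltage samples in microvolts.
#' @param sampling_rate sampling rate in Hz (default 10 kHz).
#' @param t_start time of the first sample in seconds.
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(electrode_id, samples, sampling_rate = 10000, t_start = 0) {
  samples <- as.numeric(samples)
  stopifnot(sampling_rate > 0)
  structure(list(electrode_id = as.character(electrode_id), samples = samples,
                 sampling_rate = sampling_rate, t_start = t_start),
            class = "raw_trace")
}

#' Stimulation session descriptor
#'
#' One session of low-frequency test stimulation delivered through a single
#' electrode. The default pulse descriptor records the protocol metadata:
#' biphasic, positive phase first, 400 us total with 50% duty cycle, 1.5 V
#' peak-to-peak, delivered at 0.2 Hz.
#'
#' @param stimulated_electrode identifier of the stimulated electrode.
#' @param stimulus_times stimulus delivery times in seconds, strictly
#'   increasing.
#' @param pulse_descriptor free-form metadata list describing the pulse.
#' @return An object of class `stimulation_session`.
#' @export
stimulation_session <- function(stimulated_electrode, stimulus_times,
                                pulse_descriptor = default_pulse_descriptor()) {
  stimulus_times <- as.numeric(stimulus_times)
  if (length(stimulus_times) == 0) {
    stop("stimulation_session: no stimulus times", call. = FALSE)
  }
  if (is.unsorted(stimulus_times, strictly = TRUE)) {
    stop("stimulation_session: stimulus times not strictly increasing",
         call. = FALSE)
  }
  structure(list(stimulated_electrode = as.character(stimulated_electrode),
                 stimulus_times = stimulus_times,
                 pulse_descriptor = pulse_descriptor),
            class = "stimulation_session")
}

#' @rdname stimulation_session
#' @export
default_pulse_descriptor <- function() {
  list(shape = "biphasic", polarity = "positive_first", duration_us = 400,
       duty_cycle = 0.5, amplitude_vpp = 1.5, frequency_hz = 0.2)
}

#' Recording container
#'
#' Bundles everything the pipeline consumes for one culture: layout,
#' compartment map, per-electrode spike trains, stimulation sessions and
#' metadata. `t = 0` is the recording start; stimulus times share the same
#' clock.
#'
#' @param layout an `mea_layout`.
#' @param trains named list of [spike_train()] objects (one per electrode).
#' @param compartments named character vector from [assign_compartments()]
#'   (or `NULL` for none).
#' @param sessions list of [stimulation_session()] objects.
#' @param duration recording duration in seconds.
#' @param population_label `"Cx"`, `"Hp"` or another free-form label.
#' @param sampling_rate acquisition sampling rate in Hz (metadata).
#' @param meta optional free-form metadata list.
#' @return An object of class `mea_recording`.
#' @export
mea_recording <- function(layout, trains, compartments = NULL,
                          sessions = list(), duration,
                          population_label = "other",
                          sampling_rate = 10000, meta = list()) {
  rec <- structure(
    list(layout = layout, compartments = compartments, trains = trains,
         sessions = sessions, population_label = population_label,
         duration = duration, sampling_rate = sampling_rate, meta = meta),
    class = "mea_recording"
  )
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  validate_layout(rec$layout)
  ids <- rec$layout$electrode_ids
  for (tr in rec$trains) {
    if (!inherits(tr, "spike_train")) {
      stop("recording: trains must be spike_train objects", call. = FALSE)
    }
    if (!(tr$electrode_id %in% ids)) {
      stop("recording: train references unknown electrode ", tr$electrode_id,
           call. = FALSE)
    }
    if (length(tr$times) && tr$times[length(tr$times)] > rec$duration + 1e-9) {
      stop("recording: spike time ", tr$times[length(tr$times)],
           " s exceeds duration ", rec$duration, " s on ", tr$electrode_id,
           call. = FALSE)
    }
  }
  if (anyDuplicated(vapply(rec$trains, function(t) t$electrode_id, ""))) {
    stop("recording: more than one train for the same electrode", call. = FALSE)
  }
  if (!is.null(rec$compartments)) {
    if (!all(names(rec$compartments) %in% ids)) {
      stop("recording: compartment map references unknown electrodes",
           call. = FALSE)
    }
  }
  for (s in rec$sessions) {
    if (!inherits(s, "stimulation_session")) {
      stop("recording: sessions must be stimulation_session objects",
           call. = FALSE)
    }
    if (!(s$stimulated_electrode %in% ids)) {
      stop("recording: session stimulates unknown electrode ",
           s$stimulated_electrode, call. = FALSE)
    }
    st <- s$stimulus_times
    if (st[1] < 0 || st[length(st)] > rec$duration + 1e-9) {
      stop("recording: stimulus times outside [0, duration]", call. = FALSE)
    }
  }
  invisible(rec)
}

#' @export
print.mea_recording <- function(x, ...) {
  nsp <- sum(vapply(x$trains, function(t) length(t$times), 0L))
  cat(sprintf(
    "<mea_recording> %s: %d electrodes, %d spikes, %d session(s), %g s\n",
    x$population_label, length(x$trains), nsp, length(x$sessions), x$duration))
  invisible(x)
}

#' Spike train lookup
#' @param rec an `mea_recording`.
#' @param electrode_id electrode identifier.
#' @return The electrode's [spike_train()]; an empty train if none stored.
#' @export
get_train <- function(rec, electrode_id) {
  for (tr in rec$trains) if (tr$electrode_id == electrode_id) return(tr)
  spike_train(electrode_id, numeric(0), 0, rec$duration)
}
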