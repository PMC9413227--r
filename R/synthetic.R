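#' Statistical profile of a synthetic network population
#'
#' Parameters of the synthetic-recording generator. The generator is a
#' statistical emulator, not a biophysical simulation: spontaneous activity
#' is homogeneous Poisson background plus injected burst combs, and evoked
#' activity is drawn per stimulus and electrode with an amplitude that
#' decays exponentially with distance from the stimulated electrode and a
#' latency that grows linearly with that distance.
#'
#' @param label population label (e.g. `"Cx-like"`, `"Hp-like"`).
#' @param background_rate homogeneous Poisson background, spikes/s.
#' @param burst_rate injected burst combs per minute (spontaneous phase).
#' @param burst_len spikes per burst comb.
#' @param burst_isi_ms intra-burst inter-spike interval, ms.
#' @param early_prob mean early evoked spikes per stimulus at the
#'   stimulation site (spikes/stimulus; Poisson-thinned with distance).
#' @param early_latency0_ms early latency at the stimulation site, ms.
#' @param latency_slope_ms latency increase per electrode pitch of distance,
#'   ms.
#' @param early_jitter_ms Gaussian jitter of early spike latencies, ms.
#' @param late_prob mean late evoked spikes per stimulus at the stimulation
#'   site (0 disables the late component).
#' @param late_latency_ms centre of the late component, ms.
#' @param late_spread_ms Gaussian spread of late spike latencies, ms.
#' @param spatial_decay length constant of the evoked-amplitude decay, in
#'   electrode pitches.
#' @return A list of class `population_profile`.
#' @export
population_profile <- function(label, background_rate, burst_rate, burst_len,
                               burst_isi_ms, early_prob, early_latency0_ms,
                               latency_slope_ms, early_jitter_ms, late_prob,
                               late_latency_ms, late_spread_ms, spatial_decay) {
  stopifnot(background_rate >= 0, burst_rate >= 0, burst_len >= 2,
            burst_isi_ms > 0, early_prob >= 0, early_latency0_ms >= 0,
            early_jitter_ms >= 0, late_prob >= 0, late_latency_ms >= 0,
            late_latency_ms <= 600, late_spread_ms >= 0, spatial_decay > 0)
  structure(list(label = label, background_rate = background_rate,
                 burst_rate = burst_rate, burst_len = burst_len,
                 burst_isi_ms = burst_isi_ms, early_prob = early_prob,
                 early_latency0_ms = early_latency0_ms,
                 latency_slope_ms = latency_slope_ms,
                 early_jitter_ms = early_jitter_ms, late_prob = late_prob,
                 late_latency_ms = late_latency_ms,
                 late_spread_ms = late_spread_ms,
                 spatial_decay = spatial_decay),
            class = "population_profile")
}

#' Cortical-like population profile
#'
#' Emulates the phenomenology of cortical networks under low-frequency
#' stimulation: higher background firing, long bursts, an early response
#' spread nearly uniformly over the array (large spatial decay constant)
#' whose latency grows with distance from the stimulation site, plus a late
#' evoked component a few hundred milliseconds after the stimulus.
#'
#' @return A `population_profile`.
#' @export
cx_profile <- function() {
  population_profile("Cx-like", background_rate = 2.0, burst_rate = 10,
                     burst_len = 12, burst_isi_ms = 10, early_prob = 0.8,
                     early_latency0_ms = 8, latency_slope_ms = 2,
                     early_jitter_ms = 2, late_prob = 0.6,
                     late_latency_ms = 200, late_spread_ms = 30,
                     spatial_decay = 30)
}

#' Hippocampal-like population profile
#'
#' Emulates hippocampal networks: lower background firing, shorter bursts,
#' a strong but spatially confined early response (small decay constant, so
#' only electrodes adjacent to the stimulation site respond), slightly
#' faster early latencies, and no late component.
#'
#' @return A `population_profile`.
#' @export
hp_profile <- function() {
  population_profile("Hp-like", background_rate = 0.1, burst_rate = 10,
                     burst_len = 8, burst_isi_ms = 10, early_prob = 1.8,
                     early_latency0_ms = 6, latency_slope_ms = 1.5,
                     early_jitter_ms = 1.5, late_prob = 0,
                     late_latency_ms = 200, late_spread_ms = 30,
                     spatial_decay = 2)
}

# delete spikes within min_isi of an accepted predecessor (greedy, earliest
# kept) so generated trains honour the detector's refractory contract
enforce_refractory <- function(t, min_isi = 1e-3) {
  n <- length(t)
  if (n < 2) return(t)
  keep <- logical(n)
  last <- -Inf
  for (i in seq_len(n)) {
    if (t[i] - last >= min_isi) {
      keep[i] <- TRUE
      last <- t[i]
    }
  }
  t[keep]
}

pick_stim_electrodes <- function(layout, compartments) {
  labs <- unique(stats::na.omit(as.character(compartments)))
  pos <- layout$positions
  vapply(labs, function(lb) {
    ids <- names(compartments)[!is.na(compartments) & compartments == lb]
    sel <- pos[pos$electrode_id %in% ids, , drop = FALSE]
    cx <- mean(sel$x); cy <- mean(sel$y)
    sel$electrode_id[which.min((sel$x - cx)^2 + (sel$y - cy)^2)]
  }, "")
}

#' Generate a ground-truthed synthetic recording
#'
#' Emulates one experimental session series: a spontaneous phase of
#' homogeneous Poisson background with injected burst combs, followed by
#' `n_sessions` stimulation sessions of `session_len` seconds at `stim_freq`
#' (the 0.2 Hz, 5-minute protocol yields exactly 60 stimuli per session),
#' each delivered through one electrode per compartment. Evoked early spike
#' counts per stimulus are Poisson with mean
#' `early_prob * exp(-d / spatial_decay)` at distance `d` (pitches) from the
#' stimulated electrode, at latency
#' `early_latency0 + latency_slope * d` plus Gaussian jitter; late spikes
#' (when `late_prob > 0`) are centred on `late_latency_ms`. All spike times
#' are rounded to the 0.1 ms sampling resolution and a 1 ms refractory
#' period is enforced, so the trains satisfy the detector's contract.
#'
#' @param profile a [population_profile()].
#' @param layout an `mea_layout`.
#' @param geometry compartment geometry (see [assign_compartments()]).
#' @param n_sessions number of stimulation sessions (default 3, one per
#'   compartment).
#' @param stim_freq stimulation frequency, Hz (default 0.2).
#' @param session_len session length, s (default 300).
#' @param spont_len spontaneous-phase length, s (default 600).
#' @param seed RNG seed; identical seeds reproduce the recording exactly.
#' @param stim_electrodes optional explicit stimulated electrodes (one per
#'   session); default: the electrode nearest each compartment centroid,
#'   in `session_order`.
#' @param session_order optional permutation of compartment labels giving
#'   the stimulation order (the first stimulated compartment is
#'   counterbalanced across cultures in the benchmark suite).
#' @param background_rate_per_electrode optional named vector overriding the
#'   profile background rate for selected electrodes.
#' @param response_scale optional named vector scaling the evoked response
#'   of selected electrodes (0 silences the evoked response).
#' @return List with `recording` (an `mea_recording`) and `ground_truth`
#'   (class `synthetic_ground_truth`): generator parameters, per-electrode
#'   background rates and response scales, and one truth table per session
#'   (`electrode_id`, `distance_pitches`, `early_mean`, `early_latency_ms`,
#'   `late_mean`, `late_latency_ms`).
#' @export
generate_recording <- function(profile, layout = mea_layout(),
                               geometry = default_compartment_geometry(layout),
                               n_sessions = 3, stim_freq = 0.2,
                               session_len = 300, spont_len = 600, seed = 1,
                               stim_electrodes = NULL, session_order = NULL,
                               background_rate_per_electrode = NULL,
                               response_scale = NULL) {
  stopifnot(stim_freq > 0, session_len > 0, spont_len >= 0, n_sessions >= 0)
  compartments <- assign_compartments(layout, geometry)
  ids <- layout$electrode_ids
  duration <- spont_len + n_sessions * session_len

  if (is.null(stim_electrodes)) {
    by_comp <- pick_stim_electrodes(layout, compartments)
    order_labs <- if (is.null(session_order)) names(by_comp) else session_order
    if (!all(order_labs %in% names(by_comp))) {
      stop("generate_recording: session_order names unknown compartments",
           call. = FALSE)
    }
    stim_electrodes <- unname(by_comp[order_labs])
    if (n_sessions > length(stim_electrodes)) {
      stim_electrodes <- rep_len(stim_electrodes, n_sessions)
    } else {
      stim_electrodes <- stim_electrodes[seq_len(n_sessions)]
    }
  }
  stopifnot(length(stim_electrodes) == n_sessions)

  rates <- stats::setNames(rep(profile$background_rate, length(ids)), ids)
  if (!is.null(background_rate_per_electrode)) {
    rates[names(background_rate_per_electrode)] <- background_rate_per_electrode
  }
  scales <- stats::setNames(rep(1, length(ids)), ids)
  if (!is.null(response_scale)) {
    scales[names(response_scale)] <- response_scale
  }

  n_stim <- floor(session_len * stim_freq)
  session_starts <- spont_len + (seq_len(n_sessions) - 1) * session_len
  stim_times <- lapply(session_starts, function(s0) {
    s0 + (seq_len(n_stim) - 1) / stim_freq
  })

  truth_sessions <- vector("list", n_sessions)
  spikes <- with_preserved_rng(seed, {
    per_session_dist <- lapply(stim_electrodes, function(se) {
      electrode_distances(layout, se)
    })
    for (s in seq_len(n_sessions)) {
      d <- per_session_dist[[s]][ids]
      g <- exp(-d / profile$spatial_decay) * scales[ids]
      truth_sessions[[s]] <- data.frame(
        electrode_id = ids,
        distance_pitches = unname(d),
        early_mean = unname(profile$early_prob * g),
        early_latency_ms = unname(profile$early_latency0_ms +
                                  profile$latency_slope_ms * d),
        late_mean = unname(profile$late_prob * g),
        late_latency_ms = if (profile$late_prob > 0) profile$late_latency_ms
                          else NA_real_,
        stringsAsFactors = FALSE
      )
    }
    lapply(ids, function(id) {
      # background over the whole recording
      n_bg <- stats::rpois(1, rates[[id]] * duration)
      t_all <- stats::runif(n_bg, 0, duration)
      # burst combs in the spontaneous phase only
      if (spont_len > 0 && profile$burst_rate > 0) {
        burst_dur <- (profile$burst_len - 1) * profile$burst_isi_ms / 1000
        n_b <- stats::rpois(1, profile$burst_rate / 60 * spont_len)
        if (n_b > 0) {
          onsets <- stats::runif(n_b, 0, max(spont_len - burst_dur, 0))
          comb <- (seq_len(profile$burst_len) - 1) * profile$burst_isi_ms / 1000
          t_all <- c(t_all, rep(onsets, each = profile$burst_len) + comb)
        }
      }
      # evoked components
      for (s in seq_len(n_sessions)) {
        tt <- truth_sessions[[s]]
        row <- match(id, tt$electrode_id)
        stims <- stim_times[[s]]
        me <- tt$early_mean[row]
        if (me > 0) {
          # multi-spike responses form a short comb (1.5 ms steps) with one
          # latency jitter draw per stimulus: evoked bursts, refractory-safe
          k <- stats::rpois(n_stim, me)
          hit <- which(k > 0)
          if (length(hit)) {
            base <- tt$early_latency_ms[row] +
              stats::rnorm(length(hit), 0, profile$early_jitter_ms)
            lat <- rep(base, k[hit]) + (sequence(k[hit]) - 1) * 1.5
            t_all <- c(t_all, rep(stims[hit], k[hit]) + pmax(lat, 0.2) / 1000)
          }
        }
        ml <- tt$late_mean[row]
        if (ml > 0) {
          k <- stats::rpois(n_stim, ml)
          if (sum(k) > 0) {
            lat <- profile$late_latency_ms +
              stats::rnorm(sum(k), 0, profile$late_spread_ms)
            t_all <- c(t_all, rep(stims, k) + pmax(lat, 0.2) / 1000)
          }
        }
      }
      t_all <- round_times(sort(t_all))
      t_all <- t_all[t_all >= 0 & t_all <= duration]
      t_all <- enforce_refractory(unique(t_all), 1e-3)
      spike_train(id, t_all, 0, duration)
    })
  })

  sessions <- lapply(seq_len(n_sessions), function(s) {
    stimulation_session(stim_electrodes[s], stim_times[[s]])
  })
  rec <- mea_recording(layout = layout, trains = spikes,
                       compartments = compartments, sessions = sessions,
                       duration = duration,
                       population_label = profile$label,
                       meta = list(generator = "meaevoked", seed = seed))
  truth <- structure(list(
    profile = profile, seed = seed,
    params = list(n_sessions = n_sessions, stim_freq = stim_freq,
                  session_len = session_len, spont_len = spont_len),
    background_rates = rates, response_scale = scales,
    stim_electrodes = stim_electrodes,
    stim_compartments = unname(compartments[stim_electrodes]),
    sessions = truth_sessions
  ), class = "synthetic_ground_truth")
  list(recording = rec, ground_truth = truth)
}

#' Biphasic spike waveform template
#'
#' Positive-first biphasic template used to render raw traces: a positive
#' half-sine followed by a larger negative half-sine, normalized to unit
#' peak-to-peak amplitude. The timestamp alignment point is the negative
#' trough (the extremum of larger absolute amplitude, where the detector
#' timestamps spikes).
#'
#' @param sampling_rate Hz.
#' @param pos_ms,neg_ms durations of the positive and negative phases.
#' @param pos_fraction fraction of the peak-to-peak amplitude carried by the
#'   positive phase.
#' @return List with `samples` (unit peak-to-peak), `trough_index`,
#'   `sampling_rate`.
#' @export
biphasic_template <- function(sampling_rate = 10000, pos_ms = 0.4,
                              neg_ms = 0.8, pos_fraction = 0.4) {
  np <- max(2L, round(pos_ms / 1000 * sampling_rate))
  nn <- max(2L, round(neg_ms / 1000 * sampling_rate))
  pos <- pos_fraction * sin(pi * seq_len(np) / (np + 1))
  neg <- -(1 - pos_fraction) * sin(pi * seq_len(nn) / (nn + 1))
  samples <- c(pos, neg)
  list(samples = samples, trough_index = np + which.min(neg),
       sampling_rate = sampling_rate)
}

#' Render raw voltage traces for ground-truth spike trains
#'
#' Adds a scaled spike waveform at every spike time of the selected
#' electrodes on top of Gaussian noise, for exercising the spike detector
#' against a known-injection oracle. Spikes closer than the template length
#' superpose (with a warning).
#'
#' @param rec an `mea_recording` (typically from [generate_recording()]).
#' @param electrode_ids electrodes to render (default: all).
#' @param t_start,t_stop time window to render, seconds.
#' @param amplitude_uv peak-to-peak spike amplitude in microvolts.
#' @param noise_sd_uv Gaussian noise SD in microvolts.
#' @param template waveform from [biphasic_template()].
#' @param seed RNG seed.
#' @return Named list of [raw_trace()] objects with the injected spike times
#'   attached as attribute `"injected_times"`.
#' @export
generate_raw_traces <- function(rec, electrode_ids = NULL, t_start = 0,
                                t_stop = rec$duration, amplitude_uv = 60,
                                noise_sd_uv = 3,
                                template = biphasic_template(rec$sampling_rate),
                                seed = 1) {
  stopifnot(amplitude_uv >= 0, noise_sd_uv >= 0, t_stop > t_start)
  if (is.null(electrode_ids)) {
    electrode_ids <- vapply(rec$trains, function(t) t$electrode_id, "")
  }
  fs <- template$sampling_rate
  n <- as.integer(round((t_stop - t_start) * fs))
  w <- amplitude_uv * template$samples
  wlen <- length(w)
  traces <- with_preserved_rng(seed, {
    lapply(electrode_ids, function(id) {
      x <- if (noise_sd_uv > 0) stats::rnorm(n, 0, noise_sd_uv) else numeric(n)
      tr <- get_train(rec, id)
      st <- tr$times[tr$times >= t_start & tr$times < t_stop]
      if (length(st) > 1 && min(diff(st)) < wlen / fs) {
        warning("generate_raw_traces: overlapping waveforms on ", id,
                " (superposed)", call. = FALSE)
      }
      anchor <- round((st - t_start) * fs) + 1 - (template$trough_index - 1)
      for (a in anchor) {
        lo <- max(a, 1)
        hi <- min(a + wlen - 1, n)
        if (hi >= lo) {
          x[lo:hi] <- x[lo:hi] + w[(lo - a + 1):(hi - a + 1)]
        }
      }
      out <- raw_trace(id, x, fs, t_start)
      attr(out, "injected_times") <- st
      out
    })
  })
  stats::setNames(traces, electrode_ids)
}

#' Paired cortical-like / hippocampal-like benchmark suite
#'
#' Generates the study-design-sized benchmark: `n_per_population` (default
#' 4) cortical-like and as many hippocampal-like recordings, each with one
#' spontaneous phase and 3 stimulation sessions (one stimulated electrode
#' per compartment), the first stimulated compartment rotating across
#' cultures. Fully deterministic given `seed`.
#'
#' @param seed master seed; per-recording seeds are derived from it.
#' @param n_per_population recordings per population (default 4).
#' @param layout an `mea_layout`.
#' @return List with `recordings` (named list), `ground_truths`, and a
#'   `manifest` data frame (recording, population, seed, session,
#'   stimulated electrode and compartment).
#' @export
make_benchmark_suite <- function(seed = 0, n_per_population = 4,
                                 layout = mea_layout()) {
  geometry <- default_compartment_geometry(layout)
  labs <- c("big", "small_left", "small_right")
  recs <- list()
  truths <- list()
  manifest <- list()
  base <- (abs(as.integer(seed)) %% 100000L) * 10000L
  for (pop in c("cx", "hp")) {
    profile <- if (pop == "cx") cx_profile() else hp_profile()
    for (i in seq_len(n_per_population)) {
      nm <- paste0(pop, i)
      sub_seed <- base + (if (pop == "cx") 0L else 5000L) + i
      ord <- labs[((i - 1 + 0:2) %% 3) + 1]
      g <- generate_recording(profile, layout = layout, geometry = geometry,
                              seed = sub_seed, session_order = ord)
      recs[[nm]] <- g$recording
      truths[[nm]] <- g$ground_truth
      manifest[[nm]] <- data.frame(
        recording = nm, population = profile$label, seed = sub_seed,
        session = seq_along(g$ground_truth$stim_electrodes),
        stim_electrode = g$ground_truth$stim_electrodes,
        stim_compartment = g$ground_truth$stim_compartments,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  list(recordings = recs, ground_truths = truths, manifest = manifest)
}

#' Simulate labeled PSTH profile sets
#'
#' Draws two well-separated families of PSTH profiles for exercising the
#' classifier against known labels: unimodal profiles with a single early
#' bump, and bimodal profiles with the same early bump plus a late bump.
#' Per-bin Gaussian measurement noise is added and truncated at zero.
#'
#' @param n_unimodal,n_bimodal profiles per family.
#' @param n_stimuli nominal stimulus count stored on the PSTHs.
#' @param early_center_ms,early_sd_ms early bump location and width.
#' @param late_center_ms,late_sd_ms late bump location and width.
#' @param late_fraction late bump mass as a fraction of the early mass.
#' @param noise_sd per-bin noise SD (spikes/stimulus).
#' @param seed RNG seed.
#' @return List with `psths` (list of `psth` objects) and `truth` (data
#'   frame: `electrode_id`, `has_late`).
#' @export
simulate_psth_classes <- function(n_unimodal = 20, n_bimodal = 20,
                                  n_stimuli = 60, early_center_ms = 16,
                                  early_sd_ms = 6, late_center_ms = 200,
                                  late_sd_ms = 25, late_fraction = 0.9,
                                  noise_sd = 0.005, seed = 1) {
  n_bins <- 150L
  bin_ms <- 4
  centers <- (seq_len(n_bins) - 0.5) * bin_ms
  base_early <- stats::dnorm(centers, early_center_ms, early_sd_ms) * bin_ms
  base_late <- stats::dnorm(centers, late_center_ms, late_sd_ms) * bin_ms
  make <- function(id, has_late, mass) {
    v <- mass * base_early + 0.003
    if (has_late) v <- v + late_fraction * mass * base_late
    v <- pmax(v + stats::rnorm(n_bins, 0, noise_sd), 0)
    structure(list(electrode_id = id, bin_ms = bin_ms, window_ms = 600,
                   bin_edges_ms = seq(0, 600, by = bin_ms), values = v,
                   counts = round(v * n_stimuli), n_stimuli = n_stimuli,
                   area = sum(v), raw_count_area = sum(round(v * n_stimuli)),
                   normalized_area = NA_real_, is_responsive = sum(v) >= 1,
                   is_stimulated = FALSE),
              class = "psth")
  }
  with_preserved_rng(seed, {
    flags <- c(rep(FALSE, n_unimodal), rep(TRUE, n_bimodal))
    ids <- sprintf("S%03d", seq_along(flags))
    masses <- stats::runif(length(flags), 0.85, 1.15)
    psths <- mapply(make, ids, flags, masses, SIMPLIFY = FALSE)
    list(psths = stats::setNames(psths, ids),
         truth = data.frame(electrode_id = ids, has_late = flags,
                            stringsAsFactors = FALSE))
  })
}
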