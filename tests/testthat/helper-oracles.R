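# Independent oracles and fixture builders used across the suite.
# These deliberately use the simplest possible logic (exhaustive scans,
# direct counting) and never call the implementation they check.

# maximal-run burst finder: for every spike, extend the run of <= max_isi
# gaps as far as it goes; keep runs that start maximally and are long enough
oracle_bursts <- function(times, min_spikes = 5, max_isi_ms = 100) {
  n <- length(times)
  max_isi <- max_isi_ms / 1000
  out <- list()
  for (i in seq_len(n)) {
    if (i > 1 && times[i] - times[i - 1] <= max_isi) next  # not a run start
    j <- i
    while (j + 1 <= n && times[j + 1] - times[j] <= max_isi) j <- j + 1
    if (j - i + 1 >= min_spikes) {
      out[[length(out) + 1]] <- c(start = times[i], end = times[j],
                                  n_spikes = j - i + 1)
    }
  }
  if (!length(out)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = numeric(0)))
  }
  as.data.frame(do.call(rbind, out))
}

# exhaustive local-maximum scan (interior bins only, strict both sides)
oracle_strict_local_maxima <- function(v) {
  n <- length(v)
  which(vapply(seq_len(n), function(i) {
    (i == 1 || v[i] > v[i - 1]) && (i == n || v[i] > v[i + 1])
  }, TRUE))
}

# direct in-window spike count for PSTH conservation checks; counts in
# exact 0.1 ms ticks, the declared resolution of stored spike times
oracle_window_count <- function(times, stim_times, window_s) {
  sum(vapply(stim_times, function(s) {
    d <- round((times - s) * 1e4)
    sum(d >= 0 & d < window_s * 1e4)
  }, 0L))
}

poisson_train <- function(id, rate, duration, seed) {
  set.seed(seed)
  n <- rpois(1, rate * duration)
  spike_train(id, sort(runif(n, 0, duration)), 0, duration)
}

# smooth two-bump profile on the 150-bin / 4-ms grid
two_bump_profile <- function(c1_ms, a1, sd1_ms, c2_ms = NA, a2 = 0, sd2_ms = 30,
                             baseline = 0) {
  centers <- (seq_len(150) - 0.5) * 4
  v <- a1 * exp(-(centers - c1_ms)^2 / (2 * sd1_ms^2)) + baseline
  if (!is.na(c2_ms)) v <- v + a2 * exp(-(centers - c2_ms)^2 / (2 * sd2_ms^2))
  v
}

# wrap a bare profile vector as a psth object
profile_as_psth <- function(id, values, n_stimuli = 60) {
  structure(list(electrode_id = id, bin_ms = 4, window_ms = 600,
                 bin_edges_ms = seq(0, 600, by = 4), values = values,
                 counts = round(values * n_stimuli), n_stimuli = n_stimuli,
                 area = sum(values), raw_count_area = sum(round(values * n_stimuli)),
                 normalized_area = NA_real_, is_responsive = sum(values) >= 1,
                 is_stimulated = FALSE),
            class = "psth")
}

# tiny layout + session helpers for fast unit tests
small_layout <- function(n = 4) mea_layout(n, n, pitch_um = 200, drop_corners = FALSE)

simple_session <- function(stim_id, n_stim = 60, start = 0, period = 5) {
  stimulation_session(stim_id, start + (seq_len(n_stim) - 1) * period)
}
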