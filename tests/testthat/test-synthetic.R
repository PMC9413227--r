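test_that("the 0.2 Hz, 5-minute protocol yields exactly 60 stimuli", {
  quiet <- population_profile("quiet", background_rate = 0, burst_rate = 0,
                              burst_len = 5, burst_isi_ms = 10, early_prob = 0,
                              early_latency0_ms = 10, latency_slope_ms = 0,
                              early_jitter_ms = 0, late_prob = 0,
                              late_latency_ms = 200, late_spread_ms = 10,
                              spatial_decay = 5)
  g <- generate_recording(quiet, seed = 1)
  expect_length(g$recording$sessions, 3)
  for (s in g$recording$sessions) {
    expect_length(s$stimulus_times, 60)
    expect_equal(unique(diff(s$stimulus_times)), 5)
  }
  expect_true(all(vapply(g$recording$trains,
                         function(t) length(t$times) == 0, TRUE)))
  expect_equal(g$recording$duration, 600 + 3 * 300)
})

test_that("background spike counts follow the configured Poisson rate", {
  prof <- population_profile("bg", background_rate = 5, burst_rate = 0,
                             burst_len = 5, burst_isi_ms = 10, early_prob = 0,
                             early_latency0_ms = 10, latency_slope_ms = 0,
                             early_jitter_ms = 0, late_prob = 0,
                             late_latency_ms = 200, late_spread_ms = 10,
                             spatial_decay = 5)
  g <- generate_recording(prof, n_sessions = 0, spont_len = 600, seed = 2)
  counts <- vapply(g$recording$trains, function(t) length(t$times), 0)
  expect_true(all(abs(counts - 3000) < 4 * sqrt(3000)))
})

test_that("evoked response matches its analytic expectation in the noiseless limit", {
  prof <- population_profile("det", background_rate = 0, burst_rate = 0,
                             burst_len = 5, burst_isi_ms = 10, early_prob = 1,
                             early_latency0_ms = 10, latency_slope_ms = 0,
                             early_jitter_ms = 0, late_prob = 0,
                             late_latency_ms = 200, late_spread_ms = 10,
                             spatial_decay = 6)
  g <- generate_recording(prof, n_sessions = 1, seed = 3)
  ses <- g$recording$sessions[[1]]
  tt <- g$ground_truth$sessions[[1]]
  for (id in sample(g$recording$layout$electrode_ids, 8)) {
    p <- compute_psth(get_train(g$recording, id), ses)
    mu <- tt$early_mean[tt$electrode_id == id]     # exp(-d / decay)
    expect_lt(abs(p$area - mu), 4 * sqrt(max(mu, 1e-6) / 60) + 1e-9)
    if (mu > 0.3) {
      expect_identical(which.max(p$values), 3L)    # latency 10 ms -> bin [8,12)
    }
  }
})

test_that("identical seeds reproduce identical recordings", {
  g1 <- generate_recording(cx_profile(), n_sessions = 1, session_len = 40,
                           spont_len = 40, seed = 11)
  g2 <- generate_recording(cx_profile(), n_sessions = 1, session_len = 40,
                           spont_len = 40, seed = 11)
  f1 <- tempfile(); f2 <- tempfile()
  save_recording(g1$recording, f1)
  save_recording(g2$recording, f2)
  expect_identical(readLines(f1), readLines(f2))
  g3 <- generate_recording(cx_profile(), n_sessions = 1, session_len = 40,
                           spont_len = 40, seed = 12)
  expect_false(identical(g1$recording$trains, g3$recording$trains))
})

test_that("generated trains honour the 1 ms refractory contract", {
  g <- generate_recording(hp_profile(), n_sessions = 1, session_len = 60,
                          spont_len = 60, seed = 13)
  for (tr in g$recording$trains) {
    if (length(tr$times) > 1) {
      expect_gte(min(diff(tr$times)), 1e-3 - 1e-9)
    }
  }
})

test_that("spontaneous rates stay within 3 sigma of the configuration", {
  for (seed in c(1, 2, 3)) {
    g <- generate_recording(cx_profile(), n_sessions = 0, spont_len = 600,
                            seed = seed)
    m <- spontaneous_metrics(g$recording)
    # expected MFR: background + burst spikes
    mu <- 2.0 + 10 * 12 / 60
    expect_lt(abs(mean(m$mfr) - mu), 3 * sqrt(mu / 600 / 120) + 0.05)
    # burst rate: 10/min nominal; adjacent combs can merge, so allow downward
    expect_lt(abs(mean(m$mbr) - 10), 3 * sqrt(10 / 10 / 120) + 0.5)
  }
})

test_that("raw traces carry the injected spikes and configured noise", {
  lay <- small_layout()
  trains <- list(spike_train("R01C01", c(0.2, 0.5, 0.9), 0, 2),
                 spike_train("R02C02", numeric(0), 0, 2))
  rec <- mea_recording(lay, trains, duration = 2)

  silent <- generate_raw_traces(rec, "R02C02", amplitude_uv = 50,
                                noise_sd_uv = 0, seed = 1)
  expect_true(all(silent[["R02C02"]]$samples == 0))

  noisy <- generate_raw_traces(rec, "R02C02", amplitude_uv = 50,
                               noise_sd_uv = 2, seed = 2)
  est <- estimate_noise_sd(noisy[["R02C02"]])
  expect_lt(abs(est - 2) / 2, 0.02)

  spiky <- generate_raw_traces(rec, "R01C01", amplitude_uv = 30,
                               noise_sd_uv = 3, seed = 3)
  st <- detect_spikes_ptsd(spiky[["R01C01"]])           # 10x noise at k = 8
  expect_length(st$times, 3)
  expect_true(all(abs(st$times - c(0.2, 0.5, 0.9)) <= 0.5e-3))
})

test_that("benchmark suite is reproducible and counterbalanced", {
  s1 <- make_benchmark_suite(seed = 1, n_per_population = 2)
  s2 <- make_benchmark_suite(seed = 1, n_per_population = 2)
  expect_identical(names(s1$recordings), c("cx1", "cx2", "hp1", "hp2"))
  f1 <- tempfile(); f2 <- tempfile()
  save_recording(s1$recordings$cx1, f1)
  save_recording(s2$recordings$cx1, f2)
  expect_identical(readLines(f1), readLines(f2))
  # stimulation order rotates across cultures
  m <- s1$manifest
  first_cx1 <- m$stim_compartment[m$recording == "cx1" & m$session == 1]
  first_cx2 <- m$stim_compartment[m$recording == "cx2" & m$session == 1]
  expect_false(identical(first_cx1, first_cx2))
  # every session stimulates a different compartment
  for (nm in names(s1$recordings)) {
    expect_setequal(m$stim_compartment[m$recording == nm],
                    c("big", "small_left", "small_right"))
  }
})

test_that("simulated psth classes are labeled and responsive", {
  sim <- simulate_psth_classes(n_unimodal = 5, n_bimodal = 5, seed = 2)
  expect_length(sim$psths, 10)
  expect_identical(sum(sim$truth$has_late), 5L)
  expect_true(all(vapply(sim$psths, function(p) p$is_responsive, TRUE)))
  areas <- vapply(sim$psths, function(p) p$area, 0)
  expect_true(all(areas[sim$truth$has_late] > areas[!sim$truth$has_late] - 0.5))
})
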