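# meaevoked

Analysis of spontaneous and stimulus-evoked activity of cultured neuronal
networks on 120-electrode micro-electrode arrays (MEAs).

Cortical and hippocampal cultures grown in compartmentalized devices respond
very differently to low-frequency electrical test stimulation (0.2 Hz,
biphasic pulses through a single electrode). `meaevoked` implements the
complete analysis chain for such experiments:

* **Spike detection** on raw voltage traces with a precise-timing
  differential-threshold detector (peak lifetime period 2 ms, refractory
  period 1 ms, threshold 8 × the per-electrode noise SD, robust MAD noise
  estimate), with the sample-level scan compiled in C++.
* **Spontaneous metrics**: string-method burst detection (≥ 5 spikes, all
  inter-spike intervals ≤ 100 ms), mean firing rate (MFR), mean bursting
  rate (MBR), burst duration (BD), and the active-electrode filter
  (MFR < 0.1 spikes/s discards the electrode).
* **PSTH**: post-stimulus time histograms over 600 ms windows at 4 ms bins,
  normalized per stimulus; electrodes with PSTH area < 1 are removed as
  unresponsive; areas normalized to the scope maximum for cross-network
  comparison; spatial area maps on the array grid.
* **Early/late response classification** — the analytical core. Responsive
  PSTHs are clustered with k-means (k chosen by silhouette analysis over
  2…8); each class mean is smoothed with a 50 ms moving average; an early
  peak x₁ is sought within 52 ms and a late peak x₂ beyond it (≥ 10% of the
  early peak's prominence); the separation statistic

  s = 1 − PSTH_smooth(x_min) / √(PSTH_smooth(x₁) · PSTH_smooth(x₂)),

  with x_min the inter-peak local minimum, declares a genuine late
  component when s > 0.3, and x_min then splits each member electrode's own
  PSTH into early and late latencies. Electrodes of early-only classes get
  the 650 ms sentinel late latency (beyond the observation window).
* **Group statistics**: Kruskal–Wallis comparisons (tie-corrected midranks,
  p < 0.05) across populations, compartments and stimulation sites, with a
  Kolmogorov–Smirnov (Lilliefors) normality screen and box-plot-style
  descriptors.
* **Synthetic data**: a seeded generator of ground-truthed recordings
  emulating cortical-like networks (uniform early response whose latency
  grows with distance from the stimulation site, plus a late component at
  ~200 ms) and hippocampal-like networks (strong but spatially confined
  early response, no late component), so every stage is verifiable without
  instrument data.

## Worked example

```r
library(meaevoked)

gcx <- generate_recording(cx_profile(), seed = 1)   # cortical-like culture
ghp <- generate_recording(hp_profile(), seed = 2)   # hippocampal-like culture
cfg <- pipeline_config(seed = 1)
rep_cx <- run_pipeline(gcx$recording, cfg)
rep_hp <- run_pipeline(ghp$recording, cfg)
rep_cx
#> <mea_report> Cx-like: 120 active electrodes, 3 session(s)
#>   session 1 (stim R06C04, big): 120 responsive, k = 2, 120 late
#>   session 2 (stim R03C10, small_left): 120 responsive, k = 3, 120 late
#>   session 3 (stim R09C10, small_right): 120 responsive, k = 4, 120 late
rep_hp
#> <mea_report> Hp-like: 120 active electrodes, 3 session(s)
#>   session 1 (stim R06C04, big): 8 responsive, k = 2, 0 late
#>   session 2 (stim R03C10, small_left): 5 responsive, k = 2, 0 late
#>   session 3 (stim R09C10, small_right): 7 responsive, k = 2, 0 late
```

Every cortical-like electrode responds (the early response spreads over the
whole array) and every session exhibits a late component; in the
hippocampal-like culture only the handful of electrodes adjacent to the
stimulation site pass the area filter, and no class has a late component —
their late latencies are all at the 650 ms sentinel. A class record shows
the classifier's internals:

```r
rep_cx$sessions[[1]]$classification$classes[[1]][c("x1_ms", "x2_ms", "x_min_ms", "s")]
#> class 1: x1 = 2 ms, x2 = 198 ms, x_min = 50 ms, s = 0.87
```

The early peak sits at the start of the window, the late peak at ~200 ms,
and the dip between them is deep (s = 0.87 ≫ 0.3), so the class is split at
x_min = 50 ms. Cross-recording tables condense the comparison:

```r
summarize_reports(list(cx = rep_cx, hp = rep_hp))
#> Spontaneous metrics (pooled over active electrodes):
#>  recording_id population n_active mfr_mean mbr_mean   bd_mean
#>            cx    Cx-like      120 3.959083 9.640833 135.55889
#>            hp    Hp-like      120 1.433639 9.720833  73.39131
#> Evoked-response counts (compartment-session pairs):
#>  population n_early n_late
#>     Cx-like       9      9
#>     Hp-like       3      0
#> normalized_area: H = 26, p = 3.33e-07 *
#> early_latency: H = 6.23, p = 0.0126 *
```

The cortical-like culture fires faster (MFR ≈ 4.0 vs 1.4 spikes/s), bursts
equally often (MBR ≈ 9.6 vs 9.7 bursts/min) but longer (BD ≈ 136 vs 73 ms),
responds early in all 9 compartment-session pairs with a late component in
all 9, whereas the hippocampal-like culture responds only in the stimulated
compartment (3 of 9) and never late; normalized PSTH areas and early
latencies differ significantly between the populations.

`save_recording()` / `load_recording()` persist recordings as a documented
JSON schema or a per-electrode CSV directory, with spike times at 0.1 ms
resolution and deterministic output. `generate_raw_traces()` renders
Gaussian-noise voltage traces with biphasic waveforms at ground-truth spike
times for exercising `detect_spikes_ptsd()`.

See the methods vignette (`vignettes/mea-evoked-analysis.Rmd`) for the
models, parameter meanings, numerical conventions and design choices.

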