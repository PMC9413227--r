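---
title: "Spontaneous and stimulus-evoked MEA activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spontaneous and stimulus-evoked MEA activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaevoked)
```

## The system and the question

Dissociated cortical or hippocampal neurons cultured on a planar
micro-electrode array (MEA) develop spontaneous spiking and bursting within a
few weeks. When a single electrode delivers low-frequency test pulses
(0.2 Hz, biphasic, well below plasticity-inducing rates), the network answers
with an *evoked response* whose structure is informative about the circuit:
a fast **early** component within a few tens of milliseconds (conventionally
attributed to AMPA-mediated transmission) and, in some preparations, a slow
**late** component between roughly 35 and 500 ms (NMDA-mediated
nomenclature). `meaevoked` implements the full analysis chain for such
experiments on 120-electrode arrays — spike detection, burst and rate
metrics, post-stimulus time histograms (PSTHs), and an automatic early/late
response classifier — together with a ground-truthed synthetic generator so
that every stage is testable without instrument data.

The package takes no position on receptor pharmacology: *early* and *late*
are names for temporal components of the PSTH, nothing more.

## Data model

A `mea_recording` bundles an electrode layout (default: the standard
120-electrode 12 × 12 grid at 200 µm pitch with 6-electrode corner triangles
absent), a compartment map (the three-chamber PDMS device: one large and two
small chambers connected by microchannels; electrodes under the channels stay
unassigned), one spike train per electrode, and stimulation sessions
(stimulated electrode plus stimulus times). Time zero is the recording
start; all clocks are shared. Spike times are stored in seconds and
serialized at 0.1 ms — the period of the 10 kHz acquisition sampling — which
makes saving deterministic and round-trips exact. The native formats are a
single JSON document and a per-electrode CSV directory; both are plain text.

The compartment geometry differs between physical devices and is therefore a
per-dataset input (rectangles and circles in µm); `assign_compartments()`
requires the regions to be disjoint and leaves uncovered electrodes
unassigned.

## Spike detection

`detect_spikes_ptsd()` implements a precise-timing differential-threshold
detector. Its three parameters are the *peak lifetime period* (2 ms), the
*refractory period* (1 ms) and the threshold multiplier (8 × the noise SD,
estimated per electrode). The algorithm body is our interpretation of the
published scheme, which names the parameters but not every rule:

1. scan the trace for relative extrema (plateaus contribute their first
   sample);
2. pair each extremum with the opposite-polarity extremum within the peak
   lifetime period that maximizes the peak-to-peak excursion;
3. accept the pair when that differential amplitude reaches the threshold;
4. timestamp at the extremum of larger absolute voltage (ties broken toward
   the earlier one — determinism);
5. on refractory conflicts keep the larger-amplitude event, so output
   inter-spike intervals never violate refractoriness.

The threshold is differential (peak-to-peak) and polarity-agnostic. The
noise SD defaults to the scaled median absolute deviation,
`median(|x − median(x)|)/0.6745`, because the spikes themselves inflate a
global sample SD; the global SD is available for comparison, and both
estimators operate on the full trace (whether a spike-free segment should be
preferred is left to the caller). Detection counts are monotone in the
threshold, and scaling trace and threshold together leaves spike times
unchanged. No stimulus-artifact blanking is applied by default; a blanking
window after each stimulus is available (`blank_ms`).

The sample-level scan is compiled (C++) because traces are long
(10 kHz × minutes) and the extrema scan is inherently sequential.

## Spontaneous metrics

Bursts are maximal runs of at least 5 spikes whose inter-spike intervals are
all ≤ 100 ms (the "string" rule). Burst duration is measured first spike to
last spike; the source analyses leave this convention implicit, so it is
stated here and in the outputs. Per electrode we report the mean firing rate
(MFR, spikes/s over the analysis window), the mean bursting rate (MBR,
bursts/min, normalized by the full window rather than active time), and
burst durations (ms). Electrodes with MFR *strictly below* 0.1 spikes/s are
flagged inactive and excluded downstream — an MFR of exactly 0.1 keeps the
electrode, following the verbatim "lower than" rule. Spontaneous metrics are
computed on the spontaneous phase only (default: from time zero to the first
stimulus), and for population summaries the three compartments are pooled.

## PSTH

`compute_psth()` counts spikes in half-open 600 ms windows after each
stimulus, bins them at 4 ms (150 bins; a spike exactly at the stimulus time
falls in bin 1), and divides each bin by the number of stimuli — so values
are spikes per stimulus per bin and the *area* (sum over bins) is evoked
spikes per stimulus. Electrodes with area strictly below 1 are considered
unable to evoke a minimal response and are removed. For cross-network
comparability, areas are normalized by the maximum over a scope; the scope
is not fixed by the area definition, so both per-recording-session (default)
and per-dataset normalization are provided and the choice is recorded on the
result. Because the raw-count reading of an "area in spikes" is also in use,
`raw_count_area = area × n_stimuli` is always reported alongside.

Window and bin arithmetic is done in integer 0.1 ms ticks (the declared
time resolution), so edge spikes are never misplaced by binary round-off and
the conservation identity `sum(counts) = in-window spike count` holds
exactly. Overlapping stimulus windows cannot occur at 0.2 Hz but are
detected and rejected for nonconformant sessions. The stimulated electrode's
own PSTH is computed and flagged (`is_stimulated`); it is included in
statistics by default, configurable.

## Early/late response classification

This is the package's analytical core. Per stimulation session:

1. **Clustering.** The responsive electrodes' 150-bin PSTHs are clustered
   with k-means (Euclidean distance on raw profiles; multiple restarts under
   a fixed seed). The number of classes is chosen by maximizing the mean
   silhouette width over k = 2…8, restricted to at most n − 1 and to the
   number of distinct profiles. If fewer than two distinct profiles exist
   the silhouette is undefined and a single class is returned — the
   documented degenerate rule.
2. **Class profile.** Each class's member PSTHs are averaged bin-wise and
   smoothed with a centered moving average of 50 ms. At 4 ms bins this is
   realized as 13 bins (52 ms), the nearest odd width: odd windows do not
   shift peak positions. Edge bins use a shrunken window, which preserves
   constants and total interpretability at the borders.
3. **Peaks.** The early peak x₁ is the highest local maximum whose bin
   centre lies within the first 52 ms. If one exists, a late peak x₂ is
   sought among local maxima beyond 52 ms whose topographic prominence is at
   least 10% of x₁'s; the highest qualifying maximum wins. Prominence is
   computed by walking from the peak to the nearest higher point (or the
   array edge) on each side and taking the higher of the two interval
   minima as the base; a side with no samples imposes no base, so a peak in
   the first bin still has a meaningful prominence. Classes without an
   early peak are labeled non-responding and excluded from latency
   statistics.
4. **Separation.** With both peaks present, the local minimum x_min of the
   smoothed profile strictly between them is located and the separation
   statistic computed. The default `dip_depth` form is

   s = 1 − PSTH_smooth(x_min) / √(PSTH_smooth(x₁) · PSTH_smooth(x₂)),

   which is 1 when the valley reaches zero and 0 when it reaches the
   geometric mean of the peaks, so s grows with separation and the rule
   "s > 0.3 ⇒ the peaks are separable" is meaningful. The typography of the
   published statistic is ambiguous (it renders as a collapsed fraction); a
   literal product-ratio form `v/(p₁·p₂)` is provided as `literal_ratio`,
   and the form used is recorded in every result. When s > 0.3 the class
   `has_late`, and x_min becomes the class's *time threshold* dividing early
   from late; otherwise the class is early-only.
5. **Latencies.** Each classified electrode receives an early latency — the
   bin centre of the largest value of its own PSTH up to
   min(52 ms, time threshold) — and, if its class has a late component, a
   late latency (largest value beyond the time threshold). Electrodes of
   early-only classes get the sentinel 650 ms, a value beyond the 600 ms
   observation window that unambiguously codes "no late response" while
   remaining plottable and comparable.

One design choice deserves emphasis: class-level structure (x₁, x₂, x_min,
s) is computed on the *smoothed class mean*, but per-electrode latencies use
the electrode's *raw* PSTH inside the class-derived windows. A 13-bin moving
average applied to a single electrode whose evoked peak is narrower than the
window produces an 11-bin plateau of tied values, which makes an argmax
ill-defined at the 4 ms scale; the raw histogram keeps bin-level precision,
and the class windows supply the denoising that smoothing would otherwise
provide. The bridging from class-level peaks to per-electrode maps is an
interpretation either way; this one is stated and tested (latency recovery
within one bin on ground-truthed data).

Scale invariance holds throughout: multiplying all PSTHs by a positive
constant changes neither labels, peak positions, nor the dip-depth s.

## Group statistics

Distributions of evoked measures are heavily non-normal (and latencies are
tied at the 4 ms resolution), so comparisons use the Kruskal–Wallis test on
midranks with tie correction, with significance at p < 0.05. A
Kolmogorov–Smirnov normality screen (Lilliefors correction, since the normal
parameters are estimated) is run first but is advisory only — the pipeline
always proceeds nonparametrically. Descriptors report mean ± SD alongside
median and quartiles for box-plot-style summaries. No multiple-testing
correction is applied; `site_comparisons()` reports raw p-values and attaches
the number of comparisons performed so users can correct as they see fit.
For site-effect tables the default grouping unit is the compartment mean
(per stimulation), with per-electrode tables also available.

## The synthetic generator

`generate_recording()` emulates the statistical structure the analysis
assumes — it is explicitly *not* a biophysical simulation (no membranes, no
synapses), and conclusions from it are about the pipeline, not about tissue.

* **Protocol.** 600 s of spontaneous activity, then three 300 s sessions at
  0.2 Hz — exactly 60 stimuli at 5 s spacing — each stimulating the
  electrode nearest one compartment's centroid; the first stimulated
  compartment rotates across cultures of the benchmark suite.
* **Spontaneous phase.** Homogeneous Poisson background per electrode plus
  burst combs (fixed-ISI spike trains at Poisson onset times) — simple, and
  sufficient for the string method's contract. Bursts are confined to the
  spontaneous phase so that the evoked ground truth remains identifiable in
  the session windows.
* **Evoked response.** Per stimulus and electrode, the early spike count is
  Poisson with mean `early_prob · exp(−d/λ)` at distance d (in electrode
  pitches) from the stimulated electrode; its latency is
  `early_latency0 + slope · d` plus one Gaussian jitter draw per stimulus,
  and multi-spike responses form a 1.5 ms comb (an evoked mini-burst, which
  also respects the 1 ms refractory contract). Late spikes, where enabled,
  are Gaussian around a fixed late latency. Every drawn quantity is recorded
  in the ground-truth object.
* **Populations.** The cortical-like profile has higher background
  (2 spikes/s), longer bursts (12 spikes), a nearly uniform early response
  (λ = 30 pitches, mean 0.8 spikes/stimulus at the site, latency
  8 + 2·d ms) and a late component (0.6 spikes/stimulus at 200 ± 30 ms).
  The hippocampal-like profile has sparse background (0.1 spikes/s), shorter
  bursts, a strong but confined early response (λ = 2 pitches, 1.8
  spikes/stimulus at the site, latency 6 + 1.5·d ms — slightly faster) and
  no late component. These values are the package's chosen emulation
  targets: they reproduce the qualitative contrasts of interest (more
  reactive, uniformly responding cortical-like networks with a late
  component; localized, early-only hippocampal-like ones) with PSTH areas
  in the 0–2 spikes/stimulus range.

What the generator does *not* emulate: network bursts during stimulation,
electrode-to-electrode rate heterogeneity (available via explicit per-
electrode overrides), stimulus artifacts, non-stationarity, correlated
noise, and propagation along actual axonal paths. Passing tests therefore
demonstrate correctness of the algorithms under the stated statistical
model, not performance on any particular biological dataset.

All generation is deterministic given a seed; the benchmark suite
(`make_benchmark_suite()`) derives per-recording seeds from a master seed
and regenerates byte-identical files.

## Numerical conventions and edge cases

* Times at 0.1 ms resolution; PSTH windowing in integer ticks (exact).
* Half-open windows and bins throughout; bin centres reported in ms.
* Ties: argmax/argmin take the first (earliest) index; detector amplitude
  ties go to the earlier extremum; plateau local maxima report their first
  bin.
* Degenerate inputs: empty spike trains yield empty burst lists and zero
  PSTHs; all-identical profiles yield one class; zero-variance groups are
  flagged degenerate in the normality screen; all-zero areas make
  normalization an error rather than NaN.
* The test suite exercises the pipeline at study scale (120 electrodes,
  600 s spontaneous phases, 3 × 300 s sessions, a 4 + 4 culture benchmark)
  for the end-to-end checks and at reduced sizes for unit-level properties;
  the acceptance script regenerates all of it from one seed.

## Known limitations

* The PTSD algorithm body and the early→late bridging rule are documented
  interpretations of under-specified procedures; both are stated above and
  validated against ground truth, but other readings exist.
* The separation statistic's published form is typographically ambiguous;
  the default here is the reading under which its threshold rule is
  monotone in separation.
* k-means with silhouette selection can split a continuum of response
  amplitudes into arbitrary classes; latencies are robust to this (they
  depend on the class only through its time threshold), but class counts
  should not be over-interpreted.
* HDF5 containers are not supported; the JSON and CSV formats carry the
  same schema in plain text.
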