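---
title: "Methods: quantifying beaked-whale behavioral responses to sonar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying beaked-whale behavioral responses to sonar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonarpam)
library(dplyr)
```

## The problem

Beaked whales (Ziphiidae) forage in deep dives during which they produce
echolocation clicks, and they have mass-stranded in association with naval
mid-frequency active (MFA) sonar exercises. Two complementary observation
chains are used to quantify their behavioral response to sonar:

1. **Passive acoustic monitoring (PAM)** on a seafloor hydrophone array:
   clicking bouts of foraging groups are detected as *group clicking
   periods* (GCPs) and their rate and spatial distribution are compared
   across exposure phases (before / during / after a sonar exercise).
2. **Biologging**: tags that record calibrated audio, depth and movement
   measure the acoustic dose actually received by an individual
   (band sound pressure level, per-ping and cumulative sound exposure
   level) and the behavioral response (dive-parameter changes); satellite
   tags extend the movement record over weeks.

`sonarpam` implements both chains end to end, together with synthetic-data
generators that emulate the statistical structure of the field data with
ground truth retained, so every stage is testable without access to range
recordings.

## Group clicking period detection

A GCP is the interval over which click trains from one foraging group are
detected on a cluster of nearby hydrophones. The detector
(`detect_gcps()`) works on click-train event tables (one row per train per
hydrophone, with a click count) and three rules:

* **Opening rule**: a GCP begins at the first click of the earliest set of
  `min_clicks = 5` clicks that fit inside a `start_window_s = 30` s
  window on the cluster. The window is evaluated at click times (exact),
  not on a fixed grid, which removes grid-phase artifacts. Since event
  tables carry counts rather than per-click times, clicks are taken to be
  uniformly spread across each train.
* **Closing rule**: the GCP ends at the end of the last click train
  followed by more than `end_gap_s = 180` s without clicks on the cluster.
* **Clustering**: "a cluster of nearby hydrophones" is not an
  algorithmically defined object in the field protocol, so we
  operationalize it as connected components of a graph linking events
  whose hydrophones lie within `adjacency_radius_m` (default 6500 m, the
  maximum click detection range) and whose trains are separated by no more
  than the end gap. Two groups clicking simultaneously on the *same*
  cluster are not separable — they merge into one GCP, as in the original
  counting. Simultaneous activity on disjoint clusters yields separate
  GCPs.

The GCP start is taken at the first click of the qualifying window rather
than at the window's nominal start; with click trains of realistic density
the two differ by at most a few seconds.

**Edge classification** (`classify_edge()`): "edge" hydrophones are the
outermost phones at the perimeter of the range. We take all phones on the
boundary of the convex hull of the planar positions, including phones
lying on hull edges (a regular grid perimeter is mostly mid-edge points);
`rings = 2` adds one ring of dilation by peeling the hull and taking the
hull of the remainder. A GCP is "on the edge" if any of its detecting
phones is an edge phone (`rule = "any"`, default) or by majority, since
the original tabulation does not state the membership rule.

## Phase rates and the randomization test

`summarize_rates()` counts GCPs per exposure phase (assignment by start
time; the original analysis does not state how boundary-straddling GCPs
were treated) and reports rates per hour and edge percentages.
Rates are returned unrounded so that `rate_per_h * duration_h` equals the
integer count exactly; a 2-decimal rounding reproduces table-style
display values.

`randomization_test()` tests a rate difference between two phases against
the null that GCP occurrence is homogeneous over the whole observation.
The null redistributes the observed total number of GCP *start times*
uniformly at random over the union of phases; durations are ignored
because the statistic is a rate of events. Under this null the per-phase
counts are multinomial with probabilities proportional to phase
durations, and that is how the null is sampled (`rmultinom`), which is
exactly equivalent to dropping N uniform points on the time axis and far
faster than doing so. The observed statistic is the rate difference per
hour (a ratio is available via `statistic = "ratio"`; the original
statistic is not stated, and the difference is the simpler choice for
rates that can be zero). Two-tailed p-values use the add-one correction
`p = (1 + k) / (n_reps + 1)`, standard Monte Carlo practice that avoids
p = 0 and matches reporting of small p-values as bounds. The default
`n_reps` is one million, overridable for testing.

An **exhaustive mode** (`method = "exhaustive"`) enumerates every
placement of the N events over a time grid of step `grid_step_h` exactly,
via multinomial counts over grid slots. A sampled Monte Carlo p-value has
a standard error of order `sqrt(p/n_reps)` and can never be expected to
match an exact enumeration to within `1/(n_reps + 1)`; the exhaustive
mode exists precisely so the implementation can be validated against an
independent brute-force enumeration at that resolution on tiny cases. It
is practical only for small N.

The standard contrasts (`run_hypothesis_tests()`) are before vs during,
during vs recovery, during vs post-recovery, before vs recovery and
before vs post-recovery.

## Exposure metrics

All pressures are in micropascal; SPL is dB re 1 µPa (RMS), SEL is dB re
1 µPa²·s, and source levels are dB re 1 µPa at 1 m.

* **Band SPL** (`band_spl()`): the record is band-limited with a
  zero-phase Butterworth band-pass (order 4, applied forward and backward:
  ≥ 40 dB rejection one octave outside the band, no group delay, so SPL
  timing stays aligned with the transmit schedule), then RMS levels are
  computed over sliding windows of 10 or 200 ms. The analysis bands are
  the four adjacent 1/3-octave bands with edges 1960, 2467, 3111, 3920,
  4939 Hz; narrowband MFA/PRN stimuli are analyzed in the single
  3111–3920 Hz band, broadband stimuli take the maximum across the four
  bands per window (`max_band_rl()`).
* **Click rejection**: the field method names a routine that rejects
  energy from the tagged whale's own short echolocation clicks in 200-ms
  windows but does not define it. We operationalize it as: split the
  window into 10-ms sub-frames, exclude sub-frames whose mean-square level
  exceeds the window median by more than 10 dB, together with one guard
  sub-frame on each side (narrowband filtering smears a transient into its
  neighbours; without the guard, ring-down from a click sitting just
  outside the window can bias the level by over 1 dB), and average the
  remaining sub-frames. One look-ahead/behind sub-frame beyond the window
  edge participates in transient flagging for the same reason.
* **Per-ping SEL** (`ping_sel()`): band-limited squared pressure is
  integrated over a fixed 2-s window, long enough to include early
  multipath arrivals while limiting noise. Partial windows at the record
  edge are an error rather than a silent truncation.
* **Window anchoring** (`ping_exposure()`): the field description does
  not state where the 2-s window sits relative to the direct arrival. We
  anchor it at the detected ping onset: the earliest 200-ms window within
  the per-ping search interval whose SPL is within 3 dB of that ping's
  peak, minus a 0.2-s lead. Anchoring at the absolute SPL peak is fragile
  for composite pings (the loudest window can fall near the end of a
  1.4-s transmission, pushing the front of the ping out of the window);
  the earliest-near-peak rule is robust to that and is configurable.
* **Cumulative SEL** (`cumulative_sel()`) sums ping energies; the final
  value is the overall SEL of the exposure and is dominated by the last,
  loudest pings of a ramp-up (for a +3 dB/ping ramp the overall SEL sits
  about 3 dB above the final ping).
* **Received-level prediction** (`predict_rl()`): the propagation model
  used in the original exposure reconstruction is a Navy model that is
  not available; the package provides a deliberately simple stand-in,
  `TL = 20 log10(R) + 0.2 dB/km × R`, i.e. spherical spreading plus
  absorption appropriate near 3.5 kHz, with both coefficients
  configurable. Field received levels reconstructed with the full model
  are therefore not reproducible here; the stand-in supports the same
  interface and the dose-escalation simulations.

## Dive parameters

`segment_dives()` defines dives as maximal intervals with depth greater
than a surface threshold, with crossing times interpolated linearly
between samples. The threshold defaults to 2 m: "at the surface" has no
numerical definition in the field protocol, and 2 m comfortably exceeds
both sensor noise and surface splash on a 50-Hz depth series. A dive is a
*deep foraging dive* when the audit places a clicking period inside it.

`compute_dive_parameters()` follows the field definitions: descent runs
from leaving the surface to the first click, with descent rate the depth
at first click over that duration (an average from the surface, not an
instantaneous slope); clicking runs from first to last click; the silent
ascent runs from the last regular click to the next surfacing, with
ascent rate defined analogously; dive depth is the maximum depth; buzz
rate is the buzz count over the clicking duration. Buzzes outside the
clicking span but inside the dive count by default (`buzz_scope =
"dive"`); the alternative is available because the original definition is
ambiguous on this point, and where a buzz ends a bout we treat the last
regular click (not the buzz) as the end of clicking. Pre- and post-dive
intervals are measured between consecutive *deep foraging* dives and are
reported missing at record ends. Depths at click times are interpolated
linearly from the depth series.

`phase_compare_table()` produces descriptive statistics and shared-bin
histograms of the eleven parameters by condition label and retains the
full per-dive table; fitting mixed-effects models to that table is left
to the analyst (the table is exactly the export such models need).

## Track filtering

`speed_filter()` removes location fixes that imply implausible swim
speeds (default maximum 3 m/s), in the spirit of speed-based Argos
filters. The published family of such filters has variants; ours is
deterministic: while any pair of consecutive retained fixes implies a
speed above the limit, the fix (never the first) with the largest
root-mean-square speed to its retained neighbours among those involved in
violations is discarded. The procedure is idempotent, and with exactly
two fixes nothing is removed (there is no evidence to choose between
them). Distances are great-circle on a sphere of radius 6371.0 km —
ellipsoidal corrections are below 0.5% at the tens-of-km scales involved
— and `phase_distance_summary()` reports per-window means and standard
deviations of the distance from each retained fix to the range centre
(default 24.5° N, 77.5° W), per fix rather than per day.

## Synthetic data

The generators reproduce the *structure* the analyses assume, with ground
truth retained:

* `generate_array()`: a jittered rectangular grid (jitter ≤ 10% of the
  nominal 4-km spacing) in a local planar frame, standing in for the real
  range geometry, whose coordinates are not public.
* `simulate_gcp_stream()`: groups dive about every two hours and click
  for about 30 minutes; during a bout every hydrophone within 6500 m
  detects alternating on/off click trains (the on/off duty cycle is a
  free parameter — it is not a published quantity). The phone nearest the
  group is detected from the first moment of the bout through its end,
  which pins the true GCP boundaries. An avoidance rule relocates dives
  away from a designated centre during a flagged phase, emulating
  displacement from an ensonified area for power studies.
* `simulate_playback_reception()`: the MFA stimulus is the documented
  1.4-s composite (0.5-s 3.2–3.3 kHz upsweep, 0.5-s 3.43-kHz tone, 0.1-s
  silence, 0.3-s 3.75-kHz tone) repeated every 25 s with a +3 dB ramp
  from 152 to 212 dB source level; PRN matches it in band and timing with
  noise segments (160→211 dB); the killer-whale stimulus is represented
  by a 2–5 kHz sweep with a +5 dB/30 s ramp (135→196 dB). Each active
  segment is synthesized at constant RMS equal to the received level, so
  truth for the max-200-ms SPL is the received level itself and per-ping
  SEL truth is `RL + 10 log10(active duration)`. Background noise is
  Gaussian at a configurable broadband level.
* `simulate_dive_profile()`: piecewise-linear depth trajectories built
  directly from the eleven dive parameters, with dive boundaries
  expressed at the surface-threshold crossing so that generation and
  analysis share one operational definition of "leaving the surface".
* `simulate_whale_track()` / `simulate_argos_track()`: a correlated
  random walk degraded by isotropic Gaussian location error plus
  non-adjacent outlier jumps large enough to imply speeds far above the
  filter limit.

What the generators deliberately do **not** emulate: click spectra and
the 6° click beam pattern (events start at the detection level), real
ocean propagation (a spreading law stands in), Argos error ellipses and
quality classes, and correlated depth-sensor noise. Tests passing on
synthetic data therefore validate the *algorithms* — detection logic,
dB bookkeeping, estimator definitions — not the field performance of
click detectors or propagation models.

## Numerical choices and problem sizes

* Dive round-trip tolerances are one depth-sample period (0.02 s at
  50 Hz) for durations and 1% for rates and depths; the test and
  acceptance runs use 100 simulated dives in 20 records of 5 dives, which
  bounds memory for the 50-Hz series while exercising the pre/post-dive
  interval bookkeeping between consecutive dives.
* The detector validation uses one group over ~52 dive cycles (so ~50
  bouts separated by far more than the 3-minute closing gap) on a
  36-phone, 4-km array.
* Exposure recovery uses a 12-ping MFA ramp with the inter-ping interval
  shortened from 25 s to 4 s: the silence between pings carries no
  information for SPL/SEL recovery, and the shorter record keeps the
  synthesized series small. Audio is synthesized at 16 kHz, comfortably
  above twice the highest band edge (4939 Hz); tag hardware samples much
  faster, but the analysis bands do not require it.
* Monte Carlo validation uses 10^5 replicates for power checks and 1000
  null trials of 2000 replicates for the type-I error check; the add-one
  correction makes the smallest attainable p equal to 1/(n_reps + 1).
* The Butterworth band filter is order 4 (8-pole as a band-pass), applied
  zero-phase. Passband droop near band edges after the double pass is a
  few hundredths of a dB for the MFA tones and is covered by the 1-dB
  recovery tolerances.

## Known limitations

* Two groups clicking simultaneously on one cluster are counted as one
  GCP (inherent to cluster-level counting).
* The exhaustive randomization mode scales as the number of count
  compositions and is intended for validation on tiny cases only.
* The speed filter uses speed only; it cannot distinguish a genuine fast
  excursion from an error, and with two fixes it retains both.
* Field quantities that depend on unreleased data — exact received levels
  reconstructed with the Navy propagation model, the mixed-model F/P
  values for dive parameters, and the observed distance-to-centre means —
  are outside what this package can recompute; the pipeline validates
  itself on synthetic surrogates with known truth instead.
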