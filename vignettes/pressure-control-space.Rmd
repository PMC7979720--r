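---
title: "Mapping the respiratory pressure control space of the songbird syrinx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the respiratory pressure control space of the songbird syrinx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syrinxspace)
```

## The problem this package addresses

Songbirds produce voiced sound when expiratory airflow drives
self-sustained oscillation of vocal-fold-like tissue (the medial vibratory
mass, MVM) inside each bronchus of the syrinx. Two respiratory pressures
control each sound generator: the bronchial pressure `p_b` driving flow
through the syrinx, and the pressure of the surrounding interclavicular air
sac `p_icas`. Their difference, the transmural pressure
`p_t = p_b - p_icas`, loads the MVM directly. An isolated hemi-syrinx can
be characterized by ramping `p_b` from 0 to 3 kPa at 1 kPa/s while holding
`p_icas` at each of 13 equidistant setpoints between 0 and 3 kPa in
randomized order, with 2 s silent pauses between ramps: a dense sample of
the `p_b` × `p_icas` control space.

`syrinxspace` implements the complete analysis chain for such runs —
signal conditioning, per-bin acoustic and aerodynamic features, phonation
threshold detection, control-space maps, and regression/model-selection of
the driving pressures — together with a forward simulator of a hemi-syrinx
with known ground truth, used to validate the chain end to end.

## Feature pipeline

Channels are conditioned with zero-phase (forward–backward) Butterworth
filters: 0.1 kHz 3rd-order high-pass on sound and 2 kHz 3rd-order low-pass
on pressures and flow (0.3 kHz high-pass is the customary variant for
in vivo song recordings; all cutoffs are configuration). Forward–backward
application squares the magnitude response and cancels the phase; the
implementation pads each end with `3 * (order + 1)` odd-reflected samples
per pass so that no startup transient reaches the data, and refuses inputs
shorter than the padding rather than truncating silently.

All channels are then binned on one shared grid of 2 ms windows sliding by
1 ms, starting at t = 0 (`floor((N - W)/H) + 1` bins). Sound is summarized
per bin by its RMS; pressures and flow by their mean — for these slow,
non-negative signals mean and RMS nearly coincide, and a difference of RMS
values would be ill-defined for signed signals, so `p_t` is formed from the
per-bin means.

Per bin the pipeline computes:

* **Fundamental frequency** by the YIN estimator: squared difference
  function, cumulative-mean normalization (CMND), first dip below a 0.15
  threshold, parabolic interpolation of the lag. The 2 ms bin is far too
  short for f_o near 500 Hz, so f_o is estimated on a longer window
  (default 25 ms, at least two periods of the 150 Hz search floor)
  centered on the bin. The CMND value at the chosen lag is reported as the
  *aperiodicity*; f_o is reported only where aperiodicity ≤ 0.15 and the
  frame RMS ≥ 0.5 mPa (both per-recording tunables, with the customary
  tuning ranges 0.05–0.2 and 0.25–5 mPa).
* **Source level** `SL = 20 log10(p/P0) + 20 log10(r)` (dB re 20 µPa at
  1 m), with `P0 = 20` µPa and microphone distance `r = 0.15` m.
* **Wiener entropy** `WE = log10(geomean(Px)/mean(Px))` of the amplitude
  spectrum: 0 for white noise, strongly negative for tonal sound. The
  spectrum is taken from a 2048-sample Hann-tapered window centered on the
  bin (Welch-averaged with 1024-sample overlap for longer frames),
  restricted to the 0–10 kHz anti-alias band, with spectral values floored
  at machine epsilon times the spectral maximum. A 2 ms frame zero-padded
  to 2048 points would yield a sinc-smeared, nearly flat spectrum whose WE
  saturates near zero regardless of the source — the stated 2048/1024
  analysis only carries information when applied to real 2048-sample
  windows, which is what the pipeline does.
* **Mechanical efficiency**
  `ME = 10 log10(P_acoustic / P_aerodynamic)` with
  `P_acoustic = 4 π r² p² / (ρ v)` (ρ = 1.2 kg m⁻³, v = 344 m s⁻¹) and
  `P_aerodynamic = p_b V` in SI units (the kPa→Pa conversion is explicit
  at this boundary). The radiation prefactor is deliberately exposed
  (`solid_angle_factor`, default 4 reproducing the conventional printed
  form; 2 gives a literal half-sphere). Bins with flow below a 10⁻⁷
  m³ s⁻¹ floor yield missing ME.

## Phonation thresholds and run summaries

Phonation onset is detected per ramp as the first bin whose RMS sound
pressure crosses a threshold anchored to the recording's own noise floor:
`max(6 × median pre-ramp RMS, 0.25 mPa)` (both parts configurable; the
absolute floor is the lower bound of the customary power-gating range).
The onset pressures are read from the crossing bin, not interpolated, so
at 1 kPa/s and 1 ms hop the pressure resolution is about 0.001 kPa.

Two measurement subtleties at phonation boundaries deserve explanation:

* *Partial-window bins.* A 2 ms window straddling an on/offset covers
  silence for part of its span, so its RMS is biased low — by construction
  such a bin's SL lies anywhere between the detection threshold and the
  true level. Level statistics (minimal SL, WE/ME means, control-space
  maps) therefore use a "steady phonation" mask: the threshold mask eroded
  by a guard (default 10 bins) at every boundary. Onset *detection* still
  uses the raw first crossing.
* *Onset f_o.* Pitch estimates at the crossing bin are biased upward by
  the rising amplitude envelope (a growing envelope tilts the difference
  function toward shorter lags), while estimates well after onset reflect
  an already-higher `p_t`. The onset f_o is therefore obtained from a
  short linear regression of f_o on time over the first clean bins after
  the transient, extrapolated back to the crossing bin; with fewer than 5
  clean estimates it falls back to the first non-missing f_o.

Run-level summaries follow the field's definitions: *minimal f_o* is the
mean onset f_o over phonating ramps; *minimal SL* the lowest SL over
steady phonating bins; mean WE and ME are averaged over steady phonating
bins of the entire control space (a cell-averaged variant can be obtained
from the map objects). The run-level phonation threshold pressures are the
boundary values of the phonation region — the minimum onset `p_b`,
`p_icas` and `p_t` over phonating ramps. With ramps at many air-sac
setpoints the *per-ramp* onset `p_b` necessarily grows with the setpoint
(`max(PTP_b, p_icas + PTP_t)`), so only the minimum characterizes the
region boundary that a single per-side threshold refers to.

## Regression and model selection

The f_o–`p_t` relation is fit as two independent ordinary least-squares
lines over `p_t` regions S1 `[0, 0.75)` and S2 `[0.75, 2]` kPa (no
continuity constraint; the 0.75 kPa boundary belongs to S2, a declared,
configurable half-open choice). SL is fit linearly against `p_b`. Fits
pool steady phonating bins across ramps within one run.

Which pressure drives a response is decided by ΔBIC: for each candidate
(`p_b`, `p_icas`, `p_t`) and the intercept-only null, the Gaussian BIC
`n log(RSS/n) + k log(n)` is computed (k counts mean parameters plus one
for the variance; the additive `n log(2π) + n` term cancels in
differences and is omitted), and `ΔBIC = BIC - BIC_null`. The lowest ΔBIC
wins; ties within 10⁻⁹ resolve by the fixed precedence
`p_t > p_b > p_icas`. Cohort-level inference (mixed models,
likelihood-ratio tests, t-tests) is deliberately out of scope: the
pipeline exports tidy long-format tables (`report_table()`) that standard
tooling consumes directly.

## The forward simulator

`simulate_run()` generates protocol-conformant recordings from a
`syrinx_preset()` whose defaults are the adult in vitro reference values:
phonation thresholds `PTP_b` = 1.01 kPa, `PTP_icas` = 0.45 kPa,
`PTP_t` = 0.15 kPa; piecewise f_o slopes 189 and 55 Hz/kPa around the
0.75 kPa breakpoint, anchored so f_o equals the side-specific minimal
frequency (male left/right 511/513 Hz, female 529/568 Hz) at
`p_t = PTP_t`; minimal source level 45 dB re 20 µPa at 1 m rising 4 (left)
or 5 (right) dB/kPa with `p_b`. Phonation is active exactly where
`p_b ≥ PTP_b`, `p_icas ≥ PTP_icas` and `PTP_t ≤ p_t ≤ 2` kPa (the upper
limit mirrors the protocol's avoidance of high-flow regimes).

The sound model is deliberately phenomenological — a harmonic stack with
continuous phase, 8 partials decaying 6 dB per partial and capped below
the 10 kHz anti-alias band, whose total RMS realizes SL(`p_b`) through the
inverse source-level relation — not a biomechanical two-mass model: the
package tests the analysis chain, not tissue mechanics. Three further
ingredients make the synthetic data behave like measurements:

* 5 ms raised-cosine amplitude ramps at phonation on/offsets prevent
  spectral splatter;
* an aspiration (turbulence) noise component rides on the voiced source at
  −54 dB relative to its RMS. Real syringeal sound is not a clean line
  spectrum, and this broadband component is what sets the Wiener entropy
  of the synthetic data; the level was calibrated once so the full
  pipeline reports WE ≈ −1.8 dB on the default preset, and then frozen;
* Gaussian sensor noise on every channel (sound 10⁻⁵ Pa RMS, pressures
  0.002 kPa, flow 10⁻⁹ m³ s⁻¹).

Flow is `flow_conductance × p_b` while phonating (a 2% leak otherwise);
the conductance default 8 × 10⁻⁷ m³ s⁻¹ kPa⁻¹ was likewise calibrated
once so the pipeline's mean ME is ≈ −35 dB. `ground_truth()` computes
analytically, per protocol, which ramps phonate, their onset pressures and
frequencies, and the run summaries the pipeline should recover.

What the simulator does *not* emulate: bilateral coupling between the two
hemi-syrinxes (injection locking), hysteresis at phonation offset,
actuator dynamics of the pressure controllers, desiccation or other
drift, vocal-tract filtering, and period-doubling or chaotic regimes —
the synthetic syrinx bifurcates exactly once, from silence to periodic
oscillation. Passing recovery tests therefore demonstrates that the
analysis chain is correct and unbiased on data obeying the stated model,
not that the model captures every property of real preparations.

## Numerical choices and degenerate inputs

* Bins start at t = 0; `bin_center_t = start + bin_width/2`; the bin-count
  formula `floor((N - W)/H) + 1` is enforced everywhere.
* YIN: frames must hold at least two periods of the search floor;
  all-zero frames report aperiodicity 1 and missing f_o; the dip search
  descends from the first sub-threshold lag to its local minimum before
  interpolating.
* For efficiency, YIN and WE are evaluated only on bins whose sound RMS
  reaches the 0.25 mPa power floor: quieter bins are power-gated to
  missing f_o regardless, and carry missing aperiodicity/WE.
* `source_level(0)` is −Inf, stored as missing in feature tables; missing
  f_o is written as an empty CSV field, never 0.
* Zero or negative aerodynamic power yields missing ME rather than an
  error (vectorized over bins).
* Map cells without data are missing, never zero; cell SD requires at
  least two observations.
* The 13 "equidistant 0.23 kPa" levels over 0–3 kPa are internally
  inconsistent (13 equidistant levels over 0–3 span 0.25 kPa); the default
  grid spans 0–3 kPa at 0.25 kPa spacing and a `picas_spacing = 0.23`
  variant is available.

## Problem sizes used by the tests and the acceptance script

The test suite exercises the full chain on three-ramp runs at the 20 kHz
fast profile plus focused single-ramp constructions, and the recovery
criterion on five seeded 13-ramp runs at 20 kHz. The acceptance script
analyzes five seeded 13-ramp runs at the full 50 kHz acquisition rate.
These sizes are the package's own choice of a thorough-but-quick
validation; tolerances are identical across profiles.

## A worked example

```{r example, eval = FALSE}
prot <- make_protocol(sample_rate = 20000, seed = 1)
rec <- simulate_run(syrinx_preset("adult-male-left"), prot, seed = 1)
analyze_recording(rec, protocol_hint = prot)
#> <run_analysis> 13 ramps (10 phonating)
#>   threshold    0.00025 Pa RMS
#>   minimal f_o  519.5 Hz
#>   PTP_b        1.010 kPa (PTP_icas >= 0.500, PTP_t >= 0.150)
#>   minimal SL   44.4 dB re 20 uPa at 1 m
#>   mean WE      -1.63 dB, mean ME -35.0 dB
#>   f_o ~ p_t    S1 189 Hz/kPa, S2 55 Hz/kPa (best: p_t)
#>   SL ~ p_b     4.0 dB/kPa (best: p_b)
```

Note the recovered minimal f_o of ~520 Hz against the preset's 511 Hz
anchor: this is not estimator bias but the definition of the statistic.
Eight of the ten phonating ramps onset exactly at `p_t = PTP_t` (f_o =
f_min), but the two lowest phonating air-sac setpoints onset at
`p_b = PTP_b` with `p_t` above `PTP_t`, contributing higher onset
frequencies to the mean. `ground_truth()` returns the same value
analytically. The recovered PTP_icas boundary (0.50 kPa) sits one grid
step above the preset's 0.45 kPa threshold because the protocol samples
`p_icas` every 0.25 kPa.

## Known limitations

* The WAV layer reads and writes only the package's own float32
  multichannel format with JSON sidecar; original acquisition-hardware
  formats are out of scope.
* No pitch continuity smoothing or multi-pitch tracking: per-bin YIN
  output is reported raw.
* PTP detection defines onsets only; phonation-offset hysteresis is not
  analyzed.
* Minimal SL inherits a small downward wobble (a few tenths of a dB) from
  non-integer cycle counts in 2 ms RMS windows — inherent to the binning
  definition, not removed.
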