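# syrinxspace

Analysis pipeline for sound production of the isolated songbird syrinx
driven by respiratory pressures.

Each sound generator (hemi-syrinx) of a songbird's vocal organ is
controlled by two pressures: the bronchial pressure *p*<sub>b</sub> that
drives airflow, and the surrounding air-sac pressure *p*<sub>icas</sub>;
their difference, the transmural pressure
*p*<sub>t</sub> = *p*<sub>b</sub> − *p*<sub>icas</sub>, loads the
oscillating tissue directly. Ramping *p*<sub>b</sub> (0→3 kPa at 1 kPa/s)
at each of 13 air-sac setpoints densely samples the pressure control space
of one hemi-syrinx. `syrinxspace` turns such multichannel recordings
(sound, *p*<sub>b</sub>, *p*<sub>icas</sub>, flow; 50 kHz) into:

- per-bin features on a 2 ms / 1 ms sliding grid: RMS sound pressure,
  mean pressures and flow, YIN fundamental frequency *f*<sub>o</sub> with
  aperiodicity/power gating, source level
  SL = 20 log₁₀(*p*/*P*₀) + 20 log₁₀(*r*) (dB re 20 µPa at 1 m), Wiener
  entropy WE = log₁₀(geomean(*P*<sub>x</sub>)/mean(*P*<sub>x</sub>)), and
  mechanical efficiency
  ME = 10 log₁₀(*P*<sub>acoustic</sub>/*P*<sub>aerodynamic</sub>) with
  *P*<sub>acoustic</sub> = 4π*r*²*p*²/(ρ*v*) and
  *P*<sub>aerodynamic</sub> = *p*<sub>b</sub>*V̇*;
- per-ramp phonation threshold pressures (PTP) from the first
  sound-power threshold crossing, and run summaries (minimal
  *f*<sub>o</sub>, minimal SL, mean WE/ME, phonation-region boundaries);
- feature maps over the *p*<sub>b</sub> × *p*<sub>icas</sub> plane;
- piecewise *f*<sub>o</sub>–*p*<sub>t</sub> regressions (regions S1
  [0, 0.75) and S2 [0.75, 2] kPa), linear SL–*p*<sub>b</sub> fits, and
  ΔBIC selection of the driving pressure against an intercept-only null.

A forward hemi-syrinx simulator (`simulate_run()`) with analytically known
ground truth (`ground_truth()`) generates protocol-conformant recordings
for validation; its preset defaults are the adult reference values
(PTP<sub>b</sub> 1.01 kPa, minimal *f*<sub>o</sub> 511 Hz for the left
male side, S1 slope 189 Hz/kPa, minimal SL 45 dB, …).

## Worked example

```r
library(syrinxspace)

prot <- make_protocol(sample_rate = 20000, seed = 1)  # 13 ramps, randomized
rec  <- simulate_run(syrinx_preset("adult-male-left"), prot, seed = 1)
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

Reading the output: 10 of 13 ramps phonate (setpoints below the air-sac
threshold, or topping out before onset, stay silent). The phonation-region
boundary PTP<sub>b</sub> comes back at the programmed 1.01 kPa with ~1 ms
(0.001 kPa) resolution. Minimal *f*<sub>o</sub> — the mean onset
*f*<sub>o</sub> over ramps — exceeds the 511 Hz anchor because the two
lowest phonating air-sac setpoints onset at *p*<sub>t</sub> above its
threshold value; `ground_truth()` returns the same 519.9 Hz analytically.
The piecewise slopes, the SL slope, and the ΔBIC winners
(*p*<sub>t</sub> for *f*<sub>o</sub>, *p*<sub>b</sub> for SL) all match
the generator.

The numbered drivers under `analysis/` run the same chain as a workflow:
`01_simulate.R` writes one run per preset (WAV + JSON sidecar),
`02_features.R` exports the per-bin feature tables, `03_control_space.R`
the PTP/summary tables and maps, `04_model_fits.R` the regression, ΔBIC
and tidy long-format summary tables — all under `results/`.

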