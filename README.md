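# pttkit

Pulse Transit Time (PTT) is the delay between the electrical trigger of a
heartbeat — the R-peak of the ECG — and the arrival of the resulting
pressure pulse at a peripheral site, seen as the upstroke of the
photoplethysmogram (PPG). Because the pulse travels faster through stiff or
constricted arteries, PTT shortens under vasoconstriction, which makes it a
cheap, cuff-less window onto vascular response: nicotine intake, hyperbaric
oxygen exposure during therapy (HBOT), and similar interventions all leave a
visible signature in the beat-by-beat PTT series.

`pttkit` is an R toolkit for the full desk-scale workflow around
wearable-style PTT measurement, aimed at researchers who want to develop and
validate PTT analysis pipelines without access to device recordings:

* **Simulation with known ground truth** — synchronized 1 kHz ECG (PQRST
  sum-of-Gaussians template) and two-lobe PPG pulses whose upstroke
  inflection is placed analytically at `beat time + PTT`; configurable RR
  jitter, per-beat PTT modulation by saturating-exponential intervention
  events, 50 Hz mains pickup, baseline wander, and motion artifacts.
* **A device-style binary container** (`.spectre`) — four synchronized
  24-bit channels per 1 ms frame plus event markers, with a bit-exact
  reader/writer, CSV interop, and a flash-capacity calculator.
* **Signal conditioning** — zero-phase baseline removal, mains notch,
  normalization, amplitude-based artifact flagging.
* **Fiducial detection** — a Pan–Tompkins-style R-peak detector and a PPG
  fiducial detector (pulse onset, max-slope inflection with sub-sample
  refinement, systolic peak, dicrotic wave).
* **PTT analysis** — windowed R-peak/inflection pairing, outlier flagging,
  heart rate and HRV (SDNN, RMSSD), per-therapy-phase summaries, and
  nonlinear least-squares fits of intervention responses
  (baseline, drop amplitude, onset and recovery time constants).

The vascular link is the Moens–Korteweg relation for pulse wave velocity,

```
PWV = sqrt(E * h / (rho * D))
```

with Young's modulus `E`, wall thickness `h`, blood density `rho` and vessel
diameter `D`: constriction (smaller `D`, larger `E`) raises PWV and shortens
PTT. The intervention model fitted to PTT series is

```
PTT(t) = baseline + delta * (1 - exp(-(t - t_on)/tau_on))        t_on <= t <= t_off
PTT(t) = baseline + response(t_off) * exp(-(t - t_off)/tau_rec)  t > t_off
```

## Worked example

Simulate a two-minute recording with a vasoconstrictive stimulus between
30 s and 80 s, store and re-read it, and run the complete analysis:

```r
library(pttkit)

sim <- simulate_recording(
  duration = 120, mean_hr = 72, rr_jitter_sd = 0.02,
  baseline_ptt = 0.25,
  ptt_events = vaso_event(t_on = 30, t_off = 80, delta = -0.03,
                          tau_on = 15, tau_recovery = 25),
  seed = 42
)
write_recording(sim$recording, "demo.spectre")
rec <- read_recording("demo.spectre")
fs  <- rec$sample_rate

ecg   <- condition_signal(as.numeric(rec$frames$ecg), fs, ecg_filter_spec())
ppg   <- condition_signal(as.numeric(rec$frames$ppg_green), fs, ppg_filter_spec())
beats <- detect_r_peaks(ecg, fs)
hrv_metrics(beats)
#> # A tibble: 1 × 4
#>   n_beats mean_hr_bpm sdnn_ms rmssd_ms
#>     <int>       <dbl>   <dbl>    <dbl>
#> 1     144        72.0    19.5     29.1

fid <- detect_ppg_fiducials(ppg, fs, search_guides = beats$r_time_s)
ptt <- pair_beats(beats$r_time_s, fid$inflection_s) |> clean_ptt_series()

fit <- fit_intervention(ptt, t_on_hint = 30, t_off_hint = 80)
fit
#> <intervention_fit>
#>   baseline PTT : 249.5 ms
#>   delta        : -29.9 ms
#>   stimulus     : 30..80 s
#>   tau (onset)  : 15.1 s
#>   tau (recovery): 24.9 s
#>   RSS 9.23e-06 s^2 over 125 beats
```

The detector finds all 144 simulated beats at the configured 72 BPM, and the
fit recovers the programmed stimulus (−30 ms drop, 15 s onset and 25 s
recovery constants) to within a fraction of their values. `tidy(fit)` and
`glance(fit)` return the estimates as tibbles, `autoplot(ptt)` and
`autoplot(fit)` draw the series and fitted response, and

```r
moens_korteweg_pwv(vessel_params(E = 4e5, h = 1e-3, D = 8e-3))
#> [1] 6.868028
```

converts vessel parameters into a pulse wave velocity in m/s.

A command-line wrapper with `simulate`, `analyze`, `inspect` and `export`
subcommands lives in `inst/cli/pttkit-cli.R`; every run writes a YAML
manifest (package version, seed, full configuration) so results can be
reproduced exactly.

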