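# centrofret

Single-molecule fluorescence analysis of chromatin structure and dynamics,
built around the biology of the human centromere: the histone variant
CENP-A renders chromatin fibers open and dynamic, which lets the
sequence-specific DNA-binding protein CENP-B reach its 17-bp B-Box motif;
bound CENP-B in turn opens the fiber further, and in cells CENP-A presence
stabilizes CENP-B retention at centromeres. `centrofret` implements the
three quantitative readouts behind those statements, plus a seeded
simulator so every estimator is validated by parameter recovery.

## What it computes

**smFRET trace analysis.** Corrected FRET efficiencies
`E = (F_A − βF_D) / ((F_A − βF_D) + γF_D)` with bleed-through `β` and
detection-sensitivity `γ` corrections (`compute_efret()`,
`estimate_corrections()`), ALEX single-dye validation and trace selection
(`validate_alex()`, `apply_selection()`), population histograms with
0.02-wide bins decomposed as `Σ A_i exp(−((x − c_i)/σ_i)²)`
(`build_histogram()`, `fit_mixture()`), dynamic/static classification
(`classify_trace()`), and donor–acceptor cross-correlation relaxation
analysis fitting `CC(τ) = −a e^(−τ/τ_R) + c` to report the conformational
exchange time `τ_R` (`cross_correlate()`).

**Colocalization binding kinetics.** Thresholded event detection on
Chung–Kennedy-filtered traces (`detect_events()`, `ck_filter()`), dwell
survival curves, bi-exponential residence-time fits
`y = A₁e^(−t/τ_off,1) + A₂e^(−t/τ_off,2)` and mono-exponential on-rate
fits `y = A e^(−t·k_on,app)` (`survival_curve()`, `fit_biexp()`,
`fit_monoexp()`), and cross-condition summaries with t-tests
(`summarize_conditions()`).

**FRAP.** Double normalization against an unbleached reference ROI
(`frap_normalize()`), replicate averaging with SEM (`average_curves()`),
and recovery fits `R(t) = M(1 − e^(−t/τ))` with immobile fraction `1 − M`
(`fit_recovery()`).

**TIRF image processing.** Rolling-ball-style background subtraction,
spot detection with pixel-integrated 2-D Gaussian PSF fitting, affine
channel registration, fiducial-based drift correction, and aperture
photometry (`subtract_background()`, `detect_spots()`,
`fit_spot_gaussian()`, `estimate_transform()`, `correct_drift()`,
`extract_traces()`).

**Simulator.** Gillespie kinetic trajectories, FRET trace rendering with
single-step photobleaching and EMCCD-like noise, binding timelines, FRAP
curves, and two-channel movies — all seeded, all with ground truth
retained (`simulate_ctmc()`, `render_fret_trace()`,
`simulate_binding_trace()`, `simulate_frap_curves()`, `render_movie()`).

## Worked example

```r
library(centrofret)

# CENP-B residence times on B-Box DNA: simulate 2000 binding events from
# the published mixture and recover it from the survival curve
bp <- binding_params(k_on_app = 0.02, fractions = c(0.5, 0.5),
                     taus = c(6.9, 61))
dwells <- simulate_dwell_times(2000, bp, seed = 11)
fit <- fit_biexp(survival_curve(dwells))

# CENP-B exchange at centromeres with CENP-A present: 20 FRAP curves
fp <- frap_params(tau = 971, immobile_fraction = 0.43)
f <- fit_recovery(average_curves(simulate_frap_curves(fp, 20, seed = 11)))

# CENP-A chromatin-fiber dynamics: 500 two-state FRET traces, exchange
# rates k12 = k21 = 1/(2 tau_R), donor-acceptor cross-correlation
sch <- two_state_scheme(0.1, 0.5, k12 = 1 / (2 * cenpa_relaxation_time()))
sched <- illumination_schedule(0.1, 3e-4, rep("orange", 598), 1)
ph <- photophysics(2000, background_mean = 100, background_sd = 50,
                   excess_noise_factor = 2)
traces <- lapply(1:500, function(i) render_fret_trace(
  simulate_ctmc(sch, sched$duration + 0.2, seed = 11000 + i),
  ph, sched, seed = 11600 + i))
cc <- cross_correlate(traces, gate = 0.2, max_lag_s = 10)
```

Output:

```
tau_off_1 = 7.3 s, tau_off_2 = 59.8 s, fractions = 0.51 / 0.49
tau = 992 s, immobile fraction = 43.0%
tau_R = 1.75 s from 493 gated traces
```

The bi-exponential fit separates the short non-specific interactions
(`tau_off_1`, here recovered as 7.3 s for a 6.9 s ground truth) from the
long sequence-specific residences (`tau_off_2`, 59.8 s vs 61 s), with the
amplitude split telling how many events are of each kind. The FRAP fit
reports the exchange time constant of chromatin-bound protein and the
fraction that never exchanges within the model's plateau (43% here). The
cross-correlation decay time `tau_R` (1.75 s recovered for a 1.69 s
ground truth) measures how fast the fiber interconverts between its open
and compacted conformations.

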