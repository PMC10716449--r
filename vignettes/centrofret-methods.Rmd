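---
title: "Models and methods behind centrofret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind centrofret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centrofret)
```

# Scope

`centrofret` implements the computational side of three single-molecule
fluorescence readouts of chromatin structure and protein binding, centred
on the biology of the human centromere: the histone variant CENP-A makes
chromatin fibers open and dynamic, the DNA-binding protein CENP-B exploits
that opening to reach its 17-bp B-Box recognition sequence, and the two
proteins together reshape the centromeric chromatin state. The package
covers

* **smFRET trace analysis** — corrected FRET efficiencies, ALEX single-dye
  validation, trace selection, population histograms with Gaussian-mixture
  decomposition, dynamic/static classification, and donor–acceptor
  cross-correlation relaxation analysis;
* **colocalization binding kinetics** — thresholded event detection on
  filtered intensity traces, dwell-time survival curves, bi-exponential
  residence-time fits and mono-exponential on-rate fits;
* **FRAP** — double normalization against an unbleached reference,
  replicate averaging, and exponential recovery fits with an immobile
  fraction;
* **TIRF image processing** — background subtraction, spot detection and
  PSF fitting, affine channel registration, drift correction, aperture
  photometry, and Chung–Kennedy filtering;
* a **synthetic-data generator** producing all of the above inputs with
  retained ground truth, so that every estimator is validated by parameter
  recovery rather than against inaccessible microscope data.

# The generative models

## Conformational dynamics and FRET rendering

Chromatin conformational dynamics are modelled as a continuous-time Markov
chain over a small number of states, each with a mean FRET efficiency
(`kinetic_scheme()`). Trajectories are drawn with the Gillespie algorithm
(`simulate_ctmc()`); the initial state is drawn from the stationary
distribution because immobilized molecules are observed at steady state
(overridable per call). For a symmetric two-state scheme the relaxation
time observed in any linear readout is $\tau_R = 1/(k_{12}+k_{21})$, which
is the closed form every cross-correlation recovery test is anchored to.

A trajectory is rendered to camera frames (`render_fret_trace()`) by the
convention

$$F_D = I\,(1-E), \qquad F_A = \gamma I E + \beta F_D,$$

with $E$ the time-weighted mean efficiency over each integration window
(100-ms frames straddle state jumps, so frame averaging is part of the
model, not an approximation). This is the one self-consistent choice for
which the corrected-efficiency formula

$$E_\mathrm{FRET} = \frac{F_A - \beta F_D}{(F_A - \beta F_D) + \gamma F_D}$$

is an exact inverse, and the package asserts the round trip to $10^{-12}$
framewise. The default calibration $\beta = 0.071$ (donor bleed-through
into the acceptor channel) and $\gamma = 0.463$ (acceptor/donor detection
sensitivity) is the Cy3B/Alexa647 pair on the instrument the package
emulates; `estimate_corrections()` re-estimates both from donor-only
traces and acceptor-bleach steps, with $\gamma$ measured on the
bleed-corrected acceptor channel (otherwise the estimate would be biased
to $\gamma - \beta$).

Photobleaching is single-step and irreversible with exponential times per
dye; after donor bleach both FRET channels fall to background, after
acceptor bleach the donor rises to the full intensity $I$. Blinking is
omitted — the oxygen-scavenger/triplet-quencher buffer systems used for
such measurements suppress it — and both simplifications are explicit
extension points. Camera noise is Gaussian with variance
$f_\mathrm{xs}\cdot\mathrm{signal} + \sigma_\mathrm{bg}^2$, an EM-CCD
approximation that is adequate at the count levels the selection criteria
require (thousands of counts per frame); the true EM-register statistics
and conversion gain of the emulated camera are not published, so this
noise model is a declared stand-in.

## Binding timelines, FRAP curves, movies

Colocalization binding is an alternating renewal process: dark (unbound)
intervals are exponential with the apparent on-rate $k_\mathrm{on,app}$,
bright (bound) intervals come from a mixture of exponentials
$\sum_i A_i e^{-t/\tau_{\mathrm{off},i}}$ — the generative inverse of the
bi-exponential residence-time fit. Frames report the unit intensity times
the fraction of the window spent bound, plus noise.

FRAP curves follow
$R(t) = (1 - f_\mathrm{imm})\,(1 - e^{-t/\tau})$ on the normalized scale;
the raw bleached ROI additionally carries the bleach drop and an
acquisition-photobleaching decay shared with an unbleached reference ROI,
so that double normalization (`frap_normalize()`) recovers $R(t)$ exactly
in the noiseless limit. Defaults emulate the cellular measurement the
package targets: 5 pre-bleach frames, 200 post-bleach frames at 7.3 s
(a ~24-minute window), 3% per-frame intensity noise — chosen once as
realistic for confocal centromere photometry — and an acquisition bleach
rate of $2\times10^{-4}\,\mathrm{s}^{-1}$.

Two-channel movies (`render_movie()`) place pixel-integrated Gaussian
PSFs at far-red reference positions and at transform-mapped, drift-shifted
orange positions, with the same noise model; the ground-truth registry
enables the end-to-end detection/extraction tests.

# Estimators and numerical choices

**Cross-correlation relaxation analysis.** For each gated trace (mean
$E > 0.2$, excluding the zero-FRET population) the normalized
cross-covariance of donor and acceptor is computed up to the first bleach
event and averaged across traces; a single exponential
$-a\,e^{-\tau/\tau_R} + c$ is fitted. Channel means are subtracted as
*ensemble* means rather than per-trace means: subtracting each trace's own
60-s sample mean removes part of the slow fluctuation itself and biases
$\hat\tau_R$ down by roughly $\tau_R/T$ (about 13% in the regime the
package validates), whereas the trace-specific static term left by
ensemble-mean subtraction is lag-independent and is absorbed by the fitted
offset. Whether per-trace fluctuations should be pooled before or after
correlating is genuinely open; averaging per-trace correlations with their
SEM is the implemented choice. Lags start at one frame interval, and a
fitted $\tau_R$ below two frame intervals is flagged unresolvable rather
than reported.

**Bleach-step detection.** Bleaching is located by a two-plateau
least-squares change point, recursed once on each side with a one-frame
margin (the frame straddling the bleach instant would otherwise register
as a second step); a step must be downward and exceed 4 robust noise SDs.
On conformationally dynamic molecules the donor and acceptor channels
fluctuate, so per-channel step counting is unreliable; selection therefore
reads donor bleaching off the **total-intensity channel**
$F_D + (F_A - \beta F_D)/\gamma = I$, which is flat under arbitrary FRET
dynamics and steps only when the donor dies, and reads acceptor loss as
the terminal onset of zero sensitized emission. A sensitized-emission
channel that is dark throughout is *not* treated as an acceptor-bleach
event — the molecule may simply be zero-FRET — and acceptor presence is
instead decided by the direct-excitation (ALEX) frames.

**Trace selection** applies the standard criteria: initial total
fluorescence (donor plus $\gamma$-corrected acceptor) above 2000 counts
over baseline, at least 5 s before the first bleach, a single bleach event
with the expected anticorrelation signatures (donor rise to the pre-bleach
total when the acceptor bleaches first; persistent direct-excitation
acceptor signal when the donor bleaches first), and the ALEX single-dye
check. The baseline is the camera background level; for simulated traces
the generator's value is used, for user traces it is an argument.

**Histograms and mixtures.** Efficiency histograms use 0.02-wide bins on
$[-0.1, 1.1]$ (noise pushes efficiencies outside $[0,1]$), left-closed.
Each trace longer than 5 s is normalized to its own total counts before
averaging, so long traces do not dominate; independent repeats contribute
a per-bin mean and SD. The mixture model is fitted exactly in the form
$\sum_i A_i e^{-((x-c_i)/\sigma_i)^2}$ — note the exponent has no factor
$\tfrac12$, so $\sigma_i$ differs from a standard deviation by $\sqrt 2$;
this preserves the parameter scale used in the literature the package
follows, and the fitted curve at $x = c_i$ of an isolated component equals
$A_i$. Initialization takes the strongest separated local maxima with
widths from local second moments; missing components are shouldered next
to the strongest peak (a flat-region initialization makes the gradient
singular), with jittered restarts on failure. When the component count is
not fixed, three components replace two only for a $\ge 5\%$ residual
improvement.

**Dynamic/static classification.** "Anticorrelated intensity
fluctuations" is quantified as: some 2-s window has donor–acceptor Pearson
correlation below $-0.3$ *and* a filtered donor fluctuation amplitude
above 3 shot-noise SDs. The amplitude condition carries the specificity
(pure noise windows readily reach $r < -0.3$ by chance but not the
amplitude), the correlation condition the sensitivity; static traces are
split at a mean efficiency of 0.2 into low/high FRET.

**Dwell-time fitting** is performed on the unbinned empirical survival
function — the cumulative form avoids an arbitrary bin width and every
event contributes one point. The bi-exponential fit uses multi-start
initialization (time constants seeded at $0.5\times$ and $2\times$ the
sample means split at the median) to avoid the classic local minima, and
collapses to a flagged mono-exponential when the time constants are
degenerate ($\tau_2/\tau_1 < 1.5$), a component drops below 5% amplitude,
or the second component improves the residual by less than 5%. Events
shorter than 2 frames are indistinguishable from noise at 100-ms framing
and are dropped; segments whose plateau exceeds 1.8 times the unit
intensity (the median bright plateau) are excluded as overlapping events.
Dwells are not corrected for dye photobleaching, matching the convention
of reporting apparent residence times directly.

**FRAP fitting** uses the single-lifetime model
$M(1 - e^{-t/\tau})$ with the immobile fraction defined from the fitted
plateau $1 - M$, not from the last measured point: at $\tau \approx 16$
minutes the ~24-minute window never reaches plateau, so plateau-from-fit
is the only consistent estimator. A double-exponential variant exists
behind a flag. Registration of FRAP movies is out of scope; curves are
assumed extracted.

**Imaging.** Coordinates are 0-based with the pixel-center convention
everywhere, which makes renderer/fitter round trips exact. Background is
removed by grayscale opening with a disc (a rolling-ball equivalent);
opening under noise leaves a small positive residual, which aperture
photometry removes with an optional local-annulus median. Spot fitting
uses the pixel-integrated Gaussian (matching the renderer), rejecting fits
with widths outside $[0.5, \sigma_\mathrm{max}]$ px; detection pairs local
maxima above a robust threshold with non-maximum suppression. Drift is
estimated only on the far-red fiducial frames (one per 100-frame cycle) by
Fourier cross-correlation with parabolic sub-pixel refinement and linearly
interpolated across the orange frames. The Chung–Kennedy filter combines
trailing and leading running means (both including the current sample, so
a noiseless step passes through unchanged) weighted by inverse local
variance to the power $p = 2$ over 8-frame windows.

# Study conditions used for validation

The validation suite simulates at the published operating points and
requires the estimators to recover them: the two-state exchange at
$\tau_R = 1.69$ s with state efficiencies 0.1/0.5 gated at $E > 0.2$
(500 traces of 60 s at 100-ms framing); residence-time mixtures for
naked 601 DNA with and without a B-Box, H3 and CENP-A mononucleosomes,
and H3 and CENP-A 12-mer chromatin fibers (2000 events each); population
centers 0.57 (H3) and 0.44 (CENP-A) for the compacted high-FRET state;
the $\beta/\gamma$ calibration; and FRAP at
$(\tau = 971\,\mathrm{s},\ f_\mathrm{imm} = 0.43)$ and
$(381\,\mathrm{s},\ 0.42)$ with 20 curves per condition. Where the
literature prints only the slow residence-time component for the fiber
substrates, the fast component is set inside the published non-specific
range (1.6–6.9 s) subject to a $\ge 4\times$ separation — at smaller
separations the amplitude/lifetime decomposition of a few-thousand-event
sample is not statistically identifiable at the tested tolerances, by
either least squares or maximum likelihood. Problem sizes (trace counts,
event counts, movie sizes) are chosen to match the published experiments
where stated and otherwise to give comfortable estimator convergence at
interactive run times.

# What the synthetic data do and do not establish

The generator reproduces the *structure* of the real measurements —
multi-exponential dwell mixtures, seconds-scale two-state FRET exchange
under frame averaging, single-step bleaching with ALEX verification,
recovery with an immobile fraction and acquisition bleaching, EMCCD-like
noise at realistic count levels. Passing recovery tests therefore shows
the estimators are correct and calibrated *under the stated models*. Real
data differ in ways the generator deliberately omits: dye blinking and
spectral fluctuations, non-Gaussian EM-register noise at low counts,
heterogeneous molecule brightness, baseline drift, partial labelling, and
conformational dynamics richer than a k-state chain. Conclusions about
robustness to those effects require real traces, which the analysis
functions accept through the same interfaces (CSV traces, TIFF stacks).

# Known limitations

* A dynamic molecule whose final conformational transition is downward
  and never reverses within the window is indistinguishable, on that
  channel alone, from a bleach event; the post-experiment bleach-pulse
  background available in real experiments (and the ALEX frames) resolve
  most but not all such cases.
* ALEX checks are only as frequent as the far-red frames in the cycle
  (every 10 s in the default 99+1 cycle); dyes bleaching before the first
  check cannot be validated and such traces are rejected.
* The Gaussian camera-noise approximation under-disperses very low-count
  frames; selection's 2000-count threshold keeps analyses out of that
  regime.
* Bi-exponential decompositions with component separation under ~4-fold
  are reported but should not be over-interpreted: at a few thousand
  events the amplitude split is weakly identified regardless of the
  fitting method.
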