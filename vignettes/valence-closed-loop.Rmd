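---
title: "Tracking and regulating a latent emotional valence state from facial EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and regulating a latent emotional valence state from facial EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valenceloop)
```

## The problem

Emotional valence — the pleasant/unpleasant axis of Russell's circumplex — is
not directly measurable, but the electromyogram of the zygomaticus major
(zEMG, the "smiling" muscle) carries involuntary information about it.
`valenceloop` implements a complete pipeline around that idea:

1. extract a binary (spike-like) and a continuous (log-bandpower) feature
   from raw zEMG;
2. model valence as a scalar latent state observed through both features,
   and estimate the state and its person-specific parameters with a mixed
   Kalman/point-process filter, a fixed-interval smoother and EM;
3. summarize the environmental drive on valence as a 100-term sinusoidal
   harmonic model per affective class (high valence, HV; low valence, LV);
4. close the loop around a simulated *virtual subject* with a Mamdani fuzzy
   controller that inhibits high-valence episodes or excites low-valence
   ones.

Everything runs on synthetic data with known ground truth, so each stage can
be validated end to end without any external recordings.

## The state-space model

One state step corresponds to one 0.5 s feature bin (2 Hz). The latent
valence $x_k$ follows a random walk driven by the environmental stimulus
$s_k$ and the control input $u_k$:

$$x_{k+1} = x_k + \varepsilon_k + s_k + u_k,
  \qquad \varepsilon_k \sim N(0, \sigma_\varepsilon^2).$$

Two channels observe the state simultaneously. The binary channel is a
Bernoulli draw through a sigmoidal link,

$$n_k \sim \mathrm{Bern}(p_k), \qquad
  p_k = \frac{e^{\gamma + x_k}}{1 + e^{\gamma + x_k}},$$

and the continuous channel is linear-Gaussian,

$$z_k = \alpha + \beta x_k + \omega_k,
  \qquad \omega_k \sim N(0, \sigma_\omega^2).$$

$\alpha$ is the baseline log-bandpower, $\beta$ its sensitivity to valence,
and $\gamma$ sets the resting spike rate. Using both channels at once yields
narrower posterior intervals than either alone.

## Front-end feature extraction

`bandpass_notch()` applies a third-order Butterworth band-pass (10–250 Hz)
plus second-order IIR notches (quality factor 30) at 50 Hz and its next four
harmonics. Filtering is zero phase (forward–backward), which avoids phase
distortion of the envelope and doubles the design attenuation in dB; the
analytic cascade response is exposed by `filter_cascade_response()`. The
signal is then cut into non-overlapping 0.5 s bins (trailing partial bin
dropped).

For the binary feature, the filtered signal is rectified, smoothed with a
Gaussian kernel (standard deviation 25 ms — wide enough to merge motor-unit
transients without erasing bursts), and normalized by its global maximum;
the per-bin mean $y_k \in [0,1]$ gives a spike probability $q_k = a\,y_k$
with $a = 0.5$, from which $n_k \sim \mathrm{Bern}(q_k)$ is drawn. The
normalization step is our choice: it guarantees a valid probability for any
amplitude scale while preserving the amplitude-dependence of the spike rate.

For the continuous feature, each bin's power spectral density is estimated
by Welch's method — Hann windows of half the bin length with 75% overlap,
giving at least four averaged segments per bin — integrated over 10–250 Hz,
log-transformed, and min–max normalized over the whole recording. A
degenerate recording in which every bin has identical power maps to 0.5
everywhere; a zero-power bin is floored at a small positive constant before
the log (with a warning).

## Filtering, smoothing and EM

The forward filter alternates a random-walk prediction with a mixed update.
The filtered mean solves the scalar implicit equation

$$x = x_{k|k-1} + C_k\left[\beta (z_k - \alpha - \beta x_{k|k-1})
   + \sigma_\omega^2 (n_k - p(x))\right],
  \qquad C_k = \frac{\sigma^2_{k|k-1}}{\beta^2 \sigma^2_{k|k-1} + \sigma_\omega^2},$$

whose left-minus-right side is strictly monotone, so the root is unique; it
is found by Newton–Raphson started at the prediction (tolerance $10^{-10}$,
at most 50 iterations) with a bisection fallback on the analytic bracketing
interval. The filtered variance adds the Bernoulli information $p(1-p)$ to
the Gaussian information. With the binary channel disabled the update
reduces *exactly* to the textbook scalar Kalman update, and the test suite
verifies agreement with an independent Kalman/RTS implementation to
$10^{-10}$; with the continuous channel disabled it reduces to the pure
point-process filter. The filter is written once (in C++ for speed) and
shared by the batch and streaming interfaces, so online closed-loop use is
bit-identical to batch use.

The fixed-interval smoother runs backward with gain
$A_k = \sigma^2_{k|k} / \sigma^2_{k+1|k}$. The covariance pass keeps only
the lag-one smoothed cross-covariance
$\sigma_{k-1,k|K} = A_{k-1}\,\sigma^2_{k|K}$ — the only element the M-step
consumes — and forms the second moments $W_{k|K}$ and $W_{k-1,k|K}$ from it.
(The printed form of the cross-moment recursion is ambiguous about whether
its first term is a variance or a cross-covariance; only the cross-covariance
reading is dimensionally consistent with its use in the
$\sigma_\varepsilon^2$ update, so that is what is implemented.)

The EM algorithm alternates this E-step with closed-form M-step updates:
$(\alpha, \beta)$ from the 2×2 normal equations in the smoothed moments,
$\sigma_\omega^2$ from the expected continuous residual, and
$\sigma_\varepsilon^2$ from the mean expected squared state increment. The
$k = 1$ increment needs initial-state moments; inside the EM loop these use
the previous iteration's $(x_0, \sigma_\varepsilon^2)$, and in a standalone
M-step call the initial state is identified with the smoothed first bin so
the boundary term vanishes — a single $O(1/K)$ term either way.

### Identifiability and the ridge anchor

$\gamma$ is not part of the estimated parameter vector; it is fixed at the
logit of the empirical spike rate at initialization. This is necessary
because the model carries an exact invariance: remapping the state
$x \to (x - d)/c$ while sending $(\alpha, \beta, \sigma_\varepsilon^2, x_0)
\to (\alpha + \beta d,\; c\beta,\; \sigma_\varepsilon^2 / c^2,\;
(x_0 - d)/c)$ leaves the continuous likelihood and the state prior exactly
unchanged. Only the Bernoulli channel pins the state's level and scale, and
because its information content per bin is small, plain EM moves along this
two-dimensional ridge extremely slowly — on 40-minute simulations $\beta$
barely leaves its starting value. Each EM iteration therefore ends with a
closed-form re-anchor: a logistic regression of $n_k$ on the smoothed state
yields the affine remap that maximizes the binary likelihood along the
ridge, and the parameters are moved there at no cost to the rest of the
fit. The anchor is skipped when the binary channel is disabled; in that
sub-model the classical EM ascent property holds verbatim and is verified
by the test suite on the exact Gaussian-channel likelihood.

Convergence is declared when the largest relative change among
$(\alpha, \beta, \sigma_\varepsilon^2, \sigma_\omega^2)$ falls below
$10^{-6}$ (scale-free, standard EM practice), with a cap of 500 iterations.
The initial predicted variance is $v_0 = \sigma_\varepsilon^2$,
configurable. The 95% credible band is
$x_{k|K} \pm 1.96\sqrt{\sigma^2_{k|K}}$.

### What the recovery experiment emulates — and a known limitation

Parameter recovery is validated on simulated sessions of 40 one-minute
trials (K = 4800 bins) alternating LV/HV, the scale of a typical
affect-elicitation session. Real elicitation keeps valence bounded near the
trial's affective level, so the session generator applies a restoring
environmental drive $s_k = \kappa\,(m_k - x_k)$ with $\kappa = 0.1$ per bin
toward trial targets $\pm 0.25$ — targets chosen within the near-linear
range of the logistic link so the spike-rate anchor for $\gamma$ is
accurate. Under these conditions the EM recovers $\alpha$ and $\beta$ to a
few percent (median over 20 seeds) and the smoothed state correlates with
the truth above 0.95.

Coverage of the 95% band lands a few points below nominal (about 92%
pooled, as recomputed by `scripts/acceptance.R`). Two honest reasons: the
band is conditional on the estimated parameters and cannot absorb the
binomial-information-limited uncertainty of the level/scale anchor, and the
state model fitted during estimation deliberately omits the environmental
stimulus (the stimuli are "inherent in the data"), so the restoring dynamics
bias $\hat\sigma_\varepsilon^2$ slightly low. Both effects are properties
of the method as specified, not of the implementation: with the generating
parameters the same smoother covers 94–95%.

## Environmental stimuli

`derive_stimuli()` takes first differences of the estimated state, so that
cumulative summation inverts it exactly. `select_trials()` picks, per
class, the six trials with the highest (HV) or lowest (LV) combined rank of
mean and standard deviation of the estimated state, ties broken by trial
id. `fit_harmonics()` represents a class stimulus as
$s_k = \sum_{j=1}^{100} \rho_j \sin(\zeta_j k + \phi_j)$; the triples come
from the DFT bins of largest magnitude (zero frequency excluded). This is
deterministic and reproducible, has the identical functional form to a
nonlinear least-squares fit over 300 free parameters, and cannot get stuck
in local minima. `synthesize_schedule()` replays class segments (the
harmonic phase restarts per segment) and bridges class changes with a
linear ramp of 0.5 s — one bin at the 2 Hz state rate.

## The fuzzy controller

The controller regulates the *estimated* valence directly rather than an
error against a reference. Its input is the filtered state averaged over a
10 s trailing window; the output universe is $[-u_{\max}, u_{\max}]$ with
$u_{\max} = 0.1$ state-units per bin by default (no control-authority value
is dictated by the physiology; 0.1 per 0.5 s bin can traverse the full
LV-to-HV distance in about 10 s, which is the time scale of the stimulus
transitions themselves). Rule base: inhibitory mode maps LowValence to
Neutral and HighValence to Inhibition; excitatory mode maps LowValence to
Excitation and HighValence to Neutral. Inference is standard Mamdani
(min-implication, max-aggregation) and defuzzification is the centroid.

Numerical choices: the output universe is discretized at 2001 points, and
the inference grid is augmented with the exact breakpoints and
clip-crossing points of the active rules, which makes the trapezoidal
centroid exact (to floating point) for the piecewise-linear aggregates that
arise here; a zero-area aggregate defuzzifies to 0; outputs with magnitude
below $10^{-9} u_{\max}$ are snapped to exactly zero because the symmetric
Neutral centroid is an analytic zero and the residue is pure rounding.
During the first minute of a session the controller is suspended so the
online filter can converge.

Input membership functions are calibrated per subject from an open-loop
run: the universe spans the 1st–99th percentile of the open-loop filtered
state and the LowValence/HighValence trapezoids cross at the midpoint
between the LV-period and HV-period medians. The rise/fall is confined to
the central half between the medians, leaving a 25% dead band on each side.
The dead band is a deliberate design choice: it makes the controller
*exactly* silent while the smoothed state sits at its own class median,
preventing chatter inside the target class — mirroring the intended
behaviour that the control signal stays at zero throughout LV periods of an
inhibitory run. A subject whose LV median is not below its HV median has no
usable contrast and calibration refuses with an error advising exclusion,
the same screening applied to unresponsive participants in practice.

## Closed-loop simulation and evaluation

A virtual subject is a parameter set plus a per-class harmonic stimulus
model. The default bank jitters $(\alpha, \beta, \sigma_\varepsilon^2,
\sigma_\omega^2)$ by ±10% around $(0.3, 0.5, 10^{-4}, 0.01)$ with
$\gamma = -1$. The bank's stimulus models are fit to the first difference
of a smooth reference path — a 20 s rise to ±1, a hold with small
subject-specific oscillation, and a return to baseline in the second half
of a reference twice the session-half length, so that the DC-free harmonic
reconstruction holds its level across a replayed half-session. The modest
process noise emulates *emotionally responsive* subjects: the screening
described above excludes subjects whose spontaneous drift swamps their
stimulus-driven contrast, so the bank represents the population on which a
controller can meaningfully be evaluated.

Sessions last 10 minutes (1200 bins), half LV then half HV or the reverse.
Per bin: observations are emitted from the true state, the mixed filter
updates online, the controller produces $u_k$ (zero in open loop and during
the 60 s warm-up), and the state steps forward. All noise is drawn up front
from the seed, so open- and closed-loop runs with the same seed share
identical draws and any difference is attributable to the control input
alone (common random numbers). Summaries per labeled period — spike count
and mean *estimated* valence, matching what an online system can actually
observe — exclude the warm-up bins, since the filter is still converging
there. Evaluation across a subject bank uses paired two-tailed t-tests of
closed against same-seed open runs; pairing is the natural choice because
the runs share subjects and noise. Zero-variance differences (e.g. a
controller that never acted) report p = 1 when all differences are zero.

## Synthetic zEMG

`generate_recording()` emulates the front end's real input: band-limited
(20–240 Hz) Gaussian noise whose envelope follows
$\exp(0.5\,x_{\text{latent}})$ — positive and strictly increasing in the
latent level — plus 50 Hz line interference with weak harmonics at 100 and
150 Hz. The latent path is the per-trial target (LV = −1, HV = +1) plus a
within-trial random walk. It does *not* emulate motor-unit physiology,
movement artifacts, electrode drift, or inter-channel effects; passing
tests on it demonstrates that the pipeline recovers what the generative
model puts in, not that it is robust to every artifact of real recordings.

## Problem sizes used in validation

The automated checks use: 50 randomized length-200 sequences for the
Kalman/RTS equivalence; 100 randomized one-step updates against a
400 001-point grid search; 20 sessions of K = 4800 bins for EM recovery and
band coverage; 100 random rule activations against a $10^6$-point centroid
quadrature; a bank of 10 subjects × 2 stimulus orders × 3 scenarios for
closed-loop efficacy; 20 short recordings for the front-end contrast; and a
length-1024 three-sinusoid fixture for the harmonic model. These sizes give
stable statistics while keeping a full validation run to a few minutes.

## Known limitations

- The valence state is scalar and two-class (HV/LV); arousal is not
  modeled.
- $\gamma$ is anchored, not estimated; all level/scale information flows
  through the binary channel, whose information content bounds how well the
  absolute state scale can be known.
- The credible band is conditional on estimated parameters (see above).
- The controller is mono-objective: an inhibitory controller that correctly
  lowered an HV period will also leave later periods different from the
  open loop, because it cannot switch goals mid-session.
- Real-world actuation (how one would actually nudge valence) is outside
  the scope; the control signal acts directly on the simulated state.
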