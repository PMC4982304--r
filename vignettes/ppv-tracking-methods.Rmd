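---
title: "Tracking pulse pressure variation during spontaneous breathing: model, filter and design choices"
author: "ppvtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking pulse pressure variation during spontaneous breathing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 5)
```

## The problem

Pulse pressure variation (PPV) quantifies how much the beat-to-beat pulse
pressure PP (systolic minus diastolic arterial pressure) swings over a
respiratory cycle,

$$\mathrm{PPV}\,(\%) = 100\,\frac{\mathrm{PP}_{\max}-\mathrm{PP}_{\min}}
{(\mathrm{PP}_{\max}+\mathrm{PP}_{\min})/2},$$

and is used clinically as a predictor of fluid responsiveness.  During
mechanical ventilation the respiratory rhythm is known and regular; during
spontaneous breathing it is neither, and the respiratory modulation of the
arterial pressure (ABP) waveform is weak and irregular.  `ppvtrack`
estimates a continuous PPV index from a single ABP channel alone by fitting
a structured statistical model of the waveform with a dual maximum
a-posteriori marginalized particle filter, and provides the surrounding
machinery — a ground-truth simulator, envelope extraction, a per-cycle
manual-standard comparator, windowed measurements and Bland–Altman
agreement statistics — so the whole chain can be validated without any
external data.

## Signal model

The mean-centered ABP sample at time $n$ is modelled as a respiratory
baseline plus an amplitude-modulated cardiac harmonic series:

$$y_n = \gamma_n + \sum_{k=1}^{N_c} \rho_{k,n}\,\kappa_{k,n} + v_n,$$

with

* $\gamma_n = \sum_{j=1}^{N_r} r_{1,j,n}\cos(j\theta^r_n) +
  r_{2,j,n}\sin(j\theta^r_n)$ — the respiratory baseline,
* $\kappa_{k,n} = c_{1,k,n}\cos(k\theta^c_n) + c_{2,k,n}\sin(k\theta^c_n)$
  — the $k$-th cardiac partial,
* $\rho_{k,n} = 1 + \sum_{j=1}^{N_r} m_{1,k,j,n}\cos(j\theta^r_n) +
  m_{2,k,j,n}\sin(j\theta^r_n)$ — its respiratory amplitude-modulation
  factor, and
* $v_n$ white Gaussian measurement noise with variance $r$.

The angles integrate instantaneous frequencies
($\theta_{n+1} = \theta_n + 2\pi T_s f_n$); the mean frequencies follow a
random walk confined to physiological ranges by a *reflecting* clip (a
hard saturation would trap particles at the bounds), and the instantaneous
frequencies mean-revert toward them with autoregressive coefficient
$\alpha$ (default 0.95; the model prescribes mean reversion but leaves the
coefficient open, so it is exposed in the configuration).  All sinusoidal
and modulation coefficients follow independent random walks.  Because
$\rho_k \kappa_k$ multiplies modulation and cardiac coefficients, the
measurement is *bilinear* in the coefficients: conditional on the angles
it is handled by an extended (first-order linearized) Kalman filter, not
an exact one.

One modelling consequence worth stating explicitly: the model has no DC
term, so input signals are mean-centered before tracking, and the removed
mean is stored and added back when ABP envelopes are reported in mm Hg.
The same convention applies to real recordings ingested through
`read_signal()`/`preprocess_signal()` (anti-aliased decimation to 40 Hz
with a zero-phase Butterworth low-pass at 0.8× the target Nyquist, then
centering).

## The dual MAM-PF

The posterior of an instantaneous frequency given a multi-harmonic signal
is multimodal (harmonics and sub-harmonics explain the data almost as
well), so the two frequencies are estimated by particles while the
coefficient vector — unimodal given the angles — is marginalized by one
EKF per particle (a Rao-Blackwellized/marginalized particle filter).
Tracking the respiratory/cardiac frequency pair jointly would need a
two-dimensional particle grid ($N_p^2$ particles); the *dual* filter
instead runs two one-dimensional particle populations of $N_p$ particles
each — $2 N_p$ in total — one per rhythm, each conditioning on the other
space's current estimate, in the spirit of dual Kalman filtering.

Per sample and per space the filter:

1. proposes each particle's next instantaneous frequency from its own
   process model;
2. searches all $N_p$ previous particles for the best *ancestor*, the one
   maximizing accumulated MAP score plus Gaussian transition log-density
   (the measurement likelihood cancels in this argmax because it is
   evaluated with the particle's own predicted coefficient state);
3. inherits the selected ancestor's trajectory — angle, mean frequency
   and marginalized coefficient state;
4. time-updates the coefficient covariance, applies the EKF measurement
   update (Joseph form), and accumulates the score: discounted ancestor
   score + transition log-density + innovation log-likelihood; scores are
   then normalized per space (log-sum-exp to zero);
5. extracts the per-space MAP particle, and takes the coefficient
   estimate from whichever space currently has the larger accumulated
   score (per-space normalized maxima plus each space's accumulated
   log-normalizers, so the comparison is on a common scale).

Three design choices deserve emphasis, because each was forced by a
failure mode that is easy to reproduce:

**Trajectory inheritance.**  The coefficient state is phase-locked to the
angle trajectory it was estimated under: rotating the angle reference
rotates the coefficients.  If a particle inherits an ancestor's
coefficients but keeps its own angle history, every ancestry swap injects
a phase-inconsistent coefficient state; with hundreds of particles
swapping ancestry continuously this destabilizes the whole filter
(respiratory mis-lock, inflated modulation estimates, PPV spikes).  The
filter therefore inherits angle, mean frequency and coefficients together
from the selected ancestor, with only the instantaneous frequency proposed
per particle.

**Score forgetting.**  The accumulated MAP score of classic Viterbi-style
search never forgets: the ranking acquired during the first seconds —
when the opposite space's estimate is still wrong and every likelihood is
garbage — persists indefinitely, and particles that happened to fit the
transient best stay on top.  The score recursion therefore applies an
exponential forgetting factor (`score_discount`, default 0.999 per step
≈ 25 s memory at 40 Hz; set it to 1 for the pure accumulated score).

**A smooth shared reference.**  Each space conditions its EKFs on the
opposite rhythm's kinematics.  Particle angles carry an arbitrary phase
(the phase lives in the coefficients), so re-reading the MAP particle's
angle each step injects phase jumps whenever the MAP particle switches,
which poisons every EKF conditioned on it.  The shared reference instead
integrates its own angle continuously at the opposite space's
posterior-mean frequency (relaxation gain `ref_freq_gain`, default
0.02/step): any fixed phase offset of the reference is absorbed by the
coefficient estimates, and only reference *frequency* error matters.
Reconstruction uses the angle pair the winning coefficient state was
actually conditioned on, and respiratory cycles are delimited by the
smooth reference clock.

Classic weight-proportional resampling is not used; the per-step ancestor
search plays the rejuvenation role.  As a backstop against mode collapse,
when the best score exceeds the median by `rejuv_gap` for `rejuv_steps`
consecutive samples, the lowest-scoring 10 % of particles are re-spread
evenly over the frequency range with the current best particle's
coefficients, a reset (prior) covariance, and the lowest kept score, so
they must earn their ranking (`rejuv_enabled`, default on).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `n_cardiac_harmonics` | 10 | cardiac partials $N_c$ |
| `n_resp_harmonics` | 3 | respiratory partials $N_r$ |
| `n_particles_per_space` | 250 | $N_p$ (500 particles total) |
| `f_resp_min`, `f_resp_max` | 6/60, 30/60 Hz | admissible respiratory range |
| `f_card_min`, `f_card_max` | 50/60, 140/60 Hz | admissible cardiac range |
| `meas_noise_var` | var(y)/1e3 | measurement noise $r$ |
| `q_freq_resp`, `q_freq_card` | $10^{-6} T_s$ | frequency random-walk variances |
| `q_resp_coeff`, `q_card_coeff` | var(y)$\cdot 10^{-6} T_s$ | coefficient random-walk variances |
| `q_mod_coeff` | var(y)$\cdot 10^{-8} T_s$ | modulation random-walk variance |
| `init_resp_amp`, `init_card_amp` | sd(y)/10 | initial coefficient scales |
| `init_mod_amp` | sd(y)/1e3 | initial modulation scale |
| `ar_coeff` | 0.95 | frequency mean-reversion |
| `score_discount` | 0.999 | score forgetting per step |
| `ref_freq_gain` | 0.02 | shared-reference relaxation |
| `angle_grid_size` | 256 | envelope search grid |

Signal-scaled defaults resolve at fit time from the mean-centered input
(`resolve_config()`).  The harmonic-order defaults are the full published
parameterization; note that the assessment experiments that motivated
this tracker ran with 5 cardiac and 2 respiratory components, and the
heavier simulations in this package's test-suite use those orders too —
the two conventions disagree in the source material, and both are
legitimate configurations here.

The frequency random-walk variance sets the fastest rate drift the filter
can follow (roughly $\sqrt{q}$ Hz per sample of sustained selection
pressure).  The default suits quasi-stationary rhythms; a deliberate
frequency sweep — for instance the 1.0→1.4 Hz chirp exercised in the test
suite — needs a larger `q_freq_card` (the suite uses $10^{-4} T_s$).

## Particle initialization

Mean and instantaneous frequencies start on an even grid over the
admissible range plus a uniform jitter of at most 2 % of the grid
spacing; angles start at zero; all particles share one coefficient prior
(zero mean except the first-harmonic cosine amplitudes at the initial
scales; diagonal covariance from the squared scales) and uniform scores.
The shared references start at the range midpoints.  Everything after
`set.seed` is deterministic: noise is pre-generated in a fixed order
(initialization jitter, then per-space frequency noise matrices), so the
same seed gives a bit-identical track.

## Envelopes and the continuous PPV

Given the per-sample MAP coefficients and respiratory angle, the ABP
envelopes extremize the modulated cardiac sum over the cardiac angle,

$$e_{\mu,n}, e_{\ell,n} = \gamma_n + \sum_k \rho_{k,n}\,
\kappa_{\max/\min,k,n},$$

and the PP envelopes extremize
$\sum_k (1+\varrho_k(\theta))(\kappa_{\max,k,n}-\kappa_{\min,k,n})$ over
the respiratory angle; the continuous PPV is the normalized difference of
the PP envelopes.  Both one-dimensional searches use a coarse grid
(`angle_grid_size` points, ties toward the smaller angle) followed by one
golden-section refinement pass on the bracketing interval, which the test
suite verifies against a 100 000-point dense grid to $10^{-4}$ relative
error.  Early-transient coefficient estimates can push a PP envelope
negative; since PP is physically nonnegative the envelopes are clamped at
zero and the number of clamped samples is reported in the diagnostics.
PPV is reported as 0 where both envelopes vanish.

Two useful invariances: PPV is a ratio, hence invariant to uniform
scaling of the signal; and it is invariant to a common rotation of the
coefficient phase frame, which is why the arbitrary phase of the particle
angles is harmless for PPV even though it matters for instantaneous
envelope display.

## The synthetic generator

`ppv_simulate()` renders the forward model with *deterministic* frequency
profiles (constant, linear chirp, or sinusoidal drift) so the ground
truth — angles, frequencies, envelopes, continuous PPV — is exactly
known, rather than a realized random walk that the tracker could only
match in distribution.  The default record emulates a spontaneously
breathing adult: 120 s at 40 Hz, respiration 0.25 Hz, heart rate 1.2 Hz,
cardiac amplitudes 30/12/6 mm Hg, respiratory baseline 3/1 mm Hg, uniform
first-harmonic modulation of depth 0.075 on every partial (true PPV
exactly $200 m = 15\,\%$, mid-range of clinically reported values), a
90 mm Hg offset and 1 mm Hg noise.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: dicrotic-notch and reflected-wave morphology
beyond a three-harmonic series, arrhythmias, movement artifacts,
non-harmonic respiratory irregularity, and baseline drift other than the
harmonic respiratory baseline.  Performance on the synthetic suite is a
necessary, not sufficient, condition for clinical-grade behavior.

## Numerical choices

* All score arithmetic is in the log domain; per-space normalization by
  log-sum-exp after every step.
* EKF covariance updates use the Joseph form with re-symmetrization; a
  non-positive innovation variance triggers a covariance repair
  (eigenvalue floor at zero) before the update.
* The instantaneous frequencies are passed through the same reflecting
  clip as the mean frequencies so that reported MAP frequencies can never
  leave the configured ranges.
* Overshoot beyond one reflection of the clip is an error by design — it
  indicates a mis-scaled frequency noise variance.
* Grid ties in the envelope searches break toward the smaller angle;
  the refined candidate is only accepted when it beats the grid value.

## Validation summary

The test suite validates each layer against an independent path: the
measurement gradient against central differences; the envelope search
against a dense grid; the per-particle EKF against an exact Kalman filter
on the modulation-frozen linear submodel; one full filter step against a
straight-line enumeration on a three-particle toy; the envelope chain
against the generator's analytic ground truth; and, end to end, frequency
and PPV recovery on twenty 120-s synthetic records with 500 particles
(median steady-state cardiac frequency error below 0.05 Hz, respiratory
below 0.03 Hz, windowed five-cycle PPV within ±4 percentage points of the
truth in at least 19 of 20 records).  Windowed PPV measurements follow
the assessment protocol — five measurements per record, 2 min apart, each
a five-respiratory-cycle average — with the window anchor configurable;
the synthetic assessments anchor at 60 s so that the measured windows lie
in the filter's steady state rather than its acquisition transient.
Problem sizes in the routine suite (120-s records; 5 cardiac and 2
respiratory harmonics for the multi-record simulations) are the package's
standard validation conditions; the 10-minute, five-window protocol is
exercised by `scripts/acceptance.R`.

## Known limitations

* The dual decomposition assumes the two rhythms are separable; a heart
  rate inside the respiratory range (or vice versa) violates the
  partition.
* Respiratory frequency is identified from weak features (baseline and
  modulation sidebands, a few mm Hg); very low modulation depth plus a
  weak baseline makes the respiratory space slow to lock.
* The per-cycle comparator inherits the beat-quantization of the classic
  definition: with few beats per respiratory cycle the discrete beats
  miss the modulation extrema and the per-cycle PPV is biased low
  relative to the continuous index.
* Forward filtering only; no smoothing, no real-time I/O.
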