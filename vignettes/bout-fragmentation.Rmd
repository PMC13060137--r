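---
title: "Bistable attractor dynamics of feeding-bout fragmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bistable attractor dynamics of feeding-bout fragmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Animals rarely eat continuously. A refeeding session fragments into *bouts*
of ingestion separated by long pauses, and within a bout feeding is peppered
with brief *interruptions* — pauses that resolve back into eating. The
quantity of interest is not how much is eaten but how bouts end: whether a
given interruption stays an interruption or commits into a *termination*.
This package implements a dynamical account of that decision and the
analytics needed to measure it in annotated behavior and photometry-style
recordings.

The conceptual picture is a double-well system. A population activity
variable sits in a low-activity attractor while the animal feeds and in a
high-activity attractor otherwise. Interruptions are upward kicks delivered
by an external point process; whether a kick escapes the feeding well
depends on the height of the energy barrier between the wells. Neural
perturbations that change bout durations can then act in exactly two ways:
by changing the kick rate, or by changing the barrier. The package exists to
make both hypotheses quantitative and testable.

## The model

`model_params()` defines a two-population Wilson–Cowan system, an excitatory
population $E$ and an inhibitory population $I$:

$$\tau_E \dot E = -E + s(w_{EE}E - w_{IE}I + c), \qquad
  \tau_I \dot I = -I + s(w_{EI}E - w_{II}I),$$

with logistic gain $s(x) = 1/(1+e^{-a(x-\theta)})$. Defaults are
$\tau_E = 2$ s, $\tau_I = 0.4$ s, $w_{EE}=w_{II}=15$, $w_{IE}=w_{EI}=10$,
$a=1$, $\theta=8$. The tonic current $c$ enters only the excitatory gain
argument and emulates optogenetic manipulation of the pathway: $c=-0.7$ for
inhibition (eOPN3-like), $c=+0.85$ for activation (ChR2-like). The E/I pair
is a minimal bistable motif, not a literal circuit diagram; any mechanism
producing two attractors and a saddle would serve.

Interruptions are a renewal process (`renewal_params()`): waiting times are
lognormal, $\log(\text{interval}/s) \sim N(2.22,\,0.99^2)$, and each event
kicks the excitatory population by $\Delta \sim N(0.56,\,0.11^2)$, applied
as $E \leftarrow E + \Delta$ with no truncation of rare negative draws.
`rate_scale` divides sampled intervals, raising the interruption rate
without touching the landscape — the model analogue of a threat cue that
fragments feeding by adding interruptions.

Stochasticity is additive Gaussian noise with standard deviation $0.1055$
on both equations, integrated by Euler–Maruyama at $dt = 0.02$ s.

### The noise convention

"Noise of standard deviation $\sigma$ added to the equations" under
Euler–Maruyama admits two readings: a diffusion amplitude (per-step
increment $\sigma\sqrt{dt}\,\xi$) or a raw per-step perturbation
($\sigma\,\xi$). We adopt the diffusion reading — it is what an SDE means,
and the raw reading at $dt=0.02$ would swamp the attractors entirely.
Whichever convention ships must be self-consistent:
`estimate_noise_sd()` recovers $\sigma$ from simulated increments by
computing $(\Delta E - f_E\,dt)/\sqrt{dt}$ per pulse-free step, and the test
suite asserts the recovery.

## The quasi-static landscape

Because $\tau_I \ll \tau_E$, the inhibitory variable is slaved to its
E-conditional steady state $\hat I(E)$, the unique root of
$I = s(w_{EI}E - w_{II}I)$ (`solve_I_steady()`; uniqueness holds for any
$w_{II} > 0$ since the residual is strictly increasing in $I$).
Substituting gives a scalar flow (`effective_drift()`) and its potential

$$V(E) = -\int_{E_{th}}^{E} \dot E\,dE',$$

computed by trapezoidal accumulation on a uniform grid of 4096 points
(`compute_potential()`; second-order, deterministic, cheap) and zeroed at
the unstable threshold $E_{th}$. In the bistable regime the three roots of
the drift are labeled feeding (low, stable), threshold (unstable) and
non-feeding (high, stable), and the *barrier* is
$V(E_{th}) - V(E_{\text{feed}})$ — the energy an interruption must supply to
terminate a bout. At the defaults the geometry is:

| current | $E_{\text{feed}}$ | $E_{th}$ | barrier |
|---|---|---|---|
| 0 (ctrl) | 0.00034 | 0.595 | 0.0535 |
| −0.7 (eOPN3) | 0.00017 | 0.690 | 0.0711 |
| +0.85 (ChR2) | 0.00079 | 0.495 | 0.0363 |

This table is the mechanism in miniature: the mean kick is 0.56, so at
baseline a typical pulse lands just under the threshold and noise decides
the outcome; inhibition pushes the threshold out of reach of most pulses,
activation pulls it below the mean pulse. Note a legend/text discrepancy in
the source material about the sign of the excitatory-current effect; we
follow the main-text direction (positive current shortens bouts), which is
also what the landscape geometry dictates.

When a current sweep destroys bistability (saddle-node), the landscape
reports `bistable = FALSE` with $V$ zeroed at its global minimum instead of
failing; downstream state labeling refuses monostable landscapes, since the
feeding/non-feeding dichotomy is then undefined.

Root finding throughout is sign-change bracketing on the uniform E grid
followed by `uniroot` polishing (tolerance 1e-12 on the bracket, residual
checked below 1e-10); the 2-D fixed points are obtained by seeding a damped
Newton iteration from the 1-D roots (every 2-D steady state lies on
$I = \hat I(E)$, so the reduction loses nothing), deduplicated at radius
1e-6, far below the inter-root spacing.

## Simulation and event accounting

`simulate_wc()` integrates the SDE with the renewal clock attached: the
clock accrues only while $E$ is below threshold, pauses during excursions,
and restarts with a fresh interval draw at each feeding entry. States are
never clipped; a guard aborts if activity leaves $[-0.5, 1.5]$, which only
happens with a mis-set noise amplitude.

**Hysteresis labeling.** A sample is non-feeding only if it belongs to an
above-threshold excursion lasting at least `commit_time = 4` s
(`label_states()`). The 4 s mirrors the behavioral segmentation rule, so
model and behavior use a single definition of interruption vs termination.

**Events come from the pulse log.** For model output, every renewal pulse
is an interruption/termination event; the pulse whose excursion commits the
bout's end is its termination, and a bout whose escape was purely
noise-driven gets a termination stamped at the bout end
(`trajectory_bouts()`). We deliberately do *not* re-derive model events from
threshold-crossing gaps: near the threshold, diffusion produces sub-sample
crossing chatter whose count depends on the condition, which would
contaminate the event-rate comparison. The pulse log is the ground truth of
the renewal framework. The empirical renewal interval attached to each
event is the below-threshold (clock) time since the previous event, so
refitting the lognormal from event tables inverts the generator without
excursion-time bias.

**Re-entry.** How feeding restarts after a termination is outside the
model's scope (perturbation data show initiations unchanged). Noise-driven
escape back into the feeding well is permitted but slow at the calibrated
noise, so `run_condition()` enables a forced re-entry: after the excursion
commits, the state resets to the feeding fixed point after an exponential
dwell of mean 20 s. This is an orchestration device for generating rasters
of realistic density, off by default in `simulate_wc()` itself; it adds
bouts but does not touch within-bout dynamics, which is where every claim
lives.

**Problem sizes.** Between-condition comparisons use 20 sessions of 600 s
per condition, the package's standing convention (also used by the
acceptance checks); at these sizes the directional effects on duration and
termination proportion are detected at $p < 0.05$ with comfortable margins.

## Behavioral analytics

`segment_bouts()` applies the 4 s rule to annotation tables: feeding
intervals separated by gaps shorter than 4 s merge into one bout, each such
gap is an interruption event, each bout ends in exactly one termination.
The threshold is exposed because other ingestion paradigms may warrant a
different cut. Segmentation is deterministic, idempotent on its own output,
and conserves total feeding time; these are tested as properties.

`permutation_ks()` implements the distributional test used for pooled bout
ECDFs: the Kolmogorov–Smirnov statistic (two-sided, or signed for the
one-tailed gain-of-function direction) with a permutation null and the
+1-corrected estimator $p = (1 + \#\{D^{perm} \ge D\})/(n_{perm}+1)$, which
is exactly valid at finite permutation counts. Durations are pooled across
subjects for ECDF comparisons and summarized per subject for mean-duration
comparisons, mirroring the dual presentation such figures use.

`termination_glm()` models termination-vs-interruption outcomes as a
Bernoulli GLM with a condition effect and fixed per-subject intercepts.
This is a deliberate simplification of a mixed-effects model: at cohort
sizes of 5–10 subjects the fixed-intercept approximation is standard, and
it keeps the dependency surface small. Complete separation is detected and
flagged rather than silently reported as a huge coefficient.

`fit_lognormal()` is the closed-form MLE (mean and population SD of log
intervals).

## Photometry quantification

`preprocess_photometry()` fits the reference channel to the signal by OLS
(slope and intercept) and subtracts the fit before z-scoring. Plain
subtraction is brittle to gain differences between channels; the regression
is our stand-in for the upstream preprocessing pipelines that are cited but
not specified in this literature, and it is documented as such. A constant
corrected trace z-scores to 0 by a degenerate-SD guard.

`align_events()` extracts peri-event windows (lag 0 at onset, incomplete
windows dropped and counted, overlaps kept) and averages per subject first,
then across subjects. `auc_response()` is the baseline-subtracted mean:
post-event window capped at $\min(20\text{ s}, \text{duration})$, baseline
the 10 s before the event; it is invariant to trace offsets and equals the
window means of the aligned rows (tested).

`regress_signal()` partitions variance by semi-partial $R^2$: each
predictor's unique contribution is the drop in $R^2$ when it is removed,
with the remainder reported explicitly as shared variance. "Variance
explained" is ambiguous when predictors correlate — and feeding and speed
are anticorrelated by construction — so the unique-variance reading is the
defensible one and is labeled as such in outputs. The feeding regressor is
the *bout* indicator (bouts including their intra-bout pauses) rather than
the raw feeding-interval indicator: bout-locked activity is what the
regression is after, and sub-4 s pauses are not activity returns.
Predictors are used raw; an optional low-pass at the indicator level was
considered and left out of the default path to keep the estimand plain.

## The synthetic-data generator

`synth_session_spec()` describes fasted-refeeding-like sessions; the
defaults are the study conditions the rest of the package is tested under:
6 subjects (cohort-scale), 20-minute sessions, bout durations lognormal
around 25 s, inter-bout gaps $4 + \text{Exp}(26\text{ s})$, intra-bout
pauses uniform on $[0.5, 3.5]$ s, interruption intervals from the default
renewal law, a 1-z dip during bouts with 1 s onset/offset time constants,
0.8-z transients (SD 0.5 s) at interruptions, 0.3-z white noise at 20 Hz,
and speed relaxing between 6 cm/s outside and 1 cm/s inside bouts with
1 cm/s jitter. Where a quantity had no stated value these are one-time
choices at the scale a behavioral physiologist would call realistic.

Bouts are assembled from *complete* renewal-interval draws (the target
duration decides how many segments accumulate), so refitting the interval
law from segmented output is unbiased except for end-of-session truncation.
Two generation paths exist on purpose: the parametric path tests the
analytics independently of the dynamical model, and the simulator path
tests the full loop. For the simulator path, below-threshold stretches
become feeding intervals after absorbing crossings shorter than 0.3 s — an
annotator's time resolution, which the raw diffusion does not respect.

What the generator does **not** emulate: bleaching and slow drifts beyond a
deterministic artifact shared between channels, hemodynamic contamination,
annotator timing jitter and mislabeled behaviors, between-session
non-stationarity, and any coupling from speed into the calcium trace other
than through behavioral state. Passing tests on synthetic cohorts therefore
validate the estimators' arithmetic and power at realistic effect sizes,
not robustness to every artifact of real recordings.

## Known limitations

- **Termination proportion under raised interruption rates is only
  approximately invariant.** Doubling the pulse rate increases the chance
  that a pulse arrives while $E$ is still relaxing from the previous
  excursion, and such pulses cross the threshold more often (the fraction
  of intervals shorter than 4 s rises from 0.20 to 0.44). The effect is
  small (about +0.03 on a base of ~0.45 at the standing problem size) but
  real, so the "unchanged gate" claim holds statistically at cohort-scale
  power, not as an exact model identity.
- The fixed-intercept GLM understates between-subject variance relative to
  a true mixed model; with few subjects and many events the coefficient
  sign and rough magnitude are reliable, confidence intervals less so.
- Re-entry into feeding is phenomenological (exponential dwell), so
  inter-bout interval statistics from the simulator describe the
  orchestration, not the biology.
- No escape-rate (Kramers/mean-first-passage) theory is attempted; all
  claims rest on landscape geometry plus direct simulation.
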