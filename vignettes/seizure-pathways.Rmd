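---
title: "Tracking seizure pathways with a neural mass model and an assumed-density filter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking seizure pathways with a neural mass model and an assumed-density filter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seizurepath)
```

## The problem

Intracranial EEG shows that focal seizures in a given patient follow
remarkably stereotyped paths, and that many patients carry two distinct
seizure populations — short and long — that separate cleanly on the
logarithm of seizure duration.  A mechanistic question follows: do short
and long seizures start differently, or do they follow one path and
differ only in how they stop?

`seizurepath` addresses this by *model inversion*: a Jansen–Rit-type
neural mass model is fitted to every sample of each seizure's ECoG, so
that the seizure is re-expressed as a trajectory through the model's
effective-connectivity parameter space.  The statistical pipeline then
operates on those trajectories rather than on the raw signal.

## The neural mass model

Three neural populations — pyramidal (p), excitatory interneurons (e) and
inhibitory interneurons (i) — interact through four synapses, labelled
pre→post: e→p, i→p, p→e, p→i.  Each synapse is a critically damped
second-order kernel converting the presynaptic population's firing rate
into a post-synaptic potential \(v_{mn}\):

\[
\dot v = z,\qquad
\dot z = \frac{\alpha}{\tau}\,\phi(v_{\mathrm{pre}})
         - \frac{2}{\tau} z - \frac{1}{\tau^2} v ,
\]

with lumped time constants \(\tau = 10\,\mathrm{ms}\) for the excitatory
kernels and \(20\,\mathrm{ms}\) for the slower inhibitory kernel.  The
firing-rate nonlinearity is an erf sigmoid
\(\phi(v) = \tfrac12\bigl(1 + \mathrm{erf}((v - v_0)/\varsigma)\bigr)\)
with threshold \(v_0 = 6\,\mathrm{mV}\) and slope scale
\(\varsigma = 3\,\mathrm{mV}\).  The pyramidal membrane potential —
which is also what the electrode records — is
\(v_p = v_{ep} - v_{ip} + u\), where \(u\) is the external (non-local)
input.  All computations are unit-homogeneous, so the volt and millivolt
conventions differ only by a common scale (`sigmoid_params(units = )`).

Five quantities are estimated per channel: \(u\) and the four lumped
connectivity gains \(\alpha_{ep}, \alpha_{ip}, \alpha_{pe},
\alpha_{pi}\).  The gains are kept non-negative by convention; the
inhibitory minus sign lives in the structure of \(v_p\) and the
observation row.  (Printed labels elsewhere sometimes index synapses
post–pre; this package uses pre→post throughout, which is the ordering
under which the 20 ms time constant belongs to the inhibitory synapse.)

The reference parameter set (`ref_params()`) lumps the classic
Jansen–Rit constants (\(H_e = 3.25\) mV, \(H_i = 22\) mV, \(C = 135\),
maximum rate 5 s\(^{-1}\)) into this gain convention and sits inside the
oscillatory regime: it produces a bounded alpha-band pyramidal rhythm
(~10.7 Hz in the continuous model) of a few millivolts.

Discretization, for both simulation and the filter's process model, is
the exact zero-order-hold step of each critically damped kernel: the
linear part advances by its closed-form matrix exponential and the
nonlinear drive \(\alpha\,\phi\) is held constant over the step
(explicit Euler is the first-order limit of this map, but at 400 Hz
Euler audibly detunes the limit cycle — from 10.7 Hz to 5 Hz for the
reference parameters — whereas the held-input map keeps 8.8 Hz).  Tests
verify first-order convergence of the trajectory and, at fine steps
where the map is converged, agreement of the dominant oscillation
frequency with an independent Runge–Kutta integration.  The residual
detuning of the 400 Hz map is a shared property of generator and filter:
joint state-parameter estimation requires the filter's process model and
the data-generating map to coincide, so the pipeline treats the 400 Hz
map as the model.  Process noise enters the \(z\)-states only (the
\(v\)-states are exact integrals of \(z\)).

## The assumed-density filter

States and parameters are estimated jointly: the parameters are given
random-walk dynamics and appended to the state, giving a 13-dimensional
augmented state \(\xi = [x; \theta]\) with dynamics
\(\xi_t = A\xi_{t-1} + B\,g(\xi_{t-1}) + w\), where each component of
\(g\) is the *product* \(\theta_j\,\phi(c_j^\top \xi)\) of a gain and a
sigmoid of a presynaptic potential.  The filter keeps the belief
Gaussian (an assumed-density filter): each prediction step needs the
mean and covariance of \(\xi_t\) under the current Gaussian belief.

For the erf sigmoid these moments are largely available in closed form:

* \(\mathbb E[\phi(V)]\) and \(\mathbb E[\phi'(V)]\) for Gaussian \(V\)
  are exact (`gaussian_sigmoid_mean()`, `gaussian_sigmoid_slope_mean()`);
* \(\mathbb E[\theta\,\phi(V)]\) and all cross-covariances
  \(\mathrm{Cov}(\xi, \theta\phi(V))\) follow from Stein's identity and
  are exact;
* the 4×4 covariance block of \(g\) requires
  \(\mathbb E[\theta_j\theta_k\,\phi(v_j)\phi(v_k)]\).  Conditioning
  \((\theta_j,\theta_k)\) on \((v_j,v_k)\) reduces the integrand to
  \(\phi\phi\) times a quadratic; one potential is then integrated in
  closed form (Gaussian-sigmoid moments up to second order), leaving a
  single one-dimensional Gauss–Hermite quadrature.

The remaining 1-D quadratures use 31 nodes by default, switching to 201
nodes for any integral whose outer standard deviation exceeds the
sigmoid's slope scale — there the integrand approaches a step times a
quadratic and fixed low order is visibly biased (errors of several
percent on covariance entries were measured at three times the slope
scale).  Wide beliefs occur essentially only at initialization, so the
high-order branch costs little.  Convergence was checked against order
601 (relative differences below \(10^{-9}\) across random beliefs
spanning small and large covariance) and against Monte-Carlo
propagation with batch standard errors; both orders are configurable
(`gh_order`, `gh_order_wide`).

The measurement update is the standard linear Kalman step; the posterior
covariance uses the Joseph form, which is algebraically identical to the
textbook \((I - KH)P\) expression but numerically stable.  With the
nonlinearity disabled the whole filter collapses to a linear Kalman
filter, and the tests verify equality with an independent textbook
implementation to \(10^{-10}\).

### Noise scales and initialization

Neither the process-noise covariance \(Q\) nor the observation-noise
variance \(R\) can be taken from first principles, so both are explicit
configuration with documented defaults (`filter_config()`):

* \(R\) is estimated per seizure from the pre-onset baseline as the
  variance of the high-passed signal (default cutoff 100 Hz), rescaled
  by the retained bandwidth fraction — a proxy for the white-noise
  floor.  It can be overridden (`r_obs`).
* \(Q\) is diagonal.  The \(z\)-state scale is a multiple of
  \(\sqrt R\) (default 150), so the filter's dynamical freedom tracks
  the recording's noise floor.  The parameter random-walk standard
  deviation is *relative to each parameter's nominal magnitude*
  (default \(3\times10^{-3}\,|\theta_0|\) per step).  The relative
  parametrization matters: the five parameters span three orders of
  magnitude, and a common absolute scale either freezes the small
  parameters or lets the large ones swamp the update.  The default is a
  compromise between tracking speed (a 30% step in \(\alpha_{ep}\) is
  crossed in well under 2 s at 400 Hz) and drift on constant-parameter
  data (final-third means within 10% of truth over 120 s runs).
* The state block initializes at zero with variance
  \((10\,\mathrm{mV})^2\); parameters initialize at the configured
  nominal values with standard deviation 30% of those values.

Numerical safeguards: the covariance is symmetrized every step; if a
diagonal entry turns negative, a single jitter of
\(10^{-12}\,\mathrm{tr}(P)/13\) is applied; failure of that repair, a
non-finite estimate, a non-positive innovation variance, or a NaN sample
marks the trajectory invalid from that sample onward, and invalid
trajectories are excluded from the analyses (mirroring the exclusion of
numerically unstable estimates in practice, which should remain rare —
the pipeline tracks the exclusion fraction in its ledger).

## Preprocessing

Segments run from 5 minutes before onset to 1 minute after offset
(defaults of `extract_segment()`); segments with missing coverage or
telemetry dropouts (≥ 0.25 s of exactly repeated values on any channel)
are rejected with a reason.  Filtering is a second-order zero-phase
Butterworth bandpass (1–180 Hz) with a second-order bandstop at
48–52 Hz, applied forward–backward with reflected padding.  Signal
energy is the sum of squares over 1 s windows with 50% overlap; windows
overhanging the segment end are dropped so that onset-aligned window
centers match across seizures.  The filtering step is optional for
model-generated data (`apply_bandpass = FALSE` by default in
`run_config()`): synthetic ECoG has neither mains interference nor
drift, and a 1 Hz high-pass would remove exactly the slow input
component \(u\) that the filter is meant to track.  For real recordings
the bandpass should be enabled.

## The statistical pipeline

**Duration bimodality.**  Clustering operates on natural-log durations
with k = 1, 2, 3, by both k-means and a Gaussian mixture; each method's
k is selected by the gap statistic with a uniform reference over the
observed log-duration range (B = 100 draws) and the first-local-maximum
rule.  The one-standard-error variant of that rule was evaluated and
rejected: at the separation used by the synthetic catalogs (about
3.7 standard deviations between log-means) it misses clearly bimodal
catalogs roughly a third of the time, while the plain first-maximum rule
loses no specificity on unimodal catalogs.  The long/short boundary for
k = 2 is the midpoint of the two cluster means on the log scale.
Patients with fewer than 20 seizures are excluded, matching the
inclusion rule of the cohort the pipeline emulates.

**Baseline normalization.**  Each parameter trajectory is expressed as
percent change from its pre-ictal baseline, the mean over
[−120 s, −60 s] before onset by default; division is by the absolute
baseline so the direction of change survives negative baselines, and
near-zero baselines are flagged unusable rather than normalized.

**Mean trajectories and significance.**  Onset-aligned averages include,
at each time point, only the seizures still ongoing, with n(t) reported
alongside; the 95% CI is mean ± 1.96 SE and per-time two-sided
one-sample t-tests at p < 0.05 flag increases and decreases.  These
per-time flags are a display statistic in the tradition of the figures
they emulate — deliberately uncorrected for multiplicity — not a
confirmatory test.  A min–max normalized copy (per parameter, to
[−1, 1]) is provided for cross-parameter display.

**Long/short contrast.**  Per-time Welch t-tests between the two
duration populations, plus an overall contrast of per-seizure average
change.  **Correlations.**  Pearson correlation (configurable to
Spearman or log-duration) between seizure duration and the parameter
mean over the 5 s window before onset and before offset, averaged
across channels; significance at 0.05 divided by patients × parameters
(60 for the reference 12-patient, 5-parameter cohort).

## The synthetic cohort

Real chronic ECoG of this kind is not publicly available, so every
claim the package tests is made against its own generator, which
emulates the *statistical structure* of such cohorts with known ground
truth:

* lognormal (mixture) durations — defaults: short ~30 s and long ~90 s
  populations with 0.3 log-SD, clearly but not extremely separated;
* a stereotyped ictal motif (decrease, increase, or
  decrease-then-increase, cosine-ramped) applied multiplicatively to
  the in-going pyramidal connections (\(u, \alpha_{ep}, \alpha_{ip}\))
  on the focal channels only;
* identical onset epochs for long and short seizures; with a positive
  `link`, the pre-offset overshoot of the linked parameter
  (\(\alpha_{ep}\)) grows with duration, so duration information exists
  *only* before offset — the construction under which "seizures follow
  one path and differ at termination" is the true hypothesis;
* a per-seizure multiplicative amplitude jitter (10% SD), duration
  independent, providing the seizure-to-seizure variability against
  which the null calibration of the correlation analysis is meaningful;
* model-generated ECoG with z-state process noise (0.05 per step) and
  0.3 mV observation noise, giving a few-millivolt oscillatory signal.

What the generator does *not* emulate: patient-specific waveform
morphology, spatial spread across electrode arrays, artifacts beyond
flatline dropouts, and model mismatch (the data generator and the
filter share the neural mass equations, except for the parameter
random walk, which the generator does not use).  Passing tests
therefore demonstrate correctness of the inversion and of the
statistics under the model's own assumptions — not clinical validity on
real recordings.

## Problem sizes used in validation

The validation studies run at a reduced scale chosen to keep a
multi-seed, 100-seizure study practical on a single CPU while
preserving everything structural: `reduced_study_config()` uses 35 s of
pre-onset context (baseline window [−30, −10] s), 6 s of post-offset
context, duration populations around 10 s and 25 s (same log-separation
as the full-scale defaults), one affected channel, and a 6 s offset
epoch.  Parameter-recovery runs use 120 s of 400 Hz data; the
moment-propagation oracle uses 10⁶ Monte-Carlo samples per belief with
batch standard errors; the null calibration uses 200 replicates of
30-seizure trajectory-only catalogs (the correlation statistics operate
on window means, which do not require re-running the filter under the
null).

## Known limitations

* One model per channel: no coupling between channels, hence no
  propagation dynamics; estimates are local effective connectivity.
* The synaptic time constants are fixed, not estimated.
* Euler discretization at the sampling rate trades accuracy for speed;
  at 400 Hz the discretization error is far below the noise floor, but
  the filter's process model and the generator share it.
* The gap statistic's sensitivity degrades when duration populations
  are closer than ~3 log-SD; bimodality calls near that boundary should
  not be over-read.
* Percent-change normalization is undefined for baselines near zero;
  such trajectories are flagged rather than silently dropped or kept.
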