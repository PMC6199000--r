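# seizurepath

Focal seizures in chronic intracranial EEG follow strikingly stereotyped,
patient-specific paths, and many patients carry two distinct seizure
populations — short and long — that separate on the logarithm of seizure
duration. `seizurepath` asks *where in a mechanistic model those paths
live*: it inverts a Jansen–Rit neural mass model against every sample of
seizure ECoG, producing time-resolved estimates of effective connectivity,
and then runs the statistical pipeline that turns those estimates into
claims about seizure onset and offset mechanisms.

It is written for computational neuroscientists and epilepsy researchers
who want a self-contained, testable implementation of model-based seizure
tracking — with a synthetic-data generator providing ground truth, since
chronic human seizure ECoG of this kind is not publicly available.

## The model and the estimator

Three neural populations (pyramidal *p*, excitatory *e*, inhibitory *i*)
interact through four critically damped second-order synapses (pre→post:
e→p, i→p, p→e, p→i; τ = 10 ms except 20 ms for i→p):

    dv/dt = z
    dz/dt = (α/τ) φ(v_pre) − (2/τ) z − v/τ²

with the erf firing-rate sigmoid φ(v) = (1 + erf((v − v₀)/ς))/2
(v₀ = 6 mV, ς = 3 mV). The recorded ECoG is the pyramidal potential
v_p = v_ep − v_ip + u. Five quantities are estimated per channel: the
external input u and the four lumped gains α_ep, α_ip, α_pe, α_pi.

Estimation is an **assumed-density (Kalman) filter** on the augmented
state ξ = [x; θ]: parameters follow a random walk, and each
prediction step propagates a 13-dimensional Gaussian belief through the
nonlinear model using semi-analytic moments — E[φ], E[φ′] and all
cross-covariances Cov(ξ, θφ(v)) in closed form (Stein's identity), and
the remaining nonlinear–nonlinear covariance block reduced to
one-dimensional Gauss–Hermite quadratures. The update is a standard
linear Kalman step in Joseph form. With the nonlinearity disabled, the
filter is verified equal to a textbook Kalman filter to 1e-10.

The statistics layer implements log-duration bimodality detection
(k-means + Gaussian mixture under the gap criterion), pre-ictal
baseline-normalized trajectories with per-time significance, long/short
contrasts, and duration–connectivity correlations in 5 s windows before
onset and offset with cohort-level Bonferroni correction (0.05/60 for the
reference 12-patient × 5-parameter design).

## Worked example

The numbered drivers under `analysis/` run the full study — synthesize a
100-seizure bimodal cohort with an offset-linked excitation effect,
invert every seizure, analyze — and write tidy CSVs under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_energy.R
Rscript analysis/03_estimate.R
Rscript analysis/04_analyze.R
```

Output of the final stages (seed 1):

```
Running the filter on 100 seizures ...
Done in 82 s; excluded 0.0% of trajectories
Median reconstruction MSE: 4.07e-08 V^2 (0.202 mV RMS)
Example reconstruction envelope correlation: r = 0.748

Duration clustering: k-means k = 2, GMM k = 2 (agree); long/short boundary 15.3 s
Pre-offset correlations:
  parameter      r        p significant
1         u 0.3587 2.48e-04        TRUE
2  alpha_ep 0.9719 2.07e-63        TRUE
3  alpha_ip 0.0302 7.66e-01       FALSE
...
alpha_ep motif: 70 time points flagged decrease, 19 increase (medians 9.1 s / 27.2 s)
```

Reading those numbers: no filter run went unstable; the forward
re-simulation from the estimated parameters reproduces the recorded
seizure's amplitude envelope; both clustering methods find the two
duration populations and place the long/short boundary at 15.3 s; seizure
duration correlates with the excitatory gain α_ep in the 5 s before
*offset* (r = 0.97, Bonferroni-significant — the generator's designed
link) but with nothing before *onset*; and the mean α_ep trajectory shows
the decrease-then-increase ictal motif (early significant decreases,
late significant increases).

The same machinery is available programmatically:

```r
library(seizurepath)
res <- run_study(reduced_study_config(seed = 1, link = 3))
res$analysis$corr_offset
```

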