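---
title: "Fitting phenomenological cardiac action potential models by particle swarm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting phenomenological cardiac action potential models by particle swarm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apswarm)
```

## The problem

Low-dimensional ("phenomenological") cardiac action potential models describe
the transmembrane voltage of a cardiac cell with two to four ordinary
differential equations.  They reproduce the features that matter for many
dynamical questions — action potential (AP) shape, AP duration (APD),
restitution and alternans — at a small fraction of the cost of biophysically
detailed ionic models.  The price is that their parameters are not directly
measurable: to use such a model for a specific cell, species or patient
recording, a parameter set must be found whose simulated voltage matches the
recorded one.

`apswarm` solves this estimation problem with particle swarm optimization
(PSO).  Every state of the pipeline is exposed as an R function: pacing
simulation of the models, dataset normalization and alignment, the composite
voltage/APD fitness, the constriction-coefficient swarm, a synthetic-data
generator for validation studies, and repeated-fit identifiability analysis.

## The models

All models evolve a dimensionless voltage `u` as

du/dt = I_tot(u, gates; p) + I_stim(t),

where `I_tot` is the total membrane current and `I_stim` an external pacing
stimulus (default: a square pulse of 0.2 ms^-1 for 2 ms).  The registry
provides:

| name  | variables | parameters | description |
|-------|-----------|-----------|--------------------------------------------|
| MS    | u, h      | 5         | Mitchell–Schaeffer: cubic inward current gated by h, linear outward current |
| MMS   | u, h      | 5         | modified MS: inward current vanishes below `v_gate`, outward current gated by (1−h), which removes pacemaker-like drift |
| MFHN  | u, v     | 5         | modified FitzHugh–Nagumo: cubic excitation with a linear recovery variable |
| FK    | u, v, w  | 13        | Fenton–Karma: fast inward, slow outward and slow inward currents with two gates |
| BOCF  | u, v, w, s | 27      | minimal four-variable model; reproduces a wide range of AP morphologies |
| BBOCF | u, v, w, s | 33      | BOCF with voltage-dependent `tau_w+` and s-dependent `tau_si` splits, for the saddleback ("Brugada") AP morphology |

Regime conventions (Heaviside switches) are documented in `?model_rhs`: a
regime gated at a threshold applies from the threshold upwards.  In FK, the
v-gate recovery time constant is `tau_v1_minus` (slow, 1250 ms) at or above
`u_v` and `tau_v2_minus` (fast, 19.6 ms) below, following the convention that
near-threshold voltages recover slowly.  The original minimal-model
formulation carries a resting-offset constant `u_o`; it is fixed at 0 here
and not part of the fittable roster, which therefore counts 27 parameters.
The BBOCF variant replaces `tau_w_plus` by a sigmoidal blend
(`tau_w1_plus`/`tau_w2_plus`, steepness `k_w_plus` around `u_w_plus`) and
`tau_si` by a blend in the gate `s` (`tau_si1`/`tau_si2`, steepness `k_si`
around `s_c`); with the split pairs equal it reduces exactly to BOCF.

Default parameter values follow the models' original publications, with one
deliberate exception.  The MS defaults here are `tau_in = 0.3`,
`tau_out = 6`, `tau_open = 100`, `tau_close = 120`, `v_gate = 0.13`.  With
the published 130/150 recovery constants the MS model approaches its fixed
pacing rhythm at a 300 ms cycle length only through a very slowly damped
alternating transient (tens of beats), which makes "pace to steady state at
500/400/300 ms" — the protocol of the self-fit studies below — an
ill-conditioned generator setting.  The chosen defaults reach steady state
within roughly ten beats at all three cycle lengths while keeping a
physiological APD range (203/193/169 ms).

Default fitting bounds (see `list_parameters()`) bracket each default by
roughly a factor of two to five for time constants and cover the plausible
dimensionless range for thresholds and gains.  They are deliberately generous:
tight bounds would mask the identifiability behaviour the repeated-fit
analysis is designed to reveal.

Default normalization constants are 1 for the unit-amplitude models (MS,
MMS, MFHN, FK) and 1.35 for BOCF/BBOCF, whose upstroke overshoots 1 (the
peak of the default epicardial parameter set is about 1.45).

```{r}
ap_model("FK")
head(list_parameters("MS"))
```

## Simulation

Models are integrated with the forward Euler method at a fixed `dt` of
0.02 ms.  A `pacing_protocol()` applies `n_prerecording` wash-out beats
followed by `n_stimuli` recorded beats; the voltage is sampled every
`sample_interval` (default 1 ms, the resolution of typical experimental
recordings) starting at the onset of the first recorded stimulus.

```{r, fig.width = 6, fig.height = 3}
tr <- integrate_model("MS", protocol = pacing_protocol(500, n_stimuli = 2, n_prerecording = 4))
plot(tr, main = "MS model, CL 500 ms")
```

The fitness evaluation of a swarm requires thousands of such simulations per
iteration; `integrate_batch()` evaluates a whole matrix of candidate
parameter sets in compiled code (identical results, bitwise, to looping over
`integrate_model()`).  The compiled kernel keeps the state of 16 particles in
registers across the time loop and is compiled for several SIMD widths with
runtime dispatch.  The hyperbolic tangent inside the FK/BOCF currents is
evaluated by an exp-based routine (Cody–Waite range reduction with a
degree-7 polynomial kernel, relative error about 1e-8, far below the Euler
truncation error) so that the hot loop vectorizes.

Numerical edge cases: explicit Euler can diverge for extreme parameter
proposals.  A trace that becomes non-finite is flagged (`attr(tr, "ok")`)
rather than raising, and the fitness assigns it a finite worst-case sentinel
value that exceeds any achievable error, so ordering among valid particles is
preserved and the swarm remains well defined.

Against a fourth-order Runge–Kutta reference at a 1000-fold smaller step the
dt = 0.02 ms Euler solution of the MS and FK models agrees to a few times
1e-3 in maximum absolute voltage (first-order convergence; the acceptance
tests measure the error and the order directly).

Two stimulus shapes are available.  The default square pulse matches the
documented 0.2 ms^-1 x 2 ms convention.  The biphasic option — a
hyperpolarizing phase of half the magnitude over the first half of the
duration followed by the full depolarizing magnitude — is a simple surrogate
for the upstroke current experienced through diffusive coupling in tissue
and is flagged experimental: its precise waveform is a package choice.

## Fitness

A dataset is either a voltage trace (newline-delimited file, one value per
line, fixed sample interval) with its pacing cycle length, or a
comma-separated list of APDs with the normalized-voltage threshold at which
they were measured (APD90 on unit-normalized data means a threshold of 0.1,
`apd_threshold(90)`).

The error of a candidate against a voltage dataset is computed after
normalizing the data (minimum 0, maximum `normalize_to`; 0 bypasses) and
aligning the first upstrokes: the model trace is shifted by the integer
number of samples that makes its first upward crossing of half the data
maximum coincide with the data's.  The sum of squared differences over the
overlapping samples is divided by the number of data samples, so longer
recordings do not automatically carry larger errors, and truncated overlap is
implicitly penalized.  APD errors are raw sums of squares over the listed
APDs (with a missing action potential charged one squared cycle length).
The total fitness multiplies each dataset's error by its fitting weight and
sums.

Dialect choices the package fixes (the conventions are not forced by the
problem): the alignment threshold is half the data maximum; APD crossings are
linearly interpolated between samples; the APD sum is not divided by the
number of APDs.

One practical consequence of the normalization convention deserves emphasis:
when fitting a model to data generated *by the same model*, normalization
must be bypassed (`normalize_to = 0`).  Model-generated voltages are already
on the model's own scale, and stretching their maximum to 1 (the MS model's
free-running peak is about 0.92) introduces a systematic amplitude mismatch
that visibly biases the recovered parameters.

## The particle swarm

Each particle is a candidate parameter vector over the *fitted* subset of the
roster (non-fitted parameters are held at user-supplied values).  Positions
are initialized uniformly within the per-parameter bounds, velocities at
zero.  Each iteration updates

v <- chi * (v + U(0, phi1) * (pbest - p) + U(0, phi2) * (gbest - p));
p <- p + gamma * v,

with elementwise uniform draws, the Clerc constriction coefficient
chi = 2/(phi - 2 + sqrt(phi^2 - 4 phi)), phi = phi1 + phi2 (about 0.73 at
the default phi1 = phi2 = 2.05) and learning rate gamma = 0.05.  A
coordinate leaving its range is redrawn uniformly from the three-quarters of
the range adjacent to the violated bound; the velocity component is left
untouched (a package choice — zeroing it is a plausible alternative with no
observed advantage).  Ties in best-error comparisons keep the incumbent, so
runs are exactly reproducible under a fixed seed.  Termination is after a
fixed number of iterations; the per-iteration global best error is recorded
and is non-increasing by construction.

```{r}
syn <- generate_dataset("MS", cycle_lengths = c(500, 400, 300), n_stimuli = 2)
problem <- fit_problem("MS", syn$entries,
  n_stimuli = 2, n_prerecording = 4, normalize_to = 0
)
fit <- run_fit(problem, pso_hyperparameters(256, 40, seed = 1))
fit
fit_rms(fit)
```

## Synthetic data and what passing tests show

`generate_dataset()` paces a model with known parameters until the APD
(measured at half the trace maximum) changes by less than `steady_tol`
(default 0.5 ms) between consecutive beats, then records the requested
number of beats at 1 ms resolution in the same newline-delimited dialect the
fitting tools consume, alongside a JSON truth record.  At cycle lengths
producing alternans, a stable period-2 pattern (beat k vs beat k−2) is
accepted as steady state, and recording starts on a consistent phase.  A cap
of 200 pre-pacing beats guards against non-convergent settings; a model that
never produces an AP (peak below 0.45, i.e. indistinguishable from the
stimulus artifact) raises an error naming the cycle length.

The generator emulates the *clean* limit of experimental recordings:
noise-free (optional additive Gaussian noise is available), perfectly
periodic pacing, no baseline drift, no optical-mapping upstroke blunting,
and exactly the integrator used by the fitting side.  Tests that pass on
such data therefore demonstrate correctness of the estimation machinery and
structural identifiability under ideal conditions — not robustness to the
artifacts of real recordings.

## Identifiability analysis

`repeated_fits()` runs the same fitting problem under consecutive seeds and
collects the best parameter vectors.  Parameters are reported both raw and
normalized over their bounds, so spreads are comparable across parameters.
The spread across runs is the operational measure of identifiability: a
parameter the data constrain tightly lands near the same value in every run.

Two ensembles can be compared with `sd_reduction_count()` (how many
parameters have smaller standard deviation in the second ensemble — e.g.
when adding cycle lengths) and `pairwise_parameter_tests()`, a per-parameter
two-sample test with a three-way verdict: `different` below p = 0.001,
`borderline` between 0.001 and 0.01, `not_different` otherwise.  The strict
level compensates for the many parameters and comparisons; no further
multiplicity correction is applied.  Welch's unequal-variance form is the
default (`var_equal = TRUE` gives the pooled test); which variant underlies
published "standard t-test" analyses is typically not stated, and the choice
rarely moves verdicts at these sample sizes.

On the MS self-fit with three cycle lengths (500/400/300 ms, 1024 particles,
100 iterations, 4 pre-recording beats, 20 runs — the protocol the acceptance
tests execute), `tau_close` and `tau_out` are recovered with medians within
10% of the generating values, while `tau_open` and `v_gate` spread widely:
with pacing far from the minimum diastolic interval the data carry little
information about the recovery time constant and the excitation threshold.
Adding cycle lengths tightens `tau_in` relative to a single-CL fit.  For
APD-only fitting, the wash-out must be long enough that the simulated beats
have reached the steady state the APD targets describe; the package's
APD-only examples use 8 pre-recording beats for this reason.

## Problem sizes used in the test suite

The shipped tests scale the reference experiments to desk size as the
package's own validation protocol: the MS self-fit ensembles use 1024
particles x 100 iterations x 20 runs (three-CL and one-CL); the FK
particle-count comparison uses 64 vs 4096 particles, 16 iterations, five
seeds each at one cycle length; the APD-only demonstration uses 1024 x 32;
the type-I calibration of the test harness uses 10,000 null simulations at
n = 20 per group.  The integrator oracle compares two beats at CL 300
against RK4 with 2 microsecond internal steps.

## Known limitations

* Fixed-step explicit Euler only; no adaptive or semi-implicit integration.
  This keeps batch evaluation cheap and deterministic, but extreme parameter
  proposals are handled by invalidation, not by solving stiffly.
* Each cycle length restarts from the resting state; chaining the final
  state of one CL into the next (useful to reach very short CLs without
  block) is possible via the `init` argument but is not the default
  protocol.
* Alternans fits can lock onto the wrong phase (long APs matched to short);
  the standard workaround is adjusting the pre-recording count by one.
* The error metric is the (weighted) squared error only; upstroke-excluding
  windows or coefficient-of-determination metrics are not provided.
* The biphasic stimulus is a documented surrogate waveform.
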