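---
title: "Continuous- and discrete-time models of affect dynamics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous- and discrete-time models of affect dynamics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question

Experience-sampling (ESM) studies prompt people on their smartphone a
handful of times per day, at semi-random times, to rate their momentary
positive and negative affect (PA/NA) on 0–100 sliders. The resulting
per-person time series are short (around 70 beeps over a week), bivariate,
and *unequally spaced* — a typical protocol beeps 10 times a day between
10:00 and 22:00, about every 72 minutes on average, with nothing overnight.

Two standard models of such intra-individual dynamics differ only in how
they treat time. The discrete-time lag-1 vector autoregression treats
consecutive beeps as equally spaced:

$$\mathbf{x}_i = \mathbf{c} + A\,\mathbf{x}_{i-1} + \boldsymbol\epsilon_i,
\qquad \boldsymbol\epsilon_i \sim \mathcal N(0, \Sigma_\epsilon),$$

while the continuous-time Ornstein–Uhlenbeck diffusion lets a latent state
evolve between beeps:

$$\mathrm d\mathbf{y}(t) = \theta\,(\boldsymbol\mu - \mathbf{y}(t))\,
\mathrm dt + \sigma\,\mathrm d\mathbf{W}(t).$$

Observed at a fixed spacing $\Delta t$, the OU process *is* a VAR(1) with
$A = e^{-\theta\Delta t}$, $\mathbf c = (I - A)\boldsymbol\mu$ and
$\Sigma_\epsilon = \Sigma_y - A\Sigma_y A^\top$, where $\Sigma_y$ solves
the continuous Lyapunov equation
$\theta\Sigma_y + \Sigma_y\theta^\top = \sigma\sigma^\top$. On unequal
spacings the two part ways: the OU prediction for the next beep uses the
actual elapsed time in its conditional mean
$(I - e^{-\theta\Delta t_i})\mu + e^{-\theta\Delta t_i}\,y_{i-1}$ and
conditional covariance
$\Sigma_y - e^{-\theta\Delta t_i}\Sigma_y e^{-\theta^\top\Delta t_i}$,
while the VAR makes the same prediction regardless of the gap. A
stationary Gaussian $\mathcal N(\boldsymbol\mu, \Sigma)$ completes the
family as the no-dynamics baseline.

This package fits all three families (plus measurement-error variants) to
ESM series, compares their one-step out-of-sample predictive accuracy by
walk-forward cross-validation, and studies how the comparison shifts when
large abrupt changes are removed from the training data — with a synthetic
ESM study generator standing in for restricted-access real data.

# Likelihood conventions

The min-log-likelihood of a series is the sum of per-beep negative log
Gaussian densities, organized by a *transition plan*:

* **Nights.** The gap between the last beep of a day and the first of the
  next is about 12 hours — several relaxation times for realistic
  $\theta$ — so the first beep of each day is scored under the model's
  stationary distribution (both dynamical models are assumed to relax
  completely overnight; a VAR night treated as one unit step would never
  reach stationarity and would bias the comparison).
* **Missed beeps.** A beep with any missing dimension is treated as fully
  missing (the likelihoods are joint over the $d$ dimensions). The
  transition bridges it: the OU uses the actual, longer interval; the VAR
  uses a pseudo-step count of $1+$ the number of skipped beeps, i.e.
  $A^k$ compounding. Because $A^k = e^{-\theta k}$ when the VAR is
  parameterized through the OU machinery at unit spacing, one code path
  serves both.
* **Removed transitions** (see the deviation filter below) drop out of the
  likelihood sum, but the removed transition's end point still conditions
  the following transition — the chain is never re-linked.

Measurement-error variants add independent Gaussian noise with a diagonal
covariance (one variance per dimension) on top of the latent state and are
scored by the Kalman-filter marginal likelihood. The filter restarts from
the stationary prior at each day boundary, mirroring the error-free
convention; covariance updates use the Joseph form, which stays positive
semi-definite under round-off. Filter initialization is not dictated by the
model, so the stationary prior is a package choice, covered by a dense
joint-Gaussian oracle test. The stationary family gets no measurement-error
variant: i.i.d. observation noise is not separately identifiable from the
stationary covariance.

# Estimation

Parameters are estimated by minimizing the (marginal) min-log-likelihood
with differential evolution, DE/rand/1/bin: population `np = 50`,
crossover `cr = 0.6`, 3000 generations, and the mutation weight $F$
redrawn from $U(0, 2)$ for every mutation. Stability (eigenvalues of
$\theta$ with positive real part; spectral radius of $A$ below one) is
enforced by giving unstable candidates an infinite objective. Two details
the scheme leaves open were fixed as follows:

* **Immediate replacement.** A winning trial vector enters the population
  at once rather than at the end of the generation (the same choice as
  `scipy.optimize.differential_evolution`'s default); it converges
  noticeably faster at equal budget.
* **Warm start.** One agent of the initial population is seeded with a
  moment estimate: pooled OLS of beep on previous beep over single-step
  transitions, mapped to a drift matrix by the principal matrix logarithm
  at the mean spacing, with $\sigma$ recovered from the Lyapunov relation.
  On clean and contaminated test beds the full random-start budget reaches
  the same optima; the warm start only accelerates.

Search bounds: $\boldsymbol\mu$ within the observed range widened by 50%,
$\theta$ entries in $[-10, 10]$ per hour (relaxation times down to six
minutes, far faster than anything an ESM design can resolve), lower-
triangular $\sigma$ bounded by three times the per-dimension sample SD
with non-negative diagonal (fixing the reflection invariance of
$\sigma\sigma^\top$), and error variances within the per-dimension sample
variance. The VAR family is fitted on the same machinery with unit
pseudo-steps and mapped back through the equal-spacing equivalence, so the
fitted $A$ lies in the matrix-exponential family. The stationary family's
MLE (sample mean, $1/n$ covariance of the retained beeps) is available in
closed form and is returned directly — running a stochastic optimizer to
approximate a quantity known exactly would only add noise to the model
comparison. The closed-form VAR(1) OLS estimate is kept as an independent
cross-check on the optimizer; no stability constraint is imposed on it.

# Walk-forward cross-validation

For folds $n = 1,\dots,10$, the model is refitted to the first $N - n$
beeps (beeps, not transitions; missed beeps count toward $N$) and the
$(N-n+1)$-th beep is scored under the fitted one-step predictive density:
the conditional given the last training observation at its actual elapsed
time (OU) or pseudo-steps (VAR), the stationary density when the test beep
opens a new day, and the Kalman predictive when measurement error is on.
The ten scores are averaged into one predictive min-log-likelihood per
(series, family, cutoff); a missing test beep drops its fold. Per-fold
refitting uses a fold-specific optimizer seed, so results are exactly
reproducible, and perturbing a held-out beep can change no other fold that
does not legitimately contain it in training — a property under test.

# Removal of large deviations

For each within-day transition the change speed is

$$v = \frac{1}{\Delta t}\sqrt{\sum_{j=1}^{d}
\left(\frac{x_{j,\text{next}} - x_{j,\text{prev}}}{s_j}\right)^2},$$

the Euclidean displacement of SD-normalized ratings per hour. A transition
is removed from the *training* likelihood when its speed exceeds
$\mathrm{median} + C\cdot\mathrm{MAD}$ (unscaled MAD, strict inequality;
$C = \infty$ removes nothing, and a zero MAD removes nothing either). The
normalization SDs, the median and the MAD are computed on the training
portion of each fold only, so the filter can never see the test beep.
Speeds are computed in one pass, not recomputed after removals.

# The synthetic study generator

`study_config()` encodes the study conditions: `n_series` people, 7 days
of 10 beeps in the 10:00–22:00 window, beep times from a stratified random
interval scheme (the window split into ten equal 72-minute strata, one
beep uniform in each — mean gap 72 minutes with bounded extremes), latent
bivariate OU dynamics with defaults

* $\theta = \begin{pmatrix}1.0 & 0.3\\ -0.2 & 0.8\end{pmatrix}$ per hour —
  relaxation time near one hour, with PA/NA cross-coupling;
* $\boldsymbol\mu = (60, 20)$ rating units, the usual asymmetry of PA and
  NA levels;
* $\sigma = \mathrm{diag}(8, 6)$ rating units per $\sqrt{\text{hour}}$,
  giving stationary SDs near 5 rating units;

plus optional diagonal measurement error, a 13% per-beep missingness rate
(the compliance level typical of ESM protocols), and optional external
events: each series receives a Poisson(`event_rate`) number of jumps at
uniformly chosen beeps, each an independent Gaussian perturbation of the
latent state with per-dimension SD `event_scale` (default four times the
diffusion scale) that subsequently relaxes under the same dynamics.
Mornings are drawn independently from the stationary distribution, which
is indistinguishable from simulating the night when overnight relaxation
is effectively complete — and matches the scoring convention. Clipping to
the 0–100 scale is off by default because it breaks the Gaussianity that
parameter-recovery checks rely on; switch it on for realism displays.

What the generator does *not* emulate: circadian trends, time-varying or
person-varying parameters, non-Gaussian diffusion, retrospective response
styles, or any dependence of missingness on the state. Tests passing on
this generator therefore certify the machinery — likelihoods, filters,
optimizers, cross-validation bookkeeping — not the adequacy of the OU
model for real affect data.

# Numerical choices

* $e^{-\theta\Delta t}$ uses exact closed forms in $d \le 2$ (the
  traceless-split formula, valid for oscillatory drift with complex
  eigenvalues) and a Padé routine otherwise. The closed form matters: for
  strongly rotational drift matrices a naive Padé implementation can
  silently return garbage, which the package's cross-checks would catch.
* Lyapunov equations are solved as small dense linear systems (Cramer's
  rule at $d = 2$, Kronecker vectorization otherwise), with an explicit
  positive-definiteness check.
* Every computed covariance is symmetrized as $(S + S^\top)/2$, and a
  relative jitter of $10^{-10}\cdot\overline{\mathrm{diag}}$ is added
  before inversion so that $\Delta t \to 0$ conditionals remain usable.
* Exact ties in win fractions ($|\Delta| < 10^{-12}$) are excluded from
  numerator and denominator; an all-tie comparison is reported as `NaN`
  with a warning.
* The hot paths (likelihood chains, Kalman recursion, the DE loop) are
  compiled (RcppArmadillo) with a scalar specialization for the bivariate
  error-free chain; R-level single-step functions are the reference
  implementations and the test suite asserts agreement to $10^{-8}$.

# Problem sizes and what the checks show

The test suite exercises the pipeline at desk scale, chosen so the whole
suite runs in minutes on one core: oracle checks on series of length 3–5
against dense joint-Gaussian likelihoods; 50-series pooled parameter
recovery under the default protocol (the full 3000-generation budget is
used there — at a few hundred generations the optimizer has not yet
converged on pooled problems); and walk-forward comparisons on 100-series
studies at a reduced budget (`np = 30`, 300 generations, warm-started),
which on single-series fits reaches the same optima as the full budget.

Two robust findings on synthetic data: on event-free OU worlds with the
ESM spacing, the OU model out-predicts the VAR(1) in a clear majority of
series, and out-ranks it even more clearly on in-sample AIC; and the
median$+C\cdot$MAD filter at strict cutoffs removes only a few percent of
transitions, dominated by the injected jump transitions.

One expectation did **not** materialize: on event-contaminated synthetic
studies, removing large deviations does not systematically improve the OU
model *relative to* the VAR(1) or the stationary baseline. The mechanism
is instructive. Jumps injected at uniformly chosen beeps arrive after
intervals distributed like all other intervals (mean 1.2 h, comparable to
the relaxation time), so the implausible displacement is penalized almost
identically by the continuous-time and the discrete-time likelihood, both
models are dragged down symmetrically, and the filter rescues both
symmetrically. A differential benefit for the continuous-time model
requires large deviations concentrated on intervals *short* relative to
the relaxation time — only there must the OU model distort its dynamics
disproportionately to accommodate them. Real ESM data plausibly contain
exactly that pattern; this generator's beep-time event model does not
produce it. The corresponding comparison stays in the test suite as a
documented expectation with this analysis rather than being weakened.

# Known limitations

* Beeps with any missing dimension are discarded entirely; conditioning on
  partially observed beeps would need per-dimension observation models.
* No smoothing output from the Kalman filter (only filtering/prediction,
  which is all the likelihood and CV need).
* Each series is fitted separately; no hierarchical pooling across people.
* The VAR family inherits the matrix-exponential parameterization of its
  transition matrix, excluding transition matrices with negative real
  eigenvalues (which equal-spacing ESM data essentially never favor).
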