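---
title: "Inferring the temporal and population scales of a linear perceptual readout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the temporal and population scales of a linear perceptual readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readoutscales)
```

## The model

`readoutscales` implements the "standard" linear model of percept formation
in a fine 2AFC discrimination task, and the statistical machinery needed to
*invert* it from joint recordings of spike trains and binary choices.

On each trial a population of $N_{tot}$ neurons emits spike trains
$r_i(t)$ while a stimulus of value $s$ (one of a small set around the task
threshold $s_0$) is presented. The subject's internal percept is assumed to
be built in two linear stages:

1. **Temporal integration.** Each spike train is passed through a causal
   kernel $k(t)$ of duration $w$ ending at the *extraction time* $t_R$,
   giving the integrated activity $\bar r_i = \int r_i(t)\,k(t)\,dt$. The
   default kernel is a square window of height $1/w$ on
   $[\max(0, t_R - w),\, t_R]$; when $t_R < w$ the window is truncated at
   stimulus onset and deliberately *not* renormalized. An exponential
   kernel (backward decay with time constant $w$) is available as an
   option.
2. **Population readout.** A weight vector $a$ supported on a readout
   ensemble $\mathcal E$ of $K$ neurons produces the percept
   $\hat s = a_0 + \sum_i a_i \bar r_i$.

The binary choice adds Gaussian *decision noise*
$\xi_d \sim N(\mu_d, \sigma_d^2)$ — all extra-sensory variability — and
thresholds: $c = H(\hat s + \xi_d - s_0)$.

The four quantities of scientific interest are the scales of this readout:
the integration window $w$, the extraction time $t_R$, the ensemble size
$K$, and the decision noise $\sigma_d$. Their central difficulty is the
**K–w trade-off**: psychometric sensitivity alone cannot distinguish "many
neurons, short window" from "few neurons, long window", because both move
the just-noticeable difference (JND) the same way.

## Measured and predicted indicators

The data side of the inversion consists of classical estimates, all
computed per stimulus and time bin (default $\Delta = 10$ ms):

* the PSTH $m_i(t;s)$ and its regression slope on $s$, the tuning
  $b_i(t)$ (`estimate_psth()`, `estimate_tuning()`);
* the JPSTH $C_{ij}(t,u)$, the across-trial covariance of binned rates of
  simultaneously recorded pairs, assumed stimulus-independent
  (`estimate_jpsth()`; a diagnostic reports the across-stimulus
  deviation);
* the choice-covariance (CC) curve $d_i(t;s) = \psi(s)(1-\psi(s))
  [E(r_i|s,c{=}1) - E(r_i|s,c{=}0)]$, averaged over stimuli with
  trial-count weights (`estimate_cc()`) — a linear analogue of choice
  probability;
* the psychometric curve fitted as $\psi(s) = \Phi((s+\mu_d-s_0)/Z)$ by
  trial-weighted least squares (`fit_psychometric()`; maximum likelihood
  is available as an option, and the fit pins $Z$ at a small positive
  floor under perfect separation).

Kernel-integrated versions $\bar b$, $\bar C(t)$, $\bar{\bar C}$, $\bar d$
for a candidate $(w, t_R)$ are obtained either by quadrature of the binned
statistics (`integrate_statistics()`) or directly from the integrated
counts (`integrated_statistics()`); the two routes agree exactly for a
square kernel aligned with the bin grid, and the package tests this
equivalence.

The model side rests on the characteristic equations
$\partial_s E[\hat s|s] = \bar b^\top a$,
$\mathrm{Var}[\hat s|s] = a^\top \bar{\bar C} a$, and
$\mathrm{Cov}[r(t), \hat s|s] = \bar C(t) a$, which combine with the
decision model into $1 = \bar b^\top a$,
$Z^2 = a^\top \bar{\bar C} a + \sigma_d^2$, and
$d(t) = \kappa(Z)\,\bar C(t)\,a$. The factor
$\kappa(Z) = E_s[\mathcal G(s;\, s_0-\mu_d,\, Z)]$ (`kappa()`) converts
percept covariance into choice covariance; because stimuli span a range
comparable to $Z$ it depends only weakly on $Z$, and all predictions
evaluate it at the *measured* JND.

Under **restricted optimality** — the readout extracts all information
from $\mathcal E$ and none from elsewhere — $a$ is the (ridge-regularized)
Fisher linear discriminant of the restricted statistics
(`optimal_readout()`), the predicted JND is
$Z^2 = [\bar b_r^\top (\bar{\bar C}_r + \lambda I)^{-1} \bar b_r]^{-1} +
\sigma_d^2$ (`predict_jnd()`), and the CC curve of *every* co-recorded
neuron is predicted by `predict_cc()`. Inside the ensemble the integrated
prediction collapses to $\bar d_i = \kappa(Z)(Z^2 - \sigma_d^2)\bar b_i$ —
choice signals proportional to tuning, the marker of optimality.

Because neuron identities are unknowable in undersampled recordings, the
comparison runs through two population indicators:
$q(u,t) = \langle b_i(u) d_i(t)\rangle_i$, whose support in $t$ is
essentially the integration window, and
$V = \langle\bar b^2\rangle\langle\bar d^2\rangle - \bar{\bar q}^2$, the
deviation from tuning–CC proportionality, which decreases toward zero as
$K$ approaches the whole population. $V$ mostly pins down $K$; the JND
then disentangles $\sigma_d$.

## The grid search

`fit_readout_scales()` evaluates the statistical loss

$$L(w, t_R, K, \sigma_d) = (Z^{*2} - \langle Z^2\rangle_\mathcal{E})^2
  + \lambda \iint dt\,du\,(q^* - \langle q\rangle_\mathcal{E})^2
  + \mu (V^* - \langle V\rangle_\mathcal{E})^2$$

on a full 4-d grid (defaults: $K$ = 10:10:150, $w$ = 10:10:100 ms, $t_R$ =
10:10:200 ms, $\sigma_d$ = 0:0.25:3). The weights equalize the power of
the measured indicators: $\lambda = Z^{*4}/\iint q^{*2}$ and $\mu =
Z^{*4}/\overline{V^{*2}}$, the mean squared $V^*$ over the kernel grid
(the analogue of the integrated $q^*$ power; a per-kernel $1/V^{*2}$
would infinitely amplify cells where the noisy $V^*$ happens to cross
zero). $V^*$ itself is computed per $(w, t_R)$, since it depends on the
kernel. Predictions $\langle\cdot\rangle_\mathcal{E}$ average over random
candidate ensembles drawn within each recording pool (default 2000 per
$K$; the desk-scale validation below uses 200), with out-of-ensemble CC
signals estimated on a disjoint complementary set of $I$ neurons from the
same pool and the two parts mixed with weight $p = K/N_{tot}$. Ties in the
loss are broken toward parsimony: smallest $K$, then $w$, $t_R$,
$\sigma_d$.

### Finite-data corrections

Several corrections keep the comparison between measured and predicted
indicators unbiased; all are on by default.

* **Ridge regularization of the discriminant.** The restricted covariance
  is estimated from finitely many trials, and its spurious small
  eigenvalues make the raw discriminant overestimate sensitivity.
  `choose_regularization()` picks $\lambda$ by empirical Bayes — Gaussian
  evidence maximization for the ridge regression of the stimulus on the
  integrated counts, scanned over a log-spaced grid. Inside the grid
  search $\lambda$ is chosen once per (pool, kernel, $K$) cell on a
  representative ensemble and reused across that cell's ensembles; the
  selected values change little between same-size ensembles of one pool,
  and this keeps the cost of the scan linear in the number of ensembles.
* **Noise correction of $V$.** Squared quantities turn measurement noise
  into positive bias, and $V$ is hit from two directions: the finite
  number of trials and the finite number of neurons entering each
  average. Inside the fit, both the measured $V^*$ and every predicted
  $V$ receive closed-form corrections (the default, `debias =
  "analytic"`): the per-neuron sampling variances
  $\mathrm{Var}(\hat b_i) \approx \bar{\bar C}_{ii}/(n\sigma_s^2)$ and
  $\mathrm{Var}(\hat d_i) \approx (\bar{\bar C}_{ii}\,\sigma_{c,eff}^2 +
  \bar d_i^2)/n$ are subtracted from the second moments, and the
  finite-neuron sampling variance of the set averages is subtracted from
  $\bar{\bar q}^2$ (with the matching covariance term for the
  $\langle\bar b^2\rangle\langle\bar d^2\rangle$ product). The latter
  matters most for the predictions, whose out-of-ensemble part is
  averaged over only $I$ neurons; without it the predicted $V$ is biased
  by an amount comparable to its signal. A bootstrap-based correction of
  the measured $V^*$ (`debias_V()`, trial resampling) is also available;
  the analytic route is the default because the bootstrap's own sampling
  noise re-enters the $V^*(w, t_R)$ field and blurs the kernel
  comparison. A corrected $V$ can be negative at the noise floor and is
  reported as-is.
* **Exact in-ensemble CC predictions.** For neurons inside a candidate
  ensemble the model's integrated CC prediction is exactly
  $\kappa(Z)(Z^2-\sigma_d^2)\bar b_i$; the fit uses this closed form for
  the $V$ ingredients rather than the ridge-regularized covariance
  route, because the ridge shrinks the in/out CC contrast and would
  systematically deflate the predicted $V$ (and through it bias $K$ and,
  via the K-w trade-off, $w$). The time-resolved $q(u,t)$ predictions
  keep the covariance route, which is the only one defined off the
  ensemble.
* **Smoothing of $q$.** Both $q^*$ and every prediction are smoothed with
  a separable 10 ms Gaussian with reflecting boundaries (`smooth_q()`)
  before entering the loss.

When every neuron is recorded simultaneously the statistical detour is
unnecessary and `loss_case1()` scores candidate readout weights directly
against the characteristic equations.

### Confidence regions

`bootstrap_fit()` refits the whole grid on trial-level bootstrap
resamples, stratified by (pool, stimulus) to preserve the design (default
14 resamples, matching the reference analysis), and summarizes the
scatter of best fits as 1- and 2-SD ellipses in each 2-d projection of the
parameter space. The same resamples would in principle serve the $V$
correction; the package keeps the two uses separate for clarity.

## Mode analysis for undersampled populations

When fewer neurons are recorded than plausibly participate in the readout,
only model-based extrapolation remains. `svd_modes()` decomposes the
trial-by-neuron matrix of integrated counts into population modes
$\bar r_i^{sq} = \bar r_i^0 + \sum_m \lambda_m u_i^m v_m^{sq}$ with
orthonormal shapes and unit-covariance activations, so the total
covariance is $U\Lambda^2 U^\top$. Each mode carries a tuning $\eta_m$
(`mode_tuning()`, with an algebraic cross-check through
$\bar b = U\Lambda\eta$) and a sensitivity $y_m = \sigma_s^2\eta_m^2$; the
full-population sensitivity is $Y^{tot} = \sum_m y_m$, where
$Y = \sigma_s^2/(Z^2+\sigma_s^2)$ rescales the JND onto $[0, 1]$
(`sensitivity_from_jnd()`).

For a finite ensemble the exact sensitivity and CC indicators are
functions of the mode-space projector $P$ onto the span of the sampled
neurons' activity vectors (`exact_ensemble_quantities()`). Averaging the
projector over random ensembles of size $K$ and keeping its diagonal gives
the *observation fractions* $\epsilon_m(K)$ (`observation_fractions()`):
how much of mode $m$ a random $K$-neuron recording sees. They obey the
trace identity $\sum_m \epsilon_m(K) = K$ (each sampled projector has
integer trace) and grow monotonically to 1. The analytic approximations
$\langle Y\rangle(K) \approx \sum_m \epsilon_m(K) y_m$ and the matching
expression for the CC indicator $Q$ (`approx_curves()`) track the exact
ensemble averages closely when the population has a clean low-rank
structure; the package deliberately stops short of extrapolating beyond
the recorded population, because any such extrapolation rests on
unverifiable assumptions about the unseen spectrum, and of approximating
$V(K)$ from the fractions alone, which is known to be poor. The averaged
projector's off-diagonal magnitude is reported as a diagnostic of the
diagonal approximation. Finite-trial estimation noise in the SVD itself is
not corrected — a documented limitation.

## The synthetic validation experiment

Real recordings with a known ground-truth readout do not exist, so the
package ships generators whose defaults define its reference study
conditions.

**Latent-mode surrogate** (`latent_mode_spec()`,
`simulate_latent_mode_population()`) — the workhorse. A doubly stochastic
Poisson population: rates are a baseline plus linear tuning plus a
low-rank field of Ornstein–Uhlenbeck latent modes (correlation time 20 ms,
unit variance), rectified at zero (rectified mass is tracked; an error is
raised above 5%). The defaults are fixed once and play the role of the
reference experiment:

* 600 neurons, stimuli {25, 30, 35} Hz around $s_0 = 30$ Hz, 400 ms
  trials — stimulus units are Hz throughout;
* baselines $8 + \Gamma(3, 4)$ Hz (mean ≈ 20 Hz, strictly positive
  floor); tuning slopes $N(0, 1.13^2)$ Hz/Hz clipped at $\pm 1.5$ (so
  every structural draw keeps rates nonnegative at the extreme stimuli),
  mixed polarity;
* 40 modes with three ingredients: a *tuning-aligned* mode whose
  strength sets an information-limiting percept-noise floor of about
  4 Hz² at the reference window (half the total percept noise at the
  reference readout, keeping the achieved JND near 3 Hz); a dominant
  positive "global gain" mode; and a $m^{-1/2}$ tail of random-sign
  modes. Together they give mean pairwise spike-count correlations of a
  few percent in 50 ms windows — the weak-but-real regime typical of
  cortex. The tuning-aligned component is essential, not decorative:
  choice covariance observed across a whole population, although only a
  small ensemble drives the choice, requires shared variability with a
  component along the tuning direction; with independent noise the
  out-of-ensemble CC is structurally zero and the population indicators
  are starved of signal, making the inference problem degenerate rather
  than merely hard.

What the surrogate does *not* emulate: spike-history structure
(refractoriness, bursting), stimulus-dependent covariances, nonlinear
tuning, and any feedback of the choice onto the activity. Passing tests on
it therefore validate the estimators and the inversion machinery, not the
model's adequacy for any particular real circuit.

**Ground truth and behavior.** `build_ground_truth()` draws the hidden
ensemble (reference: $K^* = 80$, $w^* = 50$ ms, $t_R^* = 100$ ms,
$\sigma_d^* = 1$ Hz) and fits its regularized optimal readout on
dedicated calibration trials (reference: 3 × 1000, large enough that the
learned readout is close to truly optimal; half are held out to evaluate
the achieved JND, which lands near 3 Hz). The readout is then rescaled
to unit mean percept slope against the held-out tuning estimate (or the
true tuning, when supplied): without this the hidden readout violates
the model's own unbiased-percept assumption and the measured JND is
inflated relative to every prediction. `generate_behavior()` applies the
forward model trial by trial. Calibration trials never enter the
analysis.

**Recording design.** `split_recording_pools()` (or the fused
`simulate_experiment()`, which only simulates each trial's recorded
neurons plus the hidden ensemble) observes the population through pools
of simultaneously recorded neurons with disjoint trial blocks. The
reference design is 4 pools × 120 neurons × 3 × 180 trials, a
deliberately reduced version of the 15 × 170 × 3 × 180 design of the
analysis this package reimplements; the grid is restricted to $K \le
110$ and the complementary set defaults to $I = \min$ pool size
$- \max K$ (= 10 here). At this scale the whole inference (200 ensembles
per $K$, 28 600 grid cells) runs in a few minutes on one CPU, and the
temporal parameters are recovered exactly on the 10 ms grid with $K$
recovered to within a few grid steps — the same qualitative picture as
the full-scale analysis: across repeated structural seeds the best-fit
$w$ and $t_R$ land on or within one grid step of the true values, $K$
within a few grid steps of 80, and $\sigma_d$ between 0 and 1.5 — $K$
and $\sigma_d$ being the two parameters the indicators separate least
sharply.

**LIF network** (`lif_network_spec()`, `simulate_lif_network()`) — the
spiking-network generator: Poisson inputs firing at the stimulus rate
drive excitatory-input and inhibitory-input groups of a sparsely coupled
recurrent LIF population (membrane τ = 20 ms, 2 ms refractory, 2%
connectivity, balanced zero-mean recurrent weights, delays up to 5 ms).
A constant bias plus white membrane noise (the diffusion approximation
of unspecific background input) keep firing fluctuation-driven and
irregular while both input groups stay active, so inhibitory input
produces measurably negative tuning. Feedforward input sharing produces
noise correlations whose strength grows with the weight and overlap of
the input projections (few strong shared inputs correlate much more than
many weak ones). Exact rates and weight distributions are the package's
own choices, so this generator is checked qualitatively — irregularity,
mixed tuning polarity, above-chance correlations — not numerically.

## Numerical choices and conventions

* Times in seconds everywhere; stimulus units are whatever the dataset's
  stimulus column uses (Hz in the reference experiment). Rates are in Hz;
  CC curves in Hz (choice is 0/1).
* Bin width defaults to 10 ms; kernels whose parameters are multiples of
  the bin width are represented exactly.
* Pooled within-stimulus covariances use unbiased per-group normalization
  (denominator $n - g$ after within-group centering), which equals
  trial-count-weighted pooling for balanced designs; per-stimulus CC uses
  the $\psi(1-\psi)$ form, i.e. the $1/n$ covariance, as its definition
  dictates. The stimulus variance $\sigma_s^2$ is the population variance
  over trials.
* Singular readouts fall back to the total-covariance form with a
  Moore–Penrose pseudoinverse; rank decisions use the standard
  $\max(\dim)\cdot\varepsilon\cdot\sigma_{max}$ cutoff.
* Choices coded in any binary scheme are remapped to {0, 1} on ingest.
* One master seed; every stochastic stage (ensemble sampling, decision
  noise, network simulation, bootstrap) derives its own named stream from
  it (`stream_seed()`), so results are bit-reproducible and stages are
  insensitive to each other's draw counts.

## A worked example

A miniature experiment (150 neurons, 2 pools of 60, 3 × 60 trials) runs
in seconds and already recovers the temporal parameters:

```{r example, eval = FALSE}
spec <- latent_mode_spec(n_neurons = 150, n_modes = 15, seed = 2)
sim <- simulate_experiment(spec, K_star = 20, w_star = 0.05, t_R_star = 0.1,
                           sigma_d_star = 1, n_pools = 2, pool_size = 60,
                           trials_per_stim = 60,
                           n_calibration_per_stim = 80, seed = 7)
grid <- readout_grid(K = c(10, 20, 30, 40), w = c(0.03, 0.05, 0.07),
                     t_R = c(0.06, 0.10, 0.14), sigma_d = c(0, 1, 2),
                     n_ensembles = 40)
fit <- fit_readout_scales(sim$data, grid, seed = 11)
fit
summary(fit)
```

## Known limitations

* The empirical-Bayes ridge mitigates but does not eliminate discriminant
  overfitting, so predicted sensitivities retain a slight optimistic
  bias; in the reference validation this surfaces as a mild overestimate
  of $K$ compensated by $\sigma_d$, mirroring the mild underestimate
  reported for the full-scale analysis. The temporal parameters are
  unaffected.
* The $V$ corrections are first-order noise-variance subtractions; they
  can overshoot into small negative values at the noise floor.
* The mode analysis assumes $\sigma_d \approx 0$ and does not correct the
  SVD for finite-trial noise.
* Trial-varying extraction times, non-separable per-neuron kernels,
  choice feedback and integration-to-bound decisions are outside the
  model family.
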