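---
title: "Memory consolidation from fluctuating connections: model and methods"
author: "spinedrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory consolidation from fluctuating connections: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinedrift)
```

## The model

Two-photon imaging shows that dendritic spines — and with them the strength
of neural connections — fluctuate substantially over days even in the
absence of learning. `spinedrift` treats each connection as a discrete-time
random walk with reflecting boundaries over `S` strength states, state 1
meaning *no connection* and state `S` the strongest, largest and least
plastic one. The model's empirical anchors are: bounded, low-precision
connection strengths; strongly right-skewed spine-size distributions;
plasticity that decreases with spine size; learning that acts chiefly on the
weakest connections (stabilising newly formed spines); and lesion
vulnerability that decreases with strength.

Given an equilibrium distribution `x` (all entries positive, summing to 1)
and plasticity factors `y` (length `S − 1`, positive), the transition matrix
has up-moves `x_{i+1} y_i`, down-moves `x_i y_i`, and the diagonal takes the
remainder. Detailed balance holds identically, so `x` is stationary for any
valid `y`:

```{r}
spec <- default_spec()
P <- build_transition_matrix(spec)
verify_equilibrium(spec, P)
```

This separation is the point of the parameterisation: `x` can be matched to
an observed spine-size distribution while `y` independently sets the time
course of consolidation and forgetting. A spec is *valid* when every
diagonal entry is nonnegative, i.e. `x_{i−1} y_{i−1} + x_{i+1} y_i ≤ 1` for
interior rows; the constructor rejects anything else, naming the offending
row.

A memory is an association between `A` input and `B` output neurons.
Learning moves a fraction `p_{1,2} μ` of each output neuron's state-1
connections to state 2 and touches nothing else (learning rules reaching
higher states are deliberately out of scope). Weights are affine in state
number, `w(i) = α (i − 1)/(S − 1)`, retrieval is a binary threshold rule,
and feedforward inhibition places that threshold half an expected learning
increment above the equilibrium background, so learned patterns sit half an
increment above threshold and unlearned ones half below. An alternative
`two_sigma` inhibition policy (equilibrium net input plus two weighted
asymptotic standard deviations) is available; `half_delta` is the default
because it makes the retrieval margin an exact algebraic identity.

## Analysis tools and their numerical policies

* **Lifetimes.** Expected dwell time in state `i` is `1/(1 − P[i,i])`; an
  absorbing state is reported as an explicit `Inf`, never an overflow. With
  the default spec the top state's exit probability is
  `y_4 x_4 = 10^{-4}` per day: a 10,000-day (27-year) expected lifetime.
* **Fundamental matrix.** `Z = (I − P + X)^{-1}` (Kemeny–Snell), computed by
  direct solve with a condition-number guard; first-passage times
  `t_{ij} = (z_{jj} − z_{ij})/x_j` and asymptotic occupancy variances
  `σ_j² = 2 x_j z_{jj} − x_j − x_j²` follow. Both are validated in the test
  suite against Monte-Carlo dwell- and hitting-time oracles.
* **Evolution.** `v P^t` is computed either by repeated squaring (exact to
  machine precision in `O(log t)` multiplications) or through the
  eigendecomposition of the symmetrised matrix `D^{1/2} P D^{-1/2}`
  (`D = diag(x)`), which is symmetric because the chain is reversible and
  therefore has a real spectrum. The two routes agree to `1e-10` and the
  tests enforce this.
* **Spectrum.** Eigenvalues are reported sorted, with the leading value
  checked against 1 at `1e-10`. The tail forgetting rate is `−ln λ₂`; the
  tail coefficient is estimated by a log-linear regression on a late-time
  window that starts where the third mode has decayed to a relative
  amplitude of `1e-8`.
* **Tolerances.** Stationarity and row-sum checks use `1e-12`, detailed
  balance `1e-14`, identity residuals of `Z` `1e-10`; equal-strength
  calibrations bisect `μ` to `1e-10` relative.

## Emergent memory laws

The experiment drivers operationalise the classic laws. Trace *strength* is
by default the excess expected net input over the equilibrium baseline,
`Δnet(t) = A Σ w(i) (v_i(t) − x_i)`, which starts at
`x_1 p_{1,2} μ A/(S − 1)` and decays to zero; a simulated recall metric
(fraction of output neurons active under a full cue) is available for
stochastic experiments.

* **Forgetting shape.** The distance from equilibrium is a mixture of `S−1`
  decaying eigenmodes. While several modes are alive the curve is well
  approximated by a power law; the remote tail is a single exponential at
  rate `ln λ₂`. `classify_curve_shape()` fits both forms on an early and a
  late window; the defaults take the lower half of the probe times (log
  scale) as "early" — the multi-mode mixture region — and the top quarter
  as "late", reflecting the spectral structure rather than any particular
  dataset. When top-state plasticity is very small the curve approaches a
  non-zero plateau over any finite horizon (permastore).
* **Jost's laws.** Two traces are brought to *equal strength* — made
  operational as bisection on the younger trace's `μ` to `1e-10` relative —
  and then (a) drifted and compared, or (b) given identical extra learning.
  The older trace decays more slowly (its mass sits in higher, less plastic
  states) and gains more from relearning (its state-1 pool has been
  replenished by drift). Calibration can be infeasible (required `μ > 1`);
  this is reported explicitly, never silently truncated.
* **Spacing.** A spaced schedule (`k` episodes separated by `gap` drift
  steps) is compared with a massed one whose `μ` is recalibrated so both
  are equally strong immediately after their final episode. During pure
  learning episodes chain fluctuations are frozen — learning operates on a
  timescale of minutes to hours, drift on days to years — and drift runs
  only between episodes.
* **Ribot gradients.** A diffuse lesion deletes each present connection in
  state `i ≥ 2` with probability `q_i`, non-increasing in `i`. The
  underlying biological assumption is only qualitative, so the package
  uses the minimal
  monotone family `q_i = q_base (1 − w(i))^γ` (default `γ = 1`; `γ = 0`
  gives uniform lesioning as a control). Post-lesion strength is measured
  against the *lesioned* background, `A Σ_{i≥2} w(i)(1 − q_i)(v_i − x_i)`,
  because the lesion hits trace and background connections alike and
  inhibition tracks the background. Recall probabilities come from a
  logistic link `p = plogis(β₀ + β₁ · strength)`; the relative retrograde
  gradient is `log p_patient / log p_control`.

```{r}
fc <- forgetting_experiment(spec, learning_params(mu = 1), A = 1000, t_max = 2e5)
classify_curve_shape(fc)
```

## Defaults and what they represent

The canonical spec (`default_spec()`) is `S = 5`,
`x = (0.60, 0.22, 0.10, 0.02, 0.06)`, `y = (0.2, 0.05, 0.02, 0.005)`, one
step per day. It encodes the qualitative picture from spine imaging: a
majority of potential connections absent or very weak, a small (≈6%)
population of large mushroom-type spines, plasticity falling steeply with
strength, and a top state whose `x_4 y_4 = 10^{-4}` exit rate yields the
10,000-day lifetime that very-long-term memory requires. Its second
eigenvalue is ≈0.99991 (a ≈30-year tail time constant).

The logistic link defaults (`β₀ = −3`, `β₁ = 0.8`) place a freshly learned
trace (`A = 1000`, `μ = 1`, strength 6.6) at recall ≈0.9 and a fully
forgotten one at ≈0.05, a typical recognition-test range. The lesion default
`q_base = 0.8, γ = 1` lesions weak states heavily (0.6 at state 2) and the
top state not at all.

The fixture generator discretises exponential, gamma or lognormal shapes —
the families empirical spine-size distributions resemble — over the `S`
states and pairs them with geometrically decreasing plasticity profiles.
The law-checking grid uses decreasing profiles only, because decreasing
plasticity with strength is one of the model's core assumptions and the
regime in which the memory laws are claimed; constant profiles remain
constructible as controls. If a recipe would produce a negative diagonal,
the unpinned plasticity entries are rescaled down and the factor reported.

## Fitting and identifiability

`fit_model()` minimises squared error between model and data either on the
relative retrograde gradient (default: the quantity retrograde-amnesia
studies plot) or on the raw retention proportions of both groups, using a
derivative-free Nelder–Mead simplex (Brent in one dimension) on
logit-rescaled coordinates with 10 seeded multi-starts. Free parameters are
any subset of `μ`, `q_base`, `γ`, `β₀`, `β₁`.

On noiseless self-generated data the fitter closes the pipeline: SSE below
`1e-10` with parameters recovered to well under 1%. Under binomial
observation noise an identifiability limit appears: the relative gradient is
a *ratio of logs*, which cancels most of the overall strength scale, so `μ`
is only weakly identified from the gradient alone. Parameter-recovery
simulations therefore fit the raw retention curves, where `μ` is strongly
identified; the gradient objective remains the right choice when only the
gradient is published. Recall probabilities are floored at `ε = 1e-6` before
log transforms, with a warning, never silently.

## What the synthetic data do and do not show

The synthetic retention generator produces exactly the model's own
two-group binomial recall data: model-generated retention probabilities
through a logistic link, independent binomial sampling per (age, group)
cell. Real retention studies differ in ways the generator does not emulate —
interference from ongoing learning, item and subject heterogeneity,
non-binomial response dependence, measurement methods (savings, free recall,
recognition) with different effective links, and rehearsal between study and
test. Passing recovery tests therefore show that the fitting machinery is
correct and well-conditioned under the model's own assumptions, not that the
model fits any particular published dataset.

## Known limitations

* Learning affects only the 1 → 2 transition; relearning of partially
  consolidated traces through higher states is not modelled.
* Activations are binary and patterns non-overlapping; interference between
  memories is out of scope.
* The chain is strictly tridiagonal (no jump transitions) and discrete in
  time and state; continuous (Brownian) strength dynamics are not
  implemented.
* The strength-to-recall link is a modelling choice; retention data alone
  do not pin it down, and fitted parameters should be read conditionally on
  the link.
* Very long horizons are analysed through the eigendecomposition; explicit
  ensemble simulation at `t ≫ 10^4` steps is possible but slow in
  comparison and intended for validation at moderate horizons.

## Problem sizes used in the tests

The shipped tests run Monte-Carlo oracles at `10^4` dwell episodes and
`10^5` hitting trajectories on a moderately plastic four-state chain,
ensemble checks at up to `10^5 × 60` connections, the law grid on ten
generated chains, and 50 replicate noisy fits — sizes chosen so the full
suite completes in well under a minute while leaving all sampling-error
margins at three to four standard errors.
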