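---
title: "State-dependent navigation models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-dependent navigation models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stapaw)
```

This vignette is the package's own account of the models it implements,
the choices that were genuinely open, and what the synthetic-data tests do
and do not establish. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` compute.

## The model

A track is a per-step kinematic series: heading change `dθ` (radians,
counter-clockwise positive, wrapped to (−π, π]) and displacement `dr`
(cm), at a default step of 5/14 s (14 Hz video down-sampled by 5). The
sensory series are the experienced concentration `C`, the perpendicular
concentration difference `dC⊥` (left sensor minus right sensor, offset
0.05 cm), and optionally a stimulus indicator `I`.

The latent state `z` follows an input-driven Markov chain: row `i` of the
per-step transition matrix is the softmax of logits `K_ij · C_hist` off
the diagonal and a scalar baseline `b_i` on it. Within a state, a
Bernoulli decision `q` selects a turn (probability
`m + (M − m)/(1 + exp(K_C · C_hist + K_h · |dθ|_hist))`, bounded in
`[m, M]`) or weathervaning. Turn heading changes mix a circular uniform
(weight `α`) with a von Mises centered at π; weathervane heading changes
are von Mises with mean `−K_dC⊥ · dC⊥_hist`; speeds are Gamma with
strategy-specific shape and scale. Heading and speed are conditionally
independent given `(z, q)`.

All kernels live on a raised-cosine basis (4 functions over 14 lags,
about 5 s) and act on *strictly past* input. Sensory inputs are z-scored
with dataset constants stored on the parameter object, so simulation and
fitting agree; history windows at track starts are zero-padded after
standardization (zero = dataset mean). Track starts drop the first two
steps, where derivatives are undefined. Displacements at or below zero
are floored at 1e-4 cm before Gamma evaluation.

Conventions that the field leaves open and we fixed:

* `K_h` acts on `|dθ|` (left/right symmetric turn-magnitude history).
* The weathervane density is a pure von Mises (no uniform component).
* `b_i` is a logit bonus on the diagonal only; off-diagonal logits carry
  only kernel terms. For two states this makes the row-wise softmax a
  plain logistic with an identifiable baseline.
* After fitting, states are relabeled by posterior-weighted mean turn
  probability, ascending: state 1 is steer-enriched (S), the last state
  turn-enriched (T). This resolves label switching deterministically.

## Inference

The E-step is scaled forward-backward (C++) with per-step transition
matrices; the marginal log-likelihood is exact. The M-step introduces the
within-state turn/weathervane responsibilities as an inner latent layer,
which separates the emission objective into independent blocks — turn
decision (logistic with box constraints, analytic gradient), turn-heading
mixture (2 parameters, multi-started because the uniform weight and the
concentration form a ridge with local optima), weathervane von Mises
regression (analytic gradient), and two weighted Gamma blocks (Newton on
the shape equation) — plus a transition block (softmax regression with
analytic gradient). Any block that fails to improve keeps its previous
value, so the data log-likelihood is non-decreasing (generalized EM). The
initial state distribution is a free parameter with the closed-form
update (mean of the first-step marginals); tying it to the transition
parameters would break the monotonicity guarantee.

**Initialization.** Replicating a single-state fit across states and
perturbing it — the obvious scheme — converges reliably to local optima
that either split steps by turn-versus-run strategy instead of by
persistent state, or absorb the sensory transition kernels into the state
baselines. The shipped scheme instead (a) segments steps by smoothed turn
rate and speed (k-means into Z levels) and takes one supervised M-step
from those hard labels, and (b) for the full input-driven family uses a
two-stage protocol: fit the nested sensory-free-transition (HMM) family
first, then restart the transition kernels from a small dictionary of
smooth zero-sum trend-detector patterns in both sign arrangements and let
the likelihood arbitrate (`stapaw_fit()`; candidates can also be compared
on a held-out track split). The label-supervised kernel estimate itself is
uninformative — a few steps of timing noise at bout boundaries decorrelate
the trend covariate — which is why the dictionary restarts are needed.

Convergence tolerance defaults to 1e-4 per 1000 data steps; EM on the
fixtures typically converges within a few tens of iterations.
Cross-validation splits whole tracks, runs several initializations per
fold, selects by training likelihood, and reports held-out log-likelihood
per second of data, with differences against the null model's mean.

## The synthetic-data generator

`fixture_params()` provides documented ground-truth presets; the
closed-loop simulator senses, transitions, decides, emits, and moves, in
that order, with a reflecting boundary. The `paperlike-2state` preset
encodes the study conditions the models target:

* baselines give sensory-free dwell times of 8.1 s (S) and 4.6 s (T);
* mirror-shaped, zero-sum derivative transition kernels (amplitudes 60 and
  40 on standardized concentration) make falling concentration drive
  S→T and rising concentration drive T→S, which yields turn-bout exits
  oriented up-gradient roughly 60% of the time in the default 0–50 mM
  linear arena, while the same preset with the kernels zeroed
  (`hmm-2state`) shows no exit bias, and negating the kernels reverses it;
* crawl speeds around 0.2 mm/s (Gamma means 0.002–0.0066 cm/step), slower
  while turning — worms nearly stop during reversals;
* turn probabilities in [0.05, 0.25] (S) and [0.12, 0.7] (T), with a
  refractory-then-rebound `|dθ|`-history kernel and a weak concentration
  kernel; steering is active in S and suppressed in T.

Several preset values were chosen for statistical identifiability at the
~5 × 10⁴-step scale of the recovery tests as much as for realism: the
uniform turn weight is 0.3 and the reversal von Mises is concentrated
(κ ≈ 2.5–3.5) so the mixture components separate; turn and run speed
distributions overlap little so the strategy responsibilities are crisp;
and the turn-state steering kernel is exactly zero so that the
sensory-free control preset is genuinely free of gradient information in
its turn bouts. What passing tests show is therefore that the estimator
recovers a *well-separated* two-state system from realistic amounts of
data — not that every real recording would be equally identifiable; real
worm data has additional features (posture noise, collisions, tracking
gaps, slow non-stationarity) that the generator does not emulate.

The exit bearing is measured at the last step inside the turn state (the
step at which the state changes). Measuring one step later would fold the
steer state's first steering draw into the "exit" and biases even the
sensory-free control above chance.

## The navigation agent

The reinforcement-learning model strips the system to a two-action POMDP:
a logistic policy `P(a = 1 | ΔC) = 1/(1 + exp(K ΔC + b))` reads only the
one-step concentration change (observed after each move) and chooses
between weathervane-like and turn-like actions whose heading-change
distributions are fixed to the two states' statistics at constant speed
(0.01 cm/step). The reward is the negative distance to the source minus a
switching penalty through a 5-step exponential action filter. Training is
REINFORCE with a mean-return baseline and Adam; gradients are averaged
over a small episode batch per epoch because single-episode gradients
made the two-parameter update oscillate at any usable learning rate. The
training plume has amplitude 50 (arbitrary odor units, a salt-like
scale): with an order-one plume the per-step ΔC is too small for the
scalar weight to traverse within a realistic epoch budget. Steering in
the weathervane action is deliberately weak (slow heading correction), so
that sensory-gated turning has something to contribute; the
chemotaxis-index radius is half the σ of whichever plume an evaluation
runs in. Controls: within-episode shuffled replay of the trained agent's
actions (identical action statistics, destroyed sensory alignment),
always-weathervane, always-turn, and rate-matched Markov switching.

## The circuit model

Two rate units (S, T) with mutual inhibition, a rectified-linear rate
function, and white noise scaled by √dt integrate a fast/slow-filtered
concentration input `I = F − S` (a transient derivative-like signal) with
*opposite-sign* input weights: rising concentration excites the steer
unit, falling concentration the turn unit. A common-sign input — the
literal reading of "both units have the same parameters" — leaves the
winner identity uninformative about the gradient, so no directed
state-switching can arise; the opposite-sign weights are the minimal
asymmetry that maps the winner onto the behavioral context. The shipped
defaults (τ = 1 s, J = −4, noise 0.9, dt = 0.1 s, filter rates α = 1,
β = 0.5, γ = 0.1) put the circuit in the regime where the comparison
against the uncoupled (J = 0) control is informative: with weak noise
both variants simply track the input sign and perform alike, whereas with
noisy units the uncoupled control dithers between strategies while mutual
inhibition integrates the input and holds a winner for seconds. The
winner series uses a sticky argmax (ties keep the current winner).

## Numerical notes and limitations

* Von Mises densities use exponentially scaled Bessel functions; sampling
  is Best-Fisher rejection.
* The double-exponential interval fits operate on the log of the binned
  density (32 log-spaced bins): intervals span two decades, and linear
  least squares on the density recovers the slow rate poorly. R² is
  reported on the same log scale, which is also why a single exponential
  can score far below zero on two-timescale data.
* State-label alignment for evaluation enumerates permutations (Z ≤ 4).
* Exhaustive path enumeration validates forward-backward only for T ≤ 8.
* The EM likelihood surface genuinely has multiple optima whose
  held-out performance differs by only tens of nats per 10⁴ steps; the
  two-stage protocol with kernel-dictionary restarts reaches the
  kernel-correct basin reliably, but a minority of emission scalars
  (typically a state's minimum turn probability) can settle 15–30% from
  the generating value at the 5 × 10⁴-step scale even when the decoded
  states and kernels are accurate. Problem sizes used by the test suite
  (tens of tracks of 500–1500 steps; 200-episode evaluations) were chosen
  to make these statements reproducible in minutes on one CPU.
* Not modeled: body posture, worm-worm interactions, plate edge
  artifacts, continuous-time transitions, semi-Markov dwell times, more
  than one stimulus channel.
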