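---
title: "Closed-loop Bayesian optimization of IVT reactions: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop Bayesian optimization of IVT reactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivtbo)
```

## The problem

In vitro transcription (IVT) converts a linear DNA template into mRNA using
T7 RNA polymerase. The yield depends on at least twelve controllable
parameters — enzyme activities (T7 RNAP, inorganic pyrophosphatase), reagent
concentrations (NTPs, DNA template, magnesium cofactor, spermidine, DTT,
RNase inhibitor), the cofactor salt, pH, temperature and reaction time. Each
wet-lab evaluation costs hours, so the optimization must be sample-efficient.
`ivtbo` implements the standard closed loop: seed with a space-filling
design, fit a probabilistic surrogate, propose the next small batch by an
acquisition rule, measure, refit, repeat.

## The search space

`ivt_space()` defines the twelve parameters with their boxed domains (e.g.
pH in [6.5, 8], T7 RNAP in [1000, 50000] U/mL, cofactor in {MgAcetate,
MgCl2} at 0–100 mM). Three representation choices matter downstream:

* **Unit-cube scaling.** Parameters span four orders of magnitude (pH vs
  T7 units); a shared prior over kernel length scales is meaningless on raw
  units, so every numeric parameter is min–max scaled to [0, 1] before any
  kernel evaluation.
* **One-hot categoricals.** The cofactor salt becomes a two-coordinate
  one-hot block with its own ARD length scale per level, which keeps the
  Matérn kernel well-defined on the mixed space; acquisition search may
  propose relaxed blocks, decoded by argmax.
* **Continuous relaxation of integers.** Integer parameters are optimized as
  reals and rounded (and clipped) at decode time; `decode(encode(c)) = c`
  for every representable condition.

The objective is stored as a real number in g/L throughout; yields are
measured to two decimals, and treating the evaluation metric as integer
would discard most of the signal.

## Latin hypercube seeding

`lhs_design()` partitions each numeric range into n equal-probability
strata, places one sample per stratum (uniform within the stratum, stratum
order permuted independently per dimension, via `lhs::randomLHS`), and
covers categorical levels by balanced cycling followed by a shuffle. The
defaults seed with n = 16. With twelve dimensions and sixteen points this is
close to plain uniform sampling in expectation, but it guarantees
non-overlapping marginal coverage, which is what the seeding step needs.
For integer parameters whose range holds fewer distinct values than n
(pyrophosphatase has eleven), exact one-per-stratum coverage cannot survive
rounding; the underlying continuous draw is still stratified.

## The Gaussian-process surrogate

`gp_fit()` implements GP regression with an anisotropic (ARD) Matérn 5/2
kernel, constant mean, and observation noise. Matérn 5/2 gives twice
differentiable sample paths — smooth enough for local reasoning without the
unrealistic infinite smoothness of the squared exponential. Per-dimension
length scales let irrelevant parameters wash out, which is also what makes
the later Shapley analysis informative. Hyperparameters are point estimates
maximizing the log marginal likelihood with analytic gradients, L-BFGS-B in
log space from eight restarts drawn from a fixed prior box (length scales
0.05–5 on the unit cube, amplitude 0.1–10 × var(y), noise 10⁻⁴–1 × var(y)).

Numerical choices: a jitter of 10⁻⁸ σ_f² on the Gram diagonal; a noise-
variance floor of 10⁻⁶ in `gp_fit()` itself; length scales bounded in
[0.03, 50] during the search (needle-thin scales in a 13-dimensional encoded
space are always noise-fitting at these sample sizes); targets fitted in raw
g/L with a learned constant mean rather than standardized, keeping the
acquisition and every plot in assay units.

One point deserves emphasis: inside the optimization loop, `bo_step()`
raises the noise floor to 0.04 (g/L)² — a 0.2 g/L standard deviation, the
low end of the assay's replicate variability. Pure maximum likelihood on a
small noisy campaign log otherwise has a degenerate optimum that drives the
noise to zero and interpolates replicate scatter; the resulting model
memorizes its data, reverts to the prior mean everywhere else, and the loop
degrades to random search. The floor encodes what the experimenter already
knows about the assay and removes that failure mode without abandoning
point-estimate fitting.

## Expected improvement and batch proposals

`expected_improvement()` is the standard analytic form
EI = (ŷ − f_max) Φ(z) + s φ(z) with z = (ŷ − f_max)/s — the expectation of
max(0, Y − f_max) under the surrogate's Gaussian prediction, degenerating to
max(0, ŷ − f_max) at s = 0. It is verified in the tests against numerical
integration to 10⁻¹⁰.

`propose_batch()` maximizes EI over a candidate pool rather than by gradient
ascent: the mixed/integer space makes pool search robust. The pool is a
fresh 20,000-point Latin hypercube plus local refinements around the best
observed points — Gaussian perturbations at two scales and axis-aligned line
scans through the top three incumbents. The line scans are the design choice
that matters: an IVT-like response surface is close to a product of
per-parameter effects, so single-coordinate refinement is the efficient
local move. Batch members after the EI maximizer are drawn at random from
candidates with EI ≥ 0.5 × max, subject to a minimum pairwise distance of
0.05 between members, falling back to next-best EI points (flagged
`fallback`) if the diverse set is exhausted. The distance is measured as the
root-mean-square per-coordinate difference — i.e. Euclidean distance
normalized by √dim — so the same threshold means the same thing in any
dimension; with a raw Euclidean threshold, 0.05 in a 13-coordinate space is
satisfied by near-duplicates and whole batches collapse into one basin. No
constant-liar fantasizing is used between batch members: the model only ever
updates on real measurements.

## The loop, stopping, and the experiment log

The experiment log — a tibble with one row per evaluated reaction and a
fixed CSV header — is the single source of truth; `record_results()` only
appends, and partial batches (NA yields) are allowed, since wet-lab batches
sometimes fail asynchronously. `stopped()` implements the two stopping
conditions: a total budget (default 150 evaluations) and a plateau rule —
best-so-far improvement below ε = 0.5 g/L over the last 30 evaluations.
"No significant improvement" had to be quantified somehow; ε matches the
typical replicate standard deviation, so progress smaller than measurement
noise does not count. The in-silico default batch size is 4 (the wet-lab
loop uses 3–5; nothing in the machinery depends on which).

## The synthetic IVT simulator

No public IVT yield dataset exists, so validation uses a calibrated
emulator, and it is worth being precise about its epistemic status: it is a
response surface consistent with every published anchor, not a mechanistic
transcription model, and every quantitative claim tied to it is a
calibration check rather than an independent prediction.

**Form.** Noise-free yield is `Y_max × Π_j f_j(x_j) × g(t)`: a plateau
ceiling, independent unimodal or saturating per-parameter responses
(generalized-bell curves for cofactor concentration, spermidine, pH,
temperature and log₁₀ T7 activity; saturating rises for NTPs, DNA, DTT,
PPase, RNase inhibitor), and a first-order kinetic saturation
g(t) = 1 − e^(−kt) in the reaction-time parameter. The only interaction is
the cofactor-salt shift: magnesium acetate tolerates higher concentrations
than the chloride, modeled as a shifted, narrower usable window for MgCl₂.
Measurements add Gaussian replicate noise (default sd 0.5 g/L, the middle of
the published ±0.23–0.98 range) truncated at zero.

**Calibration.** `calibrate_simulator()` fits the free factor parameters by
least squares against the seven published endpoint yields (12.61, 10.76,
11.76, 12.27, 12.18, 11.52 g/L for the six optimized reactions, 7.64 for the
benchmark), with box constraints placing each factor's optimum inside the
published windows (pH optimum in [6.5, 7.2], cofactor 40–60 mM, spermidine
1–3 mM, T7 6000–8000 U/mL, a temperature plateau around 37–44 °C, NTPs and
DNA saturating upward). Seven anchors under-determine ~24 parameters, so the
objective adds a small preference for wide factor responses: the published
windows describe broad favorable regions, and among near-interpolating
surfaces the widest is both the more realistic (generic IVT conditions
deliver a few g/L, not microyields) and the only one on which a 60-run
campaign — like the published one — has usable signal. The frozen fit
achieves RMSE ≈ 0.003 g/L over the anchors, far inside every printed
replicate SD, and ships as `inst/extdata/sim_params.json`.

**Kinetics.** The rate k = ln(5)/120 ≈ 0.0134 min⁻¹ is derived from the
published reading that the best run reaches 10.65 g/L at the 2-hour mark,
80% of its maximum; "maximum" is read as the kinetic plateau (10.65/0.80 =
13.31 g/L), under which the 300-min value is 98.2% of the plateau. The
kinetic amplitude carries its own calibrated scale relative to the endpoint
surface, because the published endpoint for that run (12.18 g/L at 121 min)
and its kinetic reading (10.65 g/L at 120 min) are mutually inconsistent
under any single amplitude — time-course sampling reads lower than endpoint
quantification, and the simulator reproduces both protocols rather than
averaging them. The dsRNA/RNA mass ratio ramps up after a 115-min onset with
a 30-min time constant to an asymptote of 0.05 mg/mg. Templates longer than
a 1500 bp threshold get a size factor and a post-peak exponential decline,
both solved in closed form from the published 5299 bp anchors (9.7 g/L at
145 min declining to 7.1 g/L at 300 min); the closed-form solution puts the
5299 bp template's 120-min value at 9.7 g/L, slightly under the rounded
"over 10 g/L within 2 h" narrative, and the two printed anchors were given
precedence.

**What the simulator does not emulate.** Real IVT has reagent interactions
beyond the cofactor-salt coupling (Mg²⁺–NTP complexation couples those two
concentrations mechanistically), batch effects, drift, and non-Gaussian
failure modes (precipitation, RNase contamination). Passing the in-silico
replication therefore shows that the loop's machinery works on a surface
with this anchor structure — not that it would perform identically in any
wet lab.

## Shapley explanations

`shap_values()` implements the Shapley sampling-values approximation:
features enter in sampled permutation order, absent features are imputed
from a background draw, and each parameter's effect φ_j is its average
marginal contribution; antithetic (forward + reversed) permutation pairs
halve the Monte-Carlo variance at no cost. The background defaults to the
full experiment log, attribution is per reaction parameter at the raw-label
level (not per one-hot column), and only the posterior mean is explained.
Local accuracy (φ₀ + Σφ_j ≈ prediction) and agreement with exact
2^M enumeration are property-tested. Explanations use the final refit model;
per-cycle explanations are possible but noisier.

## Surrogate comparison

`loo_errors()` / `compare_surrogates()` run leave-one-out cross-validation
with pluggable surrogate factories; random forest (`ranger`) and GBM
(`xgboost`) are comparators behind the same fit/predict contract, never
re-implemented. Replicated conditions stay as distinct points. The tests
include a canary factory proving the held-out target never reaches the
training call.

## Problem sizes in the test suite

The suite exercises every contract at sizes chosen for a desktop run: the
closed-loop replication uses the published campaign's own shape (16 LHS
seeds + EI batches of 4 to 60 evaluations, noise sd 0.5 g/L, ten seeds,
median noise-free best ≥ 10.7 g/L, with a paired random-search baseline);
LOO comparison runs on a 40-point simulated log; Shapley-vs-enumeration
checks use M ≤ 6 features; GP oracle comparisons use ≤ 20 training points.
Re-calibration from the anchors is smoke-tested with 3 restarts; the shipped
fixture was produced with 24.

## Known limitations

* The GP is refit from scratch each cycle (fine at n ≤ 150; no incremental
  updates).
* EI pool search does not guarantee the global EI maximizer, only the pool
  optimum; the pool size and refinement knobs are configurable.
* The plateau stopping rule is a heuristic quantification of "no significant
  improvement"; change ε and the window through `stopping_rule()` if your
  assay noise differs.
* Hyperparameters are point estimates; fully Bayesian treatment (or deep
  kernels) is out of scope by design.
* No multi-objective support (e.g. maximizing yield while minimizing dsRNA);
  the dsRNA ratio is reported by the simulator but not optimized.
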