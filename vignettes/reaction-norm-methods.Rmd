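---
title: "Hierarchical one-step reaction norm models for genotype-by-environment interaction"
author: "rngxe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical one-step reaction norm models for genotype-by-environment interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rngxe)
```

## The problem

In beef cattle evaluated across heterogeneous production systems, the
genetic merit of a sire can depend on the environment in which his progeny
perform: genotype-by-environment interaction (G×E). Reaction norm models
describe each animal's expected genetic value as a linear function of an
environmental gradient, `u(X) = a + b·X`, where the intercept `a` is the
breeding value in the average environment and the slope `b` measures
environmental sensitivity. When most slopes are near zero, sire rankings
are stable across environments; large slope variance signals re-ranking.

The environmental descriptor used in this model class is the effect of the
contemporary group (CG: herd, year, season of birth, and sex), estimated
from the data themselves. `rngxe` implements the *one-step* (hierarchical)
formulation: the CG effects and the reaction-norm coefficients are
estimated jointly in a single model, rather than plugging pre-estimated CG
solutions into a second-stage regression. This propagates the uncertainty
of the environmental descriptor into the genetic parameters.

## The model

For record `m` of animal `i` in contemporary group `j`:

y_ijm = x_i'β + £_j + a_i + b_i £_j + pm + ε_ijm

* `β`: fixed intercept plus linear and quadratic cow-age-at-calving
  covariates (age centered at its sample mean; months).
* `£_j ~ N(0, σ²_cg)`: random CG environmental effect. The same `£_j` that
  enters the mean also serves as the slope covariate — this is what makes
  the model one-step.
* `(a_i, b_i) ~ N(0, G ⊗ A)`: intercept and slope breeding values with the
  2×2 covariance `G = [[σ²_i, σ_il], [σ_il, σ²_l]]`, structured across
  animals by the numerator relationship matrix `A` (computed from the
  pedigree with inbreeding; its sparse inverse is built by Henderson's
  rules with Meuwissen–Luo inbreeding coefficients).
* `pm ~ N(0, σ²_pe)`: maternal permanent environment effect, indexed by
  dam.
* `ε ~ N(0, σ²_e)`: homogeneous residual.

The additive genetic variance along the gradient follows the covariance
function σ²_a(X) = σ²_i + X²σ²_l + 2Xσ_il, and the genetic covariance
between two environments `Xx`, `Xy` is σ²_i + (Xx+Xy)σ_il + Xx·Xy·σ²_l,
from which between-gradient genetic correlations follow.

## Estimation

All parameters are sampled by a Gibbs sampler written in C++ (`Rcpp`),
with conjugate full conditionals cycled in a fixed order: fixed effects
(flat prior), CG effects, the per-animal `(a_i, b_i)` pair as a joint
2-vector block (scalar updates mix poorly given the strong
intercept–slope posterior correlation), maternal permanent environment
effects, the genetic covariance `G`, and the scalar variances. Default
chain settings are 200,000 iterations, 20,000 burn-in, thinning 10;
testing profiles scale these down.

### Identifiability and extra Metropolis moves

The one-step model has three soft non-identifiability directions that
plain single-site Gibbs traverses very slowly:

1. **CG sign ambiguity.** Within a group, the likelihood sees
   `(1 + b_i)·£_j`; flipping `£_j → −£_j` together with
   `(1+b_i) → −(1+b_i)` for its members leaves every record's mean
   unchanged. When slope dispersion is large, single-site updates can
   lock individual groups into the sign-flipped configuration.
2. **Environmental scale.** `£ → c£` with `(1+b) → (1+b)/c`,
   `σ²_cg → c²σ²_cg` and `G → T G T'` (T = diag(1, 1/c)) changes the
   likelihood not at all; the only information pinning the scale is the
   zero-mean prior on the slopes (cost ≈ N(1−c)²/(2σ²_l)).
3. **Environmental origin.** `£ → £ − t` with `a → a + t·b` and the fixed
   intercept shifted by `t`.

The sampler therefore adds three Metropolis–Hastings moves — per-CG sign
flips, a joint scale move, and a location move — each accepted by the
exact prior ratio plus Jacobian, so the posterior is untouched while
mixing across these directions improves by orders of magnitude. (An
earlier design that deterministically recentred `£` each sweep was
abandoned: a deterministic transformation is not posterior-preserving, and
a cross-check against an independent implementation of the identical model
in JAGS showed it distorts the genetic covariance; the Metropolis location
move is its correct counterpart. The JAGS cross-check with the final
sampler agrees on every component to Monte Carlo error.)

### Priors

The default (`prior = "proper"`) uses an inverse-Wishart with 4 degrees of
freedom for `G` and scaled inverse chi-squares with 4 degrees of freedom
for the scalar variances, all scales set so the prior mean is 0.25 times
the phenotypic variance; these are proper but diffuse. A `prior = "flat"`
option places constant priors on all dispersion parameters, the
convention of the classical animal-breeding Gibbs samplers. A caveat
discovered while validating the scale move: when the slope variance is
large relative to `1` (so that the environmental scale is essentially
unidentified), fully flat variance priors make the posterior *improper*
along the scale direction — the prior cost of rescaling vanishes as σ²_l
grows, and a well-mixing chain drifts without bound. With realistic slope
dispersion (slope SD well below 1 on the multiplier `1 + b`) the
likelihood pins the scale and flat priors behave well. The proper default
avoids the impropriety in all regimes, at the price of some prior
sensitivity exactly where the data carry little information.

### Convergence

`geweke_diagnostic()` implements the classical early-vs-late mean z-test
with AR-smoothed spectral density estimates at frequency zero (two-sided,
α = 0.05 by default); `geweke_table()` applies it to all dispersion
parameters of a fit. A zero-variance chain is reported as degenerate
rather than producing a division by zero. Calibration is verified on iid
chains (rejection rate ≈ 5%) and against the reference implementation in
`coda`.

## Downstream summaries

* `assign_gradients()` sorts CGs by their posterior-mean solutions and
  cuts them into `k` (default 5) quantile levels of near-equal group
  counts, extra groups going to the lower levels (largest remainders
  first); each level's descriptor `X` is the mean of its member
  solutions. Gradients are built from posterior means, not per-draw
  re-ranking, so the levels are deterministic; ties break by CG id.
* `heritability_at()` evaluates h²(X) = σ²_a(X)/(σ²_a(X) + σ²_pe + σ²_e)
  draw by draw and reports posterior mean ± SD. The CG variance is
  excluded from the denominator — the environment is the gradient under
  study, not noise — but `include_cg = TRUE` switches to the wider
  denominator. Draw-wise evaluation (not plug-in at posterior means) is
  used throughout.
* `gradient_summary()` combines levels, per-level additive variances,
  heritabilities and the k×k posterior-mean genetic correlation matrix.
* `classify_sires()` classifies sires from the posterior means of their
  slopes, measured in units of the between-sire SD (denominator n−1):
  within 1 SD Extremely Robust, above 1 and below 2 Robust, at least 2
  and below 3 Plastic, at least 3 Extremely Plastic; exact boundaries
  resolve as ≤1 ER, =2 P, =3 EP. Deviations are measured from the mean of
  the sire slopes by default — this makes the scheme invariant to the
  environmental-origin choice — with `center = "zero"` available. Under a
  normal slope distribution the expected class shares are the normal
  bands (≈68.3 / 27.2 / 4.3 / 0.3%), so "robust or extremely robust"
  exceeding 90% is a structural property of near-normal slopes.

## Data editing

`apply_edits()` retains contemporary groups with at least 5 records
("more than 4 individuals") and known sires with at least 3 retained
progeny records, iterating the two rules to a fixed point because each can
re-trigger the other; records with unknown sires are exempt from the
progeny rule, whose purpose is sire connectivity. The fixed point is
verified against literal brute-force re-filtering, and the operation is
idempotent.

## The synthetic-data generator

No herd data ship with the package, so `simulate_pedigree()` and
`simulate_phenotypes()` generate populations from the model itself with
known truth. Founders receive `(a, b)` from `N(0, G)`; descendants get the
parental average plus Mendelian sampling with covariance
`G·(0.5 − 0.25(F_s + F_d))`, consistent with the `A`-structured prior used
in inference. Mating is random within the previous generation, one progeny
per mating, no selection — the simplest scheme giving a connected
multi-generation pedigree. CGs are exchangeable groups nested within
generation and sex (sex Bernoulli(0.5), folded into the CG structure as in
the herd–year–season–sex definition), with effects `N(0, σ²_cg)`. Cow age
is drawn from a normal with mean 72.63 and SD 36.65 months, truncated at
24 months, and enters with linear and quadratic coefficients (defaults
0.5 and −0.003 per month, a mild concave age effect of the size typical
for yearling weight). The default trait mean is 180 (a Nellore-like
yearling weight in kg). Population size is `n_cgs × cg_mean_size`
phenotyped animals (one record each) split over `n_generations`.

What the generator does *not* emulate: selection and genetic trend,
heterogeneous residual variances, multiple correlated traits, non-random
CG allocation, or missing-parent patterns typical of field pedigrees.
Passing the recovery tests therefore demonstrates correctness of the
machinery under the model's own assumptions, not robustness to the ways
real herd data violate them.

### Reference simulation conditions and what they showed

The package's reference parameter-recovery condition is 2,000 phenotyped
animals in 100 CGs with true components
(σ²_i, σ²_l, σ_il, σ²_cg, σ²_pe, σ²_e) = (100, 25, 20, 150, 30, 200), fit
with 20,000-iteration chains (5,000 burn-in, thinning 10). Under these
conditions σ²_i, σ²_cg and σ²_e are recovered with correct interval
coverage, the posterior of σ²_i is centred within 3 posterior SDs of the
truth in every replicate, the posterior-mean CG solutions correlate ≈0.99
with the true environmental effects, and the per-level additive variance
and heritability increase along non-negative gradient levels.

The slope-scale components are a different story, and deliberately so.
σ²_l = 25 with £ of SD ≈ 12 means the environmental multiplier `1 + b` has
SD 5 — about 42% of animals respond *negatively* to an improving
environment. In that regime the environmental scale is nearly
unidentified (the slope-mean pinning cost above is weak), so the
posteriors of σ_il and σ²_pe (and sometimes σ²_l) sit where the prior
puts them rather than at the simulated truth, for any correct sampler —
our fits agree with an independent JAGS implementation wherever the
latter is computable. With slope dispersion at realistic levels (slope SD
≲ 0.5) every component, including σ²_pe and σ_il, is recovered cleanly;
the reduced model (slopes frozen) matches REML animal-model estimates
exactly. The reference condition is kept as-is because it doubles as a
stress test documenting where the model's identification boundary lies.

## Numerical choices

* Mendelian-sampling variance shares use F = −1 for unknown parents, so
  `d` is 1 (both unknown), 0.75 − F/4 (one known), 0.5 − (F_s+F_d)/4
  (both known); `A⁻¹` entries follow Henderson's rules with 1/d weights.
* The 2×2 genetic covariance is drawn by explicit inverse-Wishart
  (Bartlett construction); every saved draw is positive definite by
  construction.
* Genetic correlations are clipped to [−1, 1] only against floating-point
  overshoot (1e-12); a zero additive variance at a gradient yields NA
  with a warning rather than ±Inf.
* Chains are driven by R's RNG (seed via `set.seed`), so runs are
  bit-reproducible, including from C++.
* Problem sizes in the test suite (hundreds to ~2,400 animals, chains of
  10³–2×10⁴ iterations) were chosen so the whole suite exercises every
  code path at meaningful scale while remaining quick to run routinely.

## Known limitations

* Single trait, single record per animal, homogeneous residual variance.
* No unknown-parent groups or genomic relationships.
* The h² denominator convention is stated, not estimated; the wider
  alternative including σ²_cg is one flag away.
* In extreme slope-variance regimes the model itself is weakly
  identified (see above); results there are prior-sensitive and the flat
  prior option is improper.
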