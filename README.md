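# rngxe

Hierarchical one-step reaction norm models for genotype-by-environment
interaction (G×E) in pedigreed populations.

## What it is for

In livestock evaluated across heterogeneous environments — the motivating
case is Nellore beef cattle recorded in many herds — a sire's genetic
merit can depend on where his progeny perform. Reaction norm models
describe each animal's genetic value as a line over an environmental
gradient, `u(X) = a + b·X`: the intercept `a` is merit in the average
environment, the slope `b` is environmental sensitivity. `rngxe` fits the
*one-step* (hierarchical) version of this model, in which the
environmental gradient itself — the contemporary-group (herd–year–season–
sex) effects `£_j` — is estimated jointly with the reaction norms:

```
y_ijm = x_i'β + £_j + a_i + b_i·£_j + pm + ε_ijm
```

with `£_j ~ N(0, σ²_cg)`, a bivariate pedigree prior
`(a, b) ~ N(0, G ⊗ A)` built from the inverse numerator relationship
matrix with inbreeding, maternal permanent environment effects `pm` by
dam, and Gaussian residuals. Everything is estimated by a Gibbs sampler
(C++ core) with extra Metropolis moves that handle the sign/scale/origin
ambiguities peculiar to one-step reaction norm models.

Downstream, the package turns posterior draws into the quantities G×E
studies report: environmental gradient levels from ascending CG
solutions, additive variances along the gradient from the covariance
function `σ²_a(X) = σ²_i + X²σ²_l + 2Xσ_il`, per-gradient heritabilities
(draw-wise mean ± SD), between-gradient genetic correlations, and a
classification of sires by environmental sensitivity (Extremely Robust /
Robust / Plastic / Extremely Plastic at 1/2/3 SD of the slope
distribution). A synthetic-data module simulates pedigreed multi-herd
populations with known parameters; it is the test surface for everything
else.

## Worked example

Simulate a 40-herd-group population with a modest, realistic level of
G×E, apply the standard edits, fit, summarize, classify:

```r
library(rngxe)

cfg <- sim_config(n_founders = 200, n_generations = 2, n_cgs = 40,
                  cg_mean_size = 15, true_G = gen_cov(100, 0.05, 1.5),
                  sigma2_cg = 150, sigma2_pe = 30, sigma2_e = 200, seed = 42)
ped <- simulate_pedigree(cfg)
sim <- simulate_phenotypes(ped, cfg)
ed  <- apply_edits(sim$phenotypes, min_cg_size = 5, min_progeny = 3)

fit <- fit_reaction_norm(ed$records, ped,
                         rn_config(n_iterations = 15000, burn_in = 3000,
                                   thin = 5, seed = 7, prior = "flat"))
gradient_summary(fit, k = 5)
class_percentages(classify_sires(sire_slopes(fit, ed$records)))
```

Output (as printed by the code above):

```
One-step reaction norm fit: 428 records, 800 animals, 39 contemporary groups
Chain: 15000 iterations, burn-in 3000, thin 5 (2400 saved draws)
Posterior means: sigma2_i=138 sigma2_l=0.0994 sigma_il=1.65
  sigma2_cg=120 sigma2_pe=33.5 sigma2_e=156

Environmental gradient summary (5 levels)
 level        X n_cgs sigma2_a_mean sigma2_a_sd h2_mean  h2_sd
     1 -13.0747     8         111.4       37.14  0.3663 0.1027
     2  -3.8336     8         126.4       37.56  0.3972 0.1017
     3  -0.0461     8         137.4       40.18  0.4169 0.1025
     4   5.7543     8         159.8       48.58  0.4518 0.1055
     5  12.3571     7         193.5       66.69  0.4945 0.1111

Posterior mean genetic correlations between levels:
      L1    L2    L3    L4    L5
L1 1.000 0.965 0.936 0.887 0.832
L2 0.965 1.000 0.995 0.976 0.944
L3 0.936 0.995 1.000 0.992 0.971
L4 0.887 0.976 0.992 1.000 0.993
L5 0.832 0.944 0.971 0.993 1.000

  ER    R    P   EP
70.5 24.8  3.8  1.0
```

Read it as a G×E study would: additive variance and heritability increase
from the poorest (level 1) to the best (level 5) environments; genetic
correlations are high between adjacent gradients and lowest (0.83)
between the extremes; and 95% of sires are robust or extremely robust —
their ranking would barely change across environments. The true simulated
values behind this fit (σ²_i = 100, σ²_cg = 150, σ²_pe = 30, σ²_e = 200,
slope SD ≈ 0.22) sit inside the posterior intervals.

The five stages can also be run as one call with a manifest:

```r
run_pipeline(pipeline_config("smoke", seed = 4), out_dir = "run1")
```

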