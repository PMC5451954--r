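# stmixmap

Bayesian space–time **mixture** disease mapping for small-area count
panels, for one to three diseases jointly.

Epidemiologists mapping county-level cancer incidence face three
entangled problems: counts are small (and often *censored* by the data
provider, who recodes 1–4 as "5" and 5–9 as "10"); risk varies over
space, over time, and in their interaction; and a rare disease can
borrow strength from a commoner disease with shared risk factors.
`stmixmap` addresses all three: truncated-Poisson imputation of
threshold-coded counts, a family of spatio-temporal mixture models with
shared components across diseases, a bespoke adaptive
Metropolis-within-Gibbs sampler, and WAIC/MSPE model comparison with
per-disease and year-window decomposition.

## The model

Counts follow a conditionally independent Poisson law,

```
y_ijk ~ Poisson(e_ijk · θ_ijk),        e_ijk = rate_k · n_ij,
```

for county *i*, year *j*, disease *k*, with expected counts `e` built
from the overall disease rate and the population at risk `n_ij`.  The
log relative risk is a convex mixture of component predictors with
county–disease-level weights:

```
log θ_ijk = α_0k + Σ_h p_ikh · M_ijkh,     Σ_h p_ikh = 1,  p_ikh ∈ [0,1].
```

Components (S = spatial, T = temporal, ST = spatio-temporal):

| variant | components | temporal walk γ | weight construction |
|---|---|---|---|
| F2PRED | S, ST | shared γ_j inside M_ST | logit(p_ik) = z_ik + a_ik |
| Alt1 | S, ST | disease-specific γ_jk | logit(p_ik) = z_ik + a_ik |
| Alt2 | S, T, ST | shared γ_j in its own M_T | p_ikh = q_ikh / Σ_h q_ikh, logit(q_ikh) = z_ikh + a_ikh |
| Alt3a | S, ST | shared, scaled: ρ_k γ_j | as F2PRED |
| Alt3b | S, ST | shared, powered: sign(γ_j)\|γ_j\|^ρ_k | as F2PRED |

with `M_S = X_i'β_kS + u_ik + v_i` and
`M_ST = X_ij'β_jkST + X_j'β_kT + γ + φ_ijk` (Alt2 moves the temporal
terms into their own `M_T`).  Here `u` is an uncorrelated spatial
effect, `v` an intrinsic-CAR correlated spatial effect **shared across
diseases**, γ a first-order random-walk temporal effect, φ an iid
space–time interaction, and the mixture logits combine a CAR-correlated
field `z` with an iid field `a`.  All random-effect standard deviations
carry Unif(0, C) priors (C = 10 by default).  In the univariate case
Alt1 and F2PRED coincide.  The fitted weights have a variance-share
reading: a county with `p = (0.1, 0.5, 0.4)` has 10% of its risk
variability explained by spatial, 50% by temporal and 40% by
spatio-temporal effects.

## Worked example

Simulate a censored 8×8-county, 10-year panel with known fixed effects,
undo the censoring, fit the univariate Alt1 model, and inspect recovery:

```r
library(stmixmap)
spec <- modelSpec("Alt1", nDiseases = 1)
ds <- syntheticDataset(spec, rows = 8, cols = 8, J = 10, seed = 7,
                       signal = signalSettings(betaS = 0.5, betaT = -0.3))
frame <- addExpectedCounts(ds$codedFrame)      # rates from coded values
frame <- imputeThresholded(frame, ds$scheme, seed = 7)
frame <- recomputeExpected(frame)              # e used for fitting
fit <- runMcmc(frame, ds$graph, ds$cov, spec,
               mcmcConfig(nChains = 2, nBurnin = 2000, nSamples = 1000, seed = 7))
```

Output (about half the cells were threshold-coded and imputed):

```
coded cells imputed: 292 of 640
beta_S: 0.38 (95% CI 0.24, 0.61)   true 0.5
beta_T: -0.48 (95% CI -1.11, -0.12)   true -0.3
corr(posterior-mean gamma, true gamma): 0.98
mean spatial mixture weight p_S: 0.69
 measure window      D1     all
    WAIC   full 3258.56 3258.56
      pD   full   98.81   98.81
    MSPE   full   32.21   32.21
```

Both 95% credible intervals cover the generating coefficients, the
recovered temporal walk tracks the truth (r = 0.98), and the mixture
weight leans spatial, matching the generating world.  `fitTable()`
produces the WAIC / pD (effective parameters) / MSPE table, optionally
split by disease and year window for comparing variants; lower WAIC and
MSPE indicate the better model.

A command-line front end over the same functions
(`simulate` / `impute` / `fit` / `assess` subcommands) is in
`inst/scripts/stmixmap.R`.

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch on
synthetic lattice data — simulate a censored bivariate panel, impute,
fit by MCMC, and produce the goodness-of-fit table — and writes its
results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/spacetime-mixture-models.Rmd` documents the model family and
priors, the sampler's numerical choices (adaptation, recentering,
coloring), what the synthetic-data generator does and does not emulate,
and known limitations.
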