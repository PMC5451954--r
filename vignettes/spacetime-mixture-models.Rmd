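---
title: "Space-time mixture models for multivariate disease mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-time mixture models for multivariate disease mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stmixmap)
```

# The model family

`stmixmap` fits Bayesian disease-mapping models to complete
county × year × disease count panels.  The likelihood is conditionally
independent Poisson, $y_{ijk} \sim \mathrm{Pois}(e_{ijk}\theta_{ijk})$,
with expected counts $e_{ijk} = \mathrm{rate}_k \cdot n_{ij}$ acting as
an offset.  The log relative risk is a *mixture* of component
predictors,

$$\log\theta_{ijk} = \alpha_{0k} + \sum_h p_{ikh} M_{ijkh},
\qquad \sum_h p_{ikh} = 1,\; p_{ikh}\in[0,1],$$

so each county–disease pair decides, through its weights, how much of
its risk variability is attributed to the spatial, temporal, and
spatio-temporal blocks.  The components are

* $M_S = X_i'\beta_{kS} + u_{ik} + v_i$ — spatial covariates, an iid
  spatial effect $u_{ik}\sim N(0,\tau_{uk}^{-1})$, and an intrinsic-CAR
  correlated effect $v_i \sim N(\bar v_{\partial i}, 1/(n_i\tau_v))$
  shared across diseases;
* $M_T = X_j'\beta_{kT} + \gamma_j$ — temporal covariates plus a
  first-order random walk $\gamma_j \sim N(\gamma_{j-1},
  \tau_\gamma^{-1})$ (a separate component only in Alt2);
* $M_{ST} = X_{ij}'\beta_{jkST} + \phi_{ijk}$ (+ the temporal terms,
  for the two-component variants) — per-year spatio-temporal
  coefficients and an iid interaction
  $\phi_{ijk}\sim N(0,\tau_{\phi k}^{-1})$.

The five variants differ only in how the temporal walk enters:
**F2PRED** shares $\gamma_j$ across diseases inside $M_{ST}$; **Alt1**
makes it disease-specific ($\gamma_{jk}$; identical to F2PRED when
$K=1$); **Alt2** gives the shared walk its own component and weight
$p_{ikT}$; **Alt3a** scales the shared walk per disease,
$\rho_k\gamma_j$; **Alt3b** raises it to a per-disease power.  Alt3
variants are defined only for bivariate/multivariate fits, since a
per-disease scaling is meaningless with one disease.

Mixture weights are built from two logit fields: a CAR-correlated field
$z$ (spatially smooth preference) and an iid field $a$ (county-level
idiosyncrasy).  Two-component variants use
$p_{ik} = \mathrm{logit}^{-1}(z_{ik} + a_{ik})$; Alt2 uses the
normalized construction $q_{ikh} = \mathrm{logit}^{-1}(z_{ikh} +
a_{ikh})$, $p_{ikh} = q_{ikh}/\sum_h q_{ikh}$, which keeps the three
weights on the simplex by construction.

Multivariate information borrowing happens through the effects written
*without* a disease subscript: $v_i$ always, and $\gamma_j$ in every
variant except Alt1.  These are stored once and read by every disease's
predictor — an invariant the test suite asserts structurally.

# Priors and tunable parameters

* Intercepts $\alpha_{0k} \sim N(0, \tau_a^{-1})$ and all fixed effects
  $\beta \sim N(0, \tau_\beta^{-1})$, precisions treated like the rest.
* Every standard deviation $\sigma = \tau^{-1/2}$ has a $U(0, C)$
  prior.  `C` defaults to 10 on the log-relative-risk scale —
  effectively uninformative for epidemiological risk surfaces — and can
  be set per effect family in `modelSpec()`.
* Alt3a: $\rho_k \sim N(0, \tau_{\rho k})$ with $\sigma_\rho \sim
  U(0,C)$; Alt3b: $\rho_k \sim \mathrm{Gamma}(2, 1)$ (mean 2), support
  $\rho_k > 0$ enforced.
* `timeVaryingBetaST` (default `TRUE`) gives each study year its own
  spatio-temporal coefficient vector $\beta_{jkST}$ with iid normal
  priors, honoring the year subscript in the model table; switching it
  off collapses them to one time-constant vector.
* For Alt2 the three CAR logit fields of a disease share one precision
  (`sharedTauZ = TRUE`), since the model table writes a single
  $\tau_p$; a per-component option exists because the original notation
  is ambiguous.

Design decisions taken where the notation was open:

* $N(m, \tau^{-1})$ is read as mean/variance (precision
  parameterization) throughout.
* Alt3a's scaling is read as $\rho_k \cdot \gamma_j$, the "scaling
  coefficient per disease" of the verbal description, rather than the
  typographically garbled power form.
* Alt3b's power of a possibly negative walk value is undefined for
  non-integer $\rho$; it is implemented sign-preservingly as
  $\mathrm{sign}(\gamma_j)|\gamma_j|^{\rho_k}$ (0 maps to 0), which is
  monotone and reduces to the identity at $\rho_k = 1$.
* Adjacency is user input (GAL or edge list); nothing in the method
  fixes a queen-vs-rook rule, so the package does not guess one.  The
  synthetic lattice uses rook contiguity.

# Censored counts

Data providers commonly recode small counts; the default
`ThresholdScheme` maps true counts 1–4 to the code 5 and 5–9 to 10.
Zeros are true zeros and are never treated as codes.  The imputation
pipeline is two-pass:

1. overall rate per disease = total (coded) incidence / total
   person-years; expected counts $e = \mathrm{rate}\cdot n$;
2. each coded cell is replaced by a draw from
   $\mathrm{Pois}(e_{ijk})$ *truncated* to its code's interval —
   sampled exactly by inverse-CDF on the finite support (the intervals
   are tiny, so exactness costs nothing); if the interval carries
   essentially no Poisson mass the draw falls back to a uniform on the
   interval with a warning;
3. expected counts are then *recomputed* from the imputed counts; these
   are the $e$ used in model fitting, and per disease they sum exactly
   to the imputed totals.

The cell-level mean $e_{ijk}$ parameterizes the truncated Poisson (the
method statement does not pin down year-specific versus whole-study
means; the cell-level choice respects county size and is documented
here).  Imputation is single-pass by design: no imputation uncertainty
is propagated into the posterior.

# The sampler

No conjugate updates exist under a Poisson likelihood with uniform
priors on SDs, so the sampler is Metropolis-within-Gibbs with Gaussian
random-walk proposals throughout:

* **Blocking and vectorization.**  Effects whose likelihood cells are
  disjoint (per-disease intercepts and $\beta$ blocks, $u$, $\phi$, the
  $a$ fields, per-year $\beta_{jkST}$) are proposed jointly and
  accepted element-wise.  The CAR fields ($v$, $z$) and the random walk
  ($\gamma$) are updated by *graph coloring*: sites of one color have
  no neighbors in common, are conditionally independent given the rest,
  and can be accepted simultaneously.  This gives single-site
  correctness at vectorized speed in pure R.
* **Adaptation.**  Proposal scales adapt every 50 iterations toward a
  0.44 acceptance rate — the scalar-update optimum — during burn-in
  only, and are frozen afterwards so the post-burn-in chain has the
  correct stationary law.
* **SDs** are updated on the log scale with the Jacobian, against the
  exact conditional kernel (iid, ICAR with rank $I - G$ for $G$ graph
  components, or RW1 with rank $J-1$), and rejected outside $(0, C)$.
* **Recentering.**  The ICAR and RW1 priors are improper (invariant to
  a level shift).  After each sweep $v$ and $\gamma$ are recentred to
  sum to zero — the convention WinBUGS' `car.normal` uses; their levels
  are intercept-like and otherwise drift.  The mixture logit fields $z$
  are deliberately **not** recentred: the level of $z$ *is* the overall
  component preference, a direction the posterior identifies (the model
  has no separate mixture-intercept to absorb it), and projecting it
  out pins every county's weights near equality.  With county-varying
  weights no exact compensation into $\alpha_{0k}$ exists, so the
  recentering is the standard uncompensated approximation; the
  posterior is proper regardless because $\alpha_{0k}$ has a proper
  prior.
* **Validation.**  `interceptOnly` and `priorOnly` switches reduce the
  model so the chain can be checked against a deterministic grid
  integration of the exact posterior, and against the known $U(0,C)$
  prior moments of a SD — both are acceptance tests.
* Posterior-predictive counts $y^{rep} \sim \mathrm{Pois}(e\theta)$ are
  drawn at every retained iteration; the pointwise log-likelihood
  matrix is stored for WAIC.

Defaults mirror the published analysis (2 chains, 45,000 burn-in,
5,000 retained draws); every test uses heavily scaled runs (hundreds to
a few thousand iterations), because run length is a budget choice, not
a correctness requirement.  Convergence is summarized by the classic
Gelman–Rubin statistic with the (package's, not the method's)
convention that $\max \hat R < 1.1$ counts as converged.

# Model assessment

* **WAIC** uses the variance-form effective-parameter penalty:
  $\mathrm{lppd} = \sum_c \log(\frac1S\sum_s e^{\ell_{sc}})$ (log-sum-exp
  stabilized), $p_{\mathrm{WAIC}} = \sum_c \mathrm{Var}_s(\ell_{sc})$,
  $\mathrm{WAIC} = -2(\mathrm{lppd} - p_{\mathrm{WAIC}})$.  The fit
  tables label $p_{\mathrm{WAIC}}$ as "pD", interpreting the published
  tables' effective-parameter row within the WAIC framework they adopt.
* **MSPE** is the mean over cells *and* posterior-predictive draws of
  $(y^{rep}-y)^2$ — full predictive draws, not plug-in posterior means,
  which is consistent with the large magnitudes such tables show under
  misfit; `mspe(..., plugin = TRUE)` scores the posterior-mean
  prediction instead, and `dic()` offers the deviance-based criterion
  for comparison without being the headline measure.
* Both decompose over disjoint cell sets, so `fitTable()` reports every
  disease × year-window combination (windows are closed, inclusive
  calendar-year ranges) and per-disease values sum to the all-disease
  row.
* WAIC differences between two fits come with the usual pointwise
  standard error (`waicCompare()`); the package reports the SE and
  leaves "statistical equivalence" judgements to the user rather than
  inventing a bolding rule.
* `randomComponentSummary()` reports the posterior of the total random
  component $p_{ikS}(u_{ik}+v_i) + p_{ikT}\gamma_j +
  p_{ikST}\phi_{ijk}$ (its two-component analogue otherwise) — the
  total confounding adjusted for by the model — and the mixture weights
  with their variance-share reading.

# The synthetic world

The generator states one fixed world per run and every default is a
modelling choice, not a tuning knob:

* rook-contiguity lattice counties; populations log-uniform on
  $[10^4, 5\times10^5]$, matching the county-size spread implied by
  realistic case ranges;
* per-disease rates default to $10^{-4}, 3\times10^{-4},
  8\times10^{-4}$ per person-year — the magnitudes of a rare, a
  moderate and a common cancer — so the default censoring scheme
  actually bites (roughly half the cells of the rarest disease);
* true states are drawn from the generative priors: centered ICAR
  fields by generalized-inverse (eigendecomposition) sampling, centered
  RW1 walks, iid normal $u/\phi/a$, fixed user-stated $\beta$;
* signal defaults (`signalSettings()`): $\sigma_u = 0.1$,
  $\sigma_v = 0.4$ (correlated spatial structure dominates the
  uncorrelated, as fitted disease-mapping models typically find),
  $\sigma_\gamma = 0.25$ (a visible decade-scale drift),
  $\sigma_\phi = 0.1$ (interaction as small noise), mixture-logit SDs
  0.75 and mean 0 (equal prior weights).

What a green test does and does not establish: the generator emulates
the *structure* of real surveillance data (lattice adjacency, censored
small counts, mixture-form risk), not its substance — no real county
geography or demography, no covariate fields with real spatial
autocorrelation, no age structure or standardization, and populations
constant over years.  Parameter-recovery and variant-discrimination
tests therefore validate the estimation machinery, not any
epidemiological conclusion.

# Known limitations

* Mixture weights are only weakly identified when one component's
  field is absent from the data; their posteriors then lean on the
  prior geometry.  This is a property of the model class, visible in
  the wide weight intervals at small grids.
* The uncompensated recentering of $v$ and $\gamma$ is an approximation
  (exact only when weights are county-constant); it is the established
  practice for these models and is confined to two intercept-like
  directions.
* Fixed effects inside a mixture component are attenuated at small
  sample sizes because only the product $p\,\beta$ enters the
  predictor; credible intervals remain calibrated at moderate grid
  sizes (the 8×8 recovery test).
* No proper/Leroux CAR, no RW2, no spatially correlated interactions,
  no HMC backend, and no propagation of imputation uncertainty — all
  out of scope by design.
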