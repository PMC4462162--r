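---
title: "Familiality and SNP heritability of depression subphenotypes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Familiality and SNP heritability of depression subphenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famvar)
```

## The problem

Age at onset (AAO) and episodicity (lifetime episode count per year of
illness) are the two subphenotypes most often used to cut the heterogeneity
of major depressive disorder. Whether they are themselves familial and
heritable is the question this package's workflow answers, on two
complementary designs:

* **families**: affected full siblings, where the correlation of a trait
  between siblings (the intraclass correlation, ICC) measures familial
  aggregation and bounds narrow-sense heritability from above; and
* **unrelated cases**: genotyped individuals, where the genetic relationship
  matrix (GRM) built from common SNPs identifies the variance those SNPs tag
  (SNP heritability), a lower bound on narrow-sense heritability.

The two bounds bracket the additive genetic control of each subphenotype.

## Track one: familial aggregation

### Age at onset

AAO is right-skewed, so it is modelled on the square-root scale. The
three-level linear mixed model is

$$\sqrt{\mathrm{AAO}}_{ijk} = x_{ijk}'\beta + c_k + f_{jk} + e_{ijk},$$

with subjects $i$ nested in families $j$ nested in centres $k$,
$c_k \sim N(0, \sigma^2_c)$, $f_{jk} \sim N(0, \sigma^2_f)$,
$e_{ijk} \sim N(0, \sigma^2_e)$, and sex (optionally age) as fixed
covariates. `fit_lmm_nested()` obtains the REML optimum through lme4; the
package evaluates its own closed-form restricted likelihood for the nested
structure (Woodbury identity over the sparse random-effects design), which
serves two purposes: an exact cross-check of the optimum in the tests, and a
numerically differentiated Hessian giving the covariance of the variance
parameters, which lme4 does not expose and which the delta-method ICC
intervals require.

The family-level **residual ICC** is
$\sigma^2_f / (\sigma^2_f + \sigma^2_e)$ — the expected correlation between
two siblings *conditional on centre*. Whether the centre variance belongs in
the ICC is a modelling choice the data cannot settle; centre is a nuisance
stratum here, so the default conditions on it, and
`residual_icc(include_center = TRUE)` gives the other convention. Confidence
intervals are computed on the logit scale and back-transformed (a symmetric
Wald interval is also reported); the published interval for the reference
ICC of 0.278 (0.185–0.395) is visibly asymmetric, which the logit scale
reproduces naturally.

Age adjustment matters because onset is a component of age: siblings
correlated in age are mechanically correlated in onset. Both the
unadjusted (sex-only) and age-adjusted models are fitted; the adjusted ICC
is expected to be smaller.

Evidence for familiality is the boundary likelihood-ratio test of
$\sigma^2_f = 0$. Because the null value sits on the parameter boundary,
the statistic is referred to the 50:50 mixture of a point mass at zero and
$\chi^2_1$: `p = 0.5 P(chi2_1 > LRT)`.

### Episode counts

Lifetime episode counts are overdispersed; episode frequency is a rate over
exposure (illness duration). The package fits the two-level
negative-binomial mixed model

$$y_{ij} \mid b_j \sim \mathrm{NB2}(m_{ij}, \alpha), \qquad
\log m_{ij} = x_{ij}'\beta + \log d_{ij} + b_j,$$

with NB2 conditional variance $m + \alpha m^2$, exposure offset
$\log d_{ij}$ (duration floored at 0.5 years so the log stays finite) and a
Gaussian family intercept $b_j \sim N(0, \sigma^2)$. Centre enters as
fixed-effect dummies. The marginal likelihood integrates each family's
contribution over $b_j$ by **adaptive Gauss–Hermite quadrature**: the node
grid is recentred at the per-family posterior mode and rescaled by the
posterior curvature at every evaluation, so seven nodes already reproduce a
51-node rule to better than $10^{-4}$ on the fixtures (the tests check this,
and monotone convergence in the node count). The mode search is a damped
Newton iteration vectorised across families; the score and curvature in the
intercept are available in closed form
($\partial\ell/\partial\eta = (y-m)/(1+\alpha m)$).

For counts the Gaussian residual ICC has no direct analogue. The package
uses a variance-decomposition ICC: with marginal expectation $\mu$, the
log-normal family intercept makes the covariance of two siblings' counts
$\mu^2(e^{\sigma^2}-1)$ and the total variance
$\mu + \alpha\mu^2 e^{\sigma^2} + \mu^2(e^{\sigma^2}-1)$, so

$$\mathrm{ICC} = \frac{\mu^2(e^{\sigma^2}-1)}
{\mu + \alpha\mu^2 e^{\sigma^2} + \mu^2(e^{\sigma^2}-1)}.$$

Two conventions needed fixing where the published account leaves room:

* **Exposure scale of $\mu$.** The ICC above depends on the scale at which
  $\mu$ is evaluated, because the Poisson-level term $\mu$ grows linearly
  with exposure while the others grow quadratically. The default evaluates
  $\mu = e^{\beta_0 + \sigma^2/2}$ per unit exposure (the episode *rate*),
  making the ICC exposure-free; `mu_mode = "empirical_mean"` substitutes the
  mean observed rate. The closed form under the default is validated against
  a Monte-Carlo oracle — the Pearson correlation of simulated sibling pairs
  sharing one latent intercept — over a $3\times3$ grid of
  $(\sigma^2, \alpha)$, rather than claimed to replicate any particular
  published variant.
* **Centre variance.** Following the reduced-model bookkeeping of the
  reference design, a centre variance is folded into both $e^{\sigma^2}$
  factors only when explicitly supplied (`center_variance`); the default
  pipeline models centre as fixed dummies, so no centre variance enters.

The ICC is computed on the *reduced* model (no subject-level covariates),
and its standard error by the delta method through the joint covariance of
$(\beta_0, \log\alpha, \log\sigma^2)$ from the numerically differentiated
marginal likelihood. The delta SE is checked against a parametric bootstrap
in the tests (within 25% on a 250-family fixture).

The simpler second method — a Gaussian mixed model for
$\log(\text{count}/\text{duration})$ — is also fitted. On both the synthetic
and the reference data it produces a larger ICC than the count model; the
count model is the one to trust, since the log-rate transform ignores the
Poisson-level sampling variability that the NB model separates out.

### From ICC to maximal heritability

For full siblings, $\mathrm{Cov} = \tfrac12 V_A + \tfrac14 V_D + V_C$.
When dominance ($V_D$) and shared environment ($V_C$) are negligible, twice
the sibling correlation estimates $V_A/V_P$; otherwise it overestimates it.
`maximal_heritability()` therefore reports $\min(2\,\mathrm{ICC}, 1)$ as an
upper bound, with interval limits transformed identically. Sibling data
alone cannot separate $V_D$ and $V_C$; no attempt is made.

## Track two: SNP heritability

The GREML engine is self-contained:

1. **GRM** (`compute_grm()`): GCTA-convention standardised allele sharing,
   $A_{jk} = M_{jk}^{-1}\sum_i (x_{ij}-2p_i)(x_{ik}-2p_i)/(2p_i(1-p_i))$,
   sample allele frequencies, MAF filter 0.01, per-pair SNP counts as
   denominators under missingness.
2. **Relatedness pruning** (`prune_relatedness()`): greedy removal of the
   individual in the most over-cutoff pairs until none remains.
3. **PCs** (`grm_pca()`): top eigenvectors scaled by root-eigenvalue, used
   as fixed covariates (10 by default).
4. **AI-REML** (`fit_greml()`): $y = Xb + g + e$, $g \sim N(0, A\sigma^2_g)$.
   One eigendecomposition of the GRM rotates the model to a diagonal
   covariance, after which every iteration (and any exact-likelihood
   evaluation) is $O(Np^2)$. Average-information steps with an active set at
   the non-negativity floor ($10^{-8}\,\mathrm{var}(y)$), EM-REML fallback
   when an AI step fails or decreases the likelihood, and a boundary snap
   when the likelihood plateaus while a variance creeps to zero. Start
   values $\sigma^2_g = \sigma^2_e = \mathrm{var}(y)/2$; convergence at
   log-likelihood change $<10^{-6}$ with score norm $<10^{-4}$; at most 100
   iterations. $\mathrm{se}(h^2)$ comes from the delta method on the inverse
   AI matrix, and the test of $\sigma^2_g = 0$ uses the same 50:50 boundary
   mixture as track one.

Phenotypes reach GREML as residuals: AAO as mixed-model residuals of
$\sqrt{\mathrm{AAO}}$ (fixed effects plus centre BLUPs subtracted — no
family level exists among unrelated cases); episodicity either as NB
deviance residuals,

$$d = \mathrm{sign}(y-\hat m)\sqrt{2\left[y\log\frac{y}{\hat m}
-\left(y+\tfrac{1}{\hat\alpha}\right)
\log\frac{1+\hat\alpha y}{1+\hat\alpha \hat m}\right]},$$

with $y\log(y/\hat m) := 0$ at $y = 0$ and the Poisson deviance as the
$\hat\alpha\to0$ limit, or as residuals of the log-frequency mixed model.
The deviance residuals use the population-averaged mean (fixed effects plus
offset), since no family effect is estimable for unrelated singletons; a
mode-conditioned option exists for family data. Skewed residuals are
rank-normalised with Blom scores $\Phi^{-1}((r-3/8)/(n+1/4))$ (average
ranks at ties; the reference account does not say how ties were handled).

### Power

In unrelated samples $\mathrm{var}(\hat h^2) \approx 2/(n^2\,\mathrm{var}(A_{jk}))$
with $\mathrm{var}(A_{jk}) \approx 2\times10^{-5}$ on common arrays (for a
simulated panel of $M$ independent SNPs, $1/M$). `greml_power()` and
`detectable_h2()` use the non-central $\chi^2_1$ form; two-sided
$\alpha = 0.05$ is the default because it reproduces both published
detectable heritabilities (0.25 at $N = 3468$, 0.37 at $N = 2368$) — the
reference text does not state sidedness. The detectable $h^2$ scales
exactly as $1/n$.

## The synthetic data

No clinical or genotype data are distributable, so the generator *is* the
study population for every test:

* 691 families (default) of 2–5 affected siblings in 8 centres, sizes
  weighted toward pairs; sex ~ Bernoulli(0.65) (female-majority).
* $\sqrt{\mathrm{AAO}}$ from the three-level Gaussian model with defaults
  $\sigma^2_f = 0.278$, $\sigma^2_e = 0.722$, $\sigma^2_c = 0.05$,
  intercept 5.1 — a true conditional-on-centre ICC of exactly 0.278 and
  onset near 26 ± 10 years. Onsets are floored at 5 years (the floor is
  2.8 SD out, so it essentially never binds and does not attenuate the
  variance components).
* **Age is onset plus a gamma-distributed illness duration** (mean 19 y,
  sd 10 y, floored at 0.5 y). This guarantees onset ≤ age by construction
  (no censoring that would bias the family variance), centres ages near
  45 ± 14 as in adult samples, and mechanically induces the sibling
  age–onset correlation that motivates the age-adjusted model. A truncated
  normal age with onset capped at age would have been the obvious
  alternative; it attenuates the family variance through the cap, which is
  why it was not used.
* Episode counts from the NB mixed model with defaults
  $\beta_0 = \log 0.3$ (0.3 episodes per illness-year), $\alpha = 0.5$,
  $\sigma^2 = 0.25$, duration as exposure — a true rate-scale count ICC of
  0.073. Counts are zero-truncated by resampling (recurrent-MDD
  ascertainment requires at least one episode); truncation is toggleable,
  and parameter-recovery studies use the untruncated model.
* Genotype panels: independent SNPs under Hardy–Weinberg at MAFs uniform on
  \[0.05, 0.5\], 500 causal SNPs by default, phenotype = standardised
  polygenic score scaled to $h^2$ plus Gaussian noise. No linkage
  disequilibrium and no population structure (beyond what a test plants
  deliberately), so passing tests demonstrate the estimators' behaviour
  under their own assumptions — not robustness to stratification,
  LD-dependent tagging, ascertainment by severity, or recall error in
  self-reported counts, all of which affect real data.

One root seed drives deterministic per-stream child seeds, so any table or
panel is bit-reproducible from `(seed)` alone.

## Problem sizes and numerical choices

The test and analysis problem sizes are chosen so each statistical claim is
sharp at desk scale: 5000 families for parameter-recovery checks (ICC
standard errors ≈ 0.01), $N = 1000 \times M = 2000$ for GREML recovery
(theoretical $\mathrm{se}(\hat h^2) = \sqrt{2M}/N \approx 0.063$, matched by
the empirical spread over 30 replicates within 30%), 500 null replicates per
boundary LRT for size calibration (three binomial MC standard errors ≈
0.03), and $6\times10^4$ sibling pairs per cell of the ICC oracle grid.

A note on the relatedness cutoff at desk scale: 0.025 presumes array-scale
marker counts; with $M$ simulated SNPs the null off-diagonal GRM noise has
sd $1/\sqrt{M}$, which exceeds 0.025 for $M \lesssim 1600$. Desk-scale runs
therefore scale the cutoff (the analysis scripts use $5/\sqrt{M}$), and the
pruning tests that exercise 0.025 itself build GRMs with array-scale noise
(sd 0.0015) and planted relatives.

Other numerical choices: variance parameters are optimised on the log scale
with boundaries detected at the transformed lower bound; nlminb's "singular
convergence" is accepted as convergence (it is the expected report at an
$\alpha = 0$ or $\sigma^2 = 0$ boundary); Hessians are central differences
with step $10^{-4}$ on the log scale, symmetrised, with an eigenvalue guard
before inversion; boundary components get zero rows in `varpar_cov` (no
curvature information exists there, and the ICC SE then conditions on the
boundary); Gauss–Hermite nodes come from the Golub–Welsch eigendecomposition
of the Jacobi matrix, so no tables are embedded.

## Known limitations

* AAO is treated as a quantitative trait; a survival formulation (shared
  frailty) would additionally use unaffected relatives and censoring, but
  is a different estimand and is out of scope.
* The NB model treats episodes as exchangeable given the family intercept;
  recurrent-event models with episode-level timing are out of scope.
* $V_D$ and $V_C$ are not separable from sibling data; the maximal
  heritability is honest about being an upper bound, nothing more.
* The delta-method ICC intervals are asymptotic; for few families the
  bootstrap-over-families cross-check in the tests is the safer reference.
* The empirical pairwise ICC estimator is moment-based and can exceed the
  \[0, 1) range on degenerate inputs; it is clipped and intended as an
  oracle, not a headline estimator.
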