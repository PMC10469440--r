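---
title: "Modelling the repeatability of untargeted metabolomics with left-censored hierarchical models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the repeatability of untargeted metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Untargeted LC-HRMS metabolomics yields thousands of features — (m/z,
retention time) entities with an intensity per sample. Before such features
can be used as exposure or disease biomarkers in epidemiology, one needs to
know how *repeatable* they are: if the same person is sampled again months
later, how much of the variation between measurements reflects stable
between-person differences rather than within-person noise? The standard
summary is the intraclass correlation coefficient (ICC), the fraction of
total variance attributable to stable differences.

Two features of real feature tables complicate the estimation:

* **Nondetects.** Many features are absent from a sizeable fraction of
  samples — not because the metabolite is absent but because its signal
  fell below the assay's limit of detection (LOD). Treating nondetects as
  missing-at-random, or substituting a constant such as LOD/2, distorts the
  variance components.
* **Multicentre structure.** When subjects are recruited at several
  centres, samples are nested in subjects nested in centres, and
  between-centre variation (biological or preanalytical) must enter the
  decomposition explicitly.

`metabicc` addresses both with a *multilevel tobit model*: a three-level
nested random-intercept model for natural-log intensities in which values
below the feature's LOD are treated as left-censored observations in the
likelihood.

## The model

For measurement $i$ of subject $j$ at centre $k$:

$$\log y_{ijk} = \beta_0 + x_{ijk}'\beta + u_k^{(3)} + u_{jk}^{(2)} + \varepsilon_{ijk}^{(1)}$$

with independent $u_k^{(3)} \sim N(0, \sigma_3^2)$ (between-centre),
$u_{jk}^{(2)} \sim N(0, \sigma_2^2)$ (between-subject) and
$\varepsilon_{ijk}^{(1)} \sim N(0, \sigma_1^2)$ (within-subject error).
Observations below the feature's LOD — defined as its lowest detected
intensity — contribute $P(y < \mathrm{LOD})$ to the likelihood instead of a
density value. The main estimand is the posterior distribution of

$$\mathrm{ICC} = \frac{\sigma_2^2 + \sigma_3^2}{\sigma_1^2 + \sigma_2^2 + \sigma_3^2},$$

the correlation between two measurements of the same subject at the same
centre. Counting $\sigma_3^2$ in the numerator treats between-centre
differences as true biological differences between the recruited
populations; the *within-centre* variant
$\sigma_2^2 / (\sigma_1^2+\sigma_2^2+\sigma_3^2)$ is reported separately
and is never larger. Both are computed **per posterior draw** and
summarized by the median and the equal-tailed 95% interval, which keeps the
estimate faithful to the joint posterior when components are correlated
(the median of per-draw ratios is not the ratio of medians — see
`icc_three_level()`'s tests for a two-draw counterexample).

A two-level variant drops the centre intercepts; under lognormality it also
admits a closed-form ICC on the original intensity scale,
$(e^{\sigma_b^2}-1)/(e^{\sigma_b^2+\sigma_w^2}-1)$, which is always below
the log-scale value (no such closed form is available for the three-level
nesting, so `icc_two_level_datascale()` refuses three-level draws).
Repeatability classes use the conventional cut-offs: below 0.40 poor,
0.40–0.75 fair, above 0.75 excellent (boundaries read literally:
$[0,0.40)$ / $[0.40,0.75]$ / $(0.75,1]$).

## Inference: Gibbs sampling with data augmentation

The paper-scale engines for this model family are generic HMC samplers;
`metabicc` instead implements the exact conditional structure of this one
model family as a blocked Gibbs sampler in C++:

* **Censored responses** are latent truncated normals, redrawn each sweep
  (inverse-CDF on the log scale, stable far into the tail).
* **Random intercepts** use the hierarchically centred parametrization
  (subject means around centre means around the grand intercept), which
  mixes well when group means are strongly identified.
* **Variance components** carry weakly informative half-$t(3, 0, 2.5\,
  \mathrm{sd}(y))$ priors on the standard deviations, implemented through
  the Huang–Wand inverse-gamma mixture so every update stays conjugate.
  The intercept has a $t(3, \mathrm{median}(y), 2.5\,\mathrm{sd}(y))$
  prior; covariate coefficients are flat.
* **Interweaving.** Centred samplers mix poorly when a variance component
  is near zero, so after each sweep both hierarchical standard deviations
  are re-updated in the non-centred parametrization by a univariate slice
  step (an ancillarity–sufficiency interweaving move). This removed the
  convergence failures we otherwise observed for features with true ICC
  near 0.2.

Defaults mirror common practice for this model family: 4 chains of 10 000
iterations, first half discarded, no thinning; split-$\hat R < 1.05$ and
bulk ESS $> 400$ per variance parameter are required for the convergence
flag (features failing are flagged, never dropped). The analysis scripts
and the validation suite use 2000-iteration chains, which on this problem
size (298 samples, 157 subjects) give estimates indistinguishable from the
defaults; a 50-feature batch at default settings passes the convergence
thresholds for ≥95% of features.

The sampler was validated two ways: against REML (`lme4`) in the
uncensored limit, where the well-identified components ($\sigma_1^2$,
$\sigma_2^2$; hundreds of subjects) agree to about 1%; and against an
independent MCMC engine (JAGS) run on the identical model, priors and
data — posterior medians of all three variance components agree within
Monte-Carlo error both uncensored and at 40% censoring.

### What four centres can and cannot identify

With only four centres, $\sigma_3^2$ has effectively three degrees of
freedom of information, and its posterior under the weakly informative
prior is strongly right-skewed: the posterior median sits near
$0.7\,S_3$ where the REML point estimate is $S_3/3$ ($S_3$ the centre
sum of squares) — roughly a factor two, *regardless of seed or sample
size per centre*. This is a property of Bayesian inference with few
groups, not a sampler defect (JAGS reproduces it), and it propagates into
the reported between-centre variance share, which averages roughly 0.10
when the generating share is 0.06. Users comparing against
method-of-moments estimates should expect this; the subject-level
components and the ICC itself (where $\sigma_3^2$ is small relative to the
total) are far less affected.

## Adjusted model

For covariate-adjusted ICCs the model adds fixed effects for sex, BMI and
a smooth term for age — a centred natural cubic spline basis
(`build_age_smooth()`, default 3 df) whose columns enter as ordinary fixed
effects; `df = 1` degenerates to a centred linear term. Covariates are
standardized internally and coefficients reported on the data scale. The
adjusted ICC computes the same variance ratio on the adjusted model's
components (explained variance is not subtracted from the denominator; on
covariate-free simulations adjusted and unadjusted medians agree within
MCMC error, which is the behaviour that motivates reporting both).

## Preprocessing rules

The feature-level filters run in study order:

1. **Blank filter** — remove features present in *every* blank injection
   unless the representative sample intensity is at least 5-fold the
   representative blank intensity. The summary statistic is the median
   over detected values (configurable; the convention is not fixed by
   common practice).
2. **Detection filter** — keep features detected in at least 40% of
   samples, `>=` on the exact fraction with no rounding.

The per-feature LOD is the lowest detected intensity, computed *after*
filtering. Annotation matches features to a compound database within
±10 ppm (relative to the database mass) and ±0.15 min, ranks candidates by
the normalized combined distance
$|\Delta\mathrm{ppm}|/10 + |\Delta\mathrm{RT}|/0.15$, and caps matches per
feature at 10. When several features map to one compound, only the feature
with the highest posterior-median ICC is reported (ties: narrower credible
interval, then lexicographic feature id, so results are deterministic).

## The synthetic-data generator

Because the model's operating characteristics cannot be verified on real
data (the truth is unknown), `simulate_study()` generates feature tables
with *known* variance components under exactly the model's assumptions.
Defaults emulate a four-centre European serum study: centres of
48/25/43/41 subjects, 90% of subjects with two samples about 107 days
apart, age 60.5 (SD 6.6) years, 61% female, BMI 25.3 (SD 4.1) kg/m².
Feature intensities are lognormal with grand means uniform on log(9–16)
(raw intensities roughly $10^4$–$10^7$), variance components drawn per
feature from $\sigma_1^2, \sigma_2^2 \sim U(0.15, 0.75)$ and
$\sigma_3^2 \sim U(0.01, 0.10)$ — chosen once so the average
between-centre share is about 6% of the total and the true ICC
distribution is centred near 0.5, the regime reported for serum LC-HRMS
features — and per-feature detection targets uniform on 40–100%.
Censoring is applied on the intensity scale after exponentiation: the
threshold is the empirical quantile matching the detection target, values
below it become missing, and the threshold is stored as the feature's true
LOD. Nondetects are emitted as *missing* cells (the alternative encoding,
zeros, is not used; the model treats missing as censored-below-LOD).

What the generator does **not** emulate: chromatographic peak shape, m/z
axes, adducts and isotopes, heteroscedastic technical noise, batch/drift
effects, or correlation between features. Passing recovery tests therefore
show that the estimator inverts its own generative assumptions — a
necessary check, not evidence about assay behaviour on real extracts.

## Validation results computed by this package

The test suite and `scripts/acceptance.R` recompute all of the following
from scratch; none of these numbers is stored:

* **Uncensored limit:** posterior medians of $\sigma_1^2, \sigma_2^2$
  within a few percent of REML on 200 subjects × 2 replicates
  ($\sigma_3^2$: see the four-centre caveat above).
* **Recovery:** over a grid of true ICC ∈ {0.2, 0.5, 0.8} × censoring ∈
  {0%, 20%, 40%} under the four-centre design, mean absolute ICC error
  below 0.10 per cell and pooled 95%-CrI coverage near nominal.
* **Substitution bias:** at 40% censoring the censored likelihood's
  $\sigma_1^2$ is far less biased than LOD/2 substitution on average
  (≈ −0.01 vs ≈ −0.23 at generating value 1). A caveat worth knowing: the
  substitution bias nearly vanishes when the total log-variance is close
  to 1, because $\ln 2 \approx 0.69$ then coincides with the expected
  shortfall of the censored tail mean below the LOD — substitution is not
  *uniformly* terrible, it is unreliably wrong.
* **Data-scale ICC:** the lognormal closed form at
  $\sigma_b^2 = \sigma_w^2 = 1$ matches the Pearson correlation of $10^6$
  simulated replicate pairs to < 0.01 and converges to the log-scale ICC
  as variances shrink.

## Numerical and design choices

* Natural logarithm throughout; ICCs are log-scale unless labelled
  data-scale.
* Truncated-normal draws by inversion with `qnorm(..., log.p = TRUE)`;
  beyond ~8 SD into the tail the draw collapses to the bound.
* Per-feature seeds derive from a master seed (`feature_seed()`), so a
  single-feature refit reproduces its batch row exactly.
* Degenerate inputs: a feature whose observed values have zero spread gets
  a floor prior scale, returns near-zero variance medians, and is flagged
  (`degenerate = TRUE`, ICC reported as `NA`) rather than erroring.
* All-censored features, designs without any replicated subject, and
  non-nested subject/centre labels are rejected up front; in batch runs a
  failing feature is reported as failed and the rest proceed.
* Which subjects provide one vs two samples is random by default;
  `deterministic_repeats = TRUE` reproduces exact counts (141/16 in the
  default design) for structural tests.
* Problem sizes in the shipped scripts (120-feature cohort, 50-feature
  recovery suite, 2000 × 4 MCMC) were chosen so the full workflow runs in
  a few minutes on one core; all scale linearly.

## Known limitations

* The between-centre component is prior-sensitive with few centres (see
  above); with ≥ 20 centres the effect disappears.
* The censored likelihood assumes the left-censoring threshold is exactly
  the per-feature LOD and that intensities are lognormal; real nondetects
  can also arise from interference or misalignment, which this model does
  not represent.
* The annotation score uses mass and retention time only (no isotope
  patterns or MS/MS), so it is a structural stand-in for vendor annotation
  pipelines, not a replacement.
* Exact reproduction of published cohort-level medians requires the
  original deposited dataset and thousands of long MCMC runs; the package
  validates the method's properties at desk scale instead.
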