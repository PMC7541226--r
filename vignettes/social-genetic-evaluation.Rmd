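---
title: "Single-step genomic evaluation with indirect genetic effects"
author: "igeblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic evaluation with indirect genetic effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Group-housed animals influence each other's performance: a pen mate that
competes aggressively for feed depresses the growth of the others.  If part
of that influence is heritable, every animal carries two breeding values
for the same trait: a *direct* genetic effect (DGE, $a_D$) on its own
phenotype and an *indirect* (social) genetic effect (IGE, $a_I$) on each of
its pen mates.  `igeblup` fits the social animal model for average daily
gain of pen-housed pigs,

$$\mathbf{y} = \mathbf{Xb} + \mathbf{Z}_D \mathbf{a}_D +
  \mathbf{Z}_I \mathbf{a}_I + \mathbf{Wu} + \mathbf{Q}_D \mathbf{l}_D +
  \mathbf{Q}_I \mathbf{l}_I + \mathbf{R}_I \mathbf{e}_I + \mathbf{e}_D,$$

where row $i$ of $\mathbf{Z}_I$, $\mathbf{Q}_I$ and $\mathbf{R}_I$ marks
the pen mates of animal $i$ (their indirect genetic, indirect litter and
indirect environmental animal effects), $\mathbf{u}$ is a random
sex-year-month contemporary-group effect, and $\mathbf{l}_D$ the direct
litter effect.  The *classical* animal model is the same equation without
$\mathbf{Z}_I \mathbf{a}_I$; it keeps the indirect litter and indirect
animal terms so that a likelihood-ratio test between the two models (two
degrees of freedom: $\sigma^2_{a_I}$ and $\sigma_{a_{D,I}}$) isolates the
existence of indirect *genetic* effects.

The genetic effects follow
$(\mathbf{a}_D', \mathbf{a}_I')' \sim N(0, \Sigma \otimes \mathbf{C})$
with $\Sigma$ the $2 \times 2$ direct-indirect covariance matrix and
$\mathbf{C}$ a relationship matrix: the pedigree-based numerator matrix
$\mathbf{A}$, or the single-step matrix $\mathbf{H}$ combining $\mathbf{A}$
with a VanRaden genomic matrix $\mathbf{G}$ so that non-genotyped animals
remain in the evaluation.  $\mathbf{G}$ is tuned (scaled and centred) to
match the mean diagonal and off-diagonal of the pedigree block of the
genotyped animals, then blended, $\mathbf{G}_w = w\,\mathbf{G}^* +
(1-w)\,\mathbf{A}_{22}$, because markers do not capture all genetic
variance; `h_inverse` assembles
$\mathbf{H}^{-1} = \mathbf{A}^{-1} + \begin{bmatrix} 0 & 0 \\ 0 &
\mathbf{G}_w^{-1} - \mathbf{A}_{22}^{-1}\end{bmatrix}$ directly.

### Fixed effects and covariates

The fixed part contains sex, the year-by-month-of-birth class, and three
continuous covariates: `sWghtAge` (starting weight linearly standardised to
the mean starting age, treating weight/age as the average growth rate from
birth), `sWghtDev` (the deviation of the date-standardised starting weight
from the pen mean, capturing the competitive disadvantage of entering the
pen lighter than the mates), and the time-averaged number of pen mates
present per day (a stocking-density correction, since removals thin the
pen).  Mean starting age is computed over the phenotyped animals;
within-group means over all penned animals.  Removed pigs keep their
covariates and pen membership -- their indirect effects still acted on the
mates -- but contribute no phenotype record.

## Variance decomposition

With $\bar n$ the average group size at test start and $r$ the mean
additive relatedness among pen mates (both recomputed from the data, never
hard-coded),

* total heritable variance:
  $\sigma^2_{TBV} = \sigma^2_{a_D} + 2(\bar n - 1)\sigma_{a_{D,I}} +
  (\bar n-1)^2 \sigma^2_{a_I}$;
* environmental variance: $\sigma^2_{env} = \sigma^2_u + \sigma^2_{l_D} +
  (\bar n - 1)(\sigma^2_{l_I} + \sigma^2_{e_I}) + \sigma^2_{e_D}$;
* phenotypic variance (social model): $\sigma^2_p = \sigma^2_{a_D} +
  (\bar n - 1)\sigma^2_{a_I} + r(\bar n - 1)(2\sigma_{a_{D,I}} +
  (\bar n - 2)\sigma^2_{a_I}) + \sigma^2_{env}$;
* direct heritability $h^2 = \sigma^2_{a_D}/\sigma^2_p$ and total
  heritability $T^2 = \sigma^2_{TBV}/\sigma^2_p$.

$T^2$ exceeds $h^2$ whenever indirect genetic variance exists with a
non-negative covariance: each animal's genes then act on $\bar n - 1$ pen
mates in addition to itself.

## REML estimation

Variance components are estimated by average-information (AI) REML with
$\mathbf{A}$ as the genetic covariance structure; $\mathbf{H}$ is used for
prediction only, following the two-stage protocol of routine evaluations
(estimating components with genomic relationships is known to shrink
them).  Two numerically equivalent engines are provided:

* the **sparse engine** works on the mixed-model equations: the restricted
  likelihood via $\log|\mathbf{V}| + \log|\mathbf{X}'\mathbf{V}^{-1}
  \mathbf{X}| = \log|\mathbf{R}| + \log|\mathbf{G}| + \log|\mathbf{M}|$,
  the gradient traces via $\mathbf{Z}'\mathbf{P}\mathbf{Z} =
  \mathbf{G}^{-1} - \mathbf{G}^{-1}\mathbf{C}\mathbf{G}^{-1}$ with the
  needed inverse entries taken from the selected inverse of the sparse
  Cholesky factor (Takahashi equations, implemented in C++), and the AI
  matrix from the working vectors $f_k = \mathbf{V}_k \mathbf{P y}$, whose
  projections are one extra multi-right-hand-side solve;
* the **dense engine** forms the phenotypic covariance
  $\mathbf{V} = \sum_k \theta_k \mathbf{V}_k$ explicitly.  It is the
  reference implementation against which the sparse engine is tested, and
  -- because pens make the mixed-model factor fill in heavily -- it is
  also the faster engine up to a few thousand phenotyped animals, so
  `engine = "auto"` prefers it at that scale.

Updates are AI (quasi-Newton) steps taken on log-variances, with the
genetic covariance on its natural scale.  The log parameterisation keeps
variances positive and makes steps multiplicative, which matters because
the social components are two to three orders of magnitude smaller than
the residual; on the natural scale the Newton steps repeatedly overshoot
these small components.  Each step is capped at a factor of 10 per
coordinate and damped Levenberg-Marquardt style until it improves the
likelihood; a few EM-type steps are used for burn-in and as a fallback.
Starting values put 10% of the phenotypic variance on each non-residual
term (covariance zero), the remainder on the residual.  Variances are
floored at $10^{-8}$ of the phenotypic variance and the covariance is kept
inside $|\sigma_{a_{D,I}}| \le 0.99\,\sigma_{a_D}\sigma_{a_I}$; the
convergence test (gradient below `tol`, default $10^{-6}$ on the
standardized scale, or relative likelihood change below $10^{-9}$) ignores
outward gradients on active bounds, since a boundary optimum -- common for
$\sigma^2_{a_I}$ in small herds -- has a genuinely non-zero raw gradient.
Standard errors come from the inverse AI matrix.  In the full pipeline the
social model is warm-started at the classical optimum, which guarantees
the nested likelihood ordering at convergence.

## Forward validation

The herd is split by date: training groups are those whose members were
*all* born before the cutoff, so no pen straddles the split.  Validation
animals' records are removed from the training equations entirely (their
effect columns remain: removed or unphenotyped mates still exert effects).
Predictive performance is the Pearson correlation between corrected
phenotypes $\mathbf{y}_c = \mathbf{y} - \mathbf{Xb}$ (fixed effects from
the full-data social fit with $\mathbf{A}$, by default) and either the
direct genetic effect or the total genetic effect
$TGE_i = \hat a_{D,i} + \sum_{j \ne i} \hat a_{I,j}$ over pen mates $j$.
Prediction bias is the regression slope of $\mathbf{y}_c$ on the genetic
level.  `w_sweep` re-predicts (never re-estimates) across the blending
grid $w \in \{0.05, \dots, 0.95, 0.99\}$; differences between dependent
correlations are tested with the Hotelling-Williams $t$ on $n - 3$ degrees
of freedom.

## The synthetic herd generator

Real herd books of this kind are proprietary, so the generator produces
herds with the structure the analysis assumes: discrete generations with
litters sired from a small per-cohort sire pool; starting weights with
genetic (scaled direct effect), litter and residual components; pens of 10
males or 9 females packed by weight rank within sex and two-week entry
cohort (heavy pigs penned together, so pen assignment is correlated with
genotype); staggered entry within 13 days of the first entrant; about
1.4% of pigs removed before test end; 96% of penned pigs genotyped, with
genotypes gene-dropped along the pedigree on two chromosomes with one
uniform crossover per meiosis (map realism is unnecessary because the
analysis never uses positions).  Defaults reproduce the herd-book summary
statistics of a nucleus herd: pens averaging 9.5-9.6 pigs from about 7.7
litters and 6.6 sires, which the per-cohort sire pool (22 sires per 24
litters) and the litter share of the weight variance control.  The true
variance components default to the published growth-model estimates, and
phenotypes are assembled term by term from the model equation, so the
design-matrix builders can be cross-checked against an independently
summed phenotype.

What the generator does *not* emulate: selection across generations,
genotype-by-environment interaction, sex-specific genetic variances,
linkage disequilibrium beyond two chromosomes, or non-genetic weight
trajectories (a linear growth approximation stands in for the sigmoid
curve).  Passing tests therefore show that the estimators recover the
generating process under the study's design, not that real herds satisfy
that process.

## Problem sizes used by the test suite

The suite exercises every stage at desk scale:

* oracle-equivalence checks run on a 67-pig fixture (the dense GLS/V
  formulas are only tractable there anyway);
* the parameter-recovery experiment uses 100 replicates of ~1,000
  phenotyped pigs (150 litters).  Smaller herds make recovery *harder*
  (wider sampling spread, more boundary truncation of
  $\sigma^2_{a_I}$), so this is a conservative scale choice.  Starting
  weights are drawn without genetic and litter components there: with the
  weight-genetics knob on, pen assignment and the starting-weight
  covariates are correlated with $\mathbf{a}_D$, the exogeneity assumed
  by the model fails, and REML (correctly) recovers *conditional*
  components -- in a 100-replicate run at the default knob the direct
  genetic variance is re-attributed downwards by about 20% into the
  litter and residual terms.  That is a property of weight-based pen
  allocation worth knowing about, not an estimator defect, so the
  recovery experiment simulates under the assumed model;
* the prediction-ordering experiment uses 50 replicates of ~1,200-pig
  genotyped herds (180 litters, 1,200 SNPs) evaluated at the true
  variance components, isolating the prediction comparison from
  estimation noise.  The forward split leaves a validation set spanning
  several months: with a single-month validation window the year-month
  fixed-effect correction absorbs almost all between-pen variation and
  with it the total-genetic-effect signal -- the same sensitivity to the
  correction that multi-month herd tests report.

## Known limitations

* The dense REML engine is capped at 4,000 phenotyped records; the sparse
  engine has no hard cap but its selected inverse grows with the fill of
  the mixed-model factor.
* Sex-chromosome dosages are treated as observed 0/1/2 values without
  male-specific scaling; the HWE filter is waived there, which is the only
  sex-aware step.
* A single blending weight is used for both direct and indirect effects;
  separate weights are deliberately out of scope.
* Unknown parents are treated as unrelated founders (no unknown-parent
  groups or metafounders).
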