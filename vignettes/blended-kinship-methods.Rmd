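---
title: "Blended pedigree–genomic kinship: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blended pedigree–genomic kinship: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the statistical models and their assumptions, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the design
decisions taken where the design was genuinely open. It states no empirical
result that the test suite does not itself compute.

## 1. The model

The unit of analysis is an inbred parental line with an adjusted phenotypic
mean (a BLUE, `blue`) and its standard error (`se`) from an upstream
phenotypic analysis — typically a weighted multi-environment analysis of
testcross trials. The prediction model for the vector of line BLUEs is

$$ y = \mathbf{1}\mu + g + e, \qquad
   g \sim N(0,\, K\sigma^2_g), \qquad
   e \sim N(0,\, \sigma^2_e\,\mathrm{diag}(se^2_i)), $$

with the kinship

$$ K(w) = w\,A + (1-w)\,G_s . $$

* $A$ is the numerator relationship matrix from the full pedigree (tabular
  method; diagonal $1+F_i$ with $F_i$ the inbreeding coefficient).
* $G$ is VanRaden's method-1 genomic matrix, $WW^\top / 2\sum_j p_j(1-p_j)$,
  with dosages column-centered at $2p_j$ using the *observed* allele
  frequencies, so its reference population is the genotyped set itself.
* $G_s = a + b\,G$ rescales $G$ to the pedigree base by solving the
  two-moment system: mean diagonal of $G_s$ equals mean diagonal of $A$
  (average inbreeding), and mean of all elements of $G_s$ equals that of $A$
  (overall relationship). The offset $a$ absorbs old relationships among
  non-genotyped ancestors; the scale $b < 1$ reflects the reduced genetic
  variance of current lines relative to the pedigree founders.
* $w \in [0,1]$ is the pedigree weight: the fraction of additive variance
  treated as residual polygenic. $w=0$ is G-BLUP; $w=1$ is A-BLUP.

The equivalent two-kernel parameterization (AG-BLUP) splits
$g = m + a$ with $m \sim N(0, G_s\sigma^2_m)$, $a \sim N(0, A\sigma^2_a)$,
$\sigma^2_g = \sigma^2_m + \sigma^2_a$. At matched variance components the
two give identical predictions with $w = \sigma^2_a/(\sigma^2_a+\sigma^2_m)$
— an exactness the suite asserts to $10^{-8}$. Under AG-BLUP, $w$ is driven
by the restricted likelihood; under K-BLUP it is chosen to maximize
cross-validated predictive ability. The two need not agree: the
likelihood-optimal weight fits the training data, not the validation lines.

Narrow-sense heritability of line means is reported as
$h^2 = \sigma^2_g/(\sigma^2_g+\sigma^2_e)$.

### Residual weighting

The squared SEs of the BLUEs enter as *known relative* residual weights:
$\mathrm{Var}(e_i) = \sigma^2_e \, se_i^2$. By default the scale
$\sigma^2_e$ is estimated, which keeps the model correct when SEs are only
proportionally right; `fixed_r = TRUE` pins $\sigma^2_e = 1$ so the residual
covariance is exactly $\mathrm{diag}(se_i^2)$, matching the classical
two-stage weighted analysis. The $h^2$ formula above is exactly calibrated
in fixed-R mode; with an estimated scale it remains interpretable when SEs
are near 1 in trait units (as the simulator's defaults guarantee,
$se \sim U(0.8, 1.2)$). This is deliberate: the same code path serves real
two-stage data and simulated data.

## 2. REML implementation

**Single kernel.** The residual-standardized kinship
$D^{-1/2} K_{TT} D^{-1/2}$ ($D = \mathrm{diag}(se^2)$) is eigendecomposed
once; the restricted likelihood is then a cheap function of the variance
ratio $\lambda = \sigma^2_g/\sigma^2_e$, maximized by Brent search
(tolerance $10^{-10}$ on the ratio) with $\mu$ profiled out by GLS at each
step. This is derivative-free, monotone and $O(n^3)$ once per fit. In
fixed-R mode the search is over $\sigma^2_g$ directly.

**Two kernels.** Direct maximization over the three variances: a
Nelder–Mead start on log-variances followed by average-information (AI)
refinement with step halving, accepting only steps that do not decrease the
restricted likelihood; convergence when its relative change drops below
$10^{-8}$ (maximum 200 iterations). Variances are floored at
$10^{-10} \times \mathrm{var}(y)$; a floor hit is flagged as a boundary
estimate, not an error — with strong family structure, $G_s$ and $A$ are
highly collinear and small datasets legitimately pin $\sigma^2_m$ or
$\sigma^2_a$ at zero.

**Likelihood convention.** $-2\ell_R = (n-p)\log 2\pi + \log|V| +
\log|X^\top V^{-1}X| + y^\top P y$ with no dropped constants, so
log-likelihoods are comparable across kinship matrices and between the
single- and two-kernel parameterizations (the Table-1-footnote-style
"maxLL" weight depends on this).

**Predictions.** $\hat g$ is returned for every id in $K$, phenotyped or
not, via the joint covariance $\hat g = \sigma^2_g K_{\cdot T} V^{-1}(y -
\hat\mu)$ — algebraically the mixed-model-equation solution with zero
residual precision on unphenotyped lines. The conditional identity
$\hat g_V = K_{VT}K_{TT}^{-1}\hat g_T$ is kept as a cross-checked test
property rather than the computational path.

**Positive definiteness.** REML needs an invertible covariance; `ensure_pd`
adds $(\epsilon - \lambda_{\min})$ to the diagonal when
$\lambda_{\min} < \epsilon = 10^{-8}$ and logs the repair. Diagonal loading
was chosen over eigenvalue truncation because it is transparent and leaves
off-diagonal structure untouched.

## 3. Genotype quality control

Markers with minor allele frequency below 2.5% or more than 20% missing
calls are removed; both statistics use pre-imputation calls, and imputation
happens strictly after filtering. Missing calls are imputed as independent
$\mathrm{Binomial}(2, \hat p_j)$ draws from the marker's marginal allele
frequency — i.e., two alleles sampled from the allele margin, not a draw
from the genotype-class margin, which would conflate the two distributions.
Imputation is seeded and leaves observed calls untouched; filter-then-impute
is idempotent on its own output.

For the rescaling's "overall relationship" equation the package uses the
mean over *all* elements of the matrix (diagonal included); an off-diagonal
variant is exposed (`use_offdiag = TRUE`, CLI `--rescale offdiag`) because
the convention is not universal.

## 4. Cross-validation design

Fivefold, two schemes, both emulating real selection decisions:

* **W-fam**: within each full-sib family, lines are shuffled (seeded) and
  dealt round-robin across the five folds from a random starting fold, so
  each fold receives $\lfloor n_f/5 \rfloor$ or $\lceil n_f/5 \rceil$ lines
  of every family and remainders are not biased toward fold 1.
* **A-fam**: whole families are shuffled and dealt round-robin, so no family
  is ever split between training and validation.

The fold seed is a deterministic hash of (base seed, scheme, replicate) —
never of the model or weight — so every model and every grid weight sees
identical folds, making differences between models purely model-driven.

Metrics are computed per replicate on the validation predictions *pooled*
across the five folds (per-fold correlations on ~20-line folds are
unstable), then averaged over replicates; the per-replicate values also feed
the spread (SD) reported in summaries. AG-BLUP inside CV re-estimates its
variance components on every training set: it competes as a model, not as a
fixed-weight K-BLUP. Lines without a phenotype for the analyzed trait are
excluded from fold construction. The optimal weight is the grid argmax of
mean predictive ability, ties broken toward the smaller weight (the less
pedigree-dependent model). Note the optimal weight is selected on the same
cross-validation it is reported from — mirroring common practice — so its
quality estimate is mildly optimistic; a nested CV is deliberately out of
scope.

Model comparisons use the Hotelling–Williams t test (Steiger's form,
df = n − 3) for two correlations sharing the realized values as common
variable, applied per replicate to the pooled validation sets; replicate
p-values are summarized by their median, with a paired t test across
replicate-level predictive abilities as a robustness companion. The
aggregation rule is this package's documented choice; the calibration of
the test itself is verified by simulation (type-I error and p-value
uniformity under a constructed null).

### MSEP

Two definitions are computed side by side: mean squared difference between
realized and predicted (default — it penalizes bias *and* imprecision) and
the mean squared OLS residual of realized on predicted (which removes
location and slope bias). The former is always at least the latter; the
reports carry both.

## 5. The synthetic breeding program

The generator replaces a proprietary dataset whose structure it emulates: a
highly structured population of inbred parental lines grouped in full-sib
families with a deep ancestral pedigree. Defaults (chosen once, at roughly
70% of the motivating program's scale, large enough for stable CV and small
enough for minutes-scale tests): 40 founders, 5 intermediate generations of
30 random matings, 60 full-sib families × 8 lines = 480 lines, 1,000
unlinked biallelic SNPs with founder frequencies uniform on (0.1, 0.9), 5%
missing calls, trait mean 0, SEs uniform on (0.8, 1.2), $h^2 = 0.6$,
polygenic share $w_{true} = 0.5$.

Mechanics: founder alleles are Bernoulli($p_j$); every offspring receives
one allele sampled from each parent's pair per marker (true gene dropping —
the allele pair is tracked, not the dosage), so Mendelian sampling variance
among full sibs arises naturally. True additive values are $g = m + a$:
$m = W\beta$ with i.i.d. normal marker effects scaled so
$\mathrm{Var}(m) \approx (1-w_{true})\sigma^2_g$, and
$a \sim N(0, A_{LL}\, w_{true}\sigma^2_g)$ drawn through a Cholesky factor
of the pedigree matrix restricted to the lines (exact target covariance, in
preference to per-meiosis sampling). $\sigma^2_g$ is set to
$h^2/(1-h^2)\cdot\overline{se^2}$ so the realized heritability of line
means matches $h^2$ in expectation. Truth is defined on *pre-masking*
genotypes, so genotype missingness and imputation error degrade estimation,
never the target.

What the generator does **not** emulate — and hence what a green test does
not establish: linkage and LD decay (markers are unlinked; G's information
comes from family structure and drift, not from population-level LD),
selection during pedigree propagation, non-additive architecture,
genotype-by-environment interaction, and the testcross/tester layer (the
pipeline starts from line BLUEs). An optional `selfing_generations`
parameter advances lines by selfing; the default is 0 because the number of
selfing generations in real programs varies and nothing downstream depends
on it.

## 6. Numerical choices and degenerate inputs

* Pedigrees are topologically sorted on construction; cycles and duplicate
  ids are errors naming the offender. Parents never declared as individuals
  are added as founders with a logged message by default (real pedigrees are
  ragged); `strict = TRUE` turns that into an error. Unknown parents
  contribute zero relationship (base-population assumption). Selfing
  records are legal — inbred-line pedigrees require them.
* $A$ is computed densely; at the target scale (≲ a few thousand
  individuals) sparse inverse machinery would add complexity without
  benefit.
* Lines with incomplete parentage form singleton full-sib families for CV —
  the conservative grouping, since it cannot inflate within-family
  relatedness.
* `rescale_g` refuses a singular two-moment system (mean diagonal equal to
  overall mean) and a non-positive scale $b$; `vanraden_g` refuses all-
  monomorphic input; QC refuses to remove every marker; fits refuse fewer
  than 10 phenotyped lines and non-positive SEs.
* REML non-convergence inside CV is recorded (metric missing, counted in
  `n_failed`) and the run continues; a failed fold never aborts a sweep.
* All randomness (simulation, imputation, folds) flows from user-visible
  seeds through a deterministic 31-bit hash; identical seeds give
  byte-identical outputs, which the suite asserts.

## 7. Known limitations

* The blending interpretation of $w$ as "fraction of additive variance not
  captured by markers" is heuristic: $A$ and $G_s$ are not orthogonal, and
  in family-structured populations they are strongly collinear, which makes
  likelihood surfaces flat in $w$ and boundary estimates common at small n.
* Predictive-ability curves over $w$ are typically flat near their optimum;
  a single dataset's argmax is noisy. Shape claims should be (and in the
  acceptance suite are) evaluated on curves averaged over simulated
  datasets.
* No single-step H matrix: all phenotyped lines are assumed genotyped, as
  in the motivating analysis.
* The Hotelling–Williams aggregation across CV replicates (median p, paired
  companion) is a pragmatic choice; replicates share data and are not
  independent, so these p-values are descriptive rather than strictly
  calibrated at the replicate-aggregate level.
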