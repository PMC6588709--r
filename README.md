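# kinblend

Blended pedigree–genomic kinship matrices for BLUP prediction of breeding
values in structured crop breeding populations.

## The problem

Early-stage breeding programs must rank candidate parental lines on their
additive genetic merit. Genomic BLUP (G-BLUP) predicts merit from a
marker-based relationship matrix **G**, but when markers do not capture all
additive variance — low marker density, incomplete linkage disequilibrium
with causal loci, complex low-heritability traits — part of the signal stays
*polygenic* and is better described by pedigree-expected relationships **A**.
`kinblend` implements the blended-kinship approach: predictions use

```
K = w A + (1 − w) Gs ,        0 ≤ w ≤ 1
```

where **Gs** = a + b·**G** is the VanRaden (method 1) genomic matrix linearly
rescaled so its average inbreeding and average relationship match **A** on
the genotyped set (the two matrices then refer to the same base population),
and *w* is the pedigree weight — the fraction of additive variance treated
as residual polygenic. `w = 0` is G-BLUP, `w = 1` is pedigree-only A-BLUP.
The model for line-level BLUEs `y` with standard errors `se` is

```
y = 1 μ + g + e,    g ~ N(0, K σg²),    e ~ N(0, σe² diag(se²))
```

fitted by REML. The package also fits the equivalent two-kernel
parameterization (AG-BLUP), `g = m + a` with `m ~ N(0, Gs σm²)`,
`a ~ N(0, A σa²)`, whose REML estimates imply the likelihood-optimal weight
`w = σa²/(σa²+σm²)`; and it determines the *predictively* optimal weight by
sweeping a grid of `w` under family-structured fivefold cross-validation:

* **W-fam** — every full-sib family is split across folds (validation lines
  have sibs in training);
* **A-fam** — whole families are held out (validation families unseen in
  training).

Prediction quality is scored by predictive ability (Pearson `r` between
predicted additive values and realized line values), the empirical bias
slope of realized on predicted (1 = unbiased, < 1 = inflated predictions),
and mean squared error of prediction; model differences are tested with the
Hotelling–Williams t test for dependent correlations. A gene-dropping
simulator generates synthetic multi-generation breeding populations (full
pedigree, unlinked SNPs with Mendelian transmission, trait BLUEs with
heteroscedastic SEs and a controllable polygenic share `w_true`) so the whole
pipeline is testable without proprietary data.

## Worked example

```r
library(kinblend)

cfg <- sim_config(seed = 2026L)   # 60 families x 8 sibs, 1000 SNPs, h2 = 0.6, w_true = 0.5
sim <- simulate_dataset(cfg)

geno <- impute_missing(qc_filter(sim$geno)$geno, seed = 1L)
A  <- rel_subset(numerator_relationship_matrix(sim$ped), geno_ids(geno))
rs <- rescale_g(vanraden_g(geno), A)
#> rescaling: Gs = 0.209 + 0.892 * G

fit <- fit_two_kernel(sim$pheno, ensure_pd(A), ensure_pd(rs$Gs))
print(fit)
#> <blup_fit AG-BLUP: mu = 0.3762, logLik = -826.868>
#>   variance components: sigma2_g = 1.336, sigma2_m = 0.2355, sigma2_a = 1.1, sigma2_e = 1.024
#>   w_implied (maxLL weight) = 0.824

sw <- run_cv(sim$pheno, A, rs$Gs, sim$families, grid = c(0, 0.3, 0.5, 0.7, 1),
             schemes = c("W-fam", "A-fam"), n_reps = 5, base_seed = 2026L,
             include_agblup = FALSE)
summarize_sweep(sw)[, c("scheme", "w", "r_pa_mean", "bias_mean", "msep_mean")]
#>  scheme   w r_pa_mean bias_mean msep_mean
#>   A-fam 0.0     0.409      0.98      2.17
#>   A-fam 0.3     0.430      1.00      2.05
#>   A-fam 0.5     0.440      1.01      1.99
#>   A-fam 0.7     0.447      1.02      1.94
#>   A-fam 1.0     0.449      1.03      1.90
#>   W-fam 0.0     0.450      1.01      2.10
#>   W-fam 0.3     0.462      1.02      2.00
#>   W-fam 0.5     0.468      1.01      1.94
#>   W-fam 0.7     0.470      1.01      1.90
#>   W-fam 1.0     0.465      1.00      1.87
select_optimal_w(sw, "W-fam")
#> [1] 0.7
```

Reading the output: the rescaling shifted **G** up by 0.209 (old
relationships among non-genotyped ancestors) and shrank it by 0.892 (reduced
genetic variance of the current lines relative to the pedigree base). In
this particular simulated draw the two-kernel fit attributes most additive
variance to the pedigree term (`w_implied = 0.82`), and cross-validated
predictive ability indeed keeps rising toward high `w`, peaking at 0.7
within families — blending beats plain G-BLUP (0.470 vs 0.450) and
within-family prediction beats among-family prediction at every weight.
Single-dataset optima are noisy because the curves are flat near the top;
averaged over 20 simulated datasets the optimum sits in the interior, near
the generating `w_true` (this is exactly what acceptance criterion 6
checks).

## Command line

```sh
Rscript inst/cli/kinblend simulate --out sim --seed 7
Rscript inst/cli/kinblend kinship  --pedigree sim/pedigree.csv --genotypes sim/genotypes.csv --w 0.5 --out kin
Rscript inst/cli/kinblend fit      --pedigree sim/pedigree.csv --genotypes sim/genotypes.csv \
                                   --phenotypes sim/phenotypes.tsv --model AG-BLUP --out fit
Rscript inst/cli/kinblend cv       --pedigree sim/pedigree.csv --genotypes sim/genotypes.csv \
                                   --phenotypes sim/phenotypes.tsv --grid 0,0.2,0.4,0.6,0.8,1 \
                                   --reps 5 --out cv
```

Every output directory contains a `run_manifest.json` (resolved config,
package version, seed) sufficient to reproduce its tables byte for byte.

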