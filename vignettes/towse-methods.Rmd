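---
title: "Testing SNP-set by environment interactions with towse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing SNP-set by environment interactions with towse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(towse)
```

## The problem

Gene-environment (G x E) interactions are one candidate explanation for the
heritability that single-variant association studies leave unexplained, for
example the age dependence of lipid levels. Single-variant interaction tests
have essentially no power for rare variants (minor allele frequency,
MAF < 1%): each variant is carried by a handful of individuals, so the
per-variant interaction coefficient is barely identified. The standard
remedy is SNP-set testing - analyzing all variants in a gene or pathway
jointly - but most SNP-set methods target the marginal genetic effect, not
its modification by an environment.

`towse` implements two permutation score tests for the interaction between
a SNP set and an environmental variable:

* **TOW-SE** - the Test of the Optimally Weighted combination of
  SNP-Environment interactions;
* **VW-TOW-SE** - a variable-weight extension that balances rare- and
  common-variant contributions.

Both accept continuous or binary traits and continuous or binary
environments, and adjust for confounder covariates.

## The model and the residualization step

For individual $i$ with trait $y_i$, environment $E_i$, covariates $Z_i$
and minor-allele dosages $G_i = (g_{i1}, \dots, g_{iM})$ over the $M$
variants of the set, the generating model is a GLM

$$f\!\left(E(y_i)\right) = \alpha_0 + Z_i a + E_i \eta + G_i \varsigma +
 (E_i G_i)\,\beta,$$

with an identity link for continuous traits and a logit link for binary
ones. The null hypothesis is $\beta = 0$: no interaction effect for any
variant in the set.

Rather than fitting the full model, both tests operate on residuals. The
trait and every interaction column $E_i g_{im}$ are adjusted for the
nuisance design (intercept, $Z$, all genotype main-effect columns, $E$):
least-squares residuals $\tilde y_i$ and $\tilde x_{im}$ for the identity
link; for binary traits the trait residual is the response residual
$y_i - \hat p_i$ from the null logistic fit, while interaction columns are
still adjusted by least squares. This choice keeps the permutation scheme
identical across trait kinds: in both cases the residual trait is
exchangeable under the null once nuisance structure has been projected out.

Degenerate adjustment columns are removed before fitting: constants and
exact duplicates are pruned with a report, and any remaining exact linear
dependence is resolved by dropping the dependent columns through the QR
pivot. The latter is deliberate rather than an error: least-squares
residuals depend only on the column space of the design, and exact
dependence among sparse rare-variant dosage columns is routine (a variant
whose carriers are exactly the union of two other variants' carriers
produces one). Interaction columns are never pruned for collinearity; the
statistic tolerates it.

## The TOW-SE statistic

For a weighted combination $\tilde x_i = \sum_m w_m \tilde x_{im}$, the
score statistic for the combined predictor is proportional to the squared
centered cross-product of $\tilde y$ with $\tilde x$, normalized by both
variances. Over all weight vectors it is maximized - exactly so when the
interaction columns are orthogonal, which rare-variant columns nearly are -
by

$$w^0_m = \frac{\sum_i (\tilde y_i - \bar{\tilde y})
                (\tilde x_{im} - \bar{\tilde x}_m)}
               {\sum_i (\tilde x_{im} - \bar{\tilde x}_m)^2}
        = \frac{C_m}{V_m},$$

the covariance-over-variance ratio. The weight grows with the strength of
association, carries its sign, and is large for low-variance (rare-variant)
interaction terms. The reported statistic is

$$T = \sum_{i} (\tilde y_i - \bar{\tilde y})
      (\tilde x^0_i - \bar{\tilde x}^0) = \sum_m \frac{C_m^2}{V_m} \ge 0,$$

computed via the right-hand closed form (one pass, numerically stable); the
weighted-combination form is retained in the test suite as an independent
oracle. The score statistic's normalizing prefactor $n / \sum (\tilde y_i -
\bar{\tilde y})^2$ is permutation invariant and omitted. Interaction
columns with zero variance (for instance a variant carried only by
individuals with $E = 0$, or a singleton-carrier column absorbed entirely
by the genotype main-effect adjustment) are dropped from the sum and
reported; their optimal weight is an uninformative $0/0$.

Significance is evaluated by permutation only: the residual trait is
reshuffled against the fixed interaction residuals, $T$ recomputed, and the
one-sided add-one p-value $(1 + \#\{T_b \ge T\}) / (1 + B)$ reported. Ties
are counted conservatively with $\ge$. An exhaustive mode enumerates all
$n!$ orderings for tiny samples and then reports exact counts without the
add-one correction.

## VW-TOW-SE: balancing rare and common variants

The optimal weights favor rare variants, so TOW-SE can lose power when
common variants also carry interaction effects. VW-TOW-SE splits the set at
a MAF threshold (default 0.01, strict `<` defines rare; the threshold is a
user-facing argument), computes the stratum statistics $T_r$ and $T_c$ on
one shared permutation stream, and mixes them as

$$T_\lambda = \lambda \frac{T_r}{\sqrt{\widehat{var}(T_r)}} +
  (1 - \lambda) \frac{T_c}{\sqrt{\widehat{var}(T_c)}}, \qquad
  \lambda \in [0, 1],$$

taking as test statistic the minimum over $\lambda$ of the permutation
p-value $p_\lambda$. Three realization choices are this package's own:

* **The $\lambda$ grid.** The minimum over the continuous interval is
  realized on the fixed grid $\{0, 0.1, \dots, 1\}$ (configurable):
  $p_\lambda$ is a rank statistic of $B$ permuted values, hence piecewise
  constant in $\lambda$ with at most $B$ jumps, and an 11-point grid is the
  standard realization of min-p statistics at permutation resolution.
* **The variance estimates.** $var(T_r)$ and $var(T_c)$ have no analytic
  form here; they are estimated from the permutation replicates, and the
  standardization also centers by the permutation mean so that the two
  strata mix on comparable scales.
* **Degenerate strata.** If one stratum has no usable interaction column,
  $\lambda$ is pinned to the other endpoint and the test reduces exactly to
  TOW-SE on the remaining stratum. A stratum whose permuted statistics have
  zero standard deviation is standardized to 0 with a warning.

Because the observed minimum p-value is itself selected over the grid, its
significance is evaluated with a single-layer min-p correction on the same
permutations: each permutation's own $\min_\lambda p_\lambda$ (its rank
within the permuted set) forms the null distribution, and the corrected
p-value is the add-one fraction of permutations at least as extreme. No
nested permutation layer is needed because $p_\lambda$ is a rank statistic
of the shared stream; the corrected p-value always dominates the raw
minimum.

## Permutation engine and reproducibility

Permutations reshuffle the residual trait only; the interaction residual
matrix is never permuted. One stream serves $T$, $T_r$, $T_c$ and every
$\lambda$ - both for speed (a single $M \times (B+1)$ cross-product per
set) and because the min-p correction requires paired permuted statistics.
A single integer seed governs a run; per-set streams are derived
deterministically from (seed, set name) so that multi-set analyses are
order independent. The default $B$ is 10,000; the experiment runners below
use $B$ = 1000, which resolves p-values to $10^{-3}$ - sufficient for
rejection decisions at $\alpha \ge 0.01$ while keeping a 1000-replicate
experiment in the minutes range on one core.

## The simulator: what it emulates, and what it does not

The validation design simulates a 10-variant gene - 8 rare variants
(MAF in [0.001, 0.01)) and 2 common (MAF in [0.05, 0.5]) - via a synthetic
haplotype pool: 64 haplotypes with power-law frequencies (jittered
lognormally), each variant's minor allele placed on a random haplotype
subset whose frequency mass lands in the target MAF range. Diploid
genotypes are two independent haplotype draws, so variants sharing
haplotypes acquire weak linkage disequilibrium rather than being
independent columns. The pool matches the *shape* of an empirical
sequenced-gene pool; it does not reproduce any particular gene's haplotype
frequencies, so power curves from it are meaningful as orderings and
trends, not as point values. Type I error, by contrast, is
distribution-free under permutation, so its calibration transfers.

Traits follow

$$Y = 0.5 Z_1 + 0.5 Z_2 + \alpha_1 E + G^T \alpha_2 +
  E\, G_r^T \beta + E\, G_{c1} \beta^c + \epsilon,$$

with $Z_1, E, \epsilon \sim N(0,1)$ i.i.d., $Z_2 \sim$ Bernoulli(0.5), and
$\alpha_1 = 0.015$. The with-main-effect scenario sets $|\alpha_2| = 0.3$
with independent random signs; the no-main-effect scenario sets
$\alpha_2 = 0$. Interaction effects apply to a configurable number of rare
variants (default 4 of 8, drawn at random) with $|\beta_j| = c$ and half
the signs positive (rounded up on odd counts); one designated common
variant carries a positive effect $\beta^c = 2c$. Under the null
($\alpha_2 = \beta = \beta^c = 0$) the analytic trait variance is
$0.25 + 0.0625 + \alpha_1^2 + 1 \approx 1.313$, which the test suite checks
against $10^5$ simulated draws. A binary-environment mode
(Bernoulli(0.5)) is provided alongside the default continuous exposure.

Experiment runners evaluate Type I error (all interaction effects zero;
rejection fractions at $\alpha \in \{0.05, 0.01, 0.001\}$ with exact
binomial intervals) and power over an effect grid ($c$ from 0.02 to 0.1 in
steps of 0.02 by default). The test suite runs the Type I experiments at
the design scale - $n = 2000$, 1000 replicates, $B = 1000$ - and the power
experiment at 300 replicates, sizes chosen so the full suite completes in
minutes while binomial bands remain tight enough to detect miscalibration.

## Numerical choices and limitations

* Zero-variance interaction columns are dropped at a relative tolerance of
  $10^{-12}$ on the centered sum of squares; rank and orthogonality
  tolerances are relative $10^{-8}$.
* Missing genotypes are mean-imputed per variant by default (preserves the
  MAF), with a complete-case alternative; missing phenotype rows are always
  dropped at alignment.
* Minor-allele orientation is enforced at load time and the flip recorded,
  so MAF partitions and weights are well defined.
* The MAF partition uses the sample MAF of the analyzed individuals, which
  near the threshold may disagree with population MAF.
* p-values are bounded below by $1/(B+1)$: genome-wide significance claims
  need correspondingly large $B$ (the default 10,000 resolves to
  $10^{-4}$).
* Asymptotic (non-permutation) p-values are not provided; neither are
  kinship adjustment, dosage genotypes, or reference-panel imputation.
  Analyses of related individuals require pre-selecting an unrelated
  subset.
* Recommended region sizes are roughly 10-30 SNPs: larger regions raise
  power in region-size experiments but also the chance of collinearity
  among interaction columns.

## A worked example

```{r example, eval = FALSE}
library(towse)

# synthetic tutorial data: VCF + phenotype TSV + SNP-set file
paths <- cmd_make_fixtures(tempdir(), n = 500, seed = 7)
geno <- load_genotypes(paths["vcf"])
pheno <- read_sample_table(paths["pheno"], trait = "trait", env = "age",
                           covariates = c("Z1", "Z2"))
sets <- read_snp_sets(paths["sets"])

gxe_interaction_test(geno, pheno, sets, B = 10000, seed = 1)
```

Simulation experiments run from a `sim_config()`:

```{r sim, eval = FALSE}
cfg <- sim_config(n = 2000, replicates = 1000, permutations = 1000,
                  main_effect = TRUE, seed = 1)
run_type1_experiment(cfg, alphas = c(0.05, 0.01))
```
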