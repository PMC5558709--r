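---
title: "Genomic prediction and pleiotropic QTL mapping with flockQTL"
author: "flockQTL authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction and pleiotropic QTL mapping with flockQTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

flockQTL implements a complete analysis chain for multi-trait genomic data
from structured livestock populations: mixed-model phenotype adjustment and
single-trait GWAS, genomic prediction by GBLUP and BayesR with
cross-validation by paternal half-sib family, three multi-trait procedures
for locating pleiotropic QTL, and an independent linear-index validation of
the selected SNPs. Because suitable sheep data sets with both dense
genotypes and tens of wool traits are not publicly deposited, the package
ships a gene-dropping simulator that generates populations with known
pleiotropic architecture; every stage of the pipeline is tested against
that known truth.

# The mixed model

All phenotype modelling starts from

$$ y = 1\mu + Xb + Z_1 a + Z_1 Q q + Z_2\, s.f + e $$

with fixed effects $b$ (flock, sex, age covariates, and any user-declared
categorical or interaction terms), a polygenic effect
$a \sim N(0, A\sigma^2_a)$ under the pedigree numerator relationship matrix
$A$, a breed random effect $q$ acting through pedigree breed proportions
$Q$, a sire-by-flock interaction $s.f$, and residual $e$. Variance
components are estimated by dense average-information REML
(`estimateVarianceComponents()`); heritability is
$\sigma^2_a / (\sigma^2_a + \sigma^2_{sf} + \sigma^2_e)$, excluding the
between-strain breed variance from the denominator.

`adjustPhenotypes()` removes the GLS fixed-effect fit and the BLUPs of the
breed and sire-by-flock effects but deliberately leaves the polygenic
effect in the residual: downstream stages (GWAS, BayesR, GBLUP) re-fit it
under their own covariance structures. Exact idempotence cannot hold for a
BLUP-based adjustment: BLUPs are shrunken, so the residuals retain part of
the intraclass covariance and a second pass removes more of it. On
simulated data re-adjustment is a small perturbation (correlation above
0.97 with the first pass, change of at most a few tenths of a standard
deviation for traits with strong group structure), which is the property
the test suite asserts.

## Association testing

The GWAS fits each SNP one at a time as a fixed effect alongside the
polygenic term. Rather than re-solving the full mixed model per SNP, the
model is rotated once per trait into the eigenbasis of $A$ (restricted to
the phenotyped animals), after which every SNP test is an exact
generalized-least-squares regression with diagonal weights — identical, at
the REML variance components, to the full per-SNP fit, which the test
suite verifies against an explicit GLS oracle. P-values use the normal
reference; at the sample sizes involved the difference from a
t-distribution is negligible.

The analytical false discovery rate for a threshold $P$ with $A$
significant among $T$ tests is
$\mathrm{FDR}\% = 100\,P(1 - A/T) / \big[(A/T)(1 - P)\big]$,
the expected proportion of false positives among the declared discoveries.
Values above 100% are reported as unavailable. This closed form reproduces,
to the printed decimal, every populated worked example in the literature
tables the package's acceptance tests encode.

# Genomic prediction

`buildGrm()` implements the first VanRaden form
$G = ZZ' / 2\sum_j p_j(1-p_j)$ on allele-frequency-centred dosages, with
SNPs at minor allele frequency $\le$ 0.005 excluded. `gblupFit()` solves
the GBLUP equations per cross-validation fold with validation phenotypes
treated as unknown, re-estimating $\sigma^2_g$ and $\sigma^2_e$ by REML on
each fold's training animals (an eigen-decomposition of the training GRM
makes this a one-dimensional profile optimisation). GBLUP is algebraically
identical to SNP-BLUP ridge regression at $\lambda = c\,\sigma^2_e /
\sigma^2_g$; the tests assert this equivalence to $10^{-6}$.

Folds are built from whole paternal half-sib families: crossbred animals
($0.25 < Q \le 0.90$) and straightbreds sharing a sire with a crossbred
are pinned to training, and the remaining straightbred families are
allocated to five folds at random. No validation animal therefore has a
paternal half-sib in training, which depresses accuracy relative to a
random split but reflects how genomic prediction is deployed across
flocks. Accuracy is the validation-set correlation between GEBV and
adjusted phenotype divided by $\sqrt{h^2}$, the standard estimator of the
correlation with true breeding values, and on simulation it agrees with
the directly computed truth correlation within ±0.1.

## BayesR

SNP effects are modelled as a four-component normal mixture with variances
0, 0.01%, 0.1% and 1% of the genetic variance, Dirichlet(1,1,1,1) prior on
the mixture proportions, scaled-inverse-chi-square updates of the genetic
and residual variance levels (class variances stay tied to the current
genetic variance), and a residual polygenic effect with covariance $A$.
The Gibbs sampler is written in C++; the polygenic block is drawn jointly
per iteration by exploiting that, with one record per animal, its
conditional precision is diagonal in the eigenbasis of $A$. Sampler
defaults (10,000 iterations, 4,000 burn-in, two chains) are desk-scale
choices; the reference settings of 40,000/20,000 with five chains are a
configuration away. Chains are compared on their genetic-variance draws
and disagreement triggers a warning, never a hard failure.

One behaviour deserves emphasis. The class variances are *fractions of the
genetic variance* calibrated to dense panels of several hundred thousand
SNPs. There, assigning many null SNPs to even the smallest nonzero class
would imply phantom genetic variance far exceeding the total, so the
likelihood forces the null class towards occupancy near 1 and
`pp_nonzero` of null SNPs towards 0. On a desk-scale panel (6,000 SNPs)
the smallest class variance is below the per-SNP sampling noise
($\sigma^2_e / z'z$), the Bayes factor between class 0 and class 1 is ≈ 1,
and null SNPs therefore sit at the Dirichlet-implied plateau
(`pp_nonzero` ≈ 0.5) instead of 0. Real QTL still stand far above the
plateau, so ranking-based uses (and the local-GEBV method below) are
unaffected, but the absolute multi-PP threshold of 0.3 is meaningful only
at dense-panel scale. The tests assert the scale-appropriate properties:
a QTL explaining 30% of variance reaches `pp_nonzero` > 0.8 within 50 kb,
the null plateau stays well below that, and the large-variance class stays
clean of null SNPs.

# Multi-trait QTL mapping

Three procedures combine single-trait results:

* **multi-GWAS** — for SNP $i$, $\chi^2_i = t_i' V^{-1} t_i$ with $t_i$
  the signed t-values across traits and $V$ their correlation over all
  SNPs, referred to a chi-square with one degree of freedom per trait.
  Near-singular $V$ is shrunk towards the identity by the smallest amount
  restoring an eigenvalue floor of $10^{-6}$, and the amount is recorded.
  Within each 1-Mb tile only the most significant SNP passing
  $P < 5\times10^{-7}$ is kept.
* **multi-PP** — one minus the product over traits of the per-trait
  posterior probability of a zero effect, thresholded at 0.3; contributing
  traits are those with per-trait nonzero probability above 0.05.
* **multi-LGEBV** — per 250-kb window, local GEBV (the window's
  contribution to each animal's SNP-based GEBV) are computed per trait,
  their trait-by-trait covariance is standardized by phenotypic SDs
  ($t_{(y,x)} = \mathrm{cov}_{LGEBV}(y,x)/\sigma_y\sigma_x$), and the
  matrix is eigen-decomposed. Windows are ranked by the first eigenvalue;
  within each selected window a pseudo-trait $S_{LC} = y'x$ (standardized
  local GEBV weighted by the PC1 eigenvector, with unmeasured animals
  given the measured-animal mean) is regressed on every SNP in the window
  under a pedigree animal model, and the highest-F SNP tags the QTL.

Windows are 0-based half-open tiles anchored at position 0 of each
chromosome for both the 250-kb and the 1-Mb grids; eigenvector signs are
fixed by making the largest-magnitude loading positive. The sum of local
GEBV over windows reproduces the whole-genome GEBV to $10^{-8}$, a
conservation law the tests enforce.

`compareMethods()` reports full Venn membership over the three call sets,
by exact SNP identity by default; a proximity merge (single linkage within
a configurable distance) reflects the practice of clustering calls within
1–1.5 Mb. `candidateGenes()` reports genes whose 1-based inclusive span
comes within 50 kb (closed bound) of a called SNP, marking the nearest by
edge distance as primary.

# Linear-index validation

Missing phenotypes are completed by conditional-normal multiple regression
$\hat y_n = -(U^{nn})^{-1} U^{nm} y_m$ on the blocks of the inverse trait
covariance; this equals the familiar
$\Sigma_{nm}\Sigma_{mm}^{-1} y_m$ by the partitioned-inverse identity, an
equality the tests verify on every fixture. The pairwise-complete trait
covariance can be indefinite and is projected to positive definite by an
eigenvalue floor ($10^{-8}$ of the largest), with the shrinkage recorded.
It is estimated on all animals — a deliberate mirroring of the original
procedure, at a small cost in strict train/validation separation that the
configuration exposes.

For each selected SNP, a linear index $y_I = b'C^{-1}y$ collapses the
completed trait vector into a single composite phenotype, where $b$ holds
the SNP's training-population effects and $C$ is the covariance of raw
effect estimates (not t-values) over all SNPs in training. Because the
implied training-set regression coefficient of $y_I$ on the SNP is
$b'C^{-1}b \ge 0$, direction agreement in validation reduces to a positive
validation effect; under a no-QTL simulation agreement sits at 50% and the
significant fraction at the nominal 5%, which the null-calibration tests
confirm.

# The simulator

`simulatePedigree()` builds three generations (grandparent founders, sires
and dams, phenotyped offspring) with nested matings. Breed status is
assigned by whole sire family — a `crossbred_frac` share of families get
offspring with breed proportion $0.25 < Q \le 0.90$ — because family-wise
assignment is what keeps family-based cross-validation feasible.
`simulateGenotypes()` drops founder haplotypes through the pedigree with
Poisson crossovers at 1 cM/Mb, no interference and no mutation. Founder
haplotypes carry built-in linkage disequilibrium from a latent Gaussian
process whose correlation decays as `exp(-d / 500 kb)` (allele frequencies
uniform on [0.05, 0.5] are exact marginals), emulating descent from a
finite ancestral pool; adjacent-SNP r² is then ≈ 0.3–0.4 at the default
SNP spacing, decaying to background beyond a few Mb.
`simulateTraits()` inverts the analysis model: fixed effects of 0.5
phenotypic SD (large enough that skipping adjustment is detectable), a
breed-proportion effect, QTL effects, a pedigree polygenic term with exact
cross-trait correlation, a sire-by-flock effect, and residual, on a scale
where $\sigma^2_a + \sigma^2_{sf} + \sigma^2_e = 1$ per trait.

QTL carry `qtl_var_frac` (default 0.5) of the genetic variance; half of
them (default) are private to one trait so that multi-trait power is
separable from single-trait power. Pleiotropic effect vectors are drawn
from a multivariate normal with the configured genetic correlation and
then rescaled to a common magnitude, so no planted QTL is vanishingly
small; per-trait totals are rescaled exactly to the variance budget. QTL
are placed at least 2.5 Mb apart so each occupies its own mapping window.
Defaults — 2,000 offspring in 50 half-sib families, 3 chromosomes of
50 Mb, 6,000 SNPs, 20 QTL, 8 traits with heritabilities 0.26–0.84,
compound-symmetric genetic correlation 0.4, sire-by-flock fraction 0.05,
30% crossbred families, 10% missing phenotypes per trait — are chosen once
to emulate a wool-trait information-nucleus design at a size where the
full pipeline runs in minutes.

One global seed drives everything through a documented stream-splitting
rule (`splitSeed()`), so fixtures are exactly reproducible.

What the simulator does not emulate: genotyping error and imputation
artefacts, selection, assortative mating, dominance and epistasis, sex
chromosomes, age-repeated records, and the long-range LD of real livestock
genomes beyond what three generations of gene dropping create. Passing
tests therefore demonstrate the correctness and calibration of the
machinery under a known additive architecture, not the field performance
of the methods on real wool data.

# Numerical choices

* AI-REML with step-halving and a positivity floor of $10^{-8}$ times the
  phenotypic variance; convergence at a relative parameter change of
  $10^{-8}$, maximum 50 iterations, non-convergence flagged not fatal.
* A singular GBLUP coefficient matrix receives a ridge of $10^{-8}$ with a
  warning.
* Ties in the per-tile top-SNP selection and the per-window best-SNP
  search break towards the smaller position; eigenvalue ties in window
  ranking break by chromosome then position.
* Monomorphic SNPs are flagged and carry no statistics; they are excluded
  from denominators in validation summaries.
* Missing dosages are mean-imputed only inside the GRM; QC (call-rate,
  MAF, Hardy-Weinberg, then animal call-rate, in that order) is the
  supported path for missing genotype handling.
* The sampler derives chain seeds from the global seed; all randomness in
  C++ uses R's RNG so `set.seed()` governs end to end.

# Problem sizes used by the tests and the acceptance script

Oracle checks run on fixtures of at most 50 animals. Calibration and
recovery checks use the desk-scale population above (2,000 phenotyped
animals, 6,000 SNPs), with BayesR at 2,000 iterations and one chain, and a
dedicated strong-QTL scenario (400 animals, 800 SNPs, one QTL at 30% of
phenotypic variance, 4,000 iterations) for posterior-concentration checks.
These sizes are the package's own choice of a configuration where all
stages complete in minutes while every tested property has adequate power.

# Known limitations

* Multi-trait REML and multi-trait BayesR are out of scope; the three
  multi-trait procedures are deliberate approximations built on
  single-trait fits.
* The multi-PP threshold of 0.3 is not meaningful on sparse panels (see
  the BayesR section); interpret multi-PP at desk scale through its
  ranking.
* No single-step blending of pedigree and genomic information, no
  genotype imputation, and no binary PLINK output.
* The FDR estimator assumes independent tests when interpreting $A/T$; on
  dense panels LD makes it conservative in clusters.
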