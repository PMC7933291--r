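---
title: "Estimating cross-population genetic correlation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cross-population genetic correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xpgreml)
```

## The problem

A complex trait measured in two ancestry groups can be treated as two traits
in a bivariate variance-component model. Writing $V_{g(p_1)}$ and $V_{g(p_2)}$
for the additive genetic variances captured by genotyped SNPs in the two
populations and $C_{g(p_1,p_2)}$ for the cross-population genetic covariance,
the cross-population genetic correlation is

$$ r_g = \frac{C_{g(p_1,p_2)}}{\sqrt{V_{g(p_1)}\,V_{g(p_2)}}} . $$

$r_g < 1$ means that the per-SNP effects differ between the populations —
through genuine effect-size differences, different causal variants, or
different LD between markers and causal variants. `xpgreml` estimates $r_g$
two ways:

* **from individual-level data**, by bivariate GREML: phenotypes of the two
  populations are stacked, each population gets its own genetic and residual
  variance, and the genetic covariance ties the two blocks of a genomic
  relationship matrix (GRM) together;
* **from GWAS summary statistics**, by the errors-in-variables correlation
  $r_b$ of re-estimated SNP effects at clumped sentinel SNPs, which removes
  the attenuation caused by estimation noise.

It also tests whether $r_g$ differs between SNP strata defined by
allele-frequency differentiation ($F_{ST}$) or LD differentiation (LDCV),
using closed-form sampling variances and covariances of $\hat r_g$.

## The bivariate GREML model

For stacked phenotypes $y$ (population 1 first) with fixed effects $X$
(population-specific intercepts plus covariates such as 20 PCs),

$$ y = Xb + g + e, \qquad
   \mathrm{var}(g) = \sum_k
   \begin{pmatrix} V_{g1,k} A_{11,k} & C_k A_{12,k} \\
                   C_k A_{21,k} & V_{g2,k} A_{22,k} \end{pmatrix}, \qquad
   \mathrm{var}(e) = \begin{pmatrix} V_{e1} I & 0 \\ 0 & V_{e2} I \end{pmatrix},$$

where $A_k$ is the GRM of the $k$-th SNP set over all samples. No individual
belongs to both populations, so the residual cross-covariance is identically
zero. Genotypes are standardised as $(x - 2p)/\sqrt{2p(1-p)}$, either with
each population's own allele frequencies (*GRM-specific*; the cross-population
block then has mean zero and $C$ is identified through its realised
variation) or with pooled frequencies (*GRM-average*, which carries a
population-structure signature in its blocks: positive within, negative
between).

### Fitting

`aireml()` maximises the REML log-likelihood
$-\tfrac12[\log|V| + \log|X'V^{-1}X| + y'Py]$ by Newton steps whose Hessian is
replaced by the average-information matrix
$\mathrm{AI}_{ij} = \tfrac12\, y'P K_i P K_j P y$. Design choices that matter:

* **Starting values** are neutral and deterministic: $V_{g,k} = V_p/(2K)$,
  $V_e = V_p/2$ per population, $C_k = 0$.
* **Constraints**: variance components are bounded below at
  $10^{-6} V_p$; $C$ is unconstrained, so $\hat r_g$ may exceed 1.
  Components pinned at the bound are flagged (`boundary`); their SEs are
  unreliable and derived correlations are reported as `NA`.
* **Safeguards**: a step that leaves the positive-definite region or lowers
  the objective is halved up to five times, then retried with
  Levenberg–Marquardt damping of the AI matrix, then replaced by an EM-type
  step. Variances pinned at the bound with an outward gradient are dropped
  from the Newton system (active set). Accepted iterations never decrease
  the objective.
* **Convergence**: $|\Delta \log L| < 10^{-4}$ together with a maximum
  relative parameter change below $10^{-4}$ (or a numerically flat
  objective, which covers bound-pinned parameters).
* **Degenerate instances**: on very small data the likelihood can increase
  without bound along a ridge where $V$ approaches singularity (small
  samples, unconstrained $C$). The fitter detects collapsing Cholesky pivots
  at the optimum, warns, and sets `degenerate = TRUE`; such fits are not an
  interior optimum and downstream comparisons skip them.
* The inverse AI matrix at convergence is the sampling covariance of the
  estimates; $h^2_{\rm SNP}$ and $r_g$ standard errors follow by the delta
  method.

The test of $\hat r_g = 1$ is a Wald test on the delta-method SE, matching
the estimate/SE reporting convention; a profile-likelihood alternative was
considered and not implemented.

## Sampling variance of $\hat r_g$ and the difference test

With the variance-component sampling (co)variances from the joint fit, the
sampling variance of $\hat r_g$ in one SNP set is

$$ \mathrm{var}(\hat r_g) = r_g^2\!\left[
   \frac{\mathrm{var}(\hat V_{g1})}{4V_{g1}^2} +
   \frac{\mathrm{var}(\hat V_{g2})}{4V_{g2}^2} +
   \frac{\mathrm{var}(\hat C)}{C^2} +
   \frac{\mathrm{cov}(\hat V_{g1},\hat V_{g2})}{2V_{g1}V_{g2}} -
   \frac{\mathrm{cov}(\hat V_{g1},\hat C)}{V_{g1}C} -
   \frac{\mathrm{cov}(\hat V_{g2},\hat C)}{V_{g2}C} \right], $$

and the covariance of two sets' estimates is the analogous nine-term
expression over the cross-set sampling covariances (coefficients $1/4$ on
$V\times V$ terms, $-1/2$ on $V\times C$ terms, $1$ on the $C\times C$ term).
Both are exactly the first-order delta-method forms — the test suite verifies
the term-by-term implementations against an independent
gradient–covariance–gradient computation to $10^{-12}$ — and parameters are
replaced by their estimates in practice. At $C = 0$ the $1/C$ factors cancel
against $r_g$ analytically; `var_rg()` and `cov_rg_pair()` use those limits
rather than dividing by zero. The difference between two strata is tested by

$$ \chi^2_1 = \frac{(\hat r_{g1} - \hat r_{g2})^2}
   {\mathrm{var}(\hat r_{g1}) + \mathrm{var}(\hat r_{g2})
    - 2\,\mathrm{cov}(\hat r_{g1}, \hat r_{g2})}. $$

## SNP stratification

`snp_strata()` computes per-SNP Hudson $F_{ST}$ (Weir–Cockerham selectable),
per-population LD scores (windowed sums of bias-adjusted $r^2$,
$r^2 - (1-r^2)/(n-2)$, self term included; window 1,000 kb by default) and
LDCV $= |\ell_1-\ell_2|/(\sqrt2\,\bar\ell)$, the two-value coefficient of
variation. Choices worth knowing:

* **Hudson's estimator** is the default; the $n$ in its finite-sample
  correction is the number of sampled allele copies ($2\times$ individuals),
  which makes the numerator unbiased for the squared frequency divergence.
  The genome-wide mean is computed as a **ratio of averages**
  (`fst_mean()`): the arithmetic mean of per-SNP ratios is not consistent
  for the divergence parameter (its expectation under a Balding–Nichols
  model with $F = 0.1$ is about 0.087 at infinite sample size and about
  0.114 with $n = 2000$/population sampling noise), whereas the ratio of
  averages recovers $F$.
* **Matched bins**: SNPs are cut into equal-count bins on population-1 MAF
  and on the same allele's population-2 frequency (crossed), then into
  equal-count LD-score bins per population *nested within* each frequency
  bin. Equal-count edges were chosen over equal-width because every bin must
  be populated to be splittable. The $F_{ST}$ configuration exposes
  $125 \times 125 \times 4 \times 4 = 250{,}000$ joint bins, the LDCV
  configuration $20 \times 20 \times 25 \times 25 = 250{,}000$.
* **Splitting**: within each bin SNPs are sorted by the metric and halved;
  in odd bins the median SNP goes to either group by a seeded coin flip
  (the documented randomisation for 3-SNP bins, generalised to any odd
  size). Ties break by SNP index, so the split is deterministic given the
  seed. Matching is only meaningful when bins hold a few SNPs each
  (roughly $m \gtrsim 4$ per bin, as with $\sim$1M SNPs in the 250k-bin
  configuration); far below that density most bins are singletons and the
  split degenerates to a random halving, which balances nothing beyond
  chance.

## Summary-statistics branch

`gwas_scan()` is covariate-adjusted least squares per SNP (the synthetic
cohorts are unrelated by construction, exactly the regime where a sparse-GRM
mixed model reduces to linear regression). `clump()` is greedy P-value-ordered
clumping (default $P < 5\times10^{-8}$, $r^2 > 0.01$, 1 Mb window), with a
second 10 Mb round (`clump_two_round()`) to remove long-range LD between
sentinels; LD comes from the scanned genotypes. `rb_estimate()` computes

$$ r_b = \frac{\mathrm{cov}(\hat b_1, \hat b_2)}
  {\sqrt{(\mathrm{var}(\hat b_1) - \overline{se_1^2})
         (\mathrm{var}(\hat b_2) - \overline{se_2^2})}}, $$

a moment-based errors-in-variables correlation whose denominators subtract
the mean error variance from each set's observed effect variance; its SE is a
delete-one jackknife over sentinels. The two summary sets must carry
independent errors (identical inputs are rejected), effects are aligned to a
shared effect allele with sign flips where needed, and a non-positive
corrected variance (noise exceeding signal) yields an explicit `NA`. The
winner's-curse protocol (`split_sample_reestimate()`) re-estimates sentinel
effects in samples disjoint from discovery; `negative_control()` runs
same-population split halves, whose expected $r_b$ is 1.

## The synthetic cohort generator

`simulate_cohort()` produces the study conditions every stage is tested
under:

* **Allele-frequency divergence**: ancestral frequencies uniform on
  [0.1, 0.5] by default; each population's frequency drawn from
  Beta$(p(1-F)/F,\,(1-p)(1-F)/F)$ (Balding–Nichols), whose $F$ maps directly
  onto the $F_{ST}$ axis being stratified. Default $F = 0.1$, the
  genome-wide order of European–African differentiation.
* **LD**: haplotypes from a latent-Gaussian AR(1) process within blocks of
  20 SNPs (adjacent-correlation 0.6 by default), thresholded at each SNP's
  frequency; blocks are independent, and SNPs sit 1 kb apart on one
  chromosome. This gives closed-form control of adjacency correlation; it
  does not reproduce coalescent LD decay, recombination maps, or
  chromosome-scale structure.
* **Effects**: a chosen number of causal SNPs get bivariate-normal effect
  pairs with correlation `rg_true`, applied to standardised genotypes by
  default (matching the GRM model; per-allele scaling available for the
  summary branch). Genetic values are rescaled so the realised heritability
  equals its target exactly in-sample; noise makes the phenotype variance
  about 1.
* **Optional admixture** (per-individual population-1 ancestry fractions for
  population 2, applied per haplotype block) and **uniform missingness**
  support the QC tests; both default off.
* All randomness flows through per-stage child seeds derived from one global
  seed (`child_seed()`), so identical seeds give byte-identical PLINK files
  and any stage can be re-run in isolation.

What passing tests on these data do **not** show: robustness to real LD decay
and haplotype sharing, to assortative mating or shared environment, to
genotyping/imputation error, or to residual relatedness — none of which the
generator emulates.

## QC

The filters mirror common GWAS practice: SNP missingness > 0.05, MAF < 0.01,
HWE exact $P < 0.001$ (standard exact test on genotype counts, no mid-p),
sample call rate < 0.9 (strict), PC1/PC2 outliers beyond 6 reference s.d.,
greedy relatedness pruning above 0.05 (drop the most-connected individual,
ties to the lowest index — deterministic), and per-group phenotype
preparation: outlier removal at a trait-specific s.d. cut (5 for
height-like, 7 for BMI-like traits), covariate regression, then rank-based
inverse-normal transform $\Phi^{-1}((\mathrm{rank}-0.5)/k)$ with average
ranks for ties. Outliers are removed before covariate adjustment, as the
ordering is stated; the $(r-0.5)/k$ offset was chosen with Blom's as the
noted alternative. On synthetic data the PC-outlier reference is the target
population's own mean/s.d. (no external reference panel exists there).

## Problem sizes used by the checks

The package's property checks run on one core in a few minutes; sizes are
chosen so the Monte-Carlo error is small relative to each assertion's band:

* REML-vs-direct-maximisation oracle: five well-posed instances at 30
  individuals/population, 100 SNPs (degenerate-ridge fits are skipped, see
  above).
* Parameter recovery: 20 replicates at 750/population, 1,500 SNPs, 500
  causal, $r_g = 0.7$, $h^2 = (0.5, 0.4)$ — the SE of the 20-replicate mean
  $\hat r_g$ is about 0.02.
* SE calibration and difference-test calibration: 200 replicates each at
  200/population.
* $r_b$ recovery: 50 replicates of 500 sentinel pairs at effect correlation
  0.8; plus a genotype-based same-population negative control.
* $F_{ST}$ round-trip: 10,000 Balding–Nichols SNPs at $F = 0.1$,
  2,000/population. Binning balance: 1M SNPs in the 250,000-bin
  configuration.

The end-to-end pipeline preset (`default_config()`) is desk-scale:
2,000/population, 5,000 SNPs, 1,000 causal; its clumping threshold default is
$10^{-5}$ because genome-wide power at $5\times10^{-8}$ needs far larger
cohorts than the preset simulates (the `clump()` function default remains
$5\times10^{-8}$).

## Known limitations

* Two populations only; no multi-way $r_g$ or >2 strata tests.
* The bivariate likelihood can be unbounded on very small samples
  (flagged, not silently reported).
* Wald-based $P(r_g = 1)$ relies on the delta-method SE, which is
  anti-conservative when $\hat r_g$ sits near boundaries at small $n$.
* LD scores use hard-call genotypes and a single window rule; no
  per-chromosome parallelism.
* The simulator's LD model is block-exchangeable; estimators whose behaviour
  depends on realistic LD decay should be validated on real data.
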