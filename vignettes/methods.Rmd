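---
title: "Methods: multi-tissue TWAS with repeated-measure-aware training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-tissue TWAS with repeated-measure-aware training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

A transcriptome-wide association study (TWAS) asks whether the genetically
regulated component of a gene's expression is associated with a trait. The
pipeline implemented here follows the FUSION-style two-stage design, adapted
to a multi-tissue neocortical cohort in which one individual may contribute
RNA-seq samples from several brain regions while carrying a single genotype
profile:

1. **Ancestry definition.** Variants are filtered (MAF > 1%, missingness
   < 0.1, MAF < 40%), LD-pruned (50 kb windows, pairwise r² ≤ 0.2), and the
   samples are clustered with k-means (k-means++ seeding, default k = 8) on
   every principal component explaining > 1% of genotype variance. The
   analysis set is the union of clusters containing reference individuals
   of the target ancestry.
2. **Expression preparation.** Per tissue, covariates are regressed
   iteratively: each candidate covariate is scored by the median across
   genes of its per-gene simple-regression p-value, all covariates with
   median p < 0.05 are removed jointly, and the loop repeats on the
   residuals. Diagnosis is always regressed, whether or not it reaches
   significance, because allelic effects on expression are largely
   condition-independent. Rows are then standardized to mean 0, sd 1 using
   the sample (n − 1) standard deviation, so the weight-training stage can
   assume pre-scaled input.
3. **Heritability gate.** For each gene, cis-variants within ±500 kb of
   the TSS (a 1 Mb window centred on the TSS) form a GRM `K = ZZ'/m`. The
   variance-component model `y ~ N(0, σ²_g K + σ²_e I)` is fitted by a
   one-dimensional profile-likelihood search on h² with the total variance
   profiled out analytically through the eigen-decomposition of K (a
   low-rank shortcut is used when m < n). The likelihood-ratio p-value
   against σ²_g = 0 uses the boundary-corrected 50:50 mixture of χ²₀ and
   χ²₁; genes with p < 0.01 proceed.
4. **Weight training.** Four models per gene — top1 (single best marginal
   eQTL), BLUP (ridge with shrinkage `m(1−h²)/h²`), lasso and elastic net
   (mixing 0.5, coordinate descent via glmnet) — are compared by
   cross-validation in which *all samples of an individual share a fold*
   (greedy bin-packing by descending sample count keeps fold sizes within
   5% of each other). The penalty for the sparse models is tuned on an
   inner grid using the same grouped folds. The score is the signed
   squared out-of-fold correlation (`sign(r)·r²`); its significance uses
   the number of individuals, not samples, as the effective n, because
   repeated samples of one individual are not independent. The winning
   model is refit on all data; genes whose best score is not positive are
   dropped (their imputed component would carry no variance).
5. **Association.** With GWAS summary z-scores harmonized to the weight
   alleles (swapped alleles flip z; A/T and C/G variants are removed as
   strand-ambiguous), the gene association is
   `z_TWAS = w'z / sqrt(w'Vw)` with V the LD matrix of the reference
   panel, shrunk as `0.95·V + 0.05·I` before any quadratic form.
   Benjamini–Hochberg FDR is applied with an explicit comparison count so
   the matched-comparison convention of validation analyses is available.
6. **Refinement.** Significant genes are grouped into loci (connected
   components of overlapping cis-windows). Within a locus,
   joint/conditional testing operates on the correlation of predicted
   expression, `Ω_ij = w_i'Vw_j / sqrt(w_i'Vw_i · w_j'Vw_j)`: forward
   selection repeatedly adds the gene with the largest conditional |Z|
   while any remaining gene stays BH-significant; selected genes are
   *joint* (reported with their joint Z), the rest *marginal* (conditional
   Z). SMR replication uses `T = z²_e z²_g/(z²_e + z²_g)` at the gene's
   top marginal eQTL, χ²₁ under the null. Colocalization uses Wakefield
   approximate Bayes factors (prior effect variance 0.2² for the
   case-control GWAS, 0.15² for expression; priors p1 = p2 = 1e-4,
   p12 = 1e-5) assembled into posteriors for the five standard hypotheses.
7. **Gene-set expansion.** Each hit is expanded by bootstrapped sparse
   partial regression of the target on all other genes (individuals
   resampled with replacement; elastic-net support selection followed by
   an OLS refit whose t-statistics give partial correlations), averaged
   over bootstraps and tissues. Genes inside the target's cis-window with
   mean correlation > 0.1 join the seed set. Inclusion uses an SD-multiplier
   cutoff on the mean partial correlations (an elbow diagnostic is emitted;
   default multiplier 1.3). The seed set grows through a protein-interaction
   edge list: non-seed genes touched by more than one (broad) or more than
   two (narrow) incident edges are kept if expressed in any tissue.
   Cell-type and process enrichment use the two-sided exact binomial test
   against the expressed-gene universe, BH-corrected over marker sets.

## The synthetic cohort

Every stage is exercised on generated data with known ground truth. The
generator's defaults encode the study design the package targets: 790
individuals, six neocortical tissues with per-tissue assignment
probabilities 481/248/34/41/34/50 out of 790 (≈888 expression samples in
expectation, some individuals in several tissues), cis-h² 0.3 with three
causal eQTL per gene, GWAS sample size 63,926, diagnosis shift 0.25 sd,
mediation effect 0.1 per sd of genetic expression for the mediated genes.

* **Genotypes** come from a stationary AR(1) Gaussian copula: two latent
  standard-normal haplotypes per individual evolve along the locus and are
  thresholded at the allele frequency. Thresholding attenuates
  correlation, so the latent correlation of each adjacent pair is
  calibrated by inverting a bivariate-normal orthant probability
  (48-point Gauss–Legendre quadrature + root finding, memoized on a
  0.001-rounded frequency grid) so the realized dosage correlation equals
  `ld_decay`. Minor allele frequencies drift along the locus as a
  reflected random walk inside `maf_range`, because LD partners share
  frequency in real panels and very unequal frequencies bound the
  achievable correlation.
* **Expression** shares one genetic component `Z_c β` across all tissues
  of an individual; β is rescaled so the component explains exactly h² of
  unit variance, and the realized h² is recorded. Diagnosis and optional
  nuisance covariates (age, sex, PMI, batch) add linear shifts so the
  normalization stage has real signal to remove.
* **GWAS summaries** are drawn analytically at the z level,
  `z = √N·Λα + MVN(0, Λ)` with Λ the empirical locus LD matrix and
  `α = γβ` the SNP-level mediated effect; `beta = z/√N`, `se = 1/√N`.
  γ = 0 yields an exact null. This matches the summary-statistic contract
  of the association stage and avoids simulating an individual-level
  case-control GWAS; a dedicated test confirms the summary-level z agrees
  with an individual-level regression oracle to |Δz| < 0.15 at N = 5000.

What the generator does *not* emulate: admixture beyond discrete clusters,
sex chromosomes, imputation error, non-Gaussian expression noise, and
trans-regulation. Passing tests therefore demonstrate internal consistency
and calibration of the estimators under the stated model, not robustness
to all features of real cohort data.

## Numerical and design choices

* **Loci are unlinked** (3 Mb apart, so ±500 kb windows never overlap);
  locus-overlap behaviour is exercised by dedicated constructions in the
  refinement tests rather than by the generator layout.
* **REML search**: `optimize()` on h² ∈ [0, 0.9999] with the boundary
  checked explicitly; non-convergence returns a flagged estimate with
  p = 1. Expression is mean-centred by scaling, so the mean is treated as
  known zero in the likelihood.
* **Ties**: top1 breaks ties toward the lower variant index; greedy LD
  pruning keeps the left variant; JCP forward selection breaks |Z| ties by
  gene id. All three make reruns bit-identical.
* **BH false-discovery check** is run on a 10%-mediated mixture cohort:
  under a pure global null the realized false-discovery proportion of a
  single run is 0 or 1 by definition, so a mixture is the smallest design
  in which the proportion is measurable; the gate-calibration and
  Kolmogorov–Smirnov checks use the pure null.
* **JCP demotion**: the BH correction of joint p-values is applied to the
  jointly selected genes; conditionally explained genes keep the
  *marginal* label. Applying the correction to marginal genes would
  reclassify essentially all of them, contradicting the intended
  three-way reading (joint / marginal / dropped).
* **cv_p convention**: two-sided correlation test at n = individuals.
  Whether the original convention used samples or individuals is not
  documented anywhere authoritative; individuals is the conservative
  choice consistent with the fold design.
* **Sparse-regression plug-in** for the expansion bootstrap: the
  spike-regression statistic consumed downstream (a mean partial
  correlation) is estimator-agnostic, so the default is an elastic-net
  support selection with an OLS refit; the estimator sits behind a single
  internal function and can be swapped.
* **Problem sizes** used by the shipped checks: calibration suites use
  1000 genes at n = 500 with 10 variants per locus; recovery suites use
  50 genes per h² level at n = 800 with 20 variants; generative
  colocalization and JCP checks use 100 draws on 50- and 20-variant loci.
  These sizes give Monte-Carlo error comfortably inside the asserted
  tolerances while keeping a full run in a few minutes.

## Known limitations

* BSLMM (the sparse-Bayes mixed model of the original five-model set) is
  not in the default model list; the model registry accepts additional
  fitters with the same signature.
* The HEIDI heterogeneity test and multi-causal colocalization are out of
  scope; COLOC here assumes at most one causal variant per trait per
  locus.
* LD pruning and window logic assume within-chromosome sorted positions
  (enforced by the container) and 1-based inclusive coordinates, matching
  PLINK bim files.
* `read_plink()` supports SNP-major PLINK 1 .bed files only.
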