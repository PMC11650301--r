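---
title: "Methods: imputation-based PWAS/TWAS, colocalization, and concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imputation-based PWAS/TWAS, colocalization, and concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omixwas)
```

# The model

`omixwas` implements the imputation-based association design for molecular
traits. Individual-level omics panels (plasma proteins measured by an
aptamer assay, or transcript levels) are small — hundreds to ~1,000
samples — while GWAS of complex traits reach hundreds of thousands. The
imputation approach splits the problem:

1. **Training.** On the omics panel, each gene's residualized protein or
   expression level is regressed on its cis-SNP dosages with an elastic net,
   giving a sparse per-gene weight vector $w$.
2. **Association.** The weights are combined with external GWAS per-SNP
   Z-scores $z_l$ and a reference covariance $\Gamma$ of the model SNP
   dosages:
   $$ z_g \;=\; \frac{\sum_l w_l \,\sigma_l\, z_l}{\sigma_g},
      \qquad \sigma_g^2 = w^\top \Gamma w,\; \sigma_l^2 = \Gamma_{ll}. $$
   This is the Wald statistic one would obtain by regressing the GWAS trait
   on the genetically imputed omic level, but computed without
   individual-level GWAS data. Both $\sigma_l$ and $\sigma_g$ are taken from
   the **same** reference panel; mixing training-panel SDs with a different
   LD panel's covariance biases $z_g$ noticeably (we verified this against
   the individual-level oracle).
3. **Inference.** Two-sided normal p-values, Benjamini–Hochberg FDR within
   trait, and the association direction $\mathrm{sign}(z_g)$ reported
   separately.

Downstream layers compare proteome- and transcriptome-based results:
per-SNP Wakefield approximate Bayes factors feed a five-hypothesis
colocalization posterior (PP0–PP4), and signed $\log_{10}$ p-values are
correlated across studies per tissue (Spearman), with an exact one-sided
binomial test on the count of positive-correlation tissues.

# Preprocessing pipeline

QC runs in a fixed order, mirroring standard omics practice:

1. variants with MAF $\le$ 0.05 removed (inclusive boundary);
2. related samples pruned on an allele-frequency-standardized kinship
   matrix with cutoff $2^{-2.5}$ (duplicates $\approx 0.5$,
   parent–offspring $\approx 0.25$ on this scale), greedily removing the
   member of each flagged pair with the most flagged partners;
3. rank-based inverse normal transform per feature (Blom offsets
   $\Phi^{-1}((r - 3/8)/(n + 1/4))$, average ranks for ties — the common
   convention where the method is stated only as "inverse normalization");
4. omics PC scores and surrogate values computed; samples whose per-block
   $\chi^2_k$ statistic $T_i = \sum_j (s_{ij}/\mathrm{sd}_j)^2$ has
   $p < 0.001$ in either block removed;
5. surrogate values recomputed on the retained samples (recomputation
   avoids leverage from removed outliers; the alternative of keeping the
   pre-removal scores was rejected);
6. residualization on age, sex, group, medication, four genetic PCs and the
   surrogate values (one-hot categories, first level dropped; OLS
   residuals, orthogonal to the design by construction).

Surrogate values are defined operationally as the top principal components
of the covariate-residualized, feature-standardized omics matrix. With few
features this residual PCA would absorb the genetic signal itself, so
`run_qc()` caps the number of surrogate values at one tenth of the feature
count; real proteome panels (~1,000 features) are unaffected.

Two interpretation choices are worth flagging: the $\chi^2$ outlier
statistic uses all score columns of a block jointly (degrees of freedom =
block width), not per-score tests; and genetic PCs are computed after
relatedness filtering.

# Model training choices

* Elastic-net mixing fixed at $\alpha = 0.5$, the convention of the
  standard training frameworks for this design.
* Penalty chosen as the cross-validation MSE minimizer over a 100-point
  log-spaced path with ratio $10^{-3}$ (not the 1-SE rule); fold
  assignments are seeded, so training is bit-reproducible.
* The cis window is the gene body ± 1 Mb, closed at both boundaries, and
  candidate SNPs are restricted to those present in the GWAS.
* Genes whose selected model has no nonzero weight are discarded (the
  "nontrivial model" rule); zero-variance and duplicate-position SNPs are
  dropped before fitting.
* Reported `cv_r2`/`cv_pvalue` come from nested 5-fold cross-validation:
  the penalty is re-selected inside each training fold and held-out samples
  are predicted, so the metric is honestly out-of-sample (its mean on null
  genes is ~0). The p-value is the one-sided correlation test (positive
  predictive correlation is the alternative of interest).

# Harmonization and missing data

GWAS records are matched to model SNPs by id; identical allele pairs keep
the GWAS Z, swapped pairs negate it, inconsistent pairs are dropped and
logged. Palindromic (A/T, C/G) SNPs are matched by exact allele pair and
never frequency-inferred — the simulator controls strand, and real-data
users should pre-filter strand-ambiguous variants if their sources differ.
Model SNPs missing from the GWAS are excluded and the statistic is computed
on the remaining subset with the matching $\Gamma$ submatrix (dropping the
gene entirely was rejected to preserve coverage); the missing count is
reported per gene.

# Colocalization

Per SNP, $\log \mathrm{ABF} = \tfrac12 \log(1-r) + \tfrac{z^2}{2} r$ with
$r = W/(V+W)$, $V = \mathrm{se}^2$. Defaults: prior effect variance
$W = 0.15^2$ (quantitative-trait convention on the standardized scale) and
priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ — the established
conventions for this class of colocalization model, exposed in the
configuration. The five-hypothesis posterior is evaluated in log space
(log-sum-exp; the H3 term uses a log-difference that is exactly $-\infty$
for a single SNP, making PP3 a structural zero there). Classification uses
the 0.5 cutoff: the argmax hypothesis if its posterior exceeds 0.5, else
"underpowered". The molecular tracks are single-SNP OLS marginal statistics
on the residualized omics from the training panel (`qtl_summary()`).

# Concordance

Signed log p is $\mathrm{sign}(z_g) \cdot (-\log_{10} p)$. Per tissue,
Spearman's rho is the Pearson correlation of average ranks; its p-value is
exact (full permutation enumeration) for $n \le 9$ without ties and the
$t$ approximation otherwise. Missing gene–tissue pairs are dropped
pairwise, never imputed. The cross-tissue sign test is the exact one-sided
upper-tail binomial $P(X \ge k \mid n, 1/2)$ computed from integer binomial
coefficients; for 47 positive tissues of 49 this exact tail is
$1226/2^{49} \approx 2.2 \times 10^{-12}$ (the two-sided value would be
twice that, so the sidedness matters at the second significant figure).

# The synthetic cohort generator

`sim_config()` + the three generators emulate the statistical structure the
analysis assumes, with full ground truth:

* **Genotypes.** Per gene locus, haplotypes are drawn by thresholding a
  latent AR(1) Gaussian process at $\Phi^{-1}(f_l)$, two haplotypes summed;
  `ld_rho` controls geometric LD decay with index distance. Loci are
  spaced 3.1 Mb apart so cis windows never overlap and genes are
  independent blocks. Alternate-allele frequencies are uniform on
  `maf_range`.
* **Omics.** Protein = causal cis-score (scaled so it explains
  `h2_protein` of the score-plus-noise variance) + measured-covariate
  effects + a hidden batch factor with Gaussian loadings + noise.
  Expression is analogous; its causal set shares a `causal_overlap`
  fraction of variants with the protein set, with concordant shared signs
  unless flipped per gene via `discordant_genes`.
* **GWAS.** The trait acts through the protein levels
  ($y = \sum_g \gamma_g P_g + \varepsilon$, unit noise variance) so
  PWAS–TWAS concordance has known ground truth. Cohort mode simulates an
  independent cohort (streamed in sample blocks, so memory stays bounded)
  and computes exact per-variant OLS marginal beta/SE — the oracle used for
  calibration checks. Analytic mode draws
  $z_l = \sqrt{n}\,\rho_l + N(0,1)$ from the model-implied correlations —
  faster, with independent noise across variants (it ignores the LD
  correlation of the noise, so cohort mode is preferred whenever the joint
  null distribution matters).

Defaults reflect the scale of the motivating study design: a training
panel of 935 samples, MAF range starting at 0.05, cis-heritability 0.3
(predictive $r^2$ for significantly predictable proteins spans roughly
0.01–0.8 in practice; 0.3 is a representative middle), 3 causal variants
per gene, fully shared concordant causal sets, and a protein-mediated
trait. The generator does **not** model realistic human LD maps,
recombination hotspots, population structure beyond a group label, or
assay artifacts such as aptamer cross-reactivity — so passing tests
demonstrate correctness of the statistical machinery under the stated
generative model, not robustness to every feature of real cohort data.

# Numerical choices and degenerate inputs

* MAF boundary comparisons carry a $10^{-12}$ tolerance so "0.05 or less"
  is robust to floating-point representation of dosage means.
* PCA/SVD component signs are fixed by making each component's
  largest-magnitude loading positive, so scores are deterministic.
* Elastic-net fits with a single usable SNP are handled by padding with a
  zero column (the penalized objective for the real column is unchanged).
* Degenerate cases return flagged results rather than NAs: constant
  out-of-fold predictions give `cv_r2 = 0`, `cv_pvalue = 1`; a gene whose
  model variance $w^\top \Gamma w$ is nonpositive is skipped with a
  diagnostic; an all-zero GWAS Z vector makes the weight-decomposition
  average 0 with a flag; p-values of exactly 0 are clamped to the smallest
  representable double with a warning before taking logs.

# Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen to keep Monte-Carlo error well inside the asserted bands: oracle
equivalence at 50 genes x 200 cis-SNPs with a 5,000-sample GWAS cohort;
null calibration over 500 genes; heritability recovery over 20 genes at
5,000 training samples; colocalization over 5 replicate loci; concordance
over 20 synthetic tissues of 40 genes. The headline counts of the
motivating analyses (hundreds of significant proteins, correlations of
~0.1 across 49 tissues) depend on restricted consortium data and are not
reproduced here; what the package verifies is the machinery that produces
such numbers.

# Known limitations

* Single-ancestry, single-panel training; no multi-ancestry weighting or
  fine-mapping-informed weights.
* No conditional/joint multi-gene tests and no cross-tissue combination
  statistic.
* One shared causal variant per colocalization hypothesis (no SuSiE-style
  multi-causal extension).
* Missing omics values are not imputed; the relatedness filter prunes
  rather than models family structure.
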