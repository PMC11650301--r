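# omixwas

Imputation-based proteome- and transcriptome-wide association studies
(PWAS/TWAS) for quantitative traits, in R.

Omics panels that measure plasma proteins or transcript levels alongside
genotypes are small (hundreds to ~1,000 samples), while GWAS of complex
traits such as blood lipids reach hundreds of thousands of individuals.
`omixwas` bridges the two: it trains sparse **elastic-net cis-genetic
prediction models** of residualized protein/expression levels on the omics
panel, then tests gene-trait associations using **only GWAS summary
statistics** plus an LD reference, via the summary-statistic imputation
statistic

```
z_g = sum_l( w_l * sigma_l * z_l ) / sigma_g,    sigma_g^2 = w' Gamma w
```

where `w` are the per-gene SNP weights, `z_l` the GWAS per-SNP Z-scores
(allele-harmonized to the model), and `Gamma` the reference covariance of
the model SNP dosages (`sigma_l^2` its diagonal). Downstream layers
colocalize gene and trait signals with Wakefield approximate Bayes factors
(posteriors PP0-PP4 over the no-signal / single-trait / distinct-causal /
shared-causal hypotheses) and quantify PWAS-TWAS direction concordance
across tissues with Spearman correlations of signed log10 p-values and an
exact binomial sign test.

The package is aimed at statistical geneticists who want a transparent,
fully testable implementation of this pipeline: every stage — QC
(MAF/relatedness filters, rank-based inverse normalization, PC and
surrogate-value outlier screening, covariate residualization), model
training with nested cross-validation, harmonization, association, FDR,
colocalization, concordance — is an exported tibble-in/tibble-out function,
and a synthetic-cohort generator with known ground truth
(`sim_config()`, `simulate_genotypes()`, `simulate_omics()`,
`simulate_gwas()`) makes the whole chain verifiable without any restricted
data.

## Worked example

Simulate a cohort whose trait acts through protein levels, run the full
pipeline (QC -> training -> PWAS/TWAS -> colocalization -> concordance),
and inspect the results:

```r
library(omixwas)

cfg <- sim_config(n_train = 300, n_gwas = 3000, n_variants_per_gene = 30,
                  n_genes = 8, protein_trait_effects = 0.3, seed = 7)
res <- run_pipeline(pipeline_config(sim = cfg), out_dir = "demo_out")

glance(res$pwas)
#> # A tibble: 1 × 4
#>   trait n_tested n_significant   fdr
#>   <chr>    <int>         <int> <dbl>
#> 1 lipid        8             8  0.05

tidy(res$pwas)[1:3, ]
#> # A tibble: 3 × 8
#>   gene_id trait zscore   pvalue   qvalue direction n_snps_used n_snps_missing
#>   <chr>   <chr>  <dbl>    <dbl>    <dbl>     <dbl>       <int>          <int>
#> 1 G001    lipid   7.44 1.04e-13 3.05e-13         1           4              0
#> 2 G002    lipid   5.61 2.07e- 8 2.77e- 8         1          12              0
#> 3 G003    lipid   7.29 3.12e-13 6.25e-13         1           5              0

head(res$coloc[, c("gene_id", "pair", "PP3", "PP4", "label")], 3)
#> # A tibble: 3 × 5
#>   gene_id pair                    PP3         PP4 label
#>   <chr>   <chr>                 <dbl>       <dbl> <chr>
#> 1 G001    trait_protein      0.000438 0.869       PP4
#> 2 G001    trait_expression   1.000    0.000000705 PP3
#> 3 G001    protein_expression 0.00932  0.0511      PP2
```

Every gene here is genuinely trait-associated (each protein carries a
simulated effect of 0.3 on the trait), so all 8 are significant at FDR
0.05 with direction `+`; the per-gene Z-scores are the summary-statistic
imputation statistic above. The colocalization rows classify each signal
pair at the 0.5 posterior cutoff: for gene `G001` the trait and protein
share a causal variant (PP4 = 0.87), while this particular expression
model picked up a distinct variant (PP3 ~ 1) — exactly the kind of
per-gene heterogeneity the concordance layer then aggregates across
tissues.

`autoplot()` methods exist for association results, colocalization
posteriors, and concordance reports; `tidy()`/`glance()` methods turn
every fitted object into tibbles.

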