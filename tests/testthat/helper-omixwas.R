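# Shared fixture builders; everything is generated in code at test time.

# A panel built directly from a dosage matrix (bypasses the simulator).
make_panel <- function(dosage, chrom = "1", pos = NULL) {
  L <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  variants <- tibble::tibble(
    variant_id = sprintf("v%03d", seq_len(L)),
    chrom = chrom, pos = pos,
    ref = rep("A", L), alt = rep("G", L)
  )
  colnames(dosage) <- variants$variant_id
  genotype_panel(dosage, variants)
}

# Binomial dosages at given alt frequencies (no LD).
random_dosage <- function(n, freqs, seed = 1) {
  withr::with_seed(seed, {
    sapply(freqs, function(f) stats::rbinom(n, 2L, f))
  })
}

# Small simulated cohort: panel + omics + truth, shared across tests.
small_sim <- function(seed = 11, n_train = 400, n_genes = 4,
                      n_variants = 25, ...) {
  cfg <- sim_config(n_train = n_train, n_genes = n_genes,
                    n_variants_per_gene = n_variants, seed = seed, ...)
  panel <- simulate_genotypes(cfg)
  om <- simulate_omics(panel, cfg)
  list(cfg = cfg, panel = panel, om = om)
}

# Manual weight table for hand-constructed association tests.
manual_weights <- function(ids, weight, sigma, effect = "G", other = "A",
                           gene_id = "G1") {
  tibble::tibble(gene_id = gene_id, variant_id = ids,
                 effect_allele = effect, other_allele = other,
                 weight = weight, sigma = sigma)
}

# GWAS rows matching manual_weights allele coding.
manual_gwas <- function(ids, z, effect = "G", other = "A", se = 0.01) {
  tibble::tibble(variant_id = ids, chrom = "1",
                 pos = seq_along(ids), effect_allele = effect,
                 other_allele = other, beta = z * se, se = se, z = z,
                 n = 1000L)
}
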