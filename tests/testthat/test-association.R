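test_that("harmonization aligns, flips, and excludes by allele pair", {
  w <- tibble::tibble(
    gene_id = "G1",
    variant_id = c("v1", "v2", "v3", "v4"),
    effect_allele = c("A", "A", "A", "A"),
    other_allele = c("G", "G", "G", "G"),
    weight = c(0.5, 0.5, 0.5, 0.5), sigma = 1
  )
  gwas <- tibble::tibble(
    variant_id = c("v1", "v2", "v3"),
    effect_allele = c("A", "G", "A"),
    other_allele = c("G", "A", "C"),
    beta = c(0.3, 0.3, 0.3), se = 0.1, z = c(3, 3, 3)
  )
  h <- harmonize(w, gwas)
  expect_identical(h$aligned$variant_id, c("v1", "v2"))
  expect_equal(h$aligned$z, c(3, -3))       # identical coding; swapped coding
  expect_equal(h$aligned$beta, c(0.3, -0.3))
  expect_setequal(h$exclusions$reason, c("allele_mismatch", "missing_in_gwas"))
  expect_identical(
    h$exclusions$variant_id[h$exclusions$reason == "allele_mismatch"], "v3")
  expect_identical(
    h$exclusions$variant_id[h$exclusions$reason == "missing_in_gwas"], "v4")
})

test_that("the gene Z statistic reproduces closed-form cases", {
  # single SNP, unit weight: z_g = z_l regardless of sigma
  w <- manual_weights("v1", weight = 1, sigma = 2)
  g <- manual_gwas("v1", z = 3.7)
  h <- harmonize(w, g)
  ld <- matrix(4, 1, 1, dimnames = list("v1", "v1"))
  res <- association_z(h$aligned, ld, "G1", "t")
  expect_equal(res$zscore, 3.7, tolerance = 1e-12)
  expect_equal(res$pvalue, 2 * stats::pnorm(-3.7), tolerance = 1e-12)

  # two SNPs in perfect LD, equal sigma: numerator 4*sigma, sigma_g = sigma
  w2 <- manual_weights(c("v1", "v2"), weight = c(0.5, 0.5), sigma = c(1, 1))
  g2 <- manual_gwas(c("v1", "v2"), z = c(4, 4))
  ld2 <- matrix(1, 2, 2, dimnames = list(c("v1", "v2"), c("v1", "v2")))
  res2 <- association_z(harmonize(w2, g2)$aligned, ld2, "G1", "t")
  expect_equal(res2$zscore, 4, tolerance = 1e-12)

  # degenerate model (zero LD variance) is skipped
  ld0 <- matrix(0, 1, 1, dimnames = list("v1", "v1"))
  expect_identical(nrow(association_z(h$aligned, ld0, "G1", "t")), 0L)
})

test_that("gene Z is invariant under allele recoding of model or GWAS", {
  s <- small_sim(seed = 81, n_train = 300, n_genes = 2, n_variants = 15,
                 covariate_strength = 0, confounder_strength = 0)
  ann <- simulate_annotations(s$cfg)
  m <- train_models(s$panel, s$om$protein, ann, seed = 2)
  ld <- build_ld_reference(s$panel, m)
  gwas <- simulate_gwas(s$panel, s$cfg, s$om$truth, n_gwas = 2000)
  base <- run_xwas(m, list(t = gwas), ld)$associations

  # flip ref/alt and negate beta for a random subset of GWAS rows
  flipped <- withr::with_seed(9, {
    g2 <- gwas
    idx <- sample(nrow(g2), nrow(g2) %/% 2)
    tmp <- g2$effect_allele[idx]
    g2$effect_allele[idx] <- g2$other_allele[idx]
    g2$other_allele[idx] <- tmp
    g2$beta[idx] <- -g2$beta[idx]
    g2$z[idx] <- -g2$z[idx]
    g2
  })
  rec <- run_xwas(m, list(t = flipped), ld)$associations
  expect_equal(base$zscore, rec$zscore, tolerance = 1e-12)
  expect_equal(base$qvalue, rec$qvalue, tolerance = 1e-12)
})

test_that("BH q-values match the step-up rule and a brute-force oracle", {
  expect_equal(bh_fdr(c(0.001, 0.02, 0.03, 0.5)),
               c(0.004, 0.04, 0.04, 0.5), tolerance = 1e-12)
  expect_equal(bh_fdr(rep(0.01, 10)), rep(0.01, 10), tolerance = 1e-12)
  expect_equal(bh_fdr(0.3), 0.3)
  expect_error(bh_fdr(numeric()), "empty")

  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- vapply(seq_len(m), function(i) {
      min(m * p[o][i:m] / (i:m))
    }, numeric(1))
    q <- numeric(m)
    q[o] <- q_sorted
    q
  }
  for (s in 1:20) {
    p <- withr::with_seed(s, stats::runif(25)^2)
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("the weight decomposition orients SNPs and averages by |Z|", {
  w <- manual_weights(c("v1", "v2"), weight = c(0.4, 0.1), sigma = c(1, 1))
  g <- manual_gwas(c("v1", "v2"), z = c(5, -1))
  d <- decompose_contributions(harmonize(w, g)$aligned)
  expect_true(all(d$table$z >= 0))
  expect_equal(d$table$weight, c(0.4, -0.1))
  expect_equal(d$weighted_average, (0.4 * 5 - 0.1 * 1) / 6, tolerance = 1e-12)

  # recoding an allele in the GWAS leaves the decomposition unchanged
  g2 <- g
  g2$effect_allele[1] <- "A"
  g2$other_allele[1] <- "G"
  g2$z[1] <- -g2$z[1]
  g2$beta[1] <- -g2$beta[1]
  d2 <- decompose_contributions(harmonize(w, g2)$aligned)
  expect_equal(d2$table$weight, d$table$weight, tolerance = 1e-12)
  expect_equal(d2$weighted_average, d$weighted_average, tolerance = 1e-12)

  # single SNP: average equals the weight, same sign as z_g
  d1 <- decompose_contributions(
    harmonize(manual_weights("v1", 0.7, 1), manual_gwas("v1", 2))$aligned)
  expect_equal(d1$weighted_average, 0.7)

  # all-zero Z: flagged, average reported as 0
  d0 <- decompose_contributions(
    harmonize(manual_weights("v1", 0.7, 1), manual_gwas("v1", 0))$aligned)
  expect_true(d0$all_null)
  expect_identical(d0$weighted_average, 0)
})

test_that("under the global null the gene Z is standard normal", {
  cfg <- sim_config(n_train = 400, n_gwas = 2000, n_genes = 300,
                    n_variants_per_gene = 10, protein_trait_effects = 0,
                    covariate_strength = 0, confounder_strength = 0,
                    seed = 91)
  panel <- simulate_genotypes(cfg)
  om <- simulate_omics(panel, cfg)
  gwas <- simulate_gwas(panel, cfg, om$truth, mode = "cohort")
  # random weight models over each gene's SNPs (training is irrelevant to
  # null calibration of the statistic itself)
  weights <- withr::with_seed(92, {
    dplyr::mutate(
      panel$variants[, c("gene_id", "variant_id", "alt", "ref")],
      effect_allele = alt, other_allele = ref,
      weight = stats::rnorm(dplyr::n()),
      sigma = apply(panel$dosage, 2L, stats::sd)
    )
  })
  models <- structure(list(weights = weights,
                           summary = tibble::tibble(gene_id = unique(weights$gene_id)),
                           dropped = tibble::tibble()),
                      class = "xwas_models")
  ld <- build_ld_reference(panel, models)
  res <- run_xwas(models, list(t = gwas), ld)
  z <- res$associations$zscore
  expect_gt(stats::ks.test(z, "pnorm")$p.value, 0.01)
  # BH keeps the significant set small under the global null
  expect_lte(length(res$significant$t), 0.05 * length(z))
})

test_that("multi-trait runs report significant sets, overlaps, and a table", {
  # single-SNP models make the gene Z equal the per-variant GWAS Z
  w <- dplyr::bind_rows(
    manual_weights("v1", 1, 1, gene_id = "G1"),
    manual_weights("v2", 1, 1, gene_id = "G2"),
    manual_weights("v3", 1, 1, gene_id = "G3")
  )
  models <- structure(list(weights = w,
                           summary = tibble::tibble(gene_id = c("G1", "G2", "G3")),
                           dropped = tibble::tibble()),
                      class = "xwas_models")
  ld <- structure(list(
    G1 = matrix(1, 1, 1, dimnames = list("v1", "v1")),
    G2 = matrix(1, 1, 1, dimnames = list("v2", "v2")),
    G3 = matrix(1, 1, 1, dimnames = list("v3", "v3"))
  ), class = "ld_reference")
  gwas_a <- manual_gwas(c("v1", "v2", "v3"), z = c(8, 6, 0.1))
  gwas_b <- manual_gwas(c("v1", "v2", "v3"), z = c(7, 0.2, 0.1))
  res <- run_xwas(models, list(TC = gwas_a, LDL = gwas_b), ld)
  expect_setequal(res$significant$TC, c("G1", "G2"))
  expect_identical(res$significant$LDL, "G1")
  # G1 significant for both traits -> counted once in the off-diagonal cell
  expect_identical(res$overlap["TC", "LDL"], 1L)
  expect_identical(res$overlap["TC", "TC"], 2L)
  # formatted table: -log10 p with sign for significant cells, dot otherwise
  row_g2 <- res$table[res$table$gene_id == "G2", ]
  expect_match(row_g2$TC, "\\([+-]\\)")
  expect_identical(row_g2$LDL, ".")
  expect_false("G3" %in% res$table$gene_id)

  single <- run_xwas(models, list(TC = gwas_a), ld)
  expect_identical(dim(single$overlap), c(1L, 1L))
  expect_identical(single$overlap["TC", "TC"], 2L)

  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 6L)
  gl <- glance(res)
  expect_identical(gl$n_significant, c(TC = 2L, LDL = 1L))
})

test_that("summary Z agrees with individual-level regression when the LD panel is the cohort", {
  cfg <- sim_config(n_train = 400, n_gwas = 4000, n_genes = 5,
                    n_variants_per_gene = 25, protein_trait_effects = 0.15,
                    covariate_strength = 0, confounder_strength = 0,
                    seed = 101)
  panel <- simulate_genotypes(cfg)
  om <- simulate_omics(panel, cfg)
  gw <- simulate_gwas(panel, cfg, om$truth, mode = "cohort",
                      return_cohort = TRUE)
  ann <- simulate_annotations(cfg)
  m <- train_models(panel, om$protein, ann, seed = 7)
  ld <- build_ld_reference(gw$cohort, m)
  res <- run_xwas(m, list(t = gw$summary), ld)$associations
  dz <- vapply(seq_len(nrow(res)), function(i) {
    g <- res$gene_id[i]
    wg <- m$weights[m$weights$gene_id == g, ]
    score <- drop(gw$cohort$dosage[, wg$variant_id, drop = FALSE] %*% wg$weight)
    z_ind <- summary(stats::lm(gw$trait ~ score))$coefficients[2, 3]
    abs(res$zscore[i] - z_ind)
  }, numeric(1))
  # agreement tightens as 1/sqrt(n_gwas); at this reduced cohort size allow
  # slightly more Monte-Carlo slack than at full scale
  expect_true(all(dz < 0.3))
  expect_gte(mean(dz < 0.15), 0.8)
})
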