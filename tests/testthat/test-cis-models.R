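test_that("cis window is the closed gene body plus 1 Mb flanks", {
  L <- 5
  variants <- tibble::tibble(
    variant_id = sprintf("v%03d", 1:L),
    chrom = c("1", "1", "1", "1", "2"),
    pos = c(999999, 1000000, 2025000, 3050000, 2000000),
    ref = "A", alt = "G"
  )
  dosage <- random_dosage(20, rep(0.3, L), seed = 1)
  colnames(dosage) <- variants$variant_id
  panel <- genotype_panel(dosage, variants)
  gene <- list(gene_id = "G1", chrom = "1", tss = 2000000, tes = 2050000)
  ids <- select_cis_snps(gene, panel)
  # window [1,000,000, 3,050,000]: boundary SNPs included, 999,999 excluded,
  # wrong-chromosome SNP inside the coordinate range excluded
  expect_identical(ids, c("v002", "v003", "v004"))
  expect_identical(select_cis_snps(gene, panel, allowed_ids = character()),
                   character())
  expect_identical(select_cis_snps(gene, panel, allowed_ids = c("v003")),
                   "v003")
})

test_that("elastic net recovers a planted signal among decoys", {
  hits <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    withr::with_seed(1000 + s, {
      X <- matrix(stats::rbinom(1000 * 51, 2L, 0.3), 1000, 51)
      colnames(X) <- sprintf("v%02d", 1:51)
      y <- 0.8 * X[, 1] + stats::rnorm(1000, sd = 0.1)
    })
    fit <- fit_elastic_net_cv(y, X, seed = s)
    if (fit$weights[1] > 0) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("pure-noise responses usually yield the all-zero (discarded) model", {
  zero_models <- 0L
  for (s in 1:20) {
    withr::with_seed(2000 + s, {
      X <- matrix(stats::rbinom(500 * 30, 2L, 0.3), 500, 30)
      colnames(X) <- sprintf("v%02d", 1:30)
      y <- stats::rnorm(500)
    })
    fit <- fit_elastic_net_cv(y, X, seed = s)
    if (length(fit$nonzero) == 0L) zero_models <- zero_models + 1L
  }
  expect_gt(zero_models, 10L)
})

test_that("a single-column fit approaches the OLS slope as the penalty vanishes", {
  withr::with_seed(30, {
    x <- stats::rbinom(800, 2L, 0.4)
    y <- 0.6 * x + stats::rnorm(800, sd = 0.3)
  })
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "v1"))
  foldid <- omixwas:::make_folds(800, 5L, 1L)
  fit <- omixwas:::cv_enet(y, X, alpha = 0.5, foldid = foldid,
                           lambda = c(1e-5, 1e-6, 1e-7))
  ols <- stats::coef(stats::lm(y ~ x))[2]
  expect_equal(unname(fit$weights["v1"]), unname(ols), tolerance = 1e-4)
})

test_that("weights are invariant to response shifts and equivariant to allele flips", {
  withr::with_seed(31, {
    X <- matrix(stats::rbinom(400 * 20, 2L, 0.3), 400, 20)
    colnames(X) <- sprintf("v%02d", 1:20)
    y <- 0.5 * X[, 3] - 0.4 * X[, 7] + stats::rnorm(400, sd = 0.5)
  })
  f1 <- fit_elastic_net_cv(y, X, seed = 9)
  f2 <- fit_elastic_net_cv(y + 5, X, seed = 9)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-10)

  Xf <- X
  Xf[, 3] <- 2 - X[, 3]  # recode variant 3 to the other allele
  f3 <- fit_elastic_net_cv(y, Xf, seed = 9)
  expect_equal(unname(f3$weights[3]), -unname(f1$weights[3]), tolerance = 1e-8)
  expect_equal(unname(f3$weights[-3]), unname(f1$weights[-3]), tolerance = 1e-8)
  pred1 <- drop(X %*% f1$weights) + f1$intercept
  pred3 <- drop(Xf %*% f3$weights) + f3$intercept
  expect_equal(pred1, pred3, tolerance = 1e-8)
})

test_that("cross-validated r2 approaches 1 for a noiseless signal", {
  withr::with_seed(32, {
    X <- matrix(stats::rbinom(1000 * 5, 2L, 0.4), 1000, 5)
    colnames(X) <- sprintf("v%02d", 1:5)
  })
  y <- 1.5 * X[, 2]
  ev <- evaluate_model_cv(y, X, seed = 3)
  expect_gt(ev$cv_r2, 0.95)
  expect_lt(ev$cv_pvalue, 1e-10)
})

test_that("out-of-fold prediction p-values are calibrated on null genes", {
  n_genes <- 200L
  pvals <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    withr::with_seed(3000 + g, {
      X <- matrix(stats::rbinom(120 * 10, 2L, 0.3), 120, 10)
      colnames(X) <- sprintf("v%02d", 1:10)
      y <- stats::rnorm(120)
    })
    pvals[g] <- evaluate_model_cv(y, X, seed = g)$cv_pvalue
  }
  type1 <- mean(pvals < 0.05)
  # 3-sigma binomial band around 0.05 at 200 genes
  expect_gt(type1, 0.05 - 3 * sqrt(0.05 * 0.95 / n_genes))
  expect_lt(type1, 0.05 + 3 * sqrt(0.05 * 0.95 / n_genes))
  # out-of-sample r2 is not systematically inflated under the null
  r2_null <- vapply(1:30, function(g) {
    withr::with_seed(5000 + g, {
      X <- matrix(stats::rbinom(120 * 10, 2L, 0.3), 120, 10)
      colnames(X) <- sprintf("v%02d", 1:10)
      y <- stats::rnorm(120)
    })
    evaluate_model_cv(y, X, seed = g)$cv_r2
  }, numeric(1))
  expect_lt(mean(r2_null), 0.05)
})

test_that("constant out-of-fold predictions score r2 0 and p 1", {
  X <- matrix(1, 50, 2)
  X[1, 1] <- 1  # all constant columns
  colnames(X) <- c("v1", "v2")
  y <- withr::with_seed(33, stats::rnorm(50))
  ev <- evaluate_model_cv(y, X, seed = 1)
  expect_identical(ev$cv_r2, 0)
  expect_identical(ev$cv_pvalue, 1)
})

test_that("training over genes applies the nontrivial-model and FDR rules", {
  s <- small_sim(seed = 51, n_train = 500, n_genes = 6, n_variants = 30,
                 covariate_strength = 0, confounder_strength = 0)
  ann <- simulate_annotations(s$cfg)
  # a gene on another chromosome has an empty window -> drop report
  ann2 <- dplyr::bind_rows(
    ann, tibble::tibble(gene_id = "GX", symbol = "GX", chrom = "9",
                        tss = 1e6, tes = 2e6, strand = "+")
  )
  omics <- cbind(s$om$protein, GX = stats::rnorm(500))
  m <- train_models(s$panel, omics, ann2, seed = 4)
  expect_true("GX" %in% m$dropped$gene_id)
  expect_false("GX" %in% m$summary$gene_id)
  expect_true(all(m$summary$n_snps_nonzero >= 1))
  expect_true(all(is.finite(m$weights$weight)))
  expect_true(all(m$weights$effect_allele != m$weights$other_allele))
  # determinism: rerun gives a byte-identical weight table
  m2 <- train_models(s$panel, omics, ann2, seed = 4)
  expect_identical(m$weights, m2$weights)
  expect_identical(m$summary, m2$summary)
})

test_that("the predictable-gene fraction tracks the planted signal fraction", {
  n_signal <- 60L
  n_null <- 40L
  cfg <- sim_config(n_train = 800, n_genes = n_signal + n_null,
                    n_variants_per_gene = 20, h2_protein = 0.3,
                    covariate_strength = 0, confounder_strength = 0,
                    seed = 61)
  panel <- simulate_genotypes(cfg)
  om <- simulate_omics(panel, cfg)
  omics <- om$protein
  withr::with_seed(62, {
    for (g in (n_signal + 1):(n_signal + n_null)) {
      omics[, g] <- stats::rnorm(800)  # null genes: no genetic signal
    }
  })
  ann <- simulate_annotations(cfg)
  m <- train_models(panel, omics, ann, seed = 5)
  frac <- sum(m$summary$predictable) / cfg$n_genes
  # power at h2 = 0.3 is near 1, so the flagged fraction sits near the 60%
  # signal fraction (3-sigma binomial band plus FDR leakage)
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.68)
})

test_that("the LD reference matches the weight table layout", {
  s <- small_sim(seed = 71, n_train = 300, n_genes = 3, n_variants = 20,
                 covariate_strength = 0, confounder_strength = 0)
  ann <- simulate_annotations(s$cfg)
  m <- train_models(s$panel, s$om$protein, ann, seed = 6)
  ld <- build_ld_reference(s$panel, m)
  for (g in unique(m$weights$gene_id)) {
    ids <- m$weights$variant_id[m$weights$gene_id == g]
    expect_identical(rownames(ld[[g]]), ids)
    # diagonal equals the stored training variances
    expect_equal(sqrt(diag(ld[[g]])),
                 stats::setNames(m$weights$sigma[m$weights$gene_id == g], ids),
                 tolerance = 1e-12)
    ev <- eigen(ld[[g]], symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-8))
  }
})
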