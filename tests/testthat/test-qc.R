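test_that("MAF filter removes variants at or below the threshold", {
  # 10 samples: alt counts 1/20 (MAF 0.05), 0 (monomorphic), 2/20 (MAF 0.10),
  # 19/20 (alt freq 0.95, MAF 0.05)
  dosage <- cbind(
    c(1, rep(0, 9)),
    rep(0, 10),
    c(1, 1, rep(0, 8)),
    c(rep(2, 9), 1)
  )
  panel <- make_panel(dosage)
  out <- filter_maf(panel, 0.05)
  expect_setequal(out$report$variant_id, c("v001", "v002", "v004"))
  expect_identical(out$panel$variants$variant_id, "v003")

  # strictly-above-threshold variants are retained
  out2 <- filter_maf(panel, 0.0499999)
  expect_true(all(c("v001", "v004") %in% out2$panel$variants$variant_id))
  expect_error(filter_maf(panel, 0.6), "threshold")
})

test_that("kinship identifies duplicates and is null for unrelated samples", {
  freqs <- withr::with_seed(1, stats::runif(1000, 0.1, 0.5))
  dosage <- random_dosage(80, freqs, seed = 2)
  dosage <- rbind(dosage, dosage[1, ])  # duplicate sample 1 as sample 81
  panel <- make_panel(dosage)
  kin <- estimate_kinship(panel)
  expect_equal(kin[1, 81], 0.5, tolerance = 0.05)
  unrelated <- kin[2:80, 2:80]
  expect_lt(abs(mean(unrelated[upper.tri(unrelated)])), 0.02)

  pruned <- filter_related(kin)
  expect_length(pruned$retained, 80L)
  expect_identical(pruned$report$reason, "relatedness")
})

test_that("parent-offspring pairs fall in the first-degree band and are pruned", {
  freqs <- withr::with_seed(3, stats::runif(2000, 0.2, 0.5))
  withr::with_seed(4, {
    parents <- sapply(freqs, function(f) stats::rbinom(40, 2L, f))
    transmitted <- t(apply(parents, 1L, function(g) {
      stats::rbinom(length(g), 1L, g / 2)
    }))
    random_hap <- sapply(freqs, function(f) stats::rbinom(40, 1L, f))
    children <- transmitted + random_hap
  })
  panel <- make_panel(rbind(parents, children))
  kin <- estimate_kinship(panel)
  po <- diag(kin[1:40, 41:80])
  expect_true(all(po > 2^-2.5 & po < 2^-1.5))
  pruned <- filter_related(kin)
  # one member of each parent-child pair is removed
  for (i in 1:40) {
    expect_false(all(c(i, 40 + i) %in% match(pruned$retained,
                                             rownames(panel$dosage))))
  }
})

test_that("inverse normal transform matches Blom quantiles", {
  out <- inverse_normal_transform(c(5, 1, 9))
  # qnorm((rank - 3/8) / 3.25) at ranks 2, 1, 3
  expect_equal(out, c(0, -0.8694238, 0.8694238), tolerance = 1e-3)

  x <- withr::with_seed(5, stats::rnorm(101))
  y <- inverse_normal_transform(x)
  expect_true(all(diff(y[order(x)]) > 0))  # rank-monotone
  expect_lt(abs(mean(y)), 1e-6)            # Blom quantiles are symmetric
  expect_error(inverse_normal_transform(rep(1, 5)), "identical")
  expect_error(inverse_normal_transform(3), "at least 2")
})

test_that("genetic PCs separate diverged populations and are orthogonal", {
  withr::with_seed(6, {
    f1 <- stats::runif(150, 0.05, 0.35)
    f2 <- pmin(f1 + 0.4, 0.95)
    pop1 <- sapply(f1, function(f) stats::rbinom(100, 2L, f))
    pop2 <- sapply(f2, function(f) stats::rbinom(100, 2L, f))
  })
  panel <- make_panel(rbind(pop1, pop2))
  scores <- compute_genetic_pcs(panel, 4L)
  grp <- rep(c(0, 1), each = 100)
  expect_gt(abs(stats::cor(scores[, 1], grp)), 0.9)
  cors <- stats::cor(scores)
  expect_true(all(abs(cors[upper.tri(cors)]) < 1e-8))
  expect_identical(ncol(compute_genetic_pcs(panel, 0L)), 0L)
})

test_that("surrogate variables recover a planted batch factor", {
  n <- 500
  withr::with_seed(7, {
    covariates <- tibble::tibble(
      sample_id = sprintf("S%03d", 1:n),
      age = stats::runif(n, 45, 84), sex = stats::rbinom(n, 1, 0.5),
      group = sample(c("A", "B"), n, TRUE), medication = stats::rbinom(n, 1, 0.2)
    )
    batch <- stats::rnorm(n)
    loadings <- stats::rnorm(200, sd = 2)
    omics <- outer(batch, loadings) + matrix(stats::rnorm(n * 200), n, 200)
  })
  sv <- estimate_surrogate_variables(omics, covariates, 5L)
  expect_gt(abs(stats::cor(sv[, 1], batch)), 0.9)
  expect_identical(ncol(estimate_surrogate_variables(omics, covariates, 0L)), 0L)
})

test_that("without structure the leading surrogate variable is at the permutation null", {
  n <- 200
  withr::with_seed(8, {
    covariates <- tibble::tibble(
      sample_id = sprintf("S%03d", 1:n),
      age = stats::runif(n, 45, 84), sex = stats::rbinom(n, 1, 0.5),
      group = sample(c("A", "B"), n, TRUE), medication = stats::rbinom(n, 1, 0.2)
    )
    design <- covariate_design(covariates)
    omics <- design %*% matrix(stats::rnorm(ncol(design) * 150), ncol(design)) +
      matrix(stats::rnorm(n * 150), n, 150)
  })
  share <- function(m) {
    res <- scale_residuals_for_test(m, covariates)
    sv <- svd(res, nu = 0, nv = 0)$d
    sv[1]^2 / sum(sv^2)
  }
  scale_residuals_for_test <- function(m, cov) {
    r <- residualize(m, cov)
    scale(r)
  }
  obs <- share(omics)
  perm <- withr::with_seed(9, {
    vapply(1:20, function(i) {
      share(apply(omics, 2L, sample))
    }, numeric(1))
  })
  expect_lt(obs, max(perm) * 1.05)
})

test_that("chi-squared outlier screening removes extreme samples only", {
  withr::with_seed(10, {
    pc <- matrix(stats::rnorm(200 * 10), 200, 10)
    sv <- matrix(stats::rnorm(200 * 10), 200, 10)
  })
  pc[1, ] <- 0
  sv[1, ] <- 0
  pc[2, 1] <- 10 * stats::sd(pc[, 1])
  rownames(pc) <- rownames(sv) <- sprintf("S%03d", 1:200)
  out <- flag_outliers_chisq(pc, sv, alpha = 0.001)
  expect_true("S001" %in% out$retained)   # at the origin: T = 0, p = 1
  expect_false("S002" %in% out$retained)  # 10 sigma on one axis: chi2_10 >= 100
  expect_true(all(out$report$p < 0.001))
  none <- flag_outliers_chisq(pc, sv, alpha = 0)
  expect_length(none$retained, 200L)
})

test_that("residualization is exact ordinary least squares", {
  n <- 300
  withr::with_seed(11, {
    covariates <- tibble::tibble(
      sample_id = sprintf("S%03d", 1:n),
      age = stats::runif(n, 45, 84), sex = stats::rbinom(n, 1, 0.5),
      group = sample(c("A", "B", "C"), n, TRUE),
      medication = stats::rbinom(n, 1, 0.2)
    )
    noise <- stats::rnorm(n)
  })
  # a feature equal to a covariate column residualizes to ~0
  r0 <- residualize(covariates$age, covariates)
  expect_lt(max(abs(r0)), 1e-8)
  # planted linear model: residual uncorrelated with the covariate
  y <- 2 * covariates$age + noise
  r1 <- residualize(y, covariates)
  expect_lt(abs(stats::cor(r1[, 1], covariates$age)), 1e-8)
  # feature orthogonal to (centered) covariates: residual = centered feature
  design <- covariate_design(covariates)
  q <- qr.Q(qr(design))
  v <- noise - q %*% crossprod(q, noise)
  r2 <- residualize(drop(v), covariates)
  expect_equal(drop(r2), drop(v), tolerance = 1e-10)
})

test_that("the QC pipeline preserves alignment and produces no missing values", {
  s <- small_sim(seed = 12, n_train = 250, n_genes = 12, n_variants = 40)
  qc <- run_qc(s$panel, s$om$protein, s$om$covariates)
  expect_false(anyNA(qc$residuals))
  expect_identical(rownames(qc$residuals), qc$panel$samples)
  expect_identical(qc$covariates$sample_id, qc$panel$samples)
  # residuals orthogonal to every covariate column
  dots <- crossprod(qc$covariate_design, qc$residuals)
  expect_lt(max(abs(dots)) / nrow(qc$residuals), 1e-6)
  # removed and retained partition the input
  removed_samples <- qc$report$sample_id[!is.na(qc$report$sample_id)]
  expect_setequal(c(qc$panel$samples, removed_samples), s$panel$samples)
})
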