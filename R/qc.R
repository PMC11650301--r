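#' Filter variants by minor allele frequency
#'
#' Removes variants whose MAF is less than or equal to `threshold` ("0.05 or
#' less" semantics: a variant at exactly the threshold is removed). MAF is
#' `min(f_alt, 1 - f_alt)` computed from the dosages.
#'
#' @param panel a [genotype_panel()].
#' @param threshold MAF cutoff in `(0, 0.5)`.
#' @return A list with elements `panel` (filtered) and `report`, a tibble of
#'   removed variants (`variant_id`, `maf`).
#' @export
filter_maf <- function(panel, threshold = 0.05) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 0.5) {
    stop("`threshold` must be in (0, 0.5)", call. = FALSE)
  }
  if (ncol(panel$dosage) == 0L) stop("empty panel", call. = FALSE)
  # inclusive boundary ("0.05 or less"), robust to representation error
  drop <- panel$variants$maf <= threshold + 1e-12
  report <- tibble::tibble(variant_id = panel$variants$variant_id[drop],
                           maf = panel$variants$maf[drop],
                           reason = "maf")
  keep <- panel$variants$variant_id[!drop]
  list(panel = subset_panel(panel, variant_ids = keep), report = report)
}

#' Estimate pairwise kinship from dosages
#'
#' Allele-frequency-standardized kinship:
#' `phi_ij = (1/2) * sum_l (g_il - 2 p_l)(g_jl - 2 p_l) / sum_l 2 p_l (1 - p_l)`
#' with `p_l` the sample alternate-allele frequency. On this scale duplicates
#' score about 0.5, parent-offspring about 0.25, and the KING degree bands
#' apply (1st degree `[2^-2.5, 2^-1.5]`, 2nd degree `[2^-3.5, 2^-2.5]`).
#'
#' @param panel a [genotype_panel()], MAF-filtered.
#' @return A symmetric samples-by-samples kinship matrix.
#' @export
estimate_kinship <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (ncol(panel$dosage) < 2L) stop("need at least 2 variants", call. = FALSE)
  if (nrow(panel$dosage) < 2L) stop("need at least 2 samples", call. = FALSE)
  p <- colMeans(panel$dosage) / 2
  centered <- sweep(panel$dosage, 2L, 2 * p, "-")
  denom <- sum(2 * p * (1 - p))
  tcrossprod(centered) / (2 * denom)
}

#' Prune related samples from a kinship matrix
#'
#' Pairs with kinship above `threshold` are flagged; samples are removed
#' greedily, dropping from each remaining flagged pair the member with the
#' most flagged partners (ties broken toward the larger sample index), until
#' no flagged pair remains.
#'
#' @param kinship symmetric kinship matrix with sample-id dimnames.
#' @param threshold kinship cutoff; the default `2^-2.5` is the boundary
#'   between 1st- and 2nd-degree relatedness.
#' @return A list with `retained` (sample ids) and `report`, a tibble of
#'   removed samples with their maximum kinship statistic.
#' @export
filter_related <- function(kinship, threshold = 2^-2.5) {
  n <- nrow(kinship)
  ids <- rownames(kinship)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(n))
  flags <- kinship > threshold
  diag(flags) <- FALSE
  removed <- integer()
  while (any(flags)) {
    counts <- rowSums(flags)
    worst <- which(counts == max(counts))
    victim <- max(worst)  # tie: larger sample index
    removed <- c(removed, victim)
    flags[victim, ] <- FALSE
    flags[, victim] <- FALSE
  }
  report <- tibble::tibble(
    sample_id = ids[removed],
    statistic = vapply(removed, function(i) {
      max(kinship[i, -i])
    }, numeric(1)),
    reason = "relatedness"
  )
  list(retained = ids[setdiff(seq_len(n), removed)], report = report)
}

#' Rank-based inverse normal transform
#'
#' Maps values to standard-normal quantiles via Blom offsets:
#' `qnorm((rank - 3/8) / (n + 1/4))`, with average ranks for ties.
#'
#' @param values numeric vector with at least 2 finite values.
#' @return A numeric vector, rank-monotone in the input.
#' @export
inverse_normal_transform <- function(values) {
  if (length(values) < 2L || !all(is.finite(values))) {
    stop("need at least 2 finite values", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("all values identical: inverse normal transform undefined",
         call. = FALSE)
  }
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(values) + 1 / 4))
}

# top-k PCA scores (left singular vectors * singular values) with the sign of
# each component fixed so its largest-magnitude loading is positive.
pca_scores <- function(m, k) {
  if (k == 0L) {
    return(matrix(0, nrow(m), 0L, dimnames = list(rownames(m), NULL)))
  }
  if (k > min(dim(m))) stop("`k` exceeds matrix rank bound", call. = FALSE)
  s <- svd(m, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- s$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(s$u, 2L, s$d[seq_len(k)] * flip, "*")
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_len(k)))
  scores
}

#' Genetic principal-component scores
#'
#' Dosages are centered by `2 p_l` and scaled by `sqrt(2 p_l (1 - p_l))`
#' before the singular value decomposition; scores are the top-`k` left
#' singular vectors scaled by their singular values, with signs fixed so each
#' component's largest-magnitude variant loading is positive.
#'
#' @param panel a [genotype_panel()] with no zero-variance variants.
#' @param k number of components.
#' @return A samples-by-`k` score matrix.
#' @export
compute_genetic_pcs <- function(panel, k = 4L) {
  stopifnot(inherits(panel, "genotype_panel"))
  p <- colMeans(panel$dosage) / 2
  if (any(p == 0 | p == 1)) {
    stop("zero-variance variants present; MAF-filter the panel first",
         call. = FALSE)
  }
  std <- sweep(sweep(panel$dosage, 2L, 2 * p, "-"),
               2L, sqrt(2 * p * (1 - p)), "/")
  pca_scores(std, as.integer(k))
}

#' Surrogate-variable scores for an omics matrix
#'
#' Each feature is residualized on the known covariates (ordinary least
#' squares, intercept included), features are standardized, and the top-`k`
#' principal-component scores of the residual matrix are returned, sign-fixed
#' as in [compute_genetic_pcs()]. These capture unobserved structure such as
#' hidden batch factors.
#'
#' @param omics samples-by-features numeric matrix (inverse-normalized).
#' @param covariates covariate tibble (see [covariate_design()]).
#' @param k number of surrogate variables.
#' @return A samples-by-`k` score matrix.
#' @export
estimate_surrogate_variables <- function(omics, covariates, k = 10L) {
  res <- residualize(omics, covariates)
  res <- scale_safe(res)
  if (k > min(dim(res))) stop("`k` exceeds residual rank", call. = FALSE)
  pca_scores(res, as.integer(k))
}

#' Flag multivariate outliers with a chi-squared statistic
#'
#' For each score block the per-sample statistic is
#' `T_i = sum_j (s_ij / sd_j)^2`, referred to the upper tail of a chi-squared
#' distribution with `k` (the number of score columns) degrees of freedom.
#' Samples with `p < alpha` in either block are removed.
#'
#' @param pc_scores,sv_scores samples-by-k score matrices on the same samples.
#' @param alpha removal p-value threshold.
#' @return A list with `retained` sample ids and a `report` tibble
#'   (`sample_id`, `block`, `statistic`, `p`, `reason`).
#' @export
flag_outliers_chisq <- function(pc_scores, sv_scores, alpha = 0.001) {
  blocks <- list(pc = pc_scores, sv = sv_scores)
  ids <- rownames(pc_scores)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(nrow(pc_scores)))
  hits <- list()
  for (bn in names(blocks)) {
    s <- blocks[[bn]]
    if (ncol(s) == 0L) next
    sds <- apply(s, 2L, stats::sd)
    if (any(sds == 0)) stop("zero column SD in score block", call. = FALSE)
    t_stat <- rowSums(sweep(s, 2L, sds, "/")^2)
    p <- stats::pchisq(t_stat, df = ncol(s), lower.tail = FALSE)
    bad <- which(p < alpha)
    if (length(bad)) {
      hits[[bn]] <- tibble::tibble(sample_id = ids[bad], block = bn,
                                   statistic = t_stat[bad], p = p[bad],
                                   reason = "outlier")
    }
  }
  report <- if (length(hits)) dplyr::bind_rows(hits) else
    tibble::tibble(sample_id = character(), block = character(),
                   statistic = numeric(), p = numeric(), reason = character())
  list(retained = setdiff(ids, report$sample_id), report = report)
}

#' Build the covariate design matrix
#'
#' Intercept, age, sex, medication flag, one-hot group indicators (first
#' level dropped), plus any genetic PC and surrogate-value scores.
#'
#' @param covariates tibble with columns `age`, `sex`, `group`, `medication`
#'   (extra columns are ignored).
#' @param pcs,svs optional score matrices to append (row order must match).
#' @return A numeric design matrix with an intercept column.
#' @export
covariate_design <- function(covariates, pcs = NULL, svs = NULL) {
  g <- factor(covariates$group)
  mm <- stats::model.matrix(~ age + sex + medication + group,
                            data = data.frame(age = covariates$age,
                                              sex = covariates$sex,
                                              medication = covariates$medication,
                                              group = g))
  attr(mm, "assign") <- NULL
  attr(mm, "contrasts") <- NULL
  if (!is.null(pcs) && ncol(pcs) > 0L) {
    colnames(pcs) <- paste0("gPC", seq_len(ncol(pcs)))
    mm <- cbind(mm, pcs)
  }
  if (!is.null(svs) && ncol(svs) > 0L) {
    colnames(svs) <- paste0("SV", seq_len(ncol(svs)))
    mm <- cbind(mm, svs)
  }
  mm
}

#' Residualize omics features on covariates
#'
#' Per-feature ordinary-least-squares residuals against the full covariate
#' design (intercept included). Residuals are orthogonal to every covariate
#' column.
#'
#' @param omics samples-by-features numeric matrix (a vector is treated as a
#'   single feature).
#' @param covariates covariate tibble, or a prebuilt numeric design matrix.
#' @param pcs,svs optional score matrices forwarded to [covariate_design()].
#' @return Residual matrix with the dimensions of `omics`.
#' @export
residualize <- function(omics, covariates, pcs = NULL, svs = NULL) {
  if (is.vector(omics)) omics <- matrix(omics, ncol = 1L)
  design <- if (is.matrix(covariates)) covariates else
    covariate_design(covariates, pcs, svs)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    stop("covariate design is rank deficient", call. = FALSE)
  }
  res <- qr.resid(qr_d, omics)
  dimnames(res) <- dimnames(omics)
  res
}

#' Run the full omics/genotype QC pipeline
#'
#' Fixed stage order: MAF filter, relatedness filter, rank-based inverse
#' normalization, omics PCs + surrogate values, chi-squared outlier removal,
#' surrogate-value recomputation on the retained samples, covariate
#' residualization (age, sex, group, medication, genetic PCs, surrogate
#' values).
#'
#' @param panel a [genotype_panel()].
#' @param omics samples-by-features numeric matrix, rows aligned to the panel.
#' @param covariates covariate tibble with a `sample_id` column.
#' @param maf MAF threshold.
#' @param kinship_threshold kinship pruning cutoff.
#' @param n_pcs genetic PCs used as covariates.
#' @param n_omics_pcs omics PCs used for outlier screening.
#' @param n_svs surrogate values.
#' @param outlier_alpha chi-squared outlier p-value threshold.
#' @return A list of class `qc_result`: `panel` (filtered), `residuals`
#'   (QC'd omics), `covariate_design`, `genetic_pcs`, `surrogate_values`,
#'   and `report` (tibble of removed variants/samples with reasons).
#' @export
run_qc <- function(panel, omics, covariates, maf = 0.05,
                   kinship_threshold = 2^-2.5, n_pcs = 4L,
                   n_omics_pcs = 10L, n_svs = 10L, outlier_alpha = 0.001) {
  m <- filter_maf(panel, maf)
  kin <- estimate_kinship(m$panel)
  rel <- filter_related(kin, kinship_threshold)
  panel2 <- subset_panel(m$panel, samples = rel$retained)
  omics2 <- omics[match(rel$retained, rownames(omics)), , drop = FALSE]
  cov2 <- covariates[match(rel$retained, covariates$sample_id), ]

  omics_int <- apply(omics2, 2L, inverse_normal_transform)
  rownames(omics_int) <- rownames(omics2)

  # surrogate estimation needs many more features than factors; with few
  # features the SVs would absorb the signal itself
  n_svs_eff <- min(n_svs, ncol(omics_int) %/% 10L,
                   nrow(omics_int) - 1L)
  omics_pcs <- pca_scores(scale_safe(omics_int), min(n_omics_pcs, dim(omics_int)))
  svs <- estimate_surrogate_variables(omics_int, cov2, n_svs_eff)
  out <- flag_outliers_chisq(omics_pcs, svs, outlier_alpha)

  panel3 <- subset_panel(panel2, samples = out$retained)
  keep <- match(out$retained, rownames(omics_int))
  omics3 <- omics_int[keep, , drop = FALSE]
  cov3 <- cov2[match(out$retained, cov2$sample_id), ]

  gpcs <- compute_genetic_pcs(panel3, n_pcs)
  svs2 <- estimate_surrogate_variables(omics3, cov3,
                                       min(n_svs_eff, nrow(omics3) - 1L))
  design <- covariate_design(cov3, gpcs, svs2)
  residuals <- residualize(omics3, design)

  report <- dplyr::bind_rows(
    m$report,
    rel$report,
    out$report[, c("sample_id", "statistic", "p", "reason")]
  )
  structure(
    list(panel = panel3, residuals = residuals, covariate_design = design,
         genetic_pcs = gpcs, surrogate_values = svs2, report = report,
         covariates = cov3),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> %d samples, %d variants, %d features retained\n",
              nrow(x$residuals), ncol(x$panel$dosage), ncol(x$residuals)))
  cat(sprintf("  removed: %d records (%s)\n", nrow(x$report),
              paste(unique(x$report$reason), collapse = ", ")))
  invisible(x)
}
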