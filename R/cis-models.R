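#' Select cis-SNPs for a gene
#'
#' Variants on the gene's chromosome with position in the closed window
#' `[tss - window, tes + window]` (gene body plus flanks), intersected with
#' `allowed_ids` when given (typically the set of GWAS variants), ordered by
#' position.
#'
#' @param gene one-row tibble or list with `gene_id`, `chrom`, `tss`, `tes`.
#' @param panel a [genotype_panel()].
#' @param allowed_ids optional character vector restricting candidates.
#' @param window flank size in bp (default 1 Mb each side).
#' @return Character vector of variant ids (possibly empty).
#' @export
select_cis_snps <- function(gene, panel, allowed_ids = NULL, window = 1e6) {
  v <- panel$variants
  keep <- v$chrom == gene$chrom &
    v$pos >= gene$tss - window & v$pos <= gene$tes + window
  ids <- v$variant_id[keep][order(v$pos[keep])]
  if (!is.null(allowed_ids)) ids <- ids[ids %in% allowed_ids]
  ids
}

make_folds <- function(n, n_folds, seed) {
  with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
}

# cv.glmnet with a single-column fallback (glmnet needs >= 2 columns; a
# zero dummy column is appended and its coefficient discarded).
cv_enet <- function(y, X, alpha, foldid, lambda = NULL) {
  pad <- ncol(X) == 1L
  if (pad) X <- cbind(X, dummy__ = 0)
  fit <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                           nlambda = 100, lambda.min.ratio = 1e-3,
                           lambda = lambda, standardize = TRUE)
  beta <- as.numeric(stats::coef(fit, s = "lambda.min"))
  names(beta) <- c("(Intercept)", colnames(X))
  if (pad) beta <- beta[names(beta) != "dummy__"]
  list(intercept = beta[1L], weights = beta[-1L], lambda = fit$lambda.min)
}

#' Fit an elastic-net cis model with cross-validated penalty selection
#'
#' Minimizes `(1/2n) ||y - b0 - X b||^2 + lambda (alpha ||b||_1 +
#' (1 - alpha) ||b||_2^2 / 2)` with the penalty chosen as the CV mean-squared
#' -error minimizer over a 100-point log-spaced path (path ratio 1e-3). Fold
#' assignment is seeded, so fits are deterministic.
#'
#' @param y residualized omic vector.
#' @param X cis dosage matrix, rows aligned with `y`. Zero-variance columns
#'   are dropped before fitting (and reported with weight 0).
#' @param alpha elastic-net mixing parameter (0.5 by default).
#' @param n_folds folds for penalty selection.
#' @param seed fold-assignment seed.
#' @return A list with `weights` (named per-SNP vector, zeros included),
#'   `intercept`, `lambda`, and `nonzero` (ids with nonzero weight).
#' @export
fit_elastic_net_cv <- function(y, X, alpha = 0.5, n_folds = 10L, seed = 1L) {
  if (n_folds < 2L) stop("`n_folds` must be at least 2", call. = FALSE)
  if (length(y) != nrow(X)) stop("`y` and `X` misaligned", call. = FALSE)
  if (length(y) < n_folds) stop("fewer samples than folds", call. = FALSE)
  if (stats::var(y) == 0) stop("`y` has zero variance", call. = FALSE)
  keep <- apply(X, 2L, stats::var) > 0
  weights <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (!any(keep)) {
    return(list(weights = weights, intercept = mean(y), lambda = NA_real_,
                nonzero = character()))
  }
  foldid <- make_folds(length(y), n_folds, seed)
  fit <- cv_enet(y, X[, keep, drop = FALSE], alpha, foldid)
  weights[names(fit$weights)] <- fit$weights
  list(weights = weights, intercept = fit$intercept, lambda = fit$lambda,
       nonzero = names(weights)[weights != 0])
}

#' Out-of-fold cross-validated model performance
#'
#' Nested cross-validation: for each of `n_folds` outer folds the elastic net
#' (penalty re-selected by inner CV) is refit on the remaining folds and the
#' held-out samples are predicted. `cv_r2` is the squared Pearson correlation
#' between the concatenated out-of-fold predictions and `y`; `cv_pvalue` is
#' the one-sided p-value of that correlation (t distribution, n - 2 df,
#' alternative r > 0). Constant predictions yield `cv_r2 = 0`,
#' `cv_pvalue = 1`.
#'
#' @inheritParams fit_elastic_net_cv
#' @param n_folds outer folds (5 by default).
#' @return A list with `cv_r2`, `cv_pvalue`, and `predictions`.
#' @export
evaluate_model_cv <- function(y, X, alpha = 0.5, n_folds = 5L, seed = 1L) {
  if (n_folds < 2L) stop("`n_folds` must be at least 2", call. = FALSE)
  n <- length(y)
  outer_id <- make_folds(n, n_folds, seed)
  pred <- numeric(n)
  fitted_any <- FALSE
  for (f in seq_len(n_folds)) {
    tr <- outer_id != f
    Xtr <- X[tr, , drop = FALSE]
    keep <- apply(Xtr, 2L, stats::var) > 0
    if (!any(keep) || stats::var(y[tr]) == 0) {
      pred[!tr] <- mean(y[tr])
      next
    }
    fitted_any <- TRUE
    inner_id <- make_folds(sum(tr), n_folds, derive_seed(seed, f))
    fit <- cv_enet(y[tr], Xtr[, keep, drop = FALSE], alpha, inner_id)
    pred[!tr] <- drop(X[!tr, keep, drop = FALSE] %*% fit$weights) +
      fit$intercept
  }
  if (!fitted_any || stats::sd(pred) == 0 || stats::sd(y) == 0) {
    return(list(cv_r2 = 0, cv_pvalue = 1, predictions = pred))
  }
  r <- stats::cor(pred, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(cv_r2 = r^2,
       cv_pvalue = stats::pt(tt, df = n - 2, lower.tail = FALSE),
       predictions = pred)
}

#' Train elastic-net cis models for all genes
#'
#' For each annotated gene: select cis-SNPs (restricted to `allowed_ids`,
#' typically the GWAS variants), drop zero-variance and duplicate-position
#' SNPs, fit the elastic net on the full training set, and evaluate
#' out-of-fold performance by nested cross-validation. Genes with no cis-SNP
#' or an all-zero weight vector are dropped ("nontrivial model" rule:
#' at least one cis-SNP must have a nonzero weight). Benjamini-Hochberg FDR
#' over the CV p-values flags significantly predictable genes at
#' `q <= fdr`.
#'
#' @param panel QC'd training [genotype_panel()].
#' @param omics samples-by-genes matrix of residualized omic levels (column
#'   names are gene ids).
#' @param annotations gene annotation tibble (`gene_id`, `chrom`, `tss`,
#'   `tes`).
#' @param allowed_ids optional variant-id restriction (GWAS SNPs).
#' @param window cis window flank in bp.
#' @param alpha elastic-net mixing parameter.
#' @param n_folds folds for the performance cross-validation.
#' @param fdr predictability FDR level.
#' @param evaluate logical; `FALSE` skips the nested cross-validated
#'   performance metrics (`cv_r2`, `cv_pvalue`, `qvalue`, `predictable`
#'   become `NA`), which roughly halves training time when only the weights
#'   are needed.
#' @param seed base seed; each gene gets a derived fold seed.
#' @return An object of class `xwas_models`: list with `weights` (tibble:
#'   `gene_id`, `variant_id`, `effect_allele`, `other_allele`, `weight`,
#'   `sigma`), `summary` (tibble: `gene_id`, `cv_r2`, `cv_pvalue`, `qvalue`,
#'   `predictable`, `n_snps_in_window`, `n_snps_nonzero`), and `dropped`
#'   (tibble: `gene_id`, `reason`).
#' @export
train_models <- function(panel, omics, annotations, allowed_ids = NULL,
                         window = 1e6, alpha = 0.5, n_folds = 5L,
                         fdr = 0.05, evaluate = TRUE, seed = 1L) {
  genes <- intersect(annotations$gene_id, colnames(omics))
  if (length(genes) == 0L) {
    stop("no overlap between annotation and omics gene ids", call. = FALSE)
  }
  weights <- list()
  summaries <- list()
  dropped <- list()
  for (gid in genes) {
    gene <- annotations[annotations$gene_id == gid, ]
    ids <- select_cis_snps(gene, panel, allowed_ids, window)
    if (length(ids) == 0L) {
      dropped[[gid]] <- tibble::tibble(gene_id = gid, reason = "no_cis_snps")
      next
    }
    v <- panel$variants[match(ids, panel$variants$variant_id), ]
    dup <- duplicated(v$pos)
    X <- panel$dosage[, ids[!dup], drop = FALSE]
    zv <- apply(X, 2L, stats::var) == 0
    X <- X[, !zv, drop = FALSE]
    if (ncol(X) == 0L) {
      dropped[[gid]] <- tibble::tibble(gene_id = gid, reason = "no_cis_snps")
      next
    }
    y <- omics[, gid]
    gseed <- derive_seed(seed, match(gid, genes))
    fit <- fit_elastic_net_cv(y, X, alpha = alpha, n_folds = max(10L, n_folds),
                              seed = gseed)
    if (length(fit$nonzero) == 0L) {
      dropped[[gid]] <- tibble::tibble(gene_id = gid, reason = "all_zero_model")
      next
    }
    ev <- if (evaluate) {
      evaluate_model_cv(y, X, alpha = alpha, n_folds = n_folds, seed = gseed)
    } else {
      list(cv_r2 = NA_real_, cv_pvalue = NA_real_)
    }
    w <- fit$weights[fit$nonzero]
    vv <- panel$variants[match(fit$nonzero, panel$variants$variant_id), ]
    weights[[gid]] <- tibble::tibble(
      gene_id = gid, variant_id = fit$nonzero,
      effect_allele = vv$alt, other_allele = vv$ref,
      weight = unname(w),
      sigma = unname(apply(panel$dosage[, fit$nonzero, drop = FALSE], 2L,
                           stats::sd))
    )
    summaries[[gid]] <- tibble::tibble(
      gene_id = gid, cv_r2 = ev$cv_r2, cv_pvalue = ev$cv_pvalue,
      n_snps_in_window = length(ids), n_snps_nonzero = length(fit$nonzero)
    )
  }
  if (length(summaries) == 0L) {
    stop("no gene yielded a nontrivial model", call. = FALSE)
  }
  summary <- dplyr::bind_rows(summaries)
  if (evaluate) {
    summary$qvalue <- bh_fdr(summary$cv_pvalue)
    summary$predictable <- summary$qvalue <= fdr
  } else {
    summary$qvalue <- NA_real_
    summary$predictable <- NA
  }
  summary <- summary[, c("gene_id", "cv_r2", "cv_pvalue", "qvalue",
                         "predictable", "n_snps_in_window", "n_snps_nonzero")]
  structure(
    list(weights = dplyr::bind_rows(weights), summary = summary,
         dropped = if (length(dropped)) dplyr::bind_rows(dropped) else
           tibble::tibble(gene_id = character(), reason = character())),
    class = "xwas_models"
  )
}

#' @export
print.xwas_models <- function(x, ...) {
  cat(sprintf("<xwas_models> %d nontrivial models (%d dropped), %d weights\n",
              nrow(x$summary), nrow(x$dropped), nrow(x$weights)))
  cat(sprintf("  predictable at FDR: %d\n", sum(x$summary$predictable)))
  invisible(x)
}

#' Tidy per-SNP weights of trained cis models
#'
#' @param x an `xwas_models` object.
#' @param ... unused.
#' @return The weights tibble (gene, variant, alleles, weight, training SD).
#' @export
tidy.xwas_models <- function(x, ...) x$weights

#' One-row-per-gene model performance summary
#'
#' @param x an `xwas_models` object.
#' @param ... unused.
#' @return The summary tibble with CV r2, p, q, and SNP counts.
#' @export
glance.xwas_models <- function(x, ...) x$summary

#' Build a per-gene LD reference from a genotype panel
#'
#' Covariance matrices of the model SNP dosages (denominator `n - 1`), one
#' per gene, SNP order matching the weight table.
#'
#' @param panel reference [genotype_panel()] (by default the training panel).
#' @param models an `xwas_models` object (or a weights tibble).
#' @return A named list of covariance matrices of class `ld_reference`.
#' @export
build_ld_reference <- function(panel, models) {
  w <- if (inherits(models, "xwas_models")) models$weights else models
  genes <- unique(w$gene_id)
  out <- lapply(genes, function(g) {
    ids <- w$variant_id[w$gene_id == g]
    stats::cov(panel$dosage[, ids, drop = FALSE])
  })
  names(out) <- genes
  structure(out, class = "ld_reference")
}
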