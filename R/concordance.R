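#' Signed log10 p-value
#'
#' `sign(z) * (-log10 p)`: the quantity compared between proteome- and
#' transcriptome-based association studies. `p = 1` maps to 0; `p = 0` is
#' clamped to the smallest representable double with a warning.
#'
#' @param z association Z-scores (their sign is the direction).
#' @param p two-sided p-values in `(0, 1]`.
#' @return Numeric vector of signed log p-values.
#' @export
signed_logp <- function(z, p) {
  if (any(p < 0 | p > 1)) stop("p-values must be in [0, 1]", call. = FALSE)
  if (any(p == 0)) {
    warning("p-values of 0 clamped to the smallest representable double")
    p[p == 0] <- .Machine$double.xmin
  }
  sign(z) * (-log10(p))
}

#' Spearman rank correlation with p-value
#'
#' Pearson correlation of average ranks. The p-value is exact (full
#' permutation enumeration) for `n <= 9` without ties, and otherwise uses
#' the t approximation `t = rho sqrt((n - 2) / (1 - rho^2))` with `n - 2`
#' degrees of freedom, two-sided.
#'
#' @param x,y paired numeric vectors; pairs with missing values are dropped.
#' @return A list with `rho`, `p`, `n`, and `degenerate` (`TRUE` when either
#'   vector is constant, in which case `rho` and `p` are `NA`).
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  has_ties <- anyDuplicated(rx) > 0L || anyDuplicated(ry) > 0L
  if (n <= 9L && !has_ties) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1L, function(pm) stats::cor(rx, ry[pm]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n, degenerate = FALSE)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' Exact one-sided binomial sign-concordance test
#'
#' Upper-tail probability `P(X >= n_positive | n_total, 1/2)` computed by
#' exact enumeration of binomial coefficients:
#' `sum_{k >= n_positive} C(n_total, k) / 2^n_total`.
#'
#' @param n_positive number of positive outcomes (e.g., tissues with a
#'   positive correlation).
#' @param n_total number of trials.
#' @return The exact one-sided p-value.
#' @export
sign_concordance_binomial <- function(n_positive, n_total) {
  if (n_total < 1L) stop("`n_total` must be positive", call. = FALSE)
  if (n_positive < 0L || n_positive > n_total) {
    stop("`n_positive` must be between 0 and `n_total`", call. = FALSE)
  }
  sum(choose(n_total, n_positive:n_total)) / 2^n_total
}

#' PWAS-TWAS concordance report across tissues
#'
#' Joins the proteome-based associations to each tissue's transcriptome-based
#' associations on the shared genes (missing gene-tissue pairs are dropped
#' pairwise, never imputed), computes per-tissue Spearman correlations of the
#' signed log p-values, counts positive-correlation tissues, and tests that
#' count with the exact one-sided binomial sign test. Per gene, flags whether
#' both studies are significant and whether their directions agree.
#'
#' @param pwas association tibble (`gene_id`, `zscore`, `pvalue`, `qvalue`).
#' @param twas_by_tissue named list of association tibbles with the same
#'   columns, one per tissue.
#' @param fdr significance level used for the agreement flags.
#' @param min_genes tissues with fewer shared genes are skipped.
#' @return An object of class `concordance_report`: list with `tissues`
#'   (tibble: `tissue`, `n_genes`, `rho`, `p`), `n_positive`, `n_tissues`,
#'   `binomial_p`, `gene_agreement` (tibble: `tissue`, `gene_id`,
#'   `both_significant`, `concordant`), and `skipped` (character vector of
#'   skipped tissues).
#' @export
concordance_report <- function(pwas, twas_by_tissue, fdr = 0.05,
                               min_genes = 4L) {
  stopifnot(is.list(twas_by_tissue), !is.null(names(twas_by_tissue)))
  pw <- tibble::tibble(
    gene_id = pwas$gene_id,
    slp_p = signed_logp(pwas$zscore, pwas$pvalue),
    sig_p = pwas$qvalue <= fdr,
    dir_p = sign(pwas$zscore)
  )
  rows <- list()
  agreement <- list()
  skipped <- character()
  for (tis in names(twas_by_tissue)) {
    tw <- twas_by_tissue[[tis]]
    tw <- tibble::tibble(
      gene_id = tw$gene_id,
      slp_t = signed_logp(tw$zscore, tw$pvalue),
      sig_t = tw$qvalue <= fdr,
      dir_t = sign(tw$zscore)
    )
    j <- dplyr::inner_join(pw, tw, by = "gene_id")
    if (nrow(j) < min_genes) {
      skipped <- c(skipped, tis)
      next
    }
    sp <- spearman(j$slp_p, j$slp_t)
    rows[[tis]] <- tibble::tibble(tissue = tis, n_genes = sp$n,
                                  rho = sp$rho, p = sp$p)
    agreement[[tis]] <- tibble::tibble(
      tissue = tis, gene_id = j$gene_id,
      both_significant = j$sig_p & j$sig_t,
      concordant = j$dir_p == j$dir_t
    )
  }
  if (length(rows) == 0L) {
    stop("no tissue had enough shared genes", call. = FALSE)
  }
  tissues <- dplyr::bind_rows(rows)
  usable <- !is.na(tissues$rho)
  n_positive <- sum(tissues$rho[usable] > 0)
  n_tissues <- sum(usable)
  structure(
    list(tissues = tissues,
         n_positive = n_positive,
         n_tissues = n_tissues,
         binomial_p = sign_concordance_binomial(n_positive, n_tissues),
         gene_agreement = dplyr::bind_rows(agreement),
         skipped = skipped,
         fdr = fdr),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d tissues, rho > 0 in %d (binomial p = %.3g)\n",
              x$n_tissues, x$n_positive, x$binomial_p))
  invisible(x)
}

#' Tidy per-tissue concordance results
#'
#' @param x a `concordance_report`.
#' @param ... unused.
#' @return The per-tissue tibble (n genes, Spearman rho, p).
#' @export
tidy.concordance_report <- function(x, ...) x$tissues

#' One-row concordance summary
#'
#' @param x a `concordance_report`.
#' @param ... unused.
#' @return One-row tibble with the positive-correlation count and exact
#'   binomial p-value.
#' @export
glance.concordance_report <- function(x, ...) {
  tibble::tibble(n_tissues = x$n_tissues, n_positive = x$n_positive,
                 binomial_p = x$binomial_p)
}
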