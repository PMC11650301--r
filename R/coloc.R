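#' Wakefield approximate-Bayes-factor log values
#'
#' For a single-SNP association with estimate `beta`, standard error `se`
#' (`V = se^2`) and prior effect variance `W`:
#' `log ABF = (1/2) log(1 - r) + (z^2 / 2) r` with shrinkage
#' `W / (V + W)` as `r` and `z = beta / se`.
#'
#' @param beta,se effect estimates and standard errors (vectorized).
#' @param W prior effect variance; the default `0.15^2` is the quantitative
#'   -trait convention on the standardized-effect scale.
#' @return Numeric vector of log approximate Bayes factors.
#' @export
wakefield_labf <- function(beta, se, W = 0.15^2) {
  if (any(!is.finite(beta)) || any(!is.finite(se)) || !is.finite(W)) {
    stop("non-finite inputs", call. = FALSE)
  }
  if (any(se <= 0)) stop("`se` must be positive", call. = FALSE)
  if (W < 0) stop("`W` must be nonnegative", call. = FALSE)
  V <- se^2
  r <- W / (V + W)
  z <- beta / se
  0.5 * log1p(-r) + (z^2 / 2) * r
}

#' Colocalization posterior probabilities from two log-ABF tracks
#'
#' Five-hypothesis posterior over a shared SNP window: H0 no signal, H1/H2 a
#' causal variant for trait 1/2 only, H3 two distinct causal variants, H4 one
#' shared causal variant. Unnormalized weights are `1`,
#' `p1 sum_i exp(labf1_i)`, `p2 sum_j exp(labf2_j)`,
#' `p1 p2 (sum_i sum_j - sum_{i=j}) exp(labf1_i + labf2_j)`, and
#' `p12 sum_i exp(labf1_i + labf2_i)`; everything is evaluated in log space.
#'
#' @param labf1,labf2 per-SNP log-ABF vectors over the harmonized
#'   intersection (equal length, same SNP order).
#' @param p1,p2,p12 prior probabilities that a SNP is causal for trait 1,
#'   trait 2, or both.
#' @param threshold classification cutoff on the maximum posterior.
#' @return An object of class `coloc_result`: list with `pp` (named numeric,
#'   `PP0`..`PP4`, summing to 1), `n_snps`, `priors`, `label` (the argmax
#'   hypothesis when its probability exceeds `threshold`, otherwise
#'   `"underpowered"`), and `threshold`.
#' @export
coloc_pp <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                     threshold = 0.5) {
  if (length(labf1) != length(labf2) || length(labf1) < 1L) {
    stop("log-ABF tracks must have equal length >= 1", call. = FALSE)
  }
  if (p1 < 0 || p2 < 0 || p12 < 0) stop("negative priors", call. = FALSE)
  if (p1 + p2 + p12 >= 1) {
    stop("`p1 + p2 + p12` must be below 1", call. = FALSE)
  }
  l1 <- logsumexp(labf1)
  l2 <- logsumexp(labf2)
  l12 <- logsumexp(labf1 + labf2)
  lw <- c(
    PP0 = 0,
    PP1 = log(p1) + l1,
    PP2 = log(p2) + l2,
    PP3 = log(p1) + log(p2) + logdiffexp(l1 + l2, l12),
    PP4 = log(p12) + l12
  )
  pp <- exp(lw - logsumexp(lw))
  pp <- pp / sum(pp)
  label <- if (max(pp) > threshold) names(pp)[which.max(pp)] else "underpowered"
  structure(
    list(pp = pp, n_snps = length(labf1),
         priors = c(p1 = p1, p2 = p2, p12 = p12),
         label = label, threshold = threshold),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d SNPs, label: %s\n", x$n_snps, x$label))
  print(round(x$pp, 4))
  invisible(x)
}

#' Tidy colocalization posteriors
#'
#' @param x a `coloc_result`.
#' @param ... unused.
#' @return Tibble with one row per hypothesis (`hypothesis`, `pp`).
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble::tibble(hypothesis = names(x$pp), pp = unname(x$pp))
}

#' One-row colocalization summary
#'
#' @param x a `coloc_result`.
#' @param ... unused.
#' @return One-row tibble with PP0..PP4, SNP count, and label.
#' @export
glance.coloc_result <- function(x, ...) {
  tibble::tibble(PP0 = x$pp[["PP0"]], PP1 = x$pp[["PP1"]], PP2 = x$pp[["PP2"]],
                 PP3 = x$pp[["PP3"]], PP4 = x$pp[["PP4"]],
                 n_snps = x$n_snps, label = x$label)
}

#' Per-SNP marginal QTL summary statistics
#'
#' Single-SNP ordinary-least-squares regressions of a (residualized) omic
#' level on each variant's dosage; the summary-statistic input COLOC needs
#' for the molecular tracks.
#'
#' @param panel a [genotype_panel()].
#' @param y numeric phenotype vector aligned with the panel samples.
#' @param variant_ids optional subset of variants.
#' @return A GWAS-summary-shaped tibble (`variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `z`, `n`).
#' @export
qtl_summary <- function(panel, y, variant_ids = NULL) {
  ids <- if (is.null(variant_ids)) panel$variants$variant_id else variant_ids
  X <- panel$dosage[, ids, drop = FALSE]
  n <- length(y)
  xc <- sweep(X, 2L, colMeans(X), "-")
  yc <- y - mean(y)
  Sxx <- colSums(xc^2)
  Sxy <- drop(crossprod(xc, yc))
  Syy <- sum(yc^2)
  beta <- ifelse(Sxx > 0, Sxy / Sxx, 0)
  rss <- pmax(Syy - beta^2 * Sxx, 0)
  se <- ifelse(Sxx > 0, sqrt(rss / (n - 2) / Sxx), Inf)
  v <- panel$variants[match(ids, panel$variants$variant_id), ]
  tibble::tibble(
    variant_id = ids, chrom = v$chrom, pos = v$pos,
    effect_allele = v$alt, other_allele = v$ref,
    beta = beta, se = se,
    z = ifelse(is.finite(se) & se > 0, beta / se, 0),
    n = as.integer(n)
  )
}

coloc_pair <- function(s1, s2, p1, p2, p12, W, threshold) {
  shared <- intersect(s1$variant_id, s2$variant_id)
  if (length(shared) == 0L) {
    stop("empty SNP intersection for colocalization pair", call. = FALSE)
  }
  a <- s1[match(shared, s1$variant_id), ]
  b <- s2[match(shared, s2$variant_id), ]
  # align track-2 alleles to track 1 (sign is irrelevant for the ABF, but
  # inconsistent allele pairs are dropped)
  same <- a$effect_allele == b$effect_allele & a$other_allele == b$other_allele
  swap <- a$effect_allele == b$other_allele & a$other_allele == b$effect_allele
  ok <- same | swap
  a <- a[ok, ]
  b <- b[ok, ]
  if (nrow(a) == 0L) {
    stop("no allele-consistent SNPs for colocalization pair", call. = FALSE)
  }
  coloc_pp(wakefield_labf(a$beta, a$se, W),
           wakefield_labf(b$beta, b$se, W),
           p1 = p1, p2 = p2, p12 = p12, threshold = threshold)
}

#' Pairwise colocalization of trait, protein, and expression signals
#'
#' Runs COLOC-style colocalization for the three pairs
#' trait-protein, trait-expression, and protein-expression over a gene's
#' cis window, from three summary-statistic tables (the molecular tracks are
#' typically [qtl_summary()] outputs on the training panel).
#'
#' @param trait_gwas,protein_qtl,expression_qtl summary tibbles sharing
#'   variant ids over the gene's cis window.
#' @param p1,p2,p12 colocalization priors.
#' @param W Wakefield prior effect variance.
#' @param threshold classification cutoff; a pair whose maximum posterior
#'   falls below it is flagged `"underpowered"`.
#' @return A tibble with one row per pair (`pair`, `PP0`..`PP4`, `n_snps`,
#'   `label`), plus the three `coloc_result` objects in the
#'   `"results"` attribute.
#' @export
coloc_matrix <- function(trait_gwas, protein_qtl, expression_qtl,
                         p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, W = 0.15^2,
                         threshold = 0.5) {
  pairs <- list(
    trait_protein = list(trait_gwas, protein_qtl),
    trait_expression = list(trait_gwas, expression_qtl),
    protein_expression = list(protein_qtl, expression_qtl)
  )
  results <- lapply(pairs, function(p) {
    coloc_pair(p[[1]], p[[2]], p1, p2, p12, W, threshold)
  })
  out <- dplyr::bind_rows(lapply(results, glance), .id = "pair")
  attr(out, "results") <- results
  out
}
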