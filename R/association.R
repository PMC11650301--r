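#' Harmonize a gene's model weights with GWAS summary statistics
#'
#' Joins model SNPs to GWAS records by variant id and aligns effect alleles:
#' identical allele pairs keep the GWAS Z; swapped pairs (model effect allele
#' equals the GWAS other allele and vice versa) negate Z and beta;
#' inconsistent pairs are excluded with reason `"allele_mismatch"`; model
#' SNPs absent from the GWAS are excluded with reason `"missing_in_gwas"`.
#'
#' @param weights weights tibble for one gene (`variant_id`, `effect_allele`,
#'   `other_allele`, `weight`, `sigma`).
#' @param gwas GWAS summary tibble (`variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `z`).
#' @return A list with `aligned` (tibble: `variant_id`, `weight`, `sigma`,
#'   `z`, `beta`, `se`) and `exclusions` (tibble: `variant_id`, `reason`).
#' @export
harmonize <- function(weights, gwas) {
  idx <- match(weights$variant_id, gwas$variant_id)
  missing <- is.na(idx)
  excl <- list()
  if (any(missing)) {
    excl$missing <- tibble::tibble(variant_id = weights$variant_id[missing],
                                   reason = "missing_in_gwas")
  }
  w <- weights[!missing, ]
  g <- gwas[idx[!missing], ]
  same <- w$effect_allele == g$effect_allele & w$other_allele == g$other_allele
  swap <- w$effect_allele == g$other_allele & w$other_allele == g$effect_allele
  bad <- !(same | swap)
  if (any(bad)) {
    excl$mismatch <- tibble::tibble(variant_id = w$variant_id[bad],
                                    reason = "allele_mismatch")
  }
  sgn <- ifelse(swap, -1, 1)[!bad]
  aligned <- tibble::tibble(
    variant_id = w$variant_id[!bad],
    weight = w$weight[!bad],
    sigma = w$sigma[!bad],
    z = sgn * g$z[!bad],
    beta = sgn * g$beta[!bad],
    se = g$se[!bad]
  )
  exclusions <- if (length(excl)) dplyr::bind_rows(excl) else
    tibble::tibble(variant_id = character(), reason = character())
  list(aligned = aligned, exclusions = exclusions)
}

#' Gene-level association Z from weights, GWAS Z-scores, and an LD reference
#'
#' The summary-statistic imputation statistic
#' `z_g = sum_l w_l sigma_l z_l / sigma_g` with
#' `sigma_g^2 = w' Gamma w`, where `Gamma` is the LD-reference covariance of
#' the model SNP dosages and `sigma_l = sqrt(diag(Gamma))` — both variance
#' terms come from the same reference panel, which keeps the statistic
#' consistent when the LD reference is not the training panel. Model SNPs
#' missing from the GWAS are handled by computing with the available subset
#' of weights and the matching `Gamma` submatrix.
#'
#' @param aligned harmonized tibble from [harmonize()].
#' @param ld_gene covariance matrix for the gene's model SNPs (dimnames are
#'   variant ids).
#' @param gene_id,trait labels carried into the result.
#' @param n_missing count of model SNPs absent from the GWAS.
#' @return One-row tibble (`gene_id`, `trait`, `zscore`, `pvalue`,
#'   `direction`, `n_snps_used`, `n_snps_missing`), or a zero-row tibble if
#'   the model is degenerate (`sigma_g^2 <= 0`) or empty.
#' @export
association_z <- function(aligned, ld_gene, gene_id = NA_character_,
                          trait = NA_character_, n_missing = 0L) {
  empty <- tibble::tibble(gene_id = character(), trait = character(),
                          zscore = numeric(), pvalue = numeric(),
                          direction = numeric(), n_snps_used = integer(),
                          n_snps_missing = integer())
  if (nrow(aligned) == 0L) return(empty)
  ids <- aligned$variant_id
  G <- ld_gene[ids, ids, drop = FALSE]
  s2 <- drop(crossprod(aligned$weight, G %*% aligned$weight))
  if (!is.finite(s2) || s2 <= 0) return(empty)
  zg <- sum(aligned$weight * sqrt(diag(G)) * aligned$z) / sqrt(s2)
  tibble::tibble(
    gene_id = gene_id, trait = trait, zscore = zg,
    pvalue = 2 * stats::pnorm(-abs(zg)),
    direction = sign(zg),
    n_snps_used = nrow(aligned),
    n_snps_missing = as.integer(n_missing)
  )
}

#' Benjamini-Hochberg q-values
#'
#' Step-up q-values `q_(i) = min_{j >= i} m p_(j) / j`, monotone
#' nondecreasing in p.
#'
#' @param pvalues vector of p-values in `(0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) stop("empty p-value vector", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Decompose a gene association into per-SNP contributions
#'
#' Each SNP is oriented so its GWAS effect is positive (flipping an allele
#' negates both Z and the model weight). Reports the oriented weights, the
#' per-SNP contributions `w_l sigma_l z_l`, and the |Z|-weighted average of
#' oriented weights `sum |z_l| w_l / sum |z_l|`, which has the same sign as
#' (and is proportional to, under diagonal LD) the gene-level association.
#'
#' @param aligned harmonized tibble from [harmonize()].
#' @return A list with `table` (tibble: `variant_id`, `z`, `weight`,
#'   `contribution`, all on the positive-GWAS-effect orientation),
#'   `weighted_average`, and `all_null` (`TRUE` when every Z is 0, in which
#'   case the average is reported as 0).
#' @export
decompose_contributions <- function(aligned) {
  flip <- ifelse(aligned$z < 0, -1, 1)
  z_o <- flip * aligned$z
  w_o <- flip * aligned$weight
  contribution <- w_o * aligned$sigma * z_o
  all_null <- all(z_o == 0)
  wavg <- if (all_null) 0 else sum(z_o * w_o) / sum(z_o)
  list(
    table = tibble::tibble(variant_id = aligned$variant_id, z = z_o,
                           weight = w_o, sigma = aligned$sigma,
                           contribution = contribution),
    weighted_average = wavg,
    all_null = all_null
  )
}

#' Run summary-statistic association studies across traits
#'
#' For each trait's GWAS and each trained gene model: harmonize alleles,
#' compute the gene-level Z against the LD reference, and apply
#' Benjamini-Hochberg FDR within trait. Collects significant sets, pairwise
#' overlap counts, and a publication-style table of `-log10 p` with the
#' direction in parentheses (a dot marks non-significant entries).
#'
#' @param models an `xwas_models` object.
#' @param gwas_list named list of GWAS summary tibbles, one per trait.
#' @param ld an `ld_reference` from [build_ld_reference()].
#' @param fdr significance level on q-values.
#' @return An object of class `xwas_result`: list with `associations`
#'   (tibble over genes x traits), `significant` (named list of gene-id
#'   vectors), `overlap` (trait-by-trait matrix of shared significant genes),
#'   `table` (formatted tibble), `skipped` (tibble of gene/trait pairs with
#'   no usable SNPs), and `fdr`.
#' @export
run_xwas <- function(models, gwas_list, ld, fdr = 0.05) {
  stopifnot(inherits(models, "xwas_models"))
  if (is.data.frame(gwas_list)) gwas_list <- list(trait = gwas_list)
  if (is.null(names(gwas_list)) || any(names(gwas_list) == "")) {
    stop("`gwas_list` must be a named list of GWAS summary tables",
         call. = FALSE)
  }
  genes <- unique(models$weights$gene_id)
  rows <- list()
  skipped <- list()
  for (trait in names(gwas_list)) {
    gwas <- gwas_list[[trait]]
    for (g in genes) {
      w <- models$weights[models$weights$gene_id == g, ]
      h <- harmonize(w, gwas)
      n_missing <- sum(h$exclusions$reason == "missing_in_gwas")
      res <- association_z(h$aligned, ld[[g]], g, trait, n_missing)
      if (nrow(res) == 0L) {
        skipped[[paste(trait, g)]] <-
          tibble::tibble(gene_id = g, trait = trait,
                         reason = if (nrow(h$aligned) == 0L)
                           "no_gwas_overlap" else "degenerate_model")
      } else {
        rows[[paste(trait, g)]] <- res
      }
    }
  }
  if (length(rows) == 0L) stop("no testable gene for any trait", call. = FALSE)
  assoc <- dplyr::bind_rows(rows)
  assoc <- dplyr::mutate(dplyr::group_by(assoc, .data$trait),
                         qvalue = bh_fdr(.data$pvalue))
  assoc <- dplyr::ungroup(assoc)
  assoc <- assoc[, c("gene_id", "trait", "zscore", "pvalue", "qvalue",
                     "direction", "n_snps_used", "n_snps_missing")]

  traits <- names(gwas_list)
  significant <- lapply(traits, function(tr) {
    assoc$gene_id[assoc$trait == tr & assoc$qvalue <= fdr]
  })
  names(significant) <- traits
  overlap <- outer(traits, traits, Vectorize(function(a, b) {
    length(intersect(significant[[a]], significant[[b]]))
  }))
  dimnames(overlap) <- list(traits, traits)

  structure(
    list(associations = assoc, significant = significant, overlap = overlap,
         table = format_association_table(assoc, fdr),
         skipped = if (length(skipped)) dplyr::bind_rows(skipped) else
           tibble::tibble(gene_id = character(), trait = character(),
                          reason = character()),
         fdr = fdr),
    class = "xwas_result"
  )
}

# Table-1-style layout: one row per gene with at least one significant trait,
# "-log10p (sign)" per significant cell, "." otherwise.
format_association_table <- function(assoc, fdr) {
  fmt <- ifelse(
    assoc$qvalue <= fdr,
    sprintf("%.1f (%s)", -log10(assoc$pvalue),
            ifelse(assoc$direction >= 0, "+", "-")),
    "."
  )
  wide <- tidyr::pivot_wider(
    tibble::tibble(gene_id = assoc$gene_id, trait = assoc$trait, cell = fmt),
    names_from = "trait", values_from = "cell"
  )
  keep <- apply(wide[, -1, drop = FALSE], 1L, function(r) any(r != "."))
  wide[keep, , drop = FALSE]
}

#' @export
print.xwas_result <- function(x, ...) {
  cat(sprintf("<xwas_result> %d gene-trait tests, %d traits\n",
              nrow(x$associations), length(x$significant)))
  for (tr in names(x$significant)) {
    cat(sprintf("  %s: %d significant at FDR %.2g\n",
                tr, length(x$significant[[tr]]), x$fdr))
  }
  invisible(x)
}

#' Tidy gene-trait association results
#'
#' @param x an `xwas_result`.
#' @param ... unused.
#' @return The associations tibble (Z, p, q, direction, SNP counts).
#' @export
tidy.xwas_result <- function(x, ...) x$associations

#' One-row-per-trait association summary
#'
#' @param x an `xwas_result`.
#' @param ... unused.
#' @return Tibble with tested and significant gene counts per trait.
#' @export
glance.xwas_result <- function(x, ...) {
  tibble::tibble(
    trait = names(x$significant),
    n_tested = vapply(names(x$significant), function(tr) {
      sum(x$associations$trait == tr)
    }, integer(1)),
    n_significant = lengths(x$significant),
    fdr = x$fdr
  )
}
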