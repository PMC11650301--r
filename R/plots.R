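#' Plot gene-trait associations
#'
#' One point per gene and trait at `-log10 p`, colored by association
#' direction, with a dashed line at the largest p-value still significant at
#' the result's FDR level (per trait).
#'
#' @param object an `xwas_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.xwas_result <- function(object, ...) {
  df <- object$associations
  df$gene_index <- as.integer(factor(df$gene_id))
  df$dir <- factor(ifelse(df$direction >= 0, "+", "-"), levels = c("+", "-"))
  thr <- dplyr::summarise(
    dplyr::group_by(df, .data$trait),
    cut = if (any(.data$qvalue <= object$fdr)) {
      max(.data$pvalue[.data$qvalue <= object$fdr])
    } else {
      NA_real_
    }
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_index,
                                   y = -log10(.data$pvalue),
                                   colour = .data$dir)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(data = thr[!is.na(thr$cut), ],
                        ggplot2::aes(yintercept = -log10(.data$cut)),
                        linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$trait)) +
    ggplot2::labs(x = "gene", y = expression(-log[10](p)),
                  colour = "direction") +
    ggplot2::theme_minimal()
}

#' Plot colocalization posterior probabilities
#'
#' @param object a `coloc_result`.
#' @param ... unused.
#' @return A ggplot bar chart of PP0-PP4.
#' @export
autoplot.coloc_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hypothesis, y = .data$pp)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "posterior probability", x = NULL,
                  subtitle = sprintf("%d SNPs, label: %s",
                                     object$n_snps, object$label)) +
    ggplot2::theme_minimal()
}

#' Plot per-tissue concordance correlations
#'
#' @param object a `concordance_report`.
#' @param ... unused.
#' @return A ggplot bar chart of Spearman rho per tissue, colored by sign.
#' @export
autoplot.concordance_report <- function(object, ...) {
  df <- object$tissues
  df$sign <- factor(ifelse(df$rho > 0, "positive", "negative"),
                    levels = c("positive", "negative"))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$tissue, .data$rho),
                                   y = .data$rho, fill = .data$sign)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Spearman rho (signed log p)",
                  subtitle = sprintf("positive in %d of %d tissues, binomial p = %.2g",
                                     object$n_positive, object$n_tissues,
                                     object$binomial_p)) +
    ggplot2::theme_minimal()
}

#' Plot a per-SNP weight/Z decomposition
#'
#' SNPs oriented so all GWAS effects are positive; point size is the GWAS
#' |Z|, height is the oriented model weight, and the dashed line is the
#' |Z|-weighted average of the weights (same sign as the gene-level
#' association).
#'
#' @param decomposition output of [decompose_contributions()].
#' @return A ggplot object.
#' @export
plot_decomposition <- function(decomposition) {
  df <- decomposition$table
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$weight,
                                   size = .data$z)) +
    ggplot2::geom_point(alpha = 0.7, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = decomposition$weighted_average,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "cis-SNP (positive GWAS orientation)",
                  y = "model weight", size = "GWAS |Z|") +
    ggplot2::theme_minimal()
}
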