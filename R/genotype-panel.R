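#' Genotype panel container
#'
#' A genotype panel bundles a sample-by-variant dosage matrix with per-variant
#' metadata. Dosages count copies of the alternate allele (0, 1, 2, or
#' fractional imputed dosages in `[0, 2]`). Positions are 1-based.
#'
#' @param dosage numeric matrix, samples in rows, variants in columns. Column
#'   names must match `variants$variant_id`; row names are sample ids (created
#'   as `S0001...` when absent).
#' @param variants tibble with columns `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt` (one row per dosage column, same order).
#'
#' @return An object of class `genotype_panel`: a list with elements `dosage`,
#'   `variants` (with an added `maf` column computed from the dosages) and
#'   `samples`.
#' @export
genotype_panel <- function(dosage, variants) {
  if (!is.matrix(dosage) || !is.numeric(dosage)) {
    stop("`dosage` must be a numeric matrix (samples x variants)", call. = FALSE)
  }
  variants <- tibble::as_tibble(variants)
  required <- c("variant_id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0L) {
    stop("`variants` is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(variants) != ncol(dosage)) {
    stop("`variants` must have one row per dosage column", call. = FALSE)
  }
  if (anyDuplicated(variants$variant_id)) {
    stop("duplicate variant ids in panel", call. = FALSE)
  }
  if (any(!is.finite(dosage)) || any(dosage < 0) || any(dosage > 2)) {
    stop("dosages must be finite and within [0, 2]", call. = FALSE)
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
  }
  colnames(dosage) <- variants$variant_id
  f_alt <- colMeans(dosage) / 2
  variants$maf <- pmin(f_alt, 1 - f_alt)
  structure(
    list(dosage = dosage, variants = variants, samples = rownames(dosage)),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$variants$chrom), collapse = ", ")))
  cat(sprintf("  MAF range: %.3f - %.3f\n",
              min(x$variants$maf), max(x$variants$maf)))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Subset a genotype panel
#'
#' @param panel a [genotype_panel()].
#' @param samples,variant_ids character vectors of ids to keep (`NULL` keeps
#'   all). MAF is recomputed on the retained samples.
#' @return A `genotype_panel`.
#' @export
subset_panel <- function(panel, samples = NULL, variant_ids = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  keep_s <- if (is.null(samples)) panel$samples else samples
  keep_v <- if (is.null(variant_ids)) panel$variants$variant_id else variant_ids
  idx_v <- match(keep_v, panel$variants$variant_id)
  if (anyNA(idx_v)) stop("unknown variant ids in `variant_ids`", call. = FALSE)
  idx_s <- match(keep_s, panel$samples)
  if (anyNA(idx_s)) stop("unknown sample ids in `samples`", call. = FALSE)
  variants <- panel$variants[idx_v, setdiff(names(panel$variants), "maf")]
  genotype_panel(panel$dosage[idx_s, idx_v, drop = FALSE], variants)
}

#' Tidy a genotype panel into its per-variant metadata table
#'
#' @param x a [genotype_panel()].
#' @param ... unused.
#' @return A tibble with one row per variant (`variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `maf`, plus any generator columns such as `gene_id`).
#' @export
tidy.genotype_panel <- function(x, ...) {
  x$variants
}
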