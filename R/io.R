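# Interchange formats. All tables are tab-separated with a header row and an
# optional leading "# omixwas ..." comment carrying the config hash and seed;
# positions are 1-based inclusive throughout.

GWAS_COLUMNS <- c("variant_id", "chrom", "pos", "effect_allele",
                  "other_allele", "beta", "se", "n")

write_table <- function(x, path, stamp = NULL) {
  if (!is.null(stamp)) {
    writeLines(sprintf("# omixwas config_hash=%s seed=%s",
                       stamp$hash, stamp$seed), path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(x, path)
  }
  invisible(path)
}

read_table <- function(path, col_types = NULL) {
  readr::read_tsv(path, comment = "#", col_types = col_types,
                  progress = FALSE, show_col_types = FALSE)
}

require_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required columns: %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Write / read a genotype panel as a dosage TSV
#'
#' Variant metadata columns (`variant_id`, `chrom`, `pos`, `ref`, `alt`, plus
#' any generator columns) followed by one dosage column per sample.
#'
#' @param panel a [genotype_panel()].
#' @param path file path.
#' @param stamp optional list with `hash` and `seed` written as a comment.
#' @return `write_genotypes()` returns the path; `read_genotypes()` the
#'   reconstructed `genotype_panel`.
#' @export
write_genotypes <- function(panel, path, stamp = NULL) {
  meta <- panel$variants[, setdiff(names(panel$variants), "maf")]
  dos <- tibble::as_tibble(t(panel$dosage), .name_repair = "minimal")
  names(dos) <- panel$samples
  write_table(dplyr::bind_cols(meta, dos), path, stamp)
}

#' @rdname write_genotypes
#' @param format `"dosage"` (TSV as written by [write_genotypes()]) or
#'   `"vcf"` (biallelic records with GT or DS genotype fields; multiallelic
#'   records are skipped with a warning).
#' @export
read_genotypes <- function(path, format = c("dosage", "vcf")) {
  format <- match.arg(format)
  if (format == "vcf") return(read_genotypes_vcf(path))
  df <- read_table(path)
  require_columns(df, c("variant_id", "chrom", "pos", "ref", "alt"),
                  "genotype table")
  meta_cols <- intersect(c("variant_id", "chrom", "pos", "ref", "alt",
                           "gene_id", "alt_freq"), names(df))
  sample_cols <- setdiff(names(df), meta_cols)
  if (anyDuplicated(df$variant_id)) {
    stop("duplicate variant ids in genotype table", call. = FALSE)
  }
  dosage <- t(as.matrix(df[, sample_cols]))
  rownames(dosage) <- sample_cols
  meta <- df[, meta_cols]
  meta$chrom <- as.character(meta$chrom)
  genotype_panel(dosage, meta)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("skipped %d multiallelic record(s)", sum(multi)))
  }
  keep <- !multi
  fmt <- if ("DS" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID ||
             any(grepl("DS", v@gt[, 1]))) "DS" else "GT"
  if (fmt == "DS") {
    g <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    g <- apply(gt, c(1, 2), function(s) {
      if (is.na(s)) return(NA_real_)
      sum(as.integer(strsplit(s, "[/|]")[[1]]))
    })
  }
  g <- g[keep, , drop = FALSE]
  if (anyNA(g)) {
    stop(sprintf("%d missing genotype call(s); impute or filter upstream",
                 sum(is.na(g))), call. = FALSE)
  }
  ids <- fix[keep, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"])[no_id]
  meta <- tibble::tibble(
    variant_id = ids,
    chrom = as.character(fix[keep, "CHROM"]),
    pos = as.integer(fix[keep, "POS"]),
    ref = fix[keep, "REF"],
    alt = fix[keep, "ALT"]
  )
  genotype_panel(t(g), meta)
}

#' Write / read a samples-by-features omics matrix
#'
#' `sample_id` header column followed by one column per feature.
#'
#' @param omics numeric matrix with sample row names.
#' @param path file path.
#' @param stamp optional comment stamp.
#' @export
write_omics <- function(omics, path, stamp = NULL) {
  df <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(omics)),
                         tibble::as_tibble(omics))
  write_table(df, path, stamp)
}

#' @rdname write_omics
#' @export
read_omics <- function(path) {
  df <- read_table(path)
  require_columns(df, "sample_id", "omics table")
  m <- as.matrix(df[, setdiff(names(df), "sample_id")])
  rownames(m) <- df$sample_id
  m
}

#' Write / read a covariate table
#'
#' @param covariates tibble with `sample_id`, `age`, `sex`, `group`,
#'   `medication`.
#' @param path file path.
#' @param stamp optional comment stamp.
#' @export
write_covariates <- function(covariates, path, stamp = NULL) {
  write_table(covariates, path, stamp)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  df <- read_table(path)
  require_columns(df, c("sample_id", "age", "sex", "group", "medication"),
                  "covariate table")
  df
}

#' Write / read GWAS summary statistics
#'
#' Fixed columns `variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `beta`, `se`, `n`; `z` is recomputed as `beta / se` on
#' read. Rows with `se <= 0` or identical alleles are rejected with a
#' warning; duplicate variant ids are an error.
#'
#' @param gwas GWAS summary tibble.
#' @param path file path.
#' @param stamp optional comment stamp.
#' @export
write_gwas <- function(gwas, path, stamp = NULL) {
  require_columns(gwas, GWAS_COLUMNS, "GWAS table")
  write_table(gwas[, GWAS_COLUMNS], path, stamp)
}

#' @rdname write_gwas
#' @export
read_gwas <- function(path) {
  df <- read_table(path)
  require_columns(df, GWAS_COLUMNS, "GWAS table")
  df$chrom <- as.character(df$chrom)
  bad_se <- !is.finite(df$se) | df$se <= 0
  bad_alleles <- df$effect_allele == df$other_allele
  n_bad <- sum(bad_se | bad_alleles)
  if (n_bad > 0L) {
    warning(sprintf("rejected %d GWAS row(s): %d nonpositive SE, %d identical alleles",
                    n_bad, sum(bad_se), sum(bad_alleles & !bad_se)))
    df <- df[!(bad_se | bad_alleles), ]
  }
  if (anyDuplicated(df$variant_id)) {
    stop("duplicate variant ids in GWAS table", call. = FALSE)
  }
  df$z <- df$beta / df$se
  df[, c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
         "beta", "se", "z", "n")]
}

#' Write / read trained model weights and summaries
#'
#' @param models an `xwas_models` object.
#' @param weights_path,summary_path file paths.
#' @param stamp optional comment stamp.
#' @export
write_models <- function(models, weights_path, summary_path, stamp = NULL) {
  write_table(models$weights, weights_path, stamp)
  write_table(models$summary, summary_path, stamp)
  invisible(weights_path)
}

#' @rdname write_models
#' @export
read_models <- function(weights_path, summary_path = NULL) {
  weights <- read_table(weights_path)
  require_columns(weights, c("gene_id", "variant_id", "effect_allele",
                             "other_allele", "weight", "sigma"),
                  "weight table")
  summary <- if (!is.null(summary_path)) read_table(summary_path) else
    tibble::tibble(gene_id = unique(weights$gene_id))
  structure(list(weights = weights, summary = summary,
                 dropped = tibble::tibble(gene_id = character(),
                                          reason = character())),
            class = "xwas_models")
}

#' Write / read gene-trait association results
#'
#' @param associations the associations tibble of an `xwas_result`.
#' @param path file path.
#' @param stamp optional comment stamp.
#' @export
write_associations <- function(associations, path, stamp = NULL) {
  write_table(associations, path, stamp)
}

#' @rdname write_associations
#' @export
read_associations <- function(path) {
  df <- read_table(path)
  require_columns(df, c("gene_id", "trait", "zscore", "pvalue", "qvalue",
                        "direction"), "association table")
  df
}

#' Write / read the simulation ground truth as JSON
#'
#' @param truth an `omix_truth` object.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  payload <- list(
    causal = truth$causal,
    trait_effects = truth$trait_effects,
    batch = as.list(truth$batch),
    batch_loadings = truth$batch_loadings
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(causal = tibble::as_tibble(raw$causal),
         trait_effects = tibble::as_tibble(raw$trait_effects),
         batch = unlist(raw$batch),
         batch_loadings = tibble::as_tibble(raw$batch_loadings),
         config = NULL),
    class = "omix_truth"
  )
}
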