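#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: simulation settings,
#' QC thresholds, model settings, FDR level, and colocalization priors. The
#' configuration (with its hash) is serialized into every output directory.
#'
#' @param sim a [sim_config()] describing the synthetic cohort.
#' @param traits character vector of trait names; each gets its own GWAS
#'   (distinct noise realisations of the protein-mediated trait).
#' @param gwas_mode `"cohort"` or `"analytic"` (see [simulate_gwas()]).
#' @param maf MAF filter threshold.
#' @param kinship_threshold relatedness pruning cutoff.
#' @param outlier_alpha chi-squared outlier p-value threshold.
#' @param n_pcs,n_svs genetic PCs and surrogate values used as covariates.
#' @param window cis-window flank in bp.
#' @param enet_alpha elastic-net mixing parameter.
#' @param n_folds cross-validation folds.
#' @param fdr association FDR level.
#' @param coloc_p1,coloc_p2,coloc_p12,coloc_w colocalization priors and
#'   Wakefield prior effect variance.
#' @param seed master seed for the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), traits = "lipid",
                            gwas_mode = c("cohort", "analytic"),
                            maf = 0.05, kinship_threshold = 2^-2.5,
                            outlier_alpha = 0.001, n_pcs = 4L, n_svs = 10L,
                            window = 1e6, enet_alpha = 0.5, n_folds = 5L,
                            fdr = 0.05, coloc_p1 = 1e-4, coloc_p2 = 1e-4,
                            coloc_p12 = 1e-5, coloc_w = 0.15^2,
                            seed = sim$seed) {
  gwas_mode <- match.arg(gwas_mode)
  stopifnot(maf > 0, maf < 0.5, outlier_alpha >= 0, outlier_alpha <= 1,
            window > 0, enet_alpha >= 0, enet_alpha <= 1, n_folds >= 2,
            fdr > 0, fdr < 1, coloc_p1 > 0, coloc_p2 > 0, coloc_p12 > 0,
            coloc_p1 + coloc_p2 + coloc_p12 < 1, length(traits) >= 1)
  structure(
    list(sim = sim, traits = traits, gwas_mode = gwas_mode, maf = maf,
         kinship_threshold = kinship_threshold,
         outlier_alpha = outlier_alpha, n_pcs = as.integer(n_pcs),
         n_svs = as.integer(n_svs), window = window,
         enet_alpha = enet_alpha, n_folds = as.integer(n_folds), fdr = fdr,
         coloc_p1 = coloc_p1, coloc_p2 = coloc_p2, coloc_p12 = coloc_p12,
         coloc_w = coloc_w, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

config_hash <- function(config) rlang::hash(unclass(config))

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full synthetic-to-concordance pipeline
#'
#' Stage order: simulate (genotypes, omics, GWAS per trait), QC (protein and
#' expression), model training, summary-statistic association per trait and
#' omic, colocalization of the three signal pairs per gene, and
#' protein-vs-expression concordance. Every table is written to `out_dir`
#' with a comment header carrying the config hash and seed; a manifest with
#' MD5 hashes of all outputs makes reruns verifiable (identical config and
#' seed reproduce identical files).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed). `NULL` skips writing.
#' @return A list of class `pipeline_result` with elements `qc_protein`,
#'   `qc_expression`, `models_protein`, `models_expression`, `pwas`, `twas`,
#'   `coloc`, `concordance`, `truth`, and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stamp <- list(hash = config_hash(config), seed = config$seed)
  sim <- config$sim

  panel <- run_stage("simulate", simulate_genotypes(sim))
  om <- run_stage("simulate", simulate_omics(panel, sim))
  gwas_list <- run_stage("simulate", {
    gl <- lapply(seq_along(config$traits), function(i) {
      simulate_gwas(panel, sim, om$truth, mode = config$gwas_mode,
                    seed = derive_seed(sim$seed, 30L + i))
    })
    names(gl) <- config$traits
    gl
  })

  qc_p <- run_stage("qc", run_qc(panel, om$protein, om$covariates,
                                 maf = config$maf,
                                 kinship_threshold = config$kinship_threshold,
                                 n_pcs = config$n_pcs, n_svs = config$n_svs,
                                 outlier_alpha = config$outlier_alpha))
  qc_e <- run_stage("qc", run_qc(panel, om$expression, om$covariates,
                                 maf = config$maf,
                                 kinship_threshold = config$kinship_threshold,
                                 n_pcs = config$n_pcs, n_svs = config$n_svs,
                                 outlier_alpha = config$outlier_alpha))

  ann <- simulate_annotations(sim)
  gwas_ids <- gwas_list[[1]]$variant_id
  models_p <- run_stage("train",
    train_models(qc_p$panel, qc_p$residuals, ann, allowed_ids = gwas_ids,
                 window = config$window, alpha = config$enet_alpha,
                 n_folds = config$n_folds, fdr = config$fdr,
                 seed = derive_seed(config$seed, 41L)))
  models_e <- run_stage("train",
    train_models(qc_e$panel, qc_e$residuals, ann, allowed_ids = gwas_ids,
                 window = config$window, alpha = config$enet_alpha,
                 n_folds = config$n_folds, fdr = config$fdr,
                 seed = derive_seed(config$seed, 42L)))

  gwas_checked <- run_stage("assoc", {
    lapply(gwas_list, function(g) {
      require_columns(g, GWAS_COLUMNS, "GWAS table")
      if (any(!is.finite(g$se) | g$se <= 0)) {
        stop("nonpositive SE in GWAS input", call. = FALSE)
      }
      g
    })
  })
  ld_p <- build_ld_reference(qc_p$panel, models_p)
  ld_e <- build_ld_reference(qc_e$panel, models_e)
  pwas <- run_stage("assoc", run_xwas(models_p, gwas_checked, ld_p,
                                      fdr = config$fdr))
  twas <- run_stage("assoc", run_xwas(models_e, gwas_checked, ld_e,
                                      fdr = config$fdr))

  coloc <- run_stage("coloc", {
    genes <- intersect(unique(models_p$weights$gene_id),
                       unique(models_e$weights$gene_id))
    out <- lapply(genes, function(g) {
      grow <- ann[ann$gene_id == g, ]
      cis <- select_cis_snps(grow, qc_p$panel, window = config$window)
      pq <- qtl_summary(qc_p$panel, qc_p$residuals[, g], cis)
      cis_e <- intersect(cis, qc_e$panel$variants$variant_id)
      eq <- qtl_summary(qc_e$panel, qc_e$residuals[, g], cis_e)
      tg <- gwas_checked[[1]][gwas_checked[[1]]$variant_id %in% cis, ]
      cm <- coloc_matrix(tg, pq, eq, p1 = config$coloc_p1,
                         p2 = config$coloc_p2, p12 = config$coloc_p12,
                         W = config$coloc_w)
      dplyr::bind_cols(tibble::tibble(gene_id = g), cm)
    })
    dplyr::bind_rows(out)
  })

  concordance <- run_stage("concord", {
    trait1 <- config$traits[1]
    pw <- pwas$associations[pwas$associations$trait == trait1, ]
    tw <- twas$associations[twas$associations$trait == trait1, ]
    concordance_report(pw, list(PBMC = tw), fdr = config$fdr)
  })

  result <- structure(
    list(qc_protein = qc_p, qc_expression = qc_e,
         models_protein = models_p, models_expression = models_e,
         pwas = pwas, twas = twas, coloc = coloc,
         concordance = concordance, truth = om$truth, manifest = NULL,
         config = config),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) {
    result$manifest <- write_pipeline_outputs(result, panel, om, gwas_list,
                                              out_dir, stamp)
  }
  result
}

write_pipeline_outputs <- function(result, panel, om, gwas_list, out_dir,
                                   stamp) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_genotypes(panel, p("genotypes.tsv"), stamp)
  write_omics(om$protein, p("protein.tsv"), stamp)
  write_omics(om$expression, p("expression.tsv"), stamp)
  write_covariates(om$covariates, p("covariates.tsv"), stamp)
  write_truth(om$truth, p("truth.json"))
  for (tr in names(gwas_list)) {
    write_gwas(gwas_list[[tr]], p(sprintf("gwas_%s.tsv", tr)), stamp)
  }
  write_models(result$models_protein, p("weights_protein.tsv"),
               p("model_summary_protein.tsv"), stamp)
  write_models(result$models_expression, p("weights_expression.tsv"),
               p("model_summary_expression.tsv"), stamp)
  write_associations(result$pwas$associations, p("pwas.tsv"), stamp)
  write_associations(result$twas$associations, p("twas.tsv"), stamp)
  write_table(result$coloc, p("coloc.tsv"), stamp)
  write_table(result$concordance$tissues, p("tissue_concordance.tsv"), stamp)
  write_table(result$concordance$gene_agreement, p("gene_agreement.tsv"),
              stamp)
  qc_report <- dplyr::bind_rows(
    protein = result$qc_protein$report,
    expression = result$qc_expression$report, .id = "omic"
  )
  write_table(qc_report, p("qc_report.tsv"), stamp)
  jsonlite::write_json(
    list(config_hash = stamp$hash, seed = stamp$seed,
         config = unclass(result$config)[setdiff(names(unclass(result$config)), "sim")],
         sim = unclass(result$config$sim)),
    p("config.json"), auto_unbox = TRUE, digits = NA
  )
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- tibble::tibble(file = basename(files),
                             md5 = unname(tools::md5sum(files)))
  write_table(manifest, p("manifest.tsv"))
  manifest
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$pwas)
  print(x$concordance)
  invisible(x)
}
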