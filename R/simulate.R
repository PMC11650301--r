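#' Simulation configuration for synthetic multi-omic cohorts
#'
#' Bundles every knob of the synthetic-cohort generator: an LD-structured
#' genotype panel, protein and expression levels with known cis-architecture
#' and hidden batch confounding, and GWAS summary statistics for a trait that
#' acts through the protein levels.
#'
#' @param n_train number of training-panel samples.
#' @param n_gwas effective GWAS sample size.
#' @param n_variants_per_gene cis-variants simulated per gene locus.
#' @param n_genes number of gene loci (independent blocks).
#' @param maf_range length-2 alternate-allele frequency range in `(0, 0.5]`.
#' @param ld_rho AR(1) latent correlation between adjacent variants, in
#'   `[0, 1)`; controls how fast LD decays with distance.
#' @param h2_protein,h2_expression cis-heritability of each omic, in `[0, 1)`:
#'   the fraction of (genetic + noise) variance explained by the causal
#'   cis-variants.
#' @param n_causal_protein,n_causal_expression causal variants per gene.
#' @param causal_overlap fraction of the expression causal set shared with the
#'   protein causal set, in `[0, 1]`.
#' @param protein_trait_effects per-gene effect of protein level on the GWAS
#'   trait (scalar recycled, or length `n_genes`).
#' @param confounder_strength SD of the hidden batch-factor loadings on the
#'   omics features (0 disables the confounder).
#' @param covariate_strength total SD contributed by the measured covariates
#'   (age, sex, group, medication) to each omic feature.
#' @param polygenic_strength SD of a diffuse polygenic contribution to the
#'   GWAS trait spread over all variants (0 disables it).
#' @param concordant_signs logical; if `TRUE` shared causal variants get the
#'   same effect sign in expression as in protein.
#' @param discordant_genes indices (1-based) of genes whose shared expression
#'   effect signs are flipped relative to protein, regardless of
#'   `concordant_signs`; used to plant protein/expression direction
#'   discordance.
#' @param seed integer seed; the same config is bit-reproducible.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_train = 935,
                       n_gwas = 10000,
                       n_variants_per_gene = 200,
                       n_genes = 20,
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0.9,
                       h2_protein = 0.3,
                       h2_expression = 0.3,
                       n_causal_protein = 3,
                       n_causal_expression = 3,
                       causal_overlap = 1,
                       protein_trait_effects = 0.1,
                       confounder_strength = 1,
                       covariate_strength = 0.5,
                       polygenic_strength = 0,
                       concordant_signs = TRUE,
                       discordant_genes = integer(),
                       seed = 1L) {
  cfg <- list(
    n_train = as.integer(n_train), n_gwas = as.integer(n_gwas),
    n_variants_per_gene = as.integer(n_variants_per_gene),
    n_genes = as.integer(n_genes), maf_range = as.numeric(maf_range),
    ld_rho = ld_rho, h2_protein = h2_protein, h2_expression = h2_expression,
    n_causal_protein = as.integer(n_causal_protein),
    n_causal_expression = as.integer(n_causal_expression),
    causal_overlap = causal_overlap,
    protein_trait_effects = rep_len(protein_trait_effects, n_genes),
    confounder_strength = confounder_strength,
    covariate_strength = covariate_strength,
    polygenic_strength = polygenic_strength,
    concordant_signs = isTRUE(concordant_signs),
    discordant_genes = as.integer(discordant_genes),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  if (!num_ok(cfg$maf_range) || length(cfg$maf_range) != 2L ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("`maf_range` must be an increasing pair within (0, 0.5]", call. = FALSE)
  }
  if (!num_ok(cfg$ld_rho) || cfg$ld_rho < 0 || cfg$ld_rho >= 1) {
    stop("`ld_rho` must be in [0, 1)", call. = FALSE)
  }
  for (h in c("h2_protein", "h2_expression")) {
    if (!num_ok(cfg[[h]]) || cfg[[h]] < 0 || cfg[[h]] >= 1) {
      stop(sprintf("`%s` must be in [0, 1)", h), call. = FALSE)
    }
  }
  if (cfg$n_causal_protein > cfg$n_variants_per_gene ||
      cfg$n_causal_expression > cfg$n_variants_per_gene) {
    stop("causal counts cannot exceed `n_variants_per_gene`", call. = FALSE)
  }
  if (!num_ok(cfg$causal_overlap) || cfg$causal_overlap < 0 ||
      cfg$causal_overlap > 1) {
    stop("`causal_overlap` must be in [0, 1]", call. = FALSE)
  }
  n_shared <- round(cfg$causal_overlap * cfg$n_causal_expression)
  if (n_shared > cfg$n_causal_protein) {
    stop("`causal_overlap` incompatible with causal counts: shared set ",
         "exceeds the protein causal set", call. = FALSE)
  }
  if (cfg$n_train < 2L) stop("`n_train` must be at least 2", call. = FALSE)
  if (!num_ok(cfg$protein_trait_effects)) {
    stop("`protein_trait_effects` must be finite", call. = FALSE)
  }
  invisible(cfg)
}

# Gene loci are laid out on one chromosome, 3.1 Mb apart, so that the
# 1 Mb cis windows of neighbouring genes never overlap and blocks are
# independent by construction.
GENE_SPACING <- 3100000
GENE_LENGTH <- 50000

#' Gene annotations implied by a simulation configuration
#'
#' @param config a [sim_config()].
#' @return A tibble with columns `gene_id`, `symbol`, `chrom`, `tss`, `tes`,
#'   `strand` (1-based, `tss <= tes`).
#' @export
simulate_annotations <- function(config) {
  g <- seq_len(config$n_genes)
  tss <- (g - 1) * GENE_SPACING + 1000001
  tibble::tibble(
    gene_id = sprintf("G%03d", g),
    symbol = sprintf("GENE%03d", g),
    chrom = "1",
    tss = tss,
    tes = tss + GENE_LENGTH - 1,
    strand = "+"
  )
}

# Draw one gene block of dosages: latent AR(1) Gaussian per haplotype,
# thresholded at qnorm(alt frequency); the two haplotypes are summed.
draw_gene_block <- function(n, freqs, rho) {
  L <- length(freqs)
  z <- matrix(stats::rnorm(2L * n * L), nrow = 2L * n, ncol = L)
  if (rho > 0 && L > 1L) {
    R <- rho^abs(outer(seq_len(L), seq_len(L), "-"))
    z <- z %*% chol(R)
  }
  thr <- stats::qnorm(freqs)
  hap <- sweep(z, 2L, thr, "<")
  storage.mode(hap) <- "double"
  hap[seq_len(n), , drop = FALSE] + hap[n + seq_len(n), , drop = FALSE]
}

#' Simulate an LD-structured genotype panel
#'
#' Each gene locus gets `n_variants_per_gene` biallelic variants whose
#' alternate-allele frequencies are uniform on `maf_range`. Haplotypes are
#' generated by thresholding a latent AR(1) Gaussian process, so LD between
#' variants decays geometrically with index distance at rate `ld_rho`.
#'
#' @param config a [sim_config()].
#' @param n_samples number of samples to draw (defaults to `config$n_train`).
#' @param seed RNG seed (defaults to a stream derived from `config$seed`).
#' @return A [genotype_panel()] whose `variants` tibble carries the extra
#'   generator columns `gene_id` and `alt_freq` (the generating frequency).
#' @export
simulate_genotypes <- function(config, n_samples = config$n_train,
                               seed = derive_seed(config$seed, 1L)) {
  validate_sim_config(config)
  ann <- simulate_annotations(config)
  L <- config$n_variants_per_gene
  with_seed(seed, {
    blocks <- vector("list", config$n_genes)
    vmeta <- vector("list", config$n_genes)
    for (g in seq_len(config$n_genes)) {
      freqs <- stats::runif(L, config$maf_range[1], config$maf_range[2])
      blocks[[g]] <- draw_gene_block(n_samples, freqs, config$ld_rho)
      win_lo <- ann$tss[g] - 1000000
      win_hi <- ann$tes[g] + 1000000
      pos <- round(seq(win_lo, win_hi, length.out = L))
      alleles <- t(replicate(L, sample(c("A", "C", "G", "T"), 2L)))
      vmeta[[g]] <- tibble::tibble(
        variant_id = sprintf("snp_%s_%04d", ann$gene_id[g], seq_len(L)),
        chrom = "1", pos = pos, ref = alleles[, 1], alt = alleles[, 2],
        gene_id = ann$gene_id[g], alt_freq = freqs
      )
    }
    genotype_panel(do.call(cbind, blocks), dplyr::bind_rows(vmeta))
  })
}

#' Simulate protein/expression levels, covariates, and the ground truth
#'
#' Each gene's protein level is a sum of causal cis-variant effects (scaled so
#' the causal score explains `h2_protein` of the genetic-plus-noise variance),
#' measured-covariate effects, a hidden batch-factor loading, and Gaussian
#' noise. Expression is analogous with its own causal set sharing a
#' `causal_overlap` fraction of variants with the protein set; shared effect
#' signs are concordant unless flipped via `discordant_genes`.
#'
#' @param panel training [genotype_panel()] from [simulate_genotypes()].
#' @param config the [sim_config()] used to build `panel`.
#' @param seed RNG seed (defaults to a stream derived from `config$seed`).
#' @return A list with elements `protein` and `expression` (sample-by-gene
#'   matrices), `covariates` (tibble: `sample_id`, `age`, `sex`, `group`,
#'   `medication`), and `truth`, an `omix_truth` object recording the causal
#'   variants and effects, trait effects, batch factor and loadings exactly as
#'   used in generation.
#' @export
simulate_omics <- function(panel, config,
                           seed = derive_seed(config$seed, 2L)) {
  validate_sim_config(config)
  if (nrow(panel$dosage) != config$n_train) {
    stop("panel sample count does not match `config$n_train`", call. = FALSE)
  }
  n <- nrow(panel$dosage)
  genes <- unique(panel$variants$gene_id)
  G <- length(genes)
  n_shared <- round(config$causal_overlap * config$n_causal_expression)

  with_seed(seed, {
    covariates <- tibble::tibble(
      sample_id = panel$samples,
      age = round(stats::runif(n, 45, 84)),
      sex = stats::rbinom(n, 1L, 0.5),
      group = sample(c("A", "B", "C", "D"), n, replace = TRUE),
      medication = stats::rbinom(n, 1L, 0.2)
    )
    batch <- stats::rnorm(n)
    Zc <- covariate_design(covariates)[, -1, drop = FALSE]  # drop intercept
    Zc <- scale_safe(Zc)

    protein <- matrix(0, n, G, dimnames = list(panel$samples, genes))
    expression <- protein
    causal <- vector("list", 2L * G)
    loadings <- vector("list", 2L * G)

    for (gi in seq_len(G)) {
      vids <- panel$variants$variant_id[panel$variants$gene_id == genes[gi]]
      cp <- sample(vids, config$n_causal_protein)
      shared <- if (n_shared > 0L) sample(cp, n_shared) else character()
      ce_extra <- if (config$n_causal_expression > n_shared) {
        sample(setdiff(vids, cp), config$n_causal_expression - n_shared)
      } else {
        character()
      }
      ce <- c(shared, ce_extra)

      beta_p <- stats::rnorm(config$n_causal_protein)
      beta_e <- stats::rnorm(config$n_causal_expression)
      if (n_shared > 0L) {
        sgn <- sign(beta_p[match(shared, cp)])
        flip <- if (gi %in% config$discordant_genes) -1 else
          if (config$concordant_signs) 1 else -1
        beta_e[seq_len(n_shared)] <- flip * sgn * abs(beta_e[seq_len(n_shared)])
      }

      gen <- make_omic(panel, cp, beta_p, config$h2_protein, n)
      protein[, gi] <- gen$y
      causal[[gi]] <- tibble::tibble(gene_id = genes[gi], omic = "protein",
                                     variant_id = cp, beta = gen$beta)
      gen_e <- make_omic(panel, ce, beta_e, config$h2_expression, n)
      expression[, gi] <- gen_e$y
      causal[[G + gi]] <- tibble::tibble(gene_id = genes[gi],
                                         omic = "expression",
                                         variant_id = ce, beta = gen_e$beta)
    }

    # covariate and batch contributions, added on top of genetic + noise
    for (omic in c("protein", "expression")) {
      m <- if (omic == "protein") protein else expression
      coefs <- matrix(stats::rnorm(ncol(Zc) * G,
                                   sd = config$covariate_strength /
                                     max(1, sqrt(ncol(Zc)))),
                      ncol(Zc), G)
      lambda <- stats::rnorm(G, sd = config$confounder_strength)
      m <- m + Zc %*% coefs + outer(batch, lambda)
      if (omic == "protein") protein <- m else expression <- m
      loadings[[if (omic == "protein") 1L else 2L]] <-
        tibble::tibble(gene_id = genes, omic = omic, loading = lambda)
    }

    truth <- structure(
      list(
        causal = dplyr::bind_rows(causal[!vapply(causal, is.null, logical(1))]),
        trait_effects = tibble::tibble(gene_id = genes,
                                       gamma = config$protein_trait_effects[seq_len(G)]),
        batch = stats::setNames(batch, panel$samples),
        batch_loadings = dplyr::bind_rows(loadings[1:2]),
        config = config
      ),
      class = "omix_truth"
    )
    list(protein = protein, expression = expression,
         covariates = covariates, truth = truth)
  })
}

# Scale causal effects so the causal score explains h2 of (score + noise)
# variance in this panel, then add the noise. Returns the rescaled betas.
make_omic <- function(panel, causal_ids, beta_raw, h2, n) {
  if (h2 == 0 || length(causal_ids) == 0L) {
    return(list(y = stats::rnorm(n), beta = rep(0, length(beta_raw))))
  }
  X <- panel$dosage[, causal_ids, drop = FALSE]
  score <- drop(X %*% beta_raw)
  v <- stats::var(score)
  scl <- if (v > 0) sqrt(h2 / v) else 0
  beta <- beta_raw * scl
  list(y = score * scl + stats::rnorm(n, sd = sqrt(1 - h2)), beta = beta)
}

#' @export
print.omix_truth <- function(x, ...) {
  cat(sprintf("<omix_truth> %d genes, %d causal records\n",
              nrow(x$trait_effects), nrow(x$causal)))
  invisible(x)
}

#' Simulate GWAS summary statistics for a protein-mediated trait
#'
#' The trait is `y = sum_g gamma_g * protein_g + polygenic + noise` where the
#' `protein_g` follow the cis-architecture in `truth` and `var(noise) = 1`.
#' In `"cohort"` mode an independent cohort of `n_gwas` individuals is
#' simulated and per-variant marginal ordinary-least-squares beta/SE are
#' computed (the exact oracle; samples are streamed in blocks so memory stays
#' bounded). In `"analytic"` mode per-variant Z-scores are drawn directly as
#' `z = sqrt(n_gwas) * rho + N(0, 1)` with `rho` the model-implied
#' variant-trait correlation estimated from the training panel.
#'
#' @param panel the training [genotype_panel()] (defines variants and, in
#'   analytic mode, the LD used to propagate effects).
#' @param config the [sim_config()].
#' @param truth the `omix_truth` from [simulate_omics()].
#' @param mode `"cohort"` (default) or `"analytic"`.
#' @param n_gwas GWAS sample size (defaults to `config$n_gwas`).
#' @param seed RNG seed (defaults to a stream derived from `config$seed`).
#' @param return_cohort logical; in cohort mode also return the simulated
#'   cohort genotypes and trait (for individual-level oracle checks). Forces
#'   the full cohort matrix into memory.
#' @param block_size samples per streaming block in cohort mode.
#' @return A tibble with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele` (alt), `other_allele` (ref), `beta`, `se`, `z`, `n`.
#'   With `return_cohort = TRUE`, a list with elements `summary`, `cohort` (a
#'   `genotype_panel`), `trait`, and `protein` (cohort gene-level protein
#'   matrix).
#' @export
simulate_gwas <- function(panel, config, truth,
                          mode = c("cohort", "analytic"),
                          n_gwas = config$n_gwas,
                          seed = derive_seed(config$seed, 3L),
                          return_cohort = FALSE,
                          block_size = 2000L) {
  mode <- match.arg(mode)
  if (n_gwas < 2L) stop("`n_gwas` must be at least 2", call. = FALSE)
  genes <- unique(panel$variants$gene_id)
  gamma <- truth$trait_effects$gamma[match(genes, truth$trait_effects$gene_id)]
  if (anyNA(gamma)) {
    stop("`truth` is missing protein trait effects for some panel genes",
         call. = FALSE)
  }
  base <- panel$variants[, c("variant_id", "chrom", "pos", "ref", "alt")]
  if (mode == "analytic") {
    return(with_seed(seed, gwas_analytic(panel, truth, gamma, n_gwas, base)))
  }
  with_seed(seed, gwas_cohort(panel, config, truth, gamma, n_gwas, base,
                              return_cohort, block_size))
}

gwas_analytic <- function(panel, truth, gamma, n_gwas, base) {
  genes <- unique(panel$variants$gene_id)
  L_tot <- ncol(panel$dosage)
  rho <- numeric(L_tot)
  sd_l <- apply(panel$dosage, 2L, stats::sd)
  var_y <- 1
  covs <- numeric(L_tot)
  for (gi in seq_along(genes)) {
    idx <- which(panel$variants$gene_id == genes[gi])
    tr <- truth$causal[truth$causal$gene_id == genes[gi] &
                         truth$causal$omic == "protein", ]
    score <- drop(panel$dosage[, tr$variant_id, drop = FALSE] %*% tr$beta)
    var_protein <- stats::var(score) + (1 - truth$config$h2_protein)
    var_y <- var_y + gamma[gi]^2 * var_protein
    covs[idx] <- gamma[gi] *
      drop(stats::cov(panel$dosage[, idx, drop = FALSE], score))
  }
  rho <- covs / (sd_l * sqrt(var_y))
  rho[!is.finite(rho)] <- 0
  z <- sqrt(n_gwas) * rho + stats::rnorm(L_tot)
  se <- sqrt(var_y) / (sd_l * sqrt(n_gwas))
  tibble::tibble(
    base[, c("variant_id", "chrom", "pos")],
    effect_allele = base$alt, other_allele = base$ref,
    beta = z * se, se = se, z = z, n = as.integer(n_gwas)
  )
}

gwas_cohort <- function(panel, config, truth, gamma, n_gwas, base,
                        return_cohort, block_size) {
  genes <- unique(panel$variants$gene_id)
  L_tot <- ncol(panel$dosage)
  freqs <- panel$variants$alt_freq
  if (is.null(freqs)) {
    stop("cohort mode needs the generator column `alt_freq` in the panel",
         call. = FALSE)
  }
  tr_by_gene <- lapply(genes, function(g) {
    truth$causal[truth$causal$gene_id == g & truth$causal$omic == "protein", ]
  })
  poly <- if (config$polygenic_strength > 0) {
    stats::rnorm(L_tot, sd = config$polygenic_strength / sqrt(L_tot))
  } else {
    NULL
  }

  Sg <- Sgg <- Sgy <- numeric(L_tot)
  Sy <- Syy <- 0
  keep_X <- if (return_cohort) matrix(0, n_gwas, L_tot) else NULL
  keep_y <- if (return_cohort) numeric(n_gwas) else NULL
  keep_P <- if (return_cohort) matrix(0, n_gwas, length(genes)) else NULL

  done <- 0L
  while (done < n_gwas) {
    b <- min(block_size, n_gwas - done)
    Xb <- matrix(0, b, L_tot)
    y <- stats::rnorm(b)  # trait noise, var 1
    for (gi in seq_along(genes)) {
      idx <- which(panel$variants$gene_id == genes[gi])
      Xg <- draw_gene_block(b, freqs[idx], config$ld_rho)
      Xb[, idx] <- Xg
      tr <- tr_by_gene[[gi]]
      score <- drop(Xg[, match(tr$variant_id,
                               panel$variants$variant_id[idx]),
                       drop = FALSE] %*% tr$beta)
      prot <- score + stats::rnorm(b, sd = sqrt(1 - config$h2_protein))
      y <- y + gamma[gi] * prot
      if (return_cohort) keep_P[done + seq_len(b), gi] <- prot
    }
    if (!is.null(poly)) y <- y + drop(Xb %*% poly)
    Sg <- Sg + colSums(Xb)
    Sgg <- Sgg + colSums(Xb^2)
    Sgy <- Sgy + drop(crossprod(Xb, y))
    Sy <- Sy + sum(y)
    Syy <- Syy + sum(y^2)
    if (return_cohort) {
      keep_X[done + seq_len(b), ] <- Xb
      keep_y[done + seq_len(b)] <- y
    }
    done <- done + b
  }

  n <- n_gwas
  Sxx <- Sgg - Sg^2 / n
  Sxy <- Sgy - Sg * Sy / n
  Syy_c <- Syy - Sy^2 / n
  beta <- ifelse(Sxx > 0, Sxy / Sxx, 0)
  rss <- pmax(Syy_c - beta^2 * Sxx, 0)
  se <- ifelse(Sxx > 0, sqrt(rss / (n - 2) / Sxx), Inf)
  z <- ifelse(is.finite(se) & se > 0, beta / se, 0)
  summary <- tibble::tibble(
    base[, c("variant_id", "chrom", "pos")],
    effect_allele = base$alt, other_allele = base$ref,
    beta = beta, se = se, z = z, n = as.integer(n)
  )
  if (!return_cohort) return(summary)
  colnames(keep_X) <- panel$variants$variant_id
  colnames(keep_P) <- genes
  cohort <- genotype_panel(keep_X,
                           panel$variants[, c("variant_id", "chrom", "pos",
                                              "ref", "alt", "gene_id",
                                              "alt_freq")])
  list(summary = summary, cohort = cohort, trait = keep_y, protein = keep_P)
}
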