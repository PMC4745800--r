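#' Configuration for the synthetic cohort generator
#'
#' Defines a matched RPPA + expression + survival cohort driven by one
#' latent activation factor per protein. Informative proteins carry a
#' block of member genes whose expression tracks the latent factor with
#' sign +/-1; the remaining genes and proteins are pure noise. Survival
#' times are exponential, with a treatment main effect and a
#' treatment-by-score interaction carried by one designated protein's
#' true metagene.
#'
#' @param n_samples_derivation,n_samples_validation Cohort sizes.
#' @param n_proteins Total proteins measured by the synthetic RPPA panel.
#' @param n_informative_proteins Proteins with a planted gene module
#'   (the rest are pure noise).
#' @param genes_per_metagene Member genes per informative protein.
#' @param n_genes_total Genes on the synthetic array (planted members
#'   plus pure-noise genes).
#' @param effect_size Expression shift per unit latent activation, in
#'   expression units per SD of activation.
#' @param noise_sd_expr,noise_sd_rppa Gaussian noise SDs of the
#'   expression and RPPA measurements.
#' @param frac_negative_members Fraction of members planted with
#'   coefficient -1 (down-regulated).
#' @param baseline_expr Mean expression level (log-intensity scale); a
#'   positive baseline keeps multiplicative quantile alignment
#'   meaningful.
#' @param latent_blocks Optional list of integer vectors of protein
#'   indices; proteins within a block share a common latent component
#'   with correlation `latent_rho`, mimicking co-activated sub-networks.
#' @param latent_rho Within-block latent correlation.
#' @param survival List: `baseline_hazard` (events per month),
#'   `censoring_rate` (target fraction censored), `treatment_log_hr`,
#'   `interaction_log_hr_per_sd` (additional treated-arm log hazard per
#'   SD of the interaction metagene's score), `interaction_protein_index`.
#' @param validation_scale,validation_shift Affine transform applied to
#'   the validation cohort's expression values (different platform
#'   scale), exercised by [quantile_align()].
#' @param seed Default random seed for the generator functions.
#' @return A validated list of class `rppasig_sim_config`.
#' @export
sim_config <- function(n_samples_derivation = 200L,
                       n_samples_validation = 200L,
                       n_proteins = 20L,
                       n_informative_proteins = 10L,
                       genes_per_metagene = 50L,
                       n_genes_total = 2000L,
                       effect_size = 1.0,
                       noise_sd_expr = 1.0,
                       noise_sd_rppa = 1.0,
                       frac_negative_members = 0.3,
                       baseline_expr = 6.0,
                       latent_blocks = NULL,
                       latent_rho = 0.6,
                       survival = list(),
                       validation_scale = 2.0,
                       validation_shift = 0.0,
                       seed = 1L) {
  surv <- utils::modifyList(
    list(baseline_hazard = 0.05, censoring_rate = 0.3,
         treatment_log_hr = log(0.7), interaction_log_hr_per_sd = 1.0,
         interaction_protein_index = 1L),
    survival
  )
  cfg <- list(
    n_samples_derivation = as.integer(n_samples_derivation),
    n_samples_validation = as.integer(n_samples_validation),
    n_proteins = as.integer(n_proteins),
    n_informative_proteins = as.integer(n_informative_proteins),
    genes_per_metagene = as.integer(genes_per_metagene),
    n_genes_total = as.integer(n_genes_total),
    effect_size = effect_size, noise_sd_expr = noise_sd_expr,
    noise_sd_rppa = noise_sd_rppa,
    frac_negative_members = frac_negative_members,
    baseline_expr = baseline_expr,
    latent_blocks = latent_blocks, latent_rho = latent_rho,
    survival = surv,
    validation_scale = validation_scale, validation_shift = validation_shift,
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      n_samples_derivation > 0, n_samples_validation > 0, n_proteins > 0,
      n_informative_proteins >= 0, n_informative_proteins <= n_proteins,
      genes_per_metagene > 0,
      frac_negative_members >= 0, frac_negative_members <= 1,
      noise_sd_expr >= 0, noise_sd_rppa >= 0,
      surv$censoring_rate >= 0, surv$censoring_rate < 1,
      surv$baseline_hazard > 0,
      surv$interaction_protein_index >= 1,
      surv$interaction_protein_index <= max(1L, n_informative_proteins),
      latent_rho >= 0, latent_rho <= 1
    )
  })
  if (cfg$n_informative_proteins * cfg$genes_per_metagene > cfg$n_genes_total) {
    abort("infeasible config: more planted member genes than n_genes_total")
  }
  structure(cfg, class = c("rppasig_sim_config", "list"))
}

# Planted membership structure: disjoint gene blocks, signed coefficients.
sim_members <- function(cfg) {
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes_total))
  prot_ids <- sprintf("P%02d", seq_len(cfg$n_proteins))
  members <- list()
  idx <- 1L
  for (p in seq_len(cfg$n_informative_proteins)) {
    genes <- gene_ids[idx:(idx + cfg$genes_per_metagene - 1L)]
    idx <- idx + cfg$genes_per_metagene
    coefs <- ifelse(runif(length(genes)) < cfg$frac_negative_members, -1L, 1L)
    members[[prot_ids[p]]] <- tibble(gene_id = genes, coefficient = coefs)
  }
  list(gene_ids = gene_ids, prot_ids = prot_ids, members = members)
}

# One cohort from fixed membership structure.
sim_draw_cohort <- function(cfg, structure, n, sample_prefix) {
  sample_ids <- sprintf("%s%03d", sample_prefix, seq_len(n))
  # latent activation: one factor per protein, optional correlated blocks
  latent <- matrix(rnorm(cfg$n_proteins * n), cfg$n_proteins, n,
                   dimnames = list(structure$prot_ids, sample_ids))
  if (!is.null(cfg$latent_blocks)) {
    for (block in cfg$latent_blocks) {
      shared <- rnorm(n)
      latent[block, ] <- sqrt(cfg$latent_rho) *
        matrix(shared, length(block), n, byrow = TRUE) +
        sqrt(1 - cfg$latent_rho) * latent[block, , drop = FALSE]
    }
  }
  rppa <- latent + cfg$noise_sd_rppa *
    matrix(rnorm(length(latent)), nrow(latent), ncol(latent))
  dimnames(rppa) <- dimnames(latent)

  expr <- cfg$baseline_expr + cfg$noise_sd_expr *
    matrix(rnorm(cfg$n_genes_total * n), cfg$n_genes_total, n,
           dimnames = list(structure$gene_ids, sample_ids))
  for (prot in names(structure$members)) {
    mem <- structure$members[[prot]]
    expr[mem$gene_id, ] <- expr[mem$gene_id, ] +
      outer(mem$coefficient * cfg$effect_size, latent[prot, ])
  }

  clinical <- sim_survival(cfg, structure, expr, sample_ids)
  list(rppa = rppa, expr = expr, clinical = clinical, latent = latent)
}

sim_survival <- function(cfg, structure, expr, sample_ids) {
  n <- length(sample_ids)
  arm <- sample(rep(c("control", "treated"), length.out = n))
  surv <- cfg$survival
  z <- rep(0, n)
  if (cfg$n_informative_proteins > 0L) {
    prot <- structure$prot_ids[surv$interaction_protein_index]
    mem <- structure$members[[prot]]
    raw <- as.vector(crossprod(expr[mem$gene_id, , drop = FALSE], mem$coefficient))
    z <- as.vector(scale(raw))
  }
  treated <- arm == "treated"
  log_h <- log(surv$baseline_hazard) +
    treated * surv$treatment_log_hr +
    treated * z * surv$interaction_log_hr_per_sd
  hazard <- exp(log_h)
  t_event <- rexp(n, rate = hazard)
  if (surv$censoring_rate > 0) {
    target <- surv$censoring_rate
    f <- function(lc) mean(lc / (lc + hazard)) - target
    lam_c <- uniroot(f, c(1e-10, 1e6))$root
    t_cens <- rexp(n, rate = lam_c)
  } else {
    t_cens <- rep(Inf, n)
  }
  tibble(
    sample_id = sample_ids,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    arm = factor(arm, levels = c("control", "treated"))
  )
}

#' Generate one synthetic matched cohort
#'
#' Draws a single cohort (RPPA, expression, clinical outcomes) with known
#' ground truth from a [sim_config()]. Fully reproducible from `seed`.
#'
#' @param config A `rppasig_sim_config`.
#' @param seed Random seed (defaults to `config$seed`).
#' @return List with `rppa` and `expr` matrices, `clinical` tibble and
#'   `truth` (latent activations, the planted member tables as
#'   `rppasig_metagene` objects, and the interaction protein's name).
#' @export
generate_cohort <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "rppasig_sim_config"))
  set.seed(seed)
  structure_ <- sim_members(config)
  cohort <- sim_draw_cohort(config, structure_, config$n_samples_derivation, "S")
  truth <- sim_truth(config, structure_, cohort$latent)
  list(rppa = cohort$rppa, expr = cohort$expr, clinical = cohort$clinical,
       truth = truth)
}

sim_truth <- function(cfg, structure_, latent) {
  list(
    latent_activation = latent,
    true_members = purrr::imap(structure_$members, ~ metagene(.y, .x)),
    interaction_protein = if (cfg$n_informative_proteins > 0L) {
      structure_$prot_ids[cfg$survival$interaction_protein_index]
    } else NA_character_
  )
}

#' Generate paired derivation and validation cohorts
#'
#' Two cohorts drawn from the same generative model (identical planted
#' membership structure) with independent latent activations, emulating
#' a derivation dataset and an external validation dataset measured on a
#' different platform: the validation expression matrix is transformed
#' as `scale * expr + shift`.
#'
#' @inheritParams generate_cohort
#' @return List with elements `derivation` and `validation` (each with
#'   `rppa`, `expr`, `clinical`) and the shared `truth` (member tables
#'   and interaction protein).
#' @export
generate_two_datasets <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "rppasig_sim_config"))
  set.seed(seed)
  structure_ <- sim_members(config)
  der <- sim_draw_cohort(config, structure_, config$n_samples_derivation, "D")
  val <- sim_draw_cohort(config, structure_, config$n_samples_validation, "V")
  val$expr <- config$validation_scale * val$expr + config$validation_shift
  list(
    derivation = der[c("rppa", "expr", "clinical")],
    validation = val[c("rppa", "expr", "clinical")],
    truth = sim_truth(config, structure_, der$latent)
  )
}

#' Write a synthetic cohort to a directory
#'
#' Emits the standard on-disk formats (expression and RPPA TSV, clinical
#' CSV) plus a `truth.json` with the planted structure, producing a
#' ready-to-run cohort directory.
#'
#' @param cohort Result of [generate_cohort()] or one element (plus
#'   `truth`) of [generate_two_datasets()].
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(cohort$expr, file.path(dir, "expression.tsv"), id_name = "gene_id")
  write_matrix(cohort$rppa, file.path(dir, "rppa.tsv"), id_name = "protein_id")
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  if (!is.null(cohort$truth)) {
    truth <- list(
      interaction_protein = cohort$truth$interaction_protein,
      members = lapply(cohort$truth$true_members, function(mg) mg$members)
    )
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
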