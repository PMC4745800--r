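#' Configuration for the end-to-end pipeline
#'
#' Collects the file paths and thresholds that drive [run_pipeline()].
#' Thresholds default to the conventional gates of the method: per-protein
#' derivation FDR 0.05, validation Pearson 0.5 and AUC FDR 0.05, network
#' edges with at least 5 shared genes at FDR 0.05, screen FDR 0.05.
#'
#' @param expr_derivation,rppa_derivation Paths to the derivation
#'   expression and RPPA tables.
#' @param expr_validation,rppa_validation Paths to the validation tables.
#' @param clinical Path to the clinical CSV for the survival screen
#'   (samples must match the validation expression matrix); `NULL` skips
#'   the screen.
#' @param genesets Optional GMT path for functional enrichment.
#' @param out_dir Run directory (created; existing files overwritten).
#' @param fdr_derive,r_threshold,fdr_validate,min_overlap,fdr_network
#'   Stage thresholds.
#' @param covariates Covariate columns for the multivariate Cox models.
#' @param align_q Quantile used for cross-dataset alignment.
#' @param seed Seed recorded in the manifest (all stages are
#'   deterministic given the inputs; the seed covers any future
#'   stochastic stage).
#' @return A list of class `rppasig_pipeline_config`.
#' @export
pipeline_config <- function(expr_derivation, rppa_derivation,
                            expr_validation, rppa_validation,
                            clinical = NULL, genesets = NULL, out_dir,
                            fdr_derive = 0.05, r_threshold = 0.5,
                            fdr_validate = 0.05, min_overlap = 5L,
                            fdr_network = 0.05, covariates = character(),
                            align_q = 0.95, seed = 1L) {
  cfg <- list(
    expr_derivation = expr_derivation, rppa_derivation = rppa_derivation,
    expr_validation = expr_validation, rppa_validation = rppa_validation,
    clinical = clinical, genesets = genesets, out_dir = out_dir,
    fdr_derive = fdr_derive, r_threshold = r_threshold,
    fdr_validate = fdr_validate, min_overlap = as.integer(min_overlap),
    fdr_network = fdr_network, covariates = covariates,
    align_q = align_q, seed = as.integer(seed)
  )
  for (thr in c("fdr_derive", "fdr_validate", "fdr_network", "align_q")) {
    if (cfg[[thr]] <= 0 || cfg[[thr]] > 1) abort(sprintf("%s must lie in (0, 1]", thr))
  }
  structure(cfg, class = c("rppasig_pipeline_config", "list"))
}

#' Run the full derive / validate / network / screen pipeline
#'
#' Executes the stages in order against the configured input files,
#' writing per-stage TSV/JSON outputs, a machine-readable manifest
#' (input checksums, thresholds, package version, seed) and a log file
#' into the run directory. Stage outputs are pure functions of the
#' inputs, the configuration and the seed, so re-running with identical
#' inputs reproduces identical tables. A stage failure aborts with a
#' stage-named error.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with the in-memory stage results and the
#'   run directory path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "rppasig_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    inform(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, sprintf("[%s] ERROR: %s", name, conditionMessage(e))),
                 log_path)
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  set.seed(config$seed)

  inputs <- stage("read", {
    say("[read] loading input tables")
    list(
      expr_der = read_expression_matrix(config$expr_derivation),
      rppa_der = read_rppa_matrix(config$rppa_derivation),
      expr_val = read_expression_matrix(config$expr_validation),
      rppa_val = read_rppa_matrix(config$rppa_validation),
      clinical = if (!is.null(config$clinical)) read_clinical_table(config$clinical),
      genesets = if (!is.null(config$genesets)) read_gmt(config$genesets)
    )
  })

  aligned <- stage("align", {
    say("[align] matching pooled %.2f-quantiles across datasets", config$align_q)
    quantile_align(list(inputs$expr_der, inputs$expr_val), q = config$align_q)
  })
  expr_der <- aligned[[1L]]; expr_val <- aligned[[2L]]

  metagenes <- stage("derive", {
    say("[derive] deriving metagenes for %d proteins", nrow(inputs$rppa_der))
    mg <- derive_metagenes(expr_der, inputs$rppa_der,
                           fdr_threshold = config$fdr_derive)
    say("[derive] %d of %d proteins delivered a metagene", length(mg),
        nrow(inputs$rppa_der))
    mg_dir <- file.path(config$out_dir, "metagenes")
    dir.create(mg_dir, showWarnings = FALSE)
    for (m in mg) write_metagene(m, file.path(mg_dir, paste0(m$name, ".tsv")))
    if (length(mg)) write_metagenes_gmt(mg, file.path(config$out_dir, "metagenes.gmt"))
    mg
  })

  validation <- stage("validate", {
    if (length(metagenes) == 0L) {
      say("[validate] no metagenes to validate")
      val <- validate_metagenes(list(), expr_val, inputs$rppa_val)
    } else {
      say("[validate] validating %d metagenes externally", length(metagenes))
      val <- validate_metagenes(metagenes, expr_val, inputs$rppa_val,
                                r_threshold = config$r_threshold,
                                fdr_threshold = config$fdr_validate)
    }
    readr::write_tsv(val, file.path(config$out_dir, "validation.tsv"))
    val
  })
  passed <- metagenes[vapply(metagenes, function(m) {
    isTRUE(validation$passed[validation$metagene == m$name])
  }, logical(1))]
  say("[validate] %d metagenes passed the two-gate validation", length(passed))

  network <- stage("network", {
    if (length(metagenes) >= 2L) {
      net <- build_network(metagenes, universe = rownames(expr_der),
                           min_overlap = config$min_overlap,
                           fdr_threshold = config$fdr_network)
      say("[network] %d significant edges among %d pairs", nrow(net$edges),
          nrow(net$tests))
      readr::write_tsv(net$tests, file.path(config$out_dir, "network_tests.tsv"))
      write_network(net, file.path(config$out_dir, "network.graphml"), "graphml")
      write_network(net, file.path(config$out_dir, "network.sif"), "sif")
      net
    } else {
      say("[network] fewer than 2 metagenes; skipping")
      NULL
    }
  })

  enrichment <- stage("enrich", {
    if (!is.null(inputs$genesets) && length(metagenes)) {
      say("[enrich] testing %d metagenes against %d functional classes",
          length(metagenes), length(inputs$genesets))
      tab <- purrr::map_dfr(metagenes, function(m) {
        dplyr::mutate(enrich(m, inputs$genesets, rownames(expr_der)),
                      metagene = m$name, .before = 1L)
      })
      readr::write_tsv(tab, file.path(config$out_dir, "enrichment.tsv"))
      tab
    }
  })

  screen <- stage("screen", {
    if (!is.null(inputs$clinical)) {
      say("[screen] survival screen of %d validated metagenes", length(passed))
      scr <- screen_metagenes(passed, expr_val, inputs$clinical,
                              covariates = config$covariates)
      readr::write_tsv(scr, file.path(config$out_dir, "screen.tsv"))
      scr
    }
  })

  manifest <- stage("manifest", {
    in_files <- purrr::compact(config[c(
      "expr_derivation", "rppa_derivation", "expr_validation",
      "rppa_validation", "clinical", "genesets"
    )])
    man <- list(
      inputs = lapply(in_files, function(p) {
        list(path = p, md5 = unname(tools::md5sum(p)))
      }),
      thresholds = config[c("fdr_derive", "r_threshold", "fdr_validate",
                            "min_overlap", "fdr_network", "align_q")],
      covariates = config$covariates,
      seed = config$seed,
      package_version = as.character(utils::packageVersion("rppasig")),
      n_metagenes = length(metagenes),
      n_validated = length(passed)
    )
    jsonlite::write_json(man, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    man
  })
  writeLines(log_lines, log_path)

  invisible(list(metagenes = metagenes, validation = validation,
                 passed = passed, network = network, enrichment = enrichment,
                 screen = screen, manifest = manifest,
                 out_dir = config$out_dir))
}
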