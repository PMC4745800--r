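#' Score a metagene on an expression dataset
#'
#' The signature score of a sample is the scalar product of the member
#' coefficients and the member expression values,
#' `score = sum_i e_i * s_i`, with `s_i` in `{-1, +1}`. Members absent
#' from the dataset are skipped and reflected in `coverage`; scoring
#' fails when coverage drops below `min_coverage`.
#'
#' @param mg A `rppasig_metagene`.
#' @param expr Expression matrix (genes x samples).
#' @param min_coverage Minimum fraction of members that must be present
#'   (default 0.5).
#' @return A tibble (class `rppasig_scores`) with columns `sample_id` and
#'   `score`, and attributes `metagene_name`, `n_genes_used`, `coverage`.
#' @export
sigscore <- function(mg, expr, min_coverage = 0.5) {
  stopifnot(inherits(mg, "rppasig_metagene"), is.matrix(expr))
  present <- mg$members$gene_id %in% rownames(expr)
  coverage <- mean(present)
  if (coverage < min_coverage) {
    missing <- utils::head(mg$members$gene_id[!present], 10L)
    abort(sprintf(
      "metagene '%s': only %.0f%% of members present (need >= %.0f%%); missing e.g. %s",
      mg$name, 100 * coverage, 100 * min_coverage, paste(missing, collapse = ", ")
    ))
  }
  used <- mg$members[present, ]
  scores <- as.vector(crossprod(expr[used$gene_id, , drop = FALSE],
                                used$coefficient))
  out <- tibble(sample_id = colnames(expr), score = scores)
  structure(out, metagene_name = mg$name, n_genes_used = nrow(used),
            coverage = coverage,
            class = c("rppasig_scores", class(out)))
}

#' AUC for separating high- from low-protein samples
#'
#' Area under the ROC curve of a continuous score for discriminating the
#' `high` from the `low` class, computed as the Mann-Whitney U statistic
#' divided by `n_high * n_low` (ties count one half). The p-value is the
#' two-sided Mann-Whitney test under the normal approximation with tie
#' correction, equivalent to testing AUC = 0.5.
#'
#' @param scores Numeric vector.
#' @param labels Vector (same length) with values `"low"`/`"high"`;
#'   other values are not allowed.
#' @return A one-row tibble with `auc`, `p`, `n_low`, `n_high`.
#' @export
auc_high_vs_low <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!all(labels %in% c("low", "high"))) abort("labels must be 'low' or 'high'")
  n_h <- sum(labels == "high"); n_l <- sum(labels == "low")
  if (n_h < 3L || n_l < 3L) abort("need >= 3 samples in each class")
  r <- rank(scores)
  u <- sum(r[labels == "high"]) - n_h * (n_h + 1) / 2
  auc <- u / (n_h * n_l)
  p <- suppressWarnings(
    wilcox.test(scores[labels == "high"], scores[labels == "low"],
                exact = FALSE, correct = FALSE)$p.value
  )
  tibble(auc = auc, p = p, n_low = n_l, n_high = n_h)
}

#' Externally validate metagenes on an independent matched dataset
#'
#' A metagene passes validation when, on a dataset with matched
#' expression and RPPA measurements, (1) its score correlates with the
#' continuous RPPA level of its source protein with Pearson r at or above
#' `r_threshold` (signed: a correctly oriented metagene must correlate
#' positively), and (2) its score discriminates the validation dataset's
#' own quartile-derived high vs low protein groups with a ROC AUC whose
#' Benjamini-Hochberg-adjusted Mann-Whitney p-value is at or below
#' `fdr_threshold`. Intermediate samples enter the correlation but not
#' the AUC. Metagenes whose source protein is absent (or that cannot be
#' scored) are marked untestable and excluded from the BH adjustment.
#'
#' @param metagenes Named list of `rppasig_metagene` objects; names (or
#'   `$name`) must match rows of `rppa_val`.
#' @param expr_val Validation expression matrix.
#' @param rppa_val Validation RPPA matrix (same samples as `expr_val`,
#'   by name; missing values excluded pairwise).
#' @param r_threshold Pearson gate (default 0.5).
#' @param fdr_threshold FDR gate on the AUC p-values (default 0.05).
#' @param min_coverage Passed to [sigscore()].
#' @return A tibble (class `rppasig_validation`) with one row per
#'   metagene: `metagene`, `n_genes_used`, `coverage`, `pearson_r`,
#'   `auc`, `auc_p`, `auc_q`, `passed`, `testable`.
#' @export
validate_metagenes <- function(metagenes, expr_val, rppa_val,
                               r_threshold = 0.5, fdr_threshold = 0.05,
                               min_coverage = 0.5) {
  stopifnot(is.list(metagenes), is.matrix(expr_val), is.matrix(rppa_val))
  if (length(metagenes) == 0L) {
    out <- tibble(metagene = character(), n_genes_used = integer(),
                  coverage = numeric(), pearson_r = numeric(),
                  auc = numeric(), auc_p = numeric(), testable = logical(),
                  auc_q = numeric(), passed = logical())
    class(out) <- c("rppasig_validation", class(tibble()))
    return(out)
  }
  rows <- purrr::map(metagenes, function(mg) {
    base <- tibble(metagene = mg$name, n_genes_used = NA_integer_,
                   coverage = NA_real_, pearson_r = NA_real_,
                   auc = NA_real_, auc_p = NA_real_, testable = FALSE)
    if (!mg$name %in% rownames(rppa_val)) return(base)
    sc <- tryCatch(sigscore(mg, expr_val, min_coverage = min_coverage),
                   error = function(e) NULL)
    if (is.null(sc)) return(base)
    prot <- rppa_val[mg$name, sc$sample_id]
    ok <- !is.na(prot)
    if (sum(ok) < 8L || diff(range(prot[ok])) == 0) return(base)
    r <- cor(sc$score[ok], prot[ok])
    grouping <- assign_groups(prot[ok], protein_id = mg$name)
    extreme <- grouping$group != "intermediate"
    auc_res <- auc_high_vs_low(
      sc$score[match(grouping$sample_id[extreme], sc$sample_id)],
      as.character(grouping$group[extreme])
    )
    tibble(metagene = mg$name, n_genes_used = attr(sc, "n_genes_used"),
           coverage = attr(sc, "coverage"), pearson_r = r,
           auc = auc_res$auc, auc_p = auc_res$p, testable = TRUE)
  })
  out <- dplyr::bind_rows(rows)
  out$auc_q <- NA_real_
  if (any(out$testable)) {
    out$auc_q[out$testable] <- bh_adjust(out$auc_p[out$testable])
  }
  out$passed <- out$testable & out$pearson_r >= r_threshold &
    out$auc_q <= fdr_threshold
  out$passed[is.na(out$passed)] <- FALSE
  class(out) <- c("rppasig_validation", class(tibble()))
  out
}
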