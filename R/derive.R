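#' Assign samples to low/intermediate/high protein groups
#'
#' Samples are stratified by the quartiles of one protein's RPPA levels:
#' `low` holds samples at or below the lower quartile, `high` samples at
#' or above the upper quartile, the rest are `intermediate`. Quartiles use
#' linear interpolation between order statistics (type 7); boundary ties
#' are inclusive, so tied samples can enlarge the outer groups beyond 25%.
#' Samples with missing values are excluded.
#'
#' @param values Named numeric vector of protein levels (names = sample
#'   ids). At least 8 non-missing values are required and the values must
#'   not all be equal.
#' @param protein_id Optional label stored on the result.
#' @return A tibble (class `rppasig_grouping`) with columns `sample_id`
#'   and `group` (factor low/intermediate/high) and attributes `q1`, `q3`
#'   and `protein_id`.
#' @export
assign_groups <- function(values, protein_id = NULL) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  values <- values[!is.na(values)]
  if (length(values) < 8L) {
    abort(sprintf("need >= 8 non-missing protein values, got %d", length(values)))
  }
  if (diff(range(values)) == 0) {
    abort("protein values are constant; quartile groups are undefined")
  }
  q1 <- .quantile(values, 0.25)
  q3 <- .quantile(values, 0.75)
  group <- dplyr::case_when(
    values <= q1 ~ "low",
    values >= q3 ~ "high",
    TRUE ~ "intermediate"
  )
  out <- tibble(
    sample_id = names(values),
    group = factor(group, levels = c("low", "intermediate", "high"))
  )
  structure(out, q1 = q1, q3 = q3, protein_id = protein_id,
            class = c("rppasig_grouping", class(out)))
}

#' Robust two-group location test
#'
#' A Student-type two-sample test built on robust estimators of location
#' and spread, with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value from the t distribution. Two estimator pairings are
#' provided:
#'
#' * `"trimmed"` (default): Yuen's test — 20%-trimmed means with
#'   winsorized variances. Well calibrated at the nominal level and in
#'   the extreme tail, which matters when the smallest of thousands of
#'   per-gene p-values decides whether a metagene is non-empty.
#' * `"median"`: medians with 1.4826 x MAD scale. The variance terms are
#'   inflated by `pi/2`, the efficiency deficit of the median relative
#'   to the mean under approximate normality; without that factor the
#'   statistic is strongly anti-conservative. Calibrated at the nominal
#'   level but heavier-tailed than its t reference in the far tail.
#'
#' Degenerate inputs: if both groups have zero spread, equal locations
#' give `t = 0, p = 1, direction = 0`; unequal locations give `p = 0`
#' with infinite `t` and `degenerate = TRUE`.
#'
#' @param x_low,x_high Numeric vectors (each of length >= 2) for the low
#'   and high groups.
#' @param estimator `"trimmed"` or `"median"`.
#' @param trim Trimming fraction per tail for `"trimmed"` (default 0.2).
#' @return A one-row tibble with `t`, `p`, `direction` (-1/0/+1 sign of
#'   the high-minus-low robust location difference), `df` and
#'   `degenerate`.
#' @export
robust_t <- function(x_low, x_high, estimator = c("trimmed", "median"),
                     trim = 0.2) {
  stopifnot(length(x_low) >= 2L, length(x_high) >= 2L)
  estimator <- match.arg(estimator)
  res <- robust_t_matrix(matrix(x_low, nrow = 1L), matrix(x_high, nrow = 1L),
                         estimator = estimator, trim = trim)
  if (res$degenerate) warn("both groups have zero robust spread with unequal locations; p set to 0")
  res
}

# Per-row trimmed mean and the Yuen squared standard-error contribution
# d = (n - 1) * winsorized variance / (h * (h - 1)), h = n - 2*floor(trim*n).
row_yuen_stats <- function(m, trim) {
  n <- ncol(m)
  lo <- floor(trim * n)
  h <- n - 2L * lo
  s <- apply(m, 1L, sort)              # n x genes, sorted within column
  tmean <- colMeans(s[(lo + 1L):(n - lo), , drop = FALSE])
  if (lo > 0L) {
    s[seq_len(lo), ] <- rep(s[lo + 1L, ], each = lo)
    s[(n - lo + 1L):n, ] <- rep(s[n - lo, ], each = lo)
  }
  wvar <- matrixStats::colVars(s)
  list(loc = tmean, d = (n - 1L) * wvar / (h * (h - 1L)), df_n = h - 1L)
}

# Vectorised robust test: one gene per row. Shared by robust_t() and
# derive_metagene(); keeping the arithmetic in one place keeps the two
# paths identical.
robust_t_matrix <- function(low, high, estimator = "trimmed", trim = 0.2) {
  n_l <- ncol(low)
  n_h <- ncol(high)
  if (estimator == "trimmed") {
    st_l <- row_yuen_stats(low, trim)
    st_h <- row_yuen_stats(high, trim)
    loc_l <- st_l$loc; loc_h <- st_h$loc
    v_l <- st_l$d; v_h <- st_h$d
    df <- (v_l + v_h)^2 / (v_l^2 / st_l$df_n + v_h^2 / st_h$df_n)
  } else {
    loc_l <- matrixStats::rowMedians(low)
    loc_h <- matrixStats::rowMedians(high)
    k <- pi / 2                  # efficiency of the median vs the mean
    v_l <- k * matrixStats::rowMads(low)^2 / n_l   # 1.4826 x MAD scale
    v_h <- k * matrixStats::rowMads(high)^2 / n_h
    df <- (v_l + v_h)^2 / (v_l^2 / (n_l - 1L) + v_h^2 / (n_h - 1L))
  }
  delta <- loc_h - loc_l
  direction <- sign(delta)
  se <- sqrt(v_l + v_h)

  t_stat <- delta / se
  p <- 2 * pt(-abs(t_stat), df)

  zero_se <- se == 0
  degenerate <- zero_se & delta != 0
  t_stat[zero_se] <- ifelse(delta[zero_se] == 0, 0, Inf * direction[zero_se])
  p[zero_se] <- ifelse(delta[zero_se] == 0, 1, 0)
  df[zero_se] <- NA_real_

  tibble(t = t_stat, p = p, direction = direction, df = df,
         degenerate = degenerate)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate;
#' order of the input is preserved and values are clipped at 1.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(is.numeric(pvalues))
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Derive a signed metagene for one protein
#'
#' Tests every gene of the expression matrix for differential expression
#' between the protein's high and low sample groups with [robust_t()],
#' adjusts the per-protein p-values by Benjamini-Hochberg, and keeps genes
#' with `q <= fdr_threshold`. Each member carries a coefficient of `+1`
#' (up in the high-protein group) or `-1` (down), the sign of the robust
#' location difference. A protein whose genes all fail the FDR gate yields
#' no metagene (`NULL`).
#'
#' @param expr Expression matrix (genes x samples).
#' @param grouping A `rppasig_grouping` from [assign_groups()].
#' @param fdr_threshold FDR cut-off for membership (default 0.05).
#' @param name Metagene name; defaults to the grouping's protein id.
#' @inheritParams robust_t
#' @return An object of class `rppasig_metagene` (list with `name`,
#'   `members` tibble of `gene_id`, `coefficient`, `t`, `p`, `q`, and the
#'   group sizes `n_low`, `n_high`), or `NULL` when no gene passes.
#' @export
derive_metagene <- function(expr, grouping, fdr_threshold = 0.05, name = NULL,
                            estimator = c("trimmed", "median"), trim = 0.2) {
  estimator <- match.arg(estimator)
  stopifnot(is.matrix(expr), inherits(grouping, "rppasig_grouping"))
  name <- name %||% attr(grouping, "protein_id") %||% "metagene"
  low_ids <- intersect(grouping$sample_id[grouping$group == "low"], colnames(expr))
  high_ids <- intersect(grouping$sample_id[grouping$group == "high"], colnames(expr))
  if (length(low_ids) + length(high_ids) < 8L ||
      length(low_ids) < 2L || length(high_ids) < 2L) {
    abort(sprintf("metagene '%s': need >= 8 shared samples with non-empty low/high groups", name))
  }
  stats_tbl <- robust_t_matrix(expr[, low_ids, drop = FALSE],
                               expr[, high_ids, drop = FALSE],
                               estimator = estimator, trim = trim)
  stats_tbl$q <- bh_adjust(stats_tbl$p)
  keep <- stats_tbl$q <= fdr_threshold & stats_tbl$direction != 0
  if (!any(keep)) return(NULL)
  members <- tibble(
    gene_id = rownames(expr)[keep],
    coefficient = as.integer(stats_tbl$direction[keep]),
    t = stats_tbl$t[keep],
    p = stats_tbl$p[keep],
    q = stats_tbl$q[keep]
  )
  new_metagene(name, members, n_low = length(low_ids), n_high = length(high_ids))
}

new_metagene <- function(name, members, n_low = NA_integer_, n_high = NA_integer_) {
  stopifnot(all(members$coefficient %in% c(-1L, 1L)))
  structure(
    list(name = name, members = members,
         n_low = n_low, n_high = n_high),
    class = "rppasig_metagene"
  )
}

#' Construct a metagene from a member table
#'
#' Low-level constructor for signatures defined outside the derivation
#' pipeline (e.g. read from a file or planted by the simulator).
#'
#' @param name Metagene name.
#' @param members Data frame with columns `gene_id` and `coefficient`
#'   (values -1 or +1); statistics columns are optional.
#' @return A `rppasig_metagene`.
#' @export
metagene <- function(name, members) {
  members <- as_tibble(members)
  stopifnot(all(c("gene_id", "coefficient") %in% names(members)),
            nrow(members) > 0L, !anyDuplicated(members$gene_id))
  members$coefficient <- as.integer(members$coefficient)
  new_metagene(name, members)
}

#' @export
print.rppasig_metagene <- function(x, ...) {
  cat(sprintf("<rppasig_metagene> %s: %d member genes (%d up, %d down)\n",
              x$name, nrow(x$members), sum(x$members$coefficient == 1L),
              sum(x$members$coefficient == -1L)))
  invisible(x)
}

#' Derive metagenes for every protein of an RPPA matrix
#'
#' Applies [assign_groups()] and [derive_metagene()] to each antibody row.
#' Proteins with fewer than `min_values` non-missing measurements or a
#' constant profile are skipped with a warning; proteins whose genes all
#' fail the FDR gate are silently dropped (they deliver no metagene).
#'
#' @param expr Expression matrix (genes x samples).
#' @param rppa RPPA matrix (proteins x samples); missing values allowed.
#' @param fdr_threshold Per-protein FDR cut-off (default 0.05).
#' @param min_values Minimum non-missing values per protein (default 8).
#' @inheritParams robust_t
#' @return Named list of `rppasig_metagene` objects.
#' @export
derive_metagenes <- function(expr, rppa, fdr_threshold = 0.05, min_values = 8L,
                             estimator = c("trimmed", "median"), trim = 0.2) {
  stopifnot(is.matrix(expr), is.matrix(rppa))
  estimator <- match.arg(estimator)
  out <- list()
  for (prot in rownames(rppa)) {
    v <- rppa[prot, ]
    v <- v[!is.na(v)]
    if (length(v) < min_values || diff(range(v)) == 0) {
      warn(sprintf("skipping protein '%s': insufficient or constant values", prot))
      next
    }
    grouping <- assign_groups(v, protein_id = prot)
    mg <- derive_metagene(expr, grouping, fdr_threshold = fdr_threshold,
                          estimator = estimator, trim = trim)
    if (!is.null(mg)) out[[prot]] <- mg
  }
  out
}

#' Serialise a metagene to disk
#'
#' Writes a two-column TSV (`gene_id`, `coefficient`) plus a JSON sidecar
#' (`<stem>.json`) holding the derivation statistics and group sizes.
#'
#' @param mg A `rppasig_metagene`.
#' @param path Output TSV path; the sidecar replaces the extension with
#'   `.json`.
#' @export
write_metagene <- function(mg, path) {
  stopifnot(inherits(mg, "rppasig_metagene"))
  readr::write_tsv(mg$members[, c("gene_id", "coefficient")], path)
  side <- sub("\\.[^.]+$", ".json", path)
  stats_cols <- intersect(c("gene_id", "t", "p", "q"), names(mg$members))
  jsonlite::write_json(
    list(name = mg$name, n_low = mg$n_low, n_high = mg$n_high,
         stats = mg$members[stats_cols]),
    side, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' Export metagenes as signed GMT sets
#'
#' Each metagene becomes two sets, `<name>_UP` (coefficient +1) and
#' `<name>_DN` (coefficient -1); empty halves are omitted.
#'
#' @param metagenes List of `rppasig_metagene` objects.
#' @param path Output `.gmt` path.
#' @export
write_metagenes_gmt <- function(metagenes, path) {
  sets <- list()
  for (mg in metagenes) {
    up <- mg$members$gene_id[mg$members$coefficient == 1L]
    dn <- mg$members$gene_id[mg$members$coefficient == -1L]
    if (length(up)) sets[[paste0(mg$name, "_UP")]] <- up
    if (length(dn)) sets[[paste0(mg$name, "_DN")]] <- dn
  }
  write_gmt(sets, path)
}
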