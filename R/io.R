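#' Read a gene-expression matrix from delimited text
#'
#' Reads a genes-in-rows table (header row of sample identifiers, one
#' identifier column) into a numeric matrix. Rows sharing a gene identifier
#' are collapsed to their per-sample arithmetic mean, the convention for
#' multiple probe sets mapping to one gene symbol. Rows are returned in
#' lexicographic order of gene identifier so output is deterministic.
#'
#' @param path Path to a TSV/CSV file. The delimiter is inferred from the
#'   file extension (`.csv` gives comma, anything else tab) unless `delim`
#'   is supplied.
#' @param id_column Name or index of the gene-identifier column (default:
#'   first column).
#' @param delim Field delimiter, overriding the extension-based guess.
#' @return A numeric matrix (genes x samples) with unique row and column
#'   names; all values finite.
#' @export
read_expression_matrix <- function(path, id_column = 1L, delim = NULL) {
  raw <- read_id_table(path, id_column, delim, what = "expression matrix")
  if (anyNA(raw$values)) {
    bad <- which(is.na(raw$values), arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "expression matrix '%s' has a missing/non-numeric value at gene '%s', sample '%s'",
      path, raw$ids[bad[1L]], colnames(raw$values)[bad[2L]]
    ))
  }
  rownames(raw$values) <- raw$ids
  collapse_duplicates(raw$values)
}

#' Collapse duplicate row identifiers to their mean
#'
#' Rows of a named matrix that share a row name are replaced by their
#' column-wise arithmetic mean. The operation is idempotent and returns
#' rows in lexicographic order of identifier.
#'
#' @param mat A numeric matrix with row names.
#' @return A numeric matrix with unique, sorted row names.
#' @export
collapse_duplicates <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  ids <- trimws(rownames(mat))
  out <- rowsum(mat, group = ids, reorder = TRUE) / as.vector(table(ids))
  out[order(rownames(out)), , drop = FALSE]
}

#' Read an RPPA (protein) matrix from delimited text
#'
#' Reads an antibodies-in-rows table of protein levels. Missing values are
#' allowed (they are excluded pairwise downstream), but any antibody with
#' fewer than `min_values` non-missing measurements is dropped with a
#' warning: quartile grouping on fewer samples is not meaningful.
#'
#' @inheritParams read_expression_matrix
#' @param min_values Minimum number of non-missing values an antibody must
#'   have to be retained (default 8).
#' @return A numeric matrix (proteins x samples); may contain `NA`.
#' @export
read_rppa_matrix <- function(path, id_column = 1L, delim = NULL, min_values = 8L) {
  raw <- read_id_table(path, id_column, delim, what = "RPPA matrix")
  if (anyDuplicated(raw$ids)) {
    dup <- unique(raw$ids[duplicated(raw$ids)])
    abort(sprintf("duplicate antibody names in '%s': %s", path,
                  paste(dup, collapse = ", ")))
  }
  values <- raw$values
  rownames(values) <- raw$ids
  n_ok <- rowSums(!is.na(values))
  drop <- n_ok < min_values
  if (any(drop)) {
    warn(sprintf("dropping %d protein(s) with fewer than %d non-missing values: %s",
                 sum(drop), min_values, paste(raw$ids[drop], collapse = ", ")))
    values <- values[!drop, , drop = FALSE]
  }
  if (nrow(values) == 0L) abort(sprintf("no usable proteins in '%s'", path))
  values
}

# Shared reader: id column + numeric block, delimiter from extension.
read_id_table <- function(path, id_column, delim, what) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) abort(sprintf("empty or malformed %s: '%s'", what, path))
  if (is.numeric(id_column)) id_column <- names(df)[id_column]
  if (!id_column %in% names(df)) {
    abort(sprintf("id column '%s' not present in '%s'", id_column, path))
  }
  ids <- trimws(df[[id_column]])
  num <- df[setdiff(names(df), id_column)]
  if (anyDuplicated(names(num))) abort(sprintf("duplicate sample ids in '%s'", path))
  values <- matrix(NA_real_, nrow(df), ncol(num),
                   dimnames = list(NULL, names(num)))
  for (j in seq_along(num)) {
    cell <- trimws(num[[j]])
    v <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(v) & !(is.na(cell) | cell %in% c("", "NA")))
    if (length(bad)) {
      abort(sprintf("non-numeric value '%s' at row '%s', column '%s' of '%s'",
                    cell[bad[1L]], ids[bad[1L]], names(num)[j], path))
    }
    values[, j] <- v
  }
  if (any(!is.finite(values) & !is.na(values))) {
    abort(sprintf("non-finite values in %s '%s'", what, path))
  }
  list(ids = ids, values = values)
}

#' Write a matrix as a delimited genes-in-rows table
#'
#' Inverse of [read_expression_matrix()]/[read_rppa_matrix()]: writes the
#' identifier column followed by one column per sample. Values are printed
#' at full precision so a read/write round trip is lossless.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path; `.csv` extension selects comma, else tab.
#' @param id_name Header for the identifier column.
#' @export
write_matrix <- function(mat, path, id_name = "id") {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}

#' Read a clinical/survival table
#'
#' Requires columns `sample_id`, `time` (months, non-negative), `event`
#' (0/1) and `arm` (`"control"`/`"treated"`); any further columns are kept
#' as covariates. Each sample may appear at most once.
#'
#' @param path Path to a CSV/TSV file.
#' @param delim Optional delimiter override.
#' @return A tibble with `arm` as a factor with levels
#'   `c("control", "treated")`.
#' @export
read_clinical_table <- function(path, delim = NULL) {
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, progress = FALSE,
                          show_col_types = FALSE)
  validate_clinical(as_tibble(df))
}

validate_clinical <- function(df) {
  need <- c("sample_id", "time", "event", "arm")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(sprintf("clinical table lacks column(s): %s",
                                  paste(miss, collapse = ", ")))
  if (anyDuplicated(df$sample_id)) abort("duplicate sample_id in clinical table")
  if (any(!is.finite(df$time)) || any(df$time < 0)) abort("clinical time must be finite and >= 0")
  if (!all(df$event %in% c(0, 1))) abort("clinical event must be 0 or 1")
  if (!all(df$arm %in% c("control", "treated"))) {
    abort("clinical arm must be 'control' or 'treated'")
  }
  df$arm <- factor(df$arm, levels = c("control", "treated"))
  df
}

#' Read a GMT gene-set collection
#'
#' Parses the tab-separated GMT format (set name, description, member
#' genes) into a named list of character vectors. Set names must be unique
#' and sets non-empty.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of gene-symbol vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) abort(sprintf("duplicate set names in '%s'", path))
  sets <- lapply(sets, function(g) unique(trimws(g[nzchar(trimws(g))])))
  if (any(lengths(sets) == 0L)) abort(sprintf("empty gene set(s) in '%s'", path))
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional per-set description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[[(i - 1L) %% length(description) + 1L]],
            sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Align expression datasets by their pooled upper quantile
#'
#' Multiplicatively rescales each matrix so that the `q`-quantile of its
#' pooled values matches that of the first (reference) matrix, making
#' expression values comparable across datasets measured on different
#' scales. Gene and sample identifiers are unchanged. Rescaling to a
#' high quantile (default 0.95) is robust to differences in the extreme
#' tail while tracking the bulk of the intensity distribution.
#'
#' @param matrices List of numeric expression matrices; the first is the
#'   reference.
#' @param q Quantile in (0, 1) used for matching (default 0.95), computed
#'   by linear interpolation between order statistics (type 7).
#' @return List of rescaled matrices in the input order; the reference is
#'   returned unchanged.
#' @export
quantile_align <- function(matrices, q = 0.95) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  stopifnot(is.list(matrices), length(matrices) >= 1L, q > 0, q < 1)
  qs <- vapply(matrices, function(m) {
    if (length(m) == 0L) abort("cannot align an empty matrix")
    .quantile(as.vector(m), q)
  }, numeric(1))
  if (any(qs <= 0)) {
    abort(sprintf("pooled %.2f-quantile must be positive for multiplicative rescaling", q))
  }
  out <- lapply(seq_along(matrices), function(i) matrices[[i]] * (qs[1L] / qs[i]))
  names(out) <- names(matrices)
  out
}
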