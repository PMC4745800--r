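#' Upper-tail hypergeometric overlap p-value
#'
#' Probability that two gene sets of sizes `Na` and `Nb`, drawn without
#' replacement from a universe of `N` genes, share at least `n` genes:
#' `P(X >= n)` for `X ~ Hypergeometric(N, Na, Nb)`. Evaluated by the
#' numerically stable (log-space) tail of [stats::phyper()]. Vectorised
#' over its arguments.
#'
#' @param Na,Nb Sizes of the two sets.
#' @param n Observed overlap, `0 <= n <= min(Na, Nb)`.
#' @param N Universe size, `N >= max(Na, Nb)`.
#' @return Upper-tail p-value(s) in \[0, 1\].
#' @export
hypergeom_upper_p <- function(Na, Nb, n, N) {
  args <- vctrs_recycle(Na = Na, Nb = Nb, n = n, N = N)
  with(args, {
    if (any(n < 0 | Na < 0 | Nb < 0 | N < 0)) abort("counts must be non-negative")
    if (any(n > pmin(Na, Nb))) abort("overlap n cannot exceed min(Na, Nb)")
    if (any(pmax(Na, Nb) > N)) abort("set sizes cannot exceed the universe N")
    phyper(n - 1, Na, N - Na, Nb, lower.tail = FALSE)
  })
}

vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, length.out = n)
}

#' Build the metagene overlap network
#'
#' Every unordered pair of metagenes is tested for a larger-than-chance
#' overlap of member genes (coefficients ignored) with
#' [hypergeom_upper_p()] against a fixed gene universe; p-values are
#' Benjamini-Hochberg adjusted across all pairs. An edge links two
#' metagenes when they share at least `min_overlap` genes and the
#' adjusted p-value is at or below `fdr_threshold`.
#'
#' @param metagenes List of `rppasig_metagene` objects (>= 2).
#' @param universe Character vector of all measured genes; every member
#'   gene must belong to it (typically `rownames()` of the derivation
#'   expression matrix).
#' @param min_overlap Minimum shared genes for an edge (default 5).
#' @param fdr_threshold FDR cut-off for edges (default 0.05).
#' @param cluster `"components"` labels nodes by connected component;
#'   `"label_prop"` additionally runs label propagation on the edge
#'   graph; `"none"` skips labelling.
#' @return An object of class `rppasig_network`: list with `tests` (all
#'   pairs), `edges` (retained pairs), `nodes` (per-metagene size and
#'   cluster label) and `graph` (an igraph object).
#' @export
build_network <- function(metagenes, universe, min_overlap = 5L,
                          fdr_threshold = 0.05,
                          cluster = c("components", "label_prop", "none")) {
  cluster <- match.arg(cluster)
  stopifnot(is.list(metagenes), length(metagenes) >= 2L)
  universe <- unique(universe)
  if (length(universe) == 0L) abort("gene universe is empty")
  sets <- lapply(metagenes, function(mg) unique(mg$members$gene_id))
  names(sets) <- vapply(metagenes, function(mg) mg$name, character(1))
  stray <- setdiff(unlist(sets), universe)
  if (length(stray)) {
    abort(sprintf("metagene members outside the universe, e.g. %s",
                  paste(utils::head(stray, 5L), collapse = ", ")))
  }
  pairs <- utils::combn(names(sets), 2L)
  tests <- tibble(
    a = pairs[1L, ], b = pairs[2L, ],
    Na = lengths(sets)[pairs[1L, ]],
    Nb = lengths(sets)[pairs[2L, ]],
    n_overlap = vapply(seq_len(ncol(pairs)), function(i) {
      length(intersect(sets[[pairs[1L, i]]], sets[[pairs[2L, i]]]))
    }, integer(1)),
    N_universe = length(universe)
  )
  tests$p <- hypergeom_upper_p(tests$Na, tests$Nb, tests$n_overlap, tests$N_universe)
  tests$q <- bh_adjust(tests$p)
  edges <- tests[tests$n_overlap >= min_overlap & tests$q <= fdr_threshold, ]

  g <- igraph::graph_from_data_frame(
    edges[, c("a", "b", "n_overlap", "q")], directed = FALSE,
    vertices = tibble(name = names(sets), n_members = lengths(sets))
  )
  cluster_lab <- switch(
    cluster,
    none = rep(NA_integer_, length(sets)),
    components = igraph::components(g)$membership,
    label_prop = igraph::membership(igraph::cluster_label_prop(g))
  )
  nodes <- tibble(metagene = names(sets), n_members = unname(lengths(sets)),
                  cluster = as.integer(cluster_lab))
  structure(list(tests = tests, edges = edges, nodes = nodes, graph = g),
            class = "rppasig_network")
}

#' @export
print.rppasig_network <- function(x, ...) {
  cat(sprintf("<rppasig_network> %d metagenes, %d significant edges (of %d pairs)\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$tests)))
  invisible(x)
}

#' Export a metagene network
#'
#' @param network A `rppasig_network`.
#' @param path Output file.
#' @param format `"graphml"` (via igraph) or `"sif"` (simple interaction
#'   format, one `a overlap b` line per edge).
#' @export
write_network <- function(network, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "rppasig_network"))
  if (format == "graphml") {
    igraph::write_graph(network$graph, path, format = "graphml")
  } else {
    writeLines(sprintf("%s\toverlap\t%s", network$edges$a, network$edges$b), path)
  }
  invisible(path)
}

#' Functional-class enrichment of a metagene
#'
#' Tests the overlap of a metagene's member genes with each set of a
#' collection (e.g. GO or mSigDB classes) by [hypergeom_upper_p()]
#' against a fixed universe; BH adjustment is across the classes of the
#' collection. Class genes outside the universe are ignored.
#'
#' @param mg A `rppasig_metagene`.
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param universe Character vector of measured genes.
#' @return Tibble with one row per class: `class`, `Na`, `Nb`,
#'   `n_overlap`, `N_universe`, `p`, `q`, ordered by `p`.
#' @export
enrich <- function(mg, collection, universe) {
  stopifnot(inherits(mg, "rppasig_metagene"), is.list(collection))
  universe <- unique(universe)
  if (length(universe) == 0L) abort("gene universe is empty")
  members <- intersect(unique(mg$members$gene_id), universe)
  if (length(members) == 0L) abort("no metagene members inside the universe")
  out <- tibble(
    class = names(collection),
    Na = length(members),
    Nb = vapply(collection, function(s) length(intersect(s, universe)), integer(1)),
    n_overlap = vapply(collection, function(s) {
      length(intersect(members, intersect(s, universe)))
    }, integer(1)),
    N_universe = length(universe)
  )
  out <- out[out$Nb > 0L, ]
  out$p <- hypergeom_upper_p(out$Na, out$Nb, out$n_overlap, out$N_universe)
  out$q <- bh_adjust(out$p)
  out[order(out$p), ]
}

#' Rand index between two partitions
#'
#' Fraction of unordered item pairs on which two partitions agree (both
#' together or both apart), in \[0, 1\]; the plain, unadjusted index.
#' Invariant to label permutation.
#'
#' @param a,b Partitions over the same items: either tibbles with columns
#'   `item` and `cluster`, or named vectors of cluster labels.
#' @return The Rand index.
#' @export
rand_index <- function(a, b) {
  la <- as_partition_labels(a)
  lb <- as_partition_labels(b)
  if (!setequal(names(la), names(lb))) abort("partitions cover different item sets")
  lb <- lb[names(la)]
  n <- length(la)
  if (n < 2L) abort("need at least 2 items")
  tab <- table(la, lb)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_a - sum_b) / total
}

as_partition_labels <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("item", "cluster") %in% names(x)))
    out <- setNames(as.character(x$cluster), x$item)
  } else {
    stopifnot(!is.null(names(x)))
    out <- setNames(as.character(x), names(x))
  }
  if (anyDuplicated(names(out))) abort("duplicate items in partition")
  out
}

#' Partition entities by clustering their correlation matrix
#'
#' Computes the Pearson correlation matrix of the entities (rows) over
#' the shared features (columns), applies hierarchical clustering to its
#' rows with Euclidean distance and complete linkage, and cuts the tree
#' into exactly `k` classes. Zero-variance entities are excluded with a
#' warning (their correlations are undefined).
#'
#' @param profile_matrix Numeric matrix, entities x features, with row
#'   names.
#' @param k Number of classes (default 3).
#' @return A tibble with columns `item` and `cluster` (labels 1..k).
#' @export
correlation_partition <- function(profile_matrix, k = 3L) {
  stopifnot(is.matrix(profile_matrix), !is.null(rownames(profile_matrix)))
  v <- apply(profile_matrix, 1L, stats::var)
  if (any(v == 0)) {
    warn(sprintf("excluding %d zero-variance entit(ies) from clustering", sum(v == 0)))
    profile_matrix <- profile_matrix[v > 0, , drop = FALSE]
  }
  if (nrow(profile_matrix) < k) abort("fewer (usable) entities than classes k")
  cmat <- cor(t(profile_matrix))
  hc <- hclust(dist(cmat, method = "euclidean"), method = "complete")
  labels <- cutree(hc, k = k)
  tibble(item = rownames(profile_matrix), cluster = as.integer(labels))
}
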