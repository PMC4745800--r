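# Independent oracles used across the suite. Each is a deliberately
# naive implementation (loops, enumeration, exact arithmetic) kept
# separate from the package's code paths.

# Brute-force signature score: explicit loop over members and samples.
oracle_sigscore <- function(members, expr) {
  vapply(colnames(expr), function(s) {
    tot <- 0
    for (i in seq_len(nrow(members))) {
      g <- members$gene_id[i]
      if (g %in% rownames(expr)) tot <- tot + members$coefficient[i] * expr[g, s]
    }
    tot
  }, numeric(1))
}

# Exact hypergeometric upper tail by direct summation of binomial
# coefficients (exact in double precision for N <= 25).
oracle_hyper <- function(Na, Nb, n, N) {
  i <- n:min(Na, Nb)
  sum(choose(Na, i) * choose(N - Na, Nb - i)) / choose(N, Nb)
}

# Rand index by enumeration of all unordered item pairs.
oracle_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  idx <- utils::combn(length(a), 2)
  agree <- vapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    (a[i] == a[j]) == (b[i] == b[j])
  }, logical(1))
  mean(agree)
}

# Benjamini-Hochberg by the hand-applied step-up definition:
# q(i) = min over j >= i (in p-sorted order) of m * p(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Small deterministic expression fixture.
toy_expr <- function(genes = 6, samples = 4, seed = 7) {
  set.seed(seed)
  m <- matrix(rnorm(genes * samples, mean = 6), genes, samples,
              dimnames = list(sprintf("G%02d", seq_len(genes)),
                              sprintf("S%02d", seq_len(samples))))
  m
}

write_tsv_matrix <- function(mat, id_name = "gene_id") {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  rppasig::write_matrix(mat, path, id_name = id_name)
  path
}
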