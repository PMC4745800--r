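test_that("quartile grouping splits samples at Q1/Q3 with inclusive ties", {
  v <- setNames(as.numeric(1:8), paste0("s", 1:8))
  g <- assign_groups(v)
  expect_equal(attr(g, "q1"), quantile(1:8, 0.25, type = 7, names = FALSE)) # 2.75
  expect_equal(attr(g, "q3"), 6.25)
  expect_setequal(g$sample_id[g$group == "low"], c("s1", "s2"))
  expect_setequal(g$sample_id[g$group == "high"], c("s7", "s8"))
  expect_setequal(g$sample_id[g$group == "intermediate"], paste0("s", 3:6))

  # symmetric values give equal-sized tails
  v2 <- setNames(c(-4:-1, 1:4), paste0("t", 1:8))
  g2 <- assign_groups(v2)
  expect_equal(sum(g2$group == "low"), sum(g2$group == "high"))

  expect_error(assign_groups(setNames(rep(1, 10), paste0("s", 1:10))), "constant")
  expect_error(assign_groups(setNames(1:5, paste0("s", 1:5))), ">= 8")

  # missing values are excluded before grouping
  v3 <- setNames(c(as.numeric(1:9), NA), paste0("u", 1:10))
  g3 <- assign_groups(v3)
  expect_equal(nrow(g3), 9L)
})

test_that("robust test is zero under identity, antisymmetric under swap", {
  x <- c(1.2, 3.4, 0.7, 2.2, 5.1)
  same <- robust_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$direction, 0)

  set.seed(11)
  a <- rnorm(15); b <- rnorm(15, mean = 1)
  fwd <- robust_t(a, b)
  rev <- robust_t(b, a)
  expect_equal(rev$t, -fwd$t)
  expect_equal(rev$p, fwd$p)
  expect_equal(rev$direction, -fwd$direction)
})

test_that("degenerate zero-spread groups follow the declared rules", {
  equal_meds <- robust_t(rep(2, 5), rep(2, 6))
  expect_equal(equal_meds$t, 0)
  expect_equal(equal_meds$p, 1)

  expect_warning(res <- robust_t(rep(1, 5), rep(3, 5)), "zero robust spread")
  expect_equal(res$p, 0)
  expect_true(is.infinite(res$t) && res$t > 0)
  expect_true(res$degenerate)
})

test_that("the median/MAD estimator variant shares the core properties", {
  set.seed(14)
  a <- rnorm(25); b <- rnorm(25, 1)
  fwd <- robust_t(a, b, estimator = "median")
  rev <- robust_t(b, a, estimator = "median")
  expect_equal(rev$t, -fwd$t)
  expect_equal(rev$p, fwd$p)
  same <- robust_t(a, a, estimator = "median")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # median of the high group minus low group drives the sign
  expect_equal(fwd$direction, sign(median(b) - median(a)))
})

test_that("group-constant shifts leave the statistic unchanged", {
  set.seed(4)
  a <- rnorm(20); b <- rnorm(20, 0.5)
  base <- robust_t(a, b)
  shifted <- robust_t(a + 7, b + 7)
  expect_equal(shifted$t, base$t)
  expect_equal(shifted$p, base$p)
})

test_that("BH adjustment matches the step-up definition and base cases", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^2
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
})

test_that("derivation recovers planted genes and controls false members", {
  set.seed(21)
  recovered <- c(); false_frac <- c()
  for (rep in 1:5) {
    n <- 20
    ids <- sprintf("S%02d", 1:(2 * n))
    expr <- matrix(rnorm(1000 * 2 * n), 1000, 2 * n,
                   dimnames = list(sprintf("G%04d", 1:1000), ids))
    expr[1:50, (n + 1):(2 * n)] <- expr[1:50, (n + 1):(2 * n)] + 2.0
    grouping <- structure(
      tibble::tibble(sample_id = ids,
                     group = factor(rep(c("low", "high"), each = n),
                                    levels = c("low", "intermediate", "high"))),
      class = c("rppasig_grouping", class(tibble::tibble())),
      protein_id = "PLANT"
    )
    mg <- derive_metagene(expr, grouping)
    hits <- intersect(mg$members$gene_id, sprintf("G%04d", 1:50))
    expect_true(all(mg$members$coefficient[mg$members$gene_id %in% hits] == 1L))
    recovered <- c(recovered, length(hits))
    false_frac <- c(false_frac, (nrow(mg$members) - length(hits)) / nrow(mg$members))
  }
  expect_gte(mean(recovered), 45)
  expect_lte(mean(false_frac), 0.10)
})

test_that("a gene duplicating the protein is a member with coefficient +1", {
  set.seed(33)
  prot <- setNames(rnorm(40), sprintf("S%02d", 1:40))
  grouping <- assign_groups(prot, "PX")
  expr <- matrix(rnorm(20 * 40), 20, 40,
                 dimnames = list(sprintf("G%02d", 1:20), names(prot)))
  expr["G01", ] <- prot
  mg <- derive_metagene(expr, grouping)
  expect_true("G01" %in% mg$members$gene_id)
  expect_equal(mg$members$coefficient[mg$members$gene_id == "G01"], 1L)
})

test_that("negating the protein swaps groups and flips every coefficient", {
  set.seed(5)
  cohort <- generate_cohort(sim_config(n_proteins = 2, n_informative_proteins = 1,
                                       n_genes_total = 300, genes_per_metagene = 30),
                            seed = 5)
  prot <- cohort$rppa["P01", ]
  g_pos <- assign_groups(prot, "P01")
  g_neg <- assign_groups(-prot, "P01")
  expect_setequal(g_pos$sample_id[g_pos$group == "low"],
                  g_neg$sample_id[g_neg$group == "high"])
  mg_pos <- derive_metagene(cohort$expr, g_pos)
  mg_neg <- derive_metagene(cohort$expr, g_neg)
  expect_setequal(mg_pos$members$gene_id, mg_neg$members$gene_id)
  m <- match(mg_pos$members$gene_id, mg_neg$members$gene_id)
  expect_equal(mg_neg$members$coefficient[m], -mg_pos$members$coefficient)
})

test_that("members are a subset of measured genes with coefficients in {-1, +1}", {
  cohort <- generate_cohort(sim_config(n_genes_total = 500, n_proteins = 4,
                                       n_informative_proteins = 2,
                                       genes_per_metagene = 25), seed = 8)
  mgs <- suppressWarnings(derive_metagenes(cohort$expr, cohort$rppa))
  expect_gt(length(mgs), 0)
  for (mg in mgs) {
    expect_true(all(mg$members$gene_id %in% rownames(cohort$expr)))
    expect_true(all(mg$members$coefficient %in% c(-1L, 1L)))
    expect_true(all(mg$members$q <= 0.05))
  }
})

test_that("pure-noise proteins rarely deliver a metagene", {
  set.seed(77)
  nonempty <- 0L
  reps <- 60
  for (i in seq_len(reps)) {
    ids <- sprintf("S%02d", 1:80)
    expr <- matrix(rnorm(1000 * 80), 1000, 80,
                   dimnames = list(sprintf("G%04d", 1:1000), ids))
    prot <- setNames(rnorm(80), ids)
    mg <- derive_metagene(expr, assign_groups(prot, "NULLP"))
    if (!is.null(mg)) nonempty <- nonempty + 1L
  }
  # under the global null, any-discovery probability is ~alpha (Simes)
  expect_lte(nonempty / reps, 0.12)
})

test_that("metagene serialisation writes the TSV, JSON sidecar and GMT sets", {
  mg <- metagene("MG1", tibble::tibble(gene_id = c("A", "B", "C"),
                                       coefficient = c(1L, -1L, 1L)))
  dir <- withr::local_tempdir()
  write_metagene(mg, file.path(dir, "MG1.tsv"))
  back <- readr::read_tsv(file.path(dir, "MG1.tsv"), show_col_types = FALSE)
  expect_equal(back$gene_id, c("A", "B", "C"))
  expect_equal(back$coefficient, c(1, -1, 1))
  side <- jsonlite::read_json(file.path(dir, "MG1.json"))
  expect_equal(side$name, "MG1")

  write_metagenes_gmt(list(mg), file.path(dir, "mg.gmt"))
  sets <- read_gmt(file.path(dir, "mg.gmt"))
  expect_equal(sets$MG1_UP, c("A", "C"))
  expect_equal(sets$MG1_DN, "B")
})
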