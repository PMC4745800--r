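sim_surv_clinical <- function(n, log_hr_treat = 0, score = NULL,
                              log_hr_score = 0, log_hr_inter = 0,
                              censor_rate = 0.3, baseline = 0.05) {
  arm <- sample(rep(c("control", "treated"), length.out = n))
  if (is.null(score)) score <- rep(0, n)
  h <- baseline * exp((arm == "treated") * log_hr_treat +
                        score * log_hr_score +
                        (arm == "treated") * score * log_hr_inter)
  t_ev <- rexp(n, h)
  t_c <- if (censor_rate > 0) rexp(n, baseline * censor_rate / (1 - censor_rate)) else Inf
  tibble::tibble(
    sample_id = sprintf("S%04d", 1:n),
    time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c),
    arm = factor(arm, levels = c("control", "treated")),
    score = score
  )
}

test_that("median dichotomisation uses the inclusive-low tie rule", {
  s <- setNames(c(1, 2, 3, 4), paste0("s", 1:4))
  d <- dichotomize_at_median(s)
  expect_setequal(d$sample_id[d$group == "low"], c("s1", "s2"))
  expect_setequal(d$sample_id[d$group == "high"], c("s3", "s4"))

  odd <- setNames(c(1, 2, 3), paste0("s", 1:3))
  d2 <- dichotomize_at_median(odd)
  expect_equal(as.character(d2$group[d2$sample_id == "s2"]), "low")

  tied <- setNames(c(1, 2, 2, 2, 2, 2, 2, 3, 4, 5), paste0("s", 1:10))
  d3 <- dichotomize_at_median(tied)
  expect_true(all(d3$group[tied == 2] == "low"))

  expect_error(dichotomize_at_median(setNames(rep(1, 5), paste0("s", 1:5))),
               "constant")
})

test_that("Cox fit recovers a known treatment hazard ratio", {
  set.seed(41)
  clin <- sim_surv_clinical(2000, log_hr_treat = log(0.5), censor_rate = 0.3)
  res <- cox_treatment_hr(clin)
  expect_gte(res$hr, 0.44)
  expect_lte(res$hr, 0.57)
  expect_true(res$ci_lo < res$hr && res$hr < res$ci_hi)
  expect_true(res$converged)
})

test_that("Cox fit errors without events and flags monotone likelihood", {
  set.seed(43)
  clin <- sim_surv_clinical(50)
  clin$event <- 0L
  expect_error(cox_treatment_hr(clin), "events")

  # all events in one arm, none in the other -> runaway coefficient
  sep <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:40),
    time = c(rexp(20, 1), rep(10, 20)),
    event = c(rep(1L, 20), rep(0L, 20)),
    arm = factor(rep(c("treated", "control"), each = 20),
                 levels = c("control", "treated"))
  )
  res <- cox_treatment_hr(sep)
  expect_false(res$converged)
  expect_equal(res$ci_hi, Inf)
})

test_that("relabelling the arms inverts the hazard ratio and keeps the interaction p", {
  set.seed(47)
  sc <- rnorm(300)
  clin <- sim_surv_clinical(300, log_hr_treat = log(0.6), score = sc,
                            log_hr_inter = 0.5)
  flipped <- clin
  flipped$arm <- factor(ifelse(clin$arm == "treated", "control", "treated"),
                        levels = c("control", "treated"))
  hr1 <- cox_treatment_hr(clin)
  hr2 <- cox_treatment_hr(flipped)
  expect_equal(hr2$hr, 1 / hr1$hr, tolerance = 1e-6)

  scores <- setNames(clin$score, clin$sample_id)
  p1 <- interaction_test(clin, scores)
  p2 <- interaction_test(flipped, scores)
  expect_equal(p1$p_interaction, p2$p_interaction, tolerance = 1e-6)
})

test_that("the interaction Wald test detects a planted benefit modifier", {
  set.seed(53)
  hits <- 0L
  for (i in 1:30) {
    sc <- rnorm(400)
    clin <- sim_surv_clinical(400, score = sc, log_hr_inter = 0.7)
    p <- interaction_test(clin, setNames(sc, clin$sample_id))$p_interaction
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 30, 0.6)

  clin <- sim_surv_clinical(100)
  expect_error(interaction_test(clin, setNames(rep(2, 100), clin$sample_id)),
               "constant")
})

test_that("scaling scores leaves the dichotomous screen and continuous p unchanged", {
  set.seed(59)
  sc <- rnorm(300)
  clin <- sim_surv_clinical(300, score = sc, log_hr_inter = 0.6)
  scores <- setNames(sc, clin$sample_id)
  d1 <- dichotomize_at_median(scores)
  d2 <- dichotomize_at_median(scores * 7.3)
  expect_identical(d1, d2)
  p1 <- interaction_test(clin, scores)
  p2 <- interaction_test(clin, scores * 7.3)
  expect_equal(p1$p_interaction, p2$p_interaction, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(p1$log_hr_interaction, p2$log_hr_interaction)))
})

test_that("KM curves and log-rank behave at the two extremes", {
  set.seed(61)
  base <- tibble::tibble(
    sample_id = sprintf("A%02d", 1:30), time = rexp(30, 0.1),
    event = rbinom(30, 1, 0.7),
    arm = factor(rep(c("control", "treated"), 15),
                 levels = c("control", "treated"))
  )
  dup <- base
  dup$sample_id <- sprintf("B%02d", 1:30)
  both <- dplyr::bind_rows(base, dup)
  groups <- tibble::tibble(sample_id = both$sample_id,
                           group = rep(c("g1", "g2"), each = 30))
  km <- km_logrank(both, groups)
  expect_lt(km$chisq, 1e-10)
  expect_gt(km$p, 0.99)
  expect_equal(sort(unique(km$curves$group)), c("g1", "g2"))

  # complete separation, no censoring
  sep <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:100),
    time = c(runif(50, 0, 1), runif(50, 10, 11)),
    event = 1L,
    arm = factor(rep(c("control", "treated"), 50),
                 levels = c("control", "treated"))
  )
  g <- tibble::tibble(sample_id = sep$sample_id,
                      group = rep(c("early", "late"), each = 50))
  expect_lt(km_logrank(sep, g)$p, 1e-10)

  expect_error(km_logrank(base, tibble::tibble(sample_id = base$sample_id,
                                               group = "only")), "2 groups")
})

test_that("log-rank separates exponential groups with hazard ratio 2", {
  set.seed(67)
  sig <- 0L
  for (i in 1:20) {
    clin <- tibble::tibble(
      sample_id = sprintf("S%04d", 1:1000),
      time = c(rexp(500, 0.2), rexp(500, 0.1)),
      event = 1L,
      arm = factor(rep(c("control", "treated"), 500),
                   levels = c("control", "treated"))
    )
    g <- tibble::tibble(sample_id = clin$sample_id,
                        group = rep(c("fast", "slow"), each = 500))
    if (km_logrank(clin, g)$p < 0.001) sig <- sig + 1L
  }
  expect_gte(sig / 20, 0.95)
})

test_that("the screen flags empty cells, handles empty input, and ranks the planted modifier", {
  expect_equal(nrow(screen_metagenes(list(), toy_expr(), NULL)), 0L)

  set.seed(71)
  two <- generate_two_datasets(sim_config(), seed = 71)
  mgs <- two$truth$true_members
  scr <- screen_metagenes(mgs, two$validation$expr, two$validation$clinical)
  expect_true(all(scr$testable))
  expect_equal(scr$metagene[which.min(scr$q_interaction)],
               two$truth$interaction_protein)
  expect_true(all(scr$ci_lo_low <= scr$hr_low & scr$hr_low <= scr$ci_hi_low))

  # an all-treated cohort has an empty stratum x arm cell after subsetting
  clin <- two$validation$clinical
  clin$arm[] <- "treated"
  scr2 <- screen_metagenes(mgs[1], two$validation$expr, clin)
  expect_equal(nrow(scr2), 1L)
  expect_false(scr2$testable)
  expect_true(is.na(scr2$q_interaction))
})

test_that("null screens keep per-stratum hazard ratios near 1", {
  set.seed(73)
  cfg <- sim_config(survival = list(treatment_log_hr = 0,
                                    interaction_log_hr_per_sd = 0))
  two <- generate_two_datasets(cfg, seed = 73)
  scr <- screen_metagenes(two$truth$true_members, two$validation$expr,
                          two$validation$clinical)
  hrs <- c(scr$hr_low, scr$hr_high)
  expect_lt(abs(mean(log(hrs))), 0.25)
})
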