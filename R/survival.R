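#' Dichotomise scores at the median
#'
#' Splits samples into `low` (score at or below the median) and `high`
#' (above) strata; the median uses the package's interpolation convention
#' (type 7), so samples tied at the median fall in `low`.
#'
#' @param scores A `rppasig_scores` tibble (or any data frame with
#'   `sample_id` and `score`), or a named numeric vector.
#' @return A tibble with columns `sample_id` and `group` (factor
#'   low/high).
#' @export
dichotomize_at_median <- function(scores) {
  s <- as_score_vector(scores)
  if (length(unique(s)) < 2L) abort("scores are constant; median split is undefined")
  m <- .quantile(s, 0.5)
  tibble(
    sample_id = names(s),
    group = factor(ifelse(s <= m, "low", "high"), levels = c("low", "high"))
  )
}

as_score_vector <- function(scores) {
  if (is.data.frame(scores)) {
    stopifnot(all(c("sample_id", "score") %in% names(scores)))
    setNames(scores$score, scores$sample_id)
  } else {
    stopifnot(is.numeric(scores), !is.null(names(scores)))
    scores
  }
}

# Right-censored response + design checks shared by the Cox helpers.
cox_prepare <- function(clinical, covariates) {
  clinical <- validate_clinical(as_tibble(clinical))
  miss <- setdiff(covariates, names(clinical))
  if (length(miss)) abort(sprintf("covariate(s) absent from clinical table: %s",
                                  paste(miss, collapse = ", ")))
  if (sum(clinical$event) == 0) abort("no events in the data; Cox model undefined")
  if (dplyr::n_distinct(clinical$arm) < 2L) abort("both treatment arms must be present")
  clinical
}

cox_formula <- function(terms) {
  as.formula(paste("survival::Surv(time, event) ~", paste(terms, collapse = " + ")))
}

# Wald summary for one coefficient of a coxph fit, with a monotone-
# likelihood sentinel: runaway coefficients get an infinite CI and
# converged = FALSE instead of an exception.
cox_wald <- function(fit, term, conf_level = 0.95) {
  beta <- coef(fit)[term]
  se <- sqrt(diag(vcov(fit)))[term]
  z <- qnorm(1 - (1 - conf_level) / 2)
  diverged <- !is.finite(beta) || !is.finite(se) || abs(beta) > 15 || se > 100
  if (diverged) {
    return(tibble(hr = exp(unname(beta)), ci_lo = 0, ci_hi = Inf,
                  p = NA_real_, converged = FALSE))
  }
  tibble(hr = exp(unname(beta)),
         ci_lo = exp(unname(beta - z * se)),
         ci_hi = exp(unname(beta + z * se)),
         p = 2 * stats::pnorm(-abs(unname(beta / se))),
         converged = TRUE)
}

#' Treatment hazard ratio from a Cox proportional-hazards fit
#'
#' Fits `Surv(time, event) ~ arm + covariates` by partial-likelihood
#' maximisation with Efron tie handling and reports the treated-vs-control
#' hazard ratio with its Wald confidence interval and p-value. Monotone
#' likelihood (e.g. no events in one arm) yields a flagged result with an
#' infinite confidence interval rather than an error.
#'
#' @param clinical Clinical tibble with `sample_id`, `time`, `event`,
#'   `arm` and any covariate columns.
#' @param covariates Character vector of covariate column names
#'   (default none: univariate model).
#' @param conf_level Confidence level for the Wald interval.
#' @return One-row tibble: `hr`, `ci_lo`, `ci_hi`, `p`, `n`, `n_events`,
#'   `converged`.
#' @export
cox_treatment_hr <- function(clinical, covariates = character(), conf_level = 0.95) {
  clinical <- cox_prepare(clinical, covariates)
  fit <- suppressWarnings(
    survival::coxph(cox_formula(c("arm", covariates)), data = clinical,
                    ties = "efron")
  )
  res <- cox_wald(fit, "armtreated", conf_level)
  dplyr::bind_cols(res, tibble(n = nrow(clinical), n_events = sum(clinical$event)))[
    , c("hr", "ci_lo", "ci_hi", "p", "n", "n_events", "converged")]
}

#' Wald test for a treatment-by-score interaction
#'
#' Adds a treatment main effect, a score main effect and their product to
#' a Cox model (`~ arm * score + covariates`) and returns the Wald
#' p-value of the product term — the test of whether the score modifies
#' treatment benefit. The score may be continuous (a `rppasig_scores`
#' tibble or named vector) or a dichotomous low/high partition from
#' [dichotomize_at_median()] (coded 0 = low, 1 = high).
#'
#' @inheritParams cox_treatment_hr
#' @param scores Continuous scores or a low/high partition covering the
#'   clinical samples.
#' @return One-row tibble: `p_interaction`, `log_hr_interaction`, `se`,
#'   `converged`.
#' @export
interaction_test <- function(clinical, scores, covariates = character()) {
  clinical <- cox_prepare(clinical, covariates)
  s <- interaction_score(scores, clinical$sample_id)
  if (length(unique(s)) < 2L) abort("score is constant; interaction is undefined")
  clinical$.score <- s
  fit <- suppressWarnings(
    survival::coxph(cox_formula(c("arm * .score", covariates)), data = clinical,
                    ties = "efron")
  )
  term <- "armtreated:.score"
  beta <- coef(fit)[term]
  se <- sqrt(diag(vcov(fit)))[term]
  diverged <- !is.finite(beta) || !is.finite(se) || abs(beta) > 15 || se > 100
  tibble(
    p_interaction = if (diverged) NA_real_ else 2 * stats::pnorm(-abs(unname(beta / se))),
    log_hr_interaction = unname(beta),
    se = unname(se),
    converged = !diverged
  )
}

interaction_score <- function(scores, sample_ids) {
  if (is.data.frame(scores) && "group" %in% names(scores)) {
    v <- setNames(as.integer(scores$group == "high"), scores$sample_id)
  } else {
    v <- as_score_vector(scores)
  }
  if (!all(sample_ids %in% names(v))) {
    abort("scores missing for some clinical samples")
  }
  unname(v[sample_ids])
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Product-limit survival estimates per group plus the log-rank test of
#' equality of the survival distributions.
#'
#' @param clinical Clinical tibble (see [cox_treatment_hr()]).
#' @param groups Tibble with `sample_id` and `group` covering the
#'   clinical samples (at least two non-empty groups).
#' @return An object of class `rppasig_km`: list with `curves` (tibble
#'   `group`, `time`, `n_risk`, `n_event`, `surv`), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(clinical, groups) {
  clinical <- validate_clinical(as_tibble(clinical))
  stopifnot(all(c("sample_id", "group") %in% names(groups)))
  clinical$.group <- factor(groups$group[match(clinical$sample_id, groups$sample_id)])
  if (anyNA(clinical$.group)) abort("groups missing for some clinical samples")
  if (dplyr::n_distinct(clinical$.group) < 2L) abort("need at least 2 groups")
  sf <- survival::survfit(survival::Surv(time, event) ~ .group, data = clinical)
  strata_names <- sub("^\\.group=", "", rep(names(sf$strata), sf$strata))
  curves <- tibble(group = strata_names, time = sf$time, n_risk = sf$n.risk,
                   n_event = sf$n.event, surv = sf$surv)
  sd <- survival::survdiff(survival::Surv(time, event) ~ .group, data = clinical)
  df <- length(sd$n) - 1L
  structure(list(curves = curves, chisq = unname(sd$chisq), df = df,
                 p = pchisq(sd$chisq, df, lower.tail = FALSE)),
            class = "rppasig_km")
}

#' @export
print.rppasig_km <- function(x, ...) {
  cat(sprintf("<rppasig_km> %d groups; log-rank chi-square = %.3f (df = %d), p = %.3g\n",
              length(unique(x$curves$group)), x$chisq, x$df, x$p))
  invisible(x)
}

#' Screen metagenes for treatment-benefit modification
#'
#' For each metagene: scores the expression dataset, dichotomises the
#' score at the median, fits the treatment hazard ratio separately within
#' the score-low and score-high strata (multivariate if covariates are
#' given), and tests the treatment-by-score interaction both with the
#' dichotomous stratum indicator and with the continuous score. The
#' dichotomous interaction p-values are Benjamini-Hochberg adjusted
#' across all testable metagenes (`q_interaction`). A metagene with an
#' empty stratum-by-arm cell is flagged untestable.
#'
#' @param metagenes List of `rppasig_metagene` objects (typically the
#'   validated ones). May be empty, giving an empty result.
#' @param expr Expression matrix covering the clinical samples.
#' @param clinical Clinical tibble (see [cox_treatment_hr()]).
#' @param covariates Covariate column names for the multivariate models.
#' @param min_coverage Passed to [sigscore()].
#' @return A tibble (class `rppasig_screen`), one row per metagene:
#'   per-stratum hazard ratios with CIs and p-values, `p_interaction`
#'   (dichotomous), `p_interaction_continuous`, `q_interaction`, the four
#'   stratum-by-arm cell counts and `testable`.
#' @export
screen_metagenes <- function(metagenes, expr, clinical,
                             covariates = character(), min_coverage = 0.5) {
  empty <- tibble(
    metagene = character(), hr_low = numeric(), ci_lo_low = numeric(),
    ci_hi_low = numeric(), p_low = numeric(), hr_high = numeric(),
    ci_lo_high = numeric(), ci_hi_high = numeric(), p_high = numeric(),
    p_interaction = numeric(), p_interaction_continuous = numeric(),
    n_low_control = integer(), n_low_treated = integer(),
    n_high_control = integer(), n_high_treated = integer(),
    testable = logical(), q_interaction = numeric()
  )
  if (length(metagenes) == 0L) {
    class(empty) <- c("rppasig_screen", class(tibble()))
    return(empty)
  }
  clinical <- validate_clinical(as_tibble(clinical))
  shared <- intersect(clinical$sample_id, colnames(expr))
  clinical <- clinical[clinical$sample_id %in% shared, ]
  expr <- expr[, clinical$sample_id, drop = FALSE]

  rows <- purrr::map(metagenes, function(mg) {
    sc <- sigscore(mg, expr, min_coverage = min_coverage)
    strata <- dichotomize_at_median(sc)
    dat <- dplyr::left_join(clinical, strata, by = "sample_id")
    cells <- table(dat$group, dat$arm)
    out <- tibble(
      metagene = mg$name, hr_low = NA_real_, ci_lo_low = NA_real_,
      ci_hi_low = NA_real_, p_low = NA_real_, hr_high = NA_real_,
      ci_lo_high = NA_real_, ci_hi_high = NA_real_, p_high = NA_real_,
      p_interaction = NA_real_, p_interaction_continuous = NA_real_,
      n_low_control = cells["low", "control"],
      n_low_treated = cells["low", "treated"],
      n_high_control = cells["high", "control"],
      n_high_treated = cells["high", "treated"],
      testable = FALSE
    )
    if (any(cells == 0L)) return(out)
    strat_fit <- function(g) {
      tryCatch(cox_treatment_hr(dat[dat$group == g, ], covariates),
               error = function(e) NULL)
    }
    lo <- strat_fit("low"); hi <- strat_fit("high")
    if (is.null(lo) || is.null(hi)) return(out)
    pi_d <- tryCatch(interaction_test(dat, strata, covariates),
                     error = function(e) NULL)
    pi_c <- tryCatch(interaction_test(dat, sc, covariates),
                     error = function(e) NULL)
    if (is.null(pi_d) || is.null(pi_c) || !pi_d$converged) return(out)
    out$hr_low <- lo$hr; out$ci_lo_low <- lo$ci_lo; out$ci_hi_low <- lo$ci_hi
    out$p_low <- lo$p
    out$hr_high <- hi$hr; out$ci_lo_high <- hi$ci_lo; out$ci_hi_high <- hi$ci_hi
    out$p_high <- hi$p
    out$p_interaction <- pi_d$p_interaction
    out$p_interaction_continuous <- pi_c$p_interaction
    out$testable <- TRUE
    out
  })
  res <- dplyr::bind_rows(rows)
  res$q_interaction <- NA_real_
  if (any(res$testable)) {
    res$q_interaction[res$testable] <- bh_adjust(res$p_interaction[res$testable])
  }
  class(res) <- c("rppasig_screen", class(tibble()))
  res
}
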