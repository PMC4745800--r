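#' Tidy a metagene into its member table
#'
#' @param x A `rppasig_metagene`.
#' @param ... Unused.
#' @return Tibble of member genes with coefficients and, when derived
#'   from data, per-gene statistics.
#' @method tidy rppasig_metagene
#' @export
tidy.rppasig_metagene <- function(x, ...) {
  dplyr::mutate(x$members, metagene = x$name, .before = 1L)
}

#' One-row summary of a metagene
#'
#' @inheritParams tidy.rppasig_metagene
#' @return Tibble with member counts and the derivation group sizes.
#' @method glance rppasig_metagene
#' @export
glance.rppasig_metagene <- function(x, ...) {
  tibble(
    metagene = x$name,
    n_members = nrow(x$members),
    n_up = sum(x$members$coefficient == 1L),
    n_down = sum(x$members$coefficient == -1L),
    n_low = x$n_low,
    n_high = x$n_high
  )
}

#' Tidy a metagene network into its edge table
#'
#' @param x A `rppasig_network`.
#' @param ... Unused.
#' @method tidy rppasig_network
#' @export
tidy.rppasig_network <- function(x, ...) x$edges

#' One-row summary of a metagene network
#'
#' @inheritParams tidy.rppasig_network
#' @method glance rppasig_network
#' @export
glance.rppasig_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_pairs_tested = nrow(x$tests),
         n_clusters = dplyr::n_distinct(x$nodes$cluster, na.rm = TRUE))
}

#' Tidy Kaplan-Meier curves into step coordinates
#'
#' @param x A `rppasig_km`.
#' @param ... Unused.
#' @method tidy rppasig_km
#' @export
tidy.rppasig_km <- function(x, ...) x$curves

#' One-row log-rank summary
#'
#' @inheritParams tidy.rppasig_km
#' @method glance rppasig_km
#' @export
glance.rppasig_km <- function(x, ...) {
  tibble(chisq = x$chisq, df = x$df, p.value = x$p)
}

#' Plot Kaplan-Meier curves
#'
#' @param object A `rppasig_km`.
#' @param ... Unused.
#' @return A ggplot object of per-group survival step curves.
#' @method autoplot rppasig_km
#' @export
autoplot.rppasig_km <- function(object, ...) {
  curves <- dplyr::bind_rows(
    dplyr::reframe(dplyr::group_by(object$curves, .data$group),
                   time = c(0, .data$time), surv = c(1, .data$surv)),
  )
  ggplot2::ggplot(curves, ggplot2::aes(.data$time, .data$surv,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "Time (months)", y = "Survival probability", colour = NULL,
      subtitle = sprintf("log-rank p = %.3g", object$p)
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Forest plot of the treatment-benefit screen
#'
#' Per-stratum treatment hazard ratios (log scale) with 95% confidence
#' intervals for each screened metagene; the dashed line marks no effect.
#'
#' @param object A `rppasig_screen` tibble.
#' @param ... Unused.
#' @method autoplot rppasig_screen
#' @export
autoplot.rppasig_screen <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::filter(object, .data$testable),
    cols = c("hr_low", "hr_high", "ci_lo_low", "ci_hi_low",
             "ci_lo_high", "ci_hi_high"),
    names_to = "key", values_to = "value"
  )
  long$stratum <- ifelse(grepl("high$", long$key), "score high", "score low")
  long$what <- sub("_(low|high)$", "", long$key)
  wide <- tidyr::pivot_wider(
    long[, c("metagene", "stratum", "what", "value")],
    names_from = "what", values_from = "value"
  )
  ggplot2::ggplot(wide, ggplot2::aes(.data$hr, .data$metagene,
                                     colour = .data$stratum)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
      height = 0.2, position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Treatment hazard ratio (95% CI)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Validation scatter of the two external gates
#'
#' Pearson correlation against ROC AUC for every testable metagene, with
#' the pass/fail outcome of the two-gate rule.
#'
#' @param object A `rppasig_validation` tibble.
#' @param r_threshold Pearson gate drawn as a reference line.
#' @param ... Unused.
#' @method autoplot rppasig_validation
#' @export
autoplot.rppasig_validation <- function(object, r_threshold = 0.5, ...) {
  dat <- dplyr::filter(object, .data$testable)
  ggplot2::ggplot(dat, ggplot2::aes(.data$pearson_r, .data$auc,
                                    colour = .data$passed)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = r_threshold, linetype = "dashed") +
    ggplot2::labs(x = "Pearson r (score vs protein level)",
                  y = "ROC AUC (high vs low protein group)",
                  colour = "passed") +
    ggplot2::theme_minimal()
}
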