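#' Hallucination rate against complexity, per population
#'
#' Observed mean HR of each trained generator against the variant's
#' complexity, one panel per generator family, coloured by population — the
#' standard view of the complexity-to-HR relationship.
#'
#' @param experiment An `sdg_experiment` (or its `results` tibble).
#' @return A ggplot object.
#' @export
plot_hr_complexity <- function(experiment) {
  results <- if (inherits(experiment, "sdg_experiment")) {
    experiment$results
  } else experiment
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$complexity, y = .data$mean_hr,
                               colour = .data$population)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "glm", formula = y ~ x, se = FALSE,
                         method.args = list(family = stats::quasibinomial())) +
    ggplot2::facet_wrap(~generator) +
    ggplot2::labs(x = "complexity (log sum of cardinalities)",
                  y = "mean hallucination rate") +
    ggplot2::theme_minimal()
}

#' TSTR AUROC against hallucination rate, per population
#'
#' @param experiment An `sdg_experiment`.
#' @param learner Learner whose TSTR to plot.
#' @return A ggplot object.
#' @export
plot_tstr_hr <- function(experiment, learner = "gbm") {
  results <- if (inherits(experiment, "sdg_experiment")) {
    experiment$results
  } else experiment
  ycol <- paste0("tstr_", learner)
  trtr_col <- paste0("trtr_", learner)
  p <- ggplot2::ggplot(results,
                       ggplot2::aes(x = 100 * .data$mean_hr,
                                    y = .data[[ycol]],
                                    colour = .data$population)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(~generator) +
    ggplot2::labs(x = "hallucination rate (%)",
                  y = sprintf("TSTR AUROC (%s)", learner)) +
    ggplot2::theme_minimal()
  if (trtr_col %in% names(results)) {
    p <- p + ggplot2::geom_hline(
      ggplot2::aes(yintercept = .data[[trtr_col]], colour = .data$population),
      data = distinct(results, .data$population, .data[[trtr_col]]),
      linetype = "dashed", alpha = 0.6)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.sdg_experiment <- function(object, type = c("hr", "tstr"),
                                    learner = "gbm", ...) {
  type <- match.arg(type)
  if (type == "hr") plot_hr_complexity(object) else
    plot_tstr_hr(object, learner = learner)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
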