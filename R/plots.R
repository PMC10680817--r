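#' Plot a mean-field synchrony distribution
#'
#' @param object A `synchrony_pmf` from [synchrony_pmf()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot synchrony_pmf
#' @export
autoplot.synchrony_pmf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s, y = .data$prob)) +
    ggplot2::geom_col(width = 1.6 / attr(object, "n_eff"),
                      fill = "steelblue") +
    ggplot2::labs(
      x = "synchrony s", y = "P(s)",
      title = sprintf("Mean-field synchrony pmf (n_eff = %d, lambda = %.3g)",
                      attr(object, "n_eff"), attr(object, "lambda"))
    ) +
    ggplot2::theme_minimal()
}

#' Overlay an empirical synchrony histogram with a fitted model
#'
#' @param s Empirical synchrony vector.
#' @param model A [meanfield_model()] fitted to the subject.
#' @return A ggplot: the empirical distribution of synchrony (binned to the
#'   model's parity grid resolution) with the model pmf on top.
#' @export
plot_synchrony_fit <- function(s, model) {
  stopifnot(inherits(model, "meanfield_model"))
  d <- synchrony_pmf(model$n_eff, model$lambda)
  emp <- tibble::tibble(s = as.numeric(s))
  ggplot2::ggplot(emp, ggplot2::aes(x = .data$s)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(.data$density)),
      binwidth = 2 / model$n_eff, fill = "grey70", colour = "white"
    ) +
    ggplot2::geom_line(
      data = d,
      ggplot2::aes(x = .data$s, y = .data$prob * model$n_eff / 2),
      colour = "darkorange", linewidth = 1
    ) +
    ggplot2::labs(x = "synchrony s", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot an age trend of segregation
#'
#' Subjects would overplot badly at cohort scale, so the display follows
#' the binned summary: median per 5-year bin with standard-error bars.
#'
#' @param object An `age_trend` from [age_trend()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot age_trend
#' @export
autoplot.age_trend <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$age_mid, y = .data$median)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$median - .data$se,
                   ymax = .data$median + .data$se)
    ) +
    ggplot2::labs(
      x = "age (years)", y = paste("median", object$outcome),
      title = sprintf("Spearman rho = %.2f (p = %.2g), n = %d",
                      object$spearman_rho, object$p_value, object$n_included)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an edge-removal trajectory
#'
#' Pseg against average degree, mirroring how degradation experiments are
#' read: degree falls left along the x axis as edges are removed.
#'
#' @param object A `removal_trajectory` from [edge_removal_experiment()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot removal_trajectory
#' @export
autoplot.removal_trajectory <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$avg_degree, y = .data$pseg)) +
    ggplot2::geom_point(colour = "darkorange") +
    ggplot2::labs(
      x = "average degree", y = "Pseg",
      title = sprintf("Spearman rho = %.2f", object$spearman_rho)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an effective-region-count scan
#'
#' @param object A `neff_scan` from [select_neff()].
#' @param ... Unused.
#' @return A ggplot of the scan objective with the argmin highlighted.
#' @method autoplot neff_scan
#' @export
autoplot.neff_scan <- function(object, ...) {
  ggplot2::ggplot(object$scan,
                  ggplot2::aes(x = .data$n_eff, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best, linetype = "dashed",
                        colour = "darkorange") +
    ggplot2::labs(x = "candidate n_eff", y = "fourth-moment error") +
    ggplot2::theme_minimal()
}
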