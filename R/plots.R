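# ggplot2 displays for the two result types.

#' Plot a probability-curve report
#'
#' Agreement and conditional extreme-agreement probabilities as a
#' function of ERS (one panel per substantive-trait level), and the
#' category-probability curves at substantive trait 0; solid versus
#' dashed lines contrast the nominal and IRTree families.
#'
#' @param object An `"ers_curves"` tibble from [curves_report()].
#' @param measure Which measure to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ers_curves <- function(object,
                                measure = c("agreement",
                                            "conditional_extreme",
                                            "category"),
                                ...) {
  measure <- match.arg(measure)
  df <- dplyr::filter(object, .data$measure == !!measure)
  if (measure == "category") {
    ggplot2::ggplot(df, ggplot2::aes(
      x = .data$theta2, y = .data$prob,
      colour = factor(.data$category), linetype = .data$model
    )) +
      ggplot2::geom_line() +
      ggplot2::labs(
        x = "ERS trait", y = "category probability",
        colour = "category", linetype = "model"
      ) +
      ggplot2::ylim(0, 1)
  } else {
    ggplot2::ggplot(df, ggplot2::aes(
      x = .data$theta2, y = .data$prob,
      colour = factor(.data$theta1), linetype = .data$model
    )) +
      ggplot2::geom_line() +
      ggplot2::labs(
        x = "ERS trait",
        y = if (measure == "agreement") {
          "P(agree)"
        } else {
          "P(extreme agree | extreme)"
        },
        colour = "substantive trait", linetype = "model"
      ) +
      ggplot2::ylim(0, 1)
  }
}

#' Plot a bias table
#'
#' Dot-and-whisker display of focal-group bias (points, with 3
#' Monte-Carlo-SE whiskers) per condition and estimator.
#'
#' @param object An `"ers_bias"` tibble from [bias_table()].
#' @param outcome `"var"` (substantive variance) or `"mu"` (mean).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ers_bias <- function(object, outcome = c("var", "mu"), ...) {
  outcome <- match.arg(outcome)
  bias_col <- paste0(outcome, "_bias")
  se_col <- paste0(outcome, "_mc_se")
  df <- dplyr::mutate(
    object,
    cell = paste0(.data$generator, " Δ=", .data$delta_ers,
                  " J=", .data$n_items, " ", .data$base)
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[bias_col]], y = .data$cell, colour = .data$estimator
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(
        xmin = .data[[bias_col]] - 3 * .data[[se_col]],
        xmax = .data[[bias_col]] + 3 * .data[[se_col]]
      ),
      height = 0.2, position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::labs(
      x = paste0(
        "bias in focal substantive ",
        if (outcome == "var") "variance" else "mean"
      ),
      y = NULL, colour = "estimator"
    )
}
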