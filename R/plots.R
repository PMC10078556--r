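#' Plot model predictions for the four conditions
#'
#' Dodged bars of the "not all" probability (in percent) by knowledgeability
#' and alternative availability — the shape of the model-prediction panel of
#' a 2x2 condition figure.
#'
#' @param object An `rsa_prediction_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(predict_condition_table(rsa_config(alpha = 3)))
#' @method autoplot rsa_prediction_table
#' @export
autoplot.rsa_prediction_table <- function(object, ...) {
  df <- tidy(object) |>
    mutate(knowledgeability = factor(.data$knowledgeability, c("partial", "full")),
           alternatives = factor(.data$alternatives, c("no_numerals", "with_numerals"),
                                 labels = c("no numerals", "with numerals")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$knowledgeability,
                                   y = 100 * .data$p_not_all,
                                   fill = .data$alternatives)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::labs(x = "speaker knowledgeability",
                  y = "P(not all | \"some\") [%]", fill = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' Plot a mixture/rationality sweep
#'
#' "Not all" probability as a function of the mixture weight on the
#' with-numerals alternative set, one line per rationality value, faceted by
#' knowledgeability.
#'
#' @param object An `rsa_sweep` from [rsa_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rsa_sweep
#' @export
autoplot.rsa_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$p_with_numerals,
                                       y = .data$p_not_all,
                                       colour = factor(.data$alpha))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~knowledgeability) +
    ggplot2::labs(x = "P(with-numerals alternative set)",
                  y = "P(not all | \"some\")", colour = "alpha") +
    ggplot2::theme_minimal()
}

#' Plot estimated effects with bootstrap intervals
#'
#' @param object An `rsa_fit` from [estimate_effects()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rsa_fit
#' @export
autoplot.rsa_fit <- function(object, ...) {
  df <- tidy(object) |> filter(.data$term != "intercept")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::labs(x = NULL, y = "effect on not-all rating (points)") +
    ggplot2::theme_minimal()
}

#' Plot a power curve
#'
#' @param object An `rsa_power` from [power_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rsa_power
#' @export
autoplot.rsa_power <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_participants, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(0, .data$power - .data$mc_se),
                                          ymax = pmin(1, .data$power + .data$mc_se))) +
    ggplot2::geom_hline(yintercept = 0.8, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "participants", y = "power (interaction CI excludes 0)") +
    ggplot2::theme_minimal()
}
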