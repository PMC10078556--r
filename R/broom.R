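#' Tidy an effect fit
#'
#' @param x An `rsa_fit` from [estimate_effects()].
#' @param ... Unused.
#' @return A tibble with one row per term: `term`, `estimate`, `se`,
#'   `conf.low`, `conf.high`.
#' @method tidy rsa_fit
#' @export
tidy.rsa_fit <- function(x, ...) {
  x$estimates
}

#' One-row summary of an effect fit
#'
#' @param x An `rsa_fit` from [estimate_effects()].
#' @param ... Unused.
#' @return A one-row tibble with `n_participants`, `n_boot`, `conf_level`,
#'   `missing_cells`.
#' @method glance rsa_fit
#' @export
glance.rsa_fit <- function(x, ...) {
  tibble(
    n_participants = x$n_participants,
    n_boot = x$n_boot,
    conf_level = x$conf_level,
    missing_cells = x$missing_cells
  )
}

#' Tidy a condition-prediction table
#'
#' @param x An `rsa_prediction_table` from [predict_condition_table()].
#' @param ... Unused.
#' @return The underlying tibble (`knowledgeability`, `alternatives`,
#'   `p_not_all`, `percent`).
#' @method tidy rsa_prediction_table
#' @export
tidy.rsa_prediction_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "rsa_prediction_table")
  attr(out, "config") <- NULL
  out
}
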