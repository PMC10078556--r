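#' Model configuration for the pragmatic listener
#'
#' Bundles the scenario size, the world prior, the speaker's softmax
#' rationality, the two access levels contrasted by the knowledgeability
#' manipulation, and the mixture weight the listener puts on the with-numerals
#' alternative set.
#'
#' @param N Number of objects in the scenario (default 3, as in the
#'   letters/checks scenarios).
#' @param prior `"uniform"`, a numeric weight vector of length `N + 1`, or a
#'   tibble from [world_prior()].
#' @param alpha Softmax rationality `alpha >= 0`. `alpha = 1` is the plain
#'   softmax speaker; `alpha = 0` is an indifferent speaker (uniform over
#'   assertable utterances); large `alpha` approaches utility maximization.
#' @param access_partial Objects examined in the partial-knowledge condition
#'   (default `N - 1`, i.e. "2 of the 3").
#' @param access_full Objects examined in the full-knowledge condition; must
#'   equal `N`.
#' @param p_with_numerals Probability the listener assigns to the speaker
#'   having the with-numerals alternative set (mixture weight in `[0, 1]`).
#'
#' @return A list of class `rsa_config`.
#' @examples
#' rsa_config(alpha = 3)
#' @export
rsa_config <- function(N = 3, prior = "uniform", alpha = 1,
                       access_partial = N - 1, access_full = N,
                       p_with_numerals = 0) {
  N <- assert_count(N, "N", min = 1L)
  prior <- as_world_prior(prior, N)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0 ||
      !is.finite(alpha)) {
    abort("`alpha` must be a single finite number >= 0.",
          class = "altrsa_validation_error")
  }
  access_partial <- assert_count(access_partial, "access_partial", min = 1L)
  access_full <- assert_count(access_full, "access_full", min = 1L)
  if (access_full != N) {
    abort(sprintf("`access_full` must equal N = %d.", N),
          class = "altrsa_validation_error")
  }
  if (access_partial >= access_full) {
    abort("`access_partial` must be smaller than `access_full`.",
          class = "altrsa_validation_error")
  }
  p_with_numerals <- assert_prob(p_with_numerals, "p_with_numerals")
  structure(
    list(N = N, prior = prior, alpha = as.numeric(alpha),
         access_partial = access_partial, access_full = access_full,
         p_with_numerals = p_with_numerals),
    class = "rsa_config"
  )
}

#' @export
print.rsa_config <- function(x, ...) {
  cat(sprintf("<rsa_config> N = %d, alpha = %g, access %d (partial) vs %d (full), P(with numerals) = %g\n",
              x$N, x$alpha, x$access_partial, x$access_full, x$p_with_numerals))
  cat("prior over worlds 0..", x$N, ": ",
      paste(signif(x$prior$prob, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# plain-list snapshot for JSON output / manifests
config_as_list <- function(config) {
  list(
    N = config$N,
    prior = config$prior$prob,
    alpha = config$alpha,
    access_partial = config$access_partial,
    access_full = config$access_full,
    p_with_numerals = config$p_with_numerals
  )
}
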