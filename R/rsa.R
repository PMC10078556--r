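#' Literal listener
#'
#' Interprets an utterance by restricting the world prior to the utterance's
#' literal meaning and renormalizing. Worlds outside the meaning get
#' probability exactly 0.
#'
#' @param prior A world prior tibble from [world_prior()] (columns `world`,
#'   `prob`).
#' @param utt An [utterance()], or an integer vector of world counts taken as
#'   the literal meaning.
#' @return A tibble with columns `world` and `prob`, summing to 1.
#' @examples
#' literal_listener(world_prior(3), utterance("some", 1:3))
#' @export
literal_listener <- function(prior, utt) {
  prior <- as_world_prior(prior)
  meaning <- if (inherits(utt, "rsa_utterance")) utt$meaning else sort(unique(as.integer(utt)))
  label <- if (inherits(utt, "rsa_utterance")) utt$label else paste(meaning, collapse = ",")
  inside <- prior$world %in% meaning
  total <- sum(prior$prob[inside])
  if (total <= 0) {
    abort(sprintf("uninterpretable utterance '%s': its meaning has no prior mass.", label),
          class = "altrsa_uninterpretable_utterance")
  }
  tibble(world = prior$world, prob = ifelse(inside, prior$prob / total, 0))
}

#' Hypergeometric observation model
#'
#' When the speaker examines `access` of the `N` objects uniformly at random
#' without replacement in world `world`, the number of property-bearing
#' objects they observe is hypergeometric. This is the sampling law linking
#' worlds to the speaker's partial observations.
#'
#' @param N Number of objects in the scenario.
#' @param world True number of property-bearing objects (`0..N`).
#' @param access Number of objects examined (`1..N`).
#' @return A tibble with columns `observed` and `prob` over the support
#'   `max(0, world - (N - access)) .. min(access, world)`; probabilities sum
#'   to 1.
#' @examples
#' observation_model(3, world = 1, access = 2)
#' @export
observation_model <- function(N, world, access) {
  N <- assert_count(N, "N", min = 1L)
  world <- assert_count(world, "world", min = 0L)
  access <- assert_count(access, "access", min = 1L)
  if (world > N || access > N) {
    abort("`world` and `access` must be at most N.",
          class = "altrsa_validation_error")
  }
  lo <- max(0L, world - (N - access))
  hi <- min(access, world)
  obs <- lo:hi
  tibble(observed = obs, prob = dhyper(obs, world, N - world, access))
}

#' Speaker knowledge state
#'
#' The speaker has examined `access` of the `N` objects and seen `observed`
#' of them with the property. The worlds compatible with that observation are
#' `observed .. observed + (N - access)`; the speaker's belief over them is
#' the Bayesian update of the world prior by the hypergeometric observation
#' likelihood.
#'
#' @inheritParams literal_listener
#' @param access Number of objects examined (`1..N`).
#' @param observed Number of examined objects with the property
#'   (`0..access`).
#' @return An object of class `rsa_knowledge_state`: a list with `N`,
#'   `access`, `observed`, `support` (integer vector) and `belief` (tibble
#'   with columns `world`, `prob` over the support).
#' @examples
#' knowledge_state(world_prior(3), access = 2, observed = 2)
#' @export
knowledge_state <- function(prior, access, observed) {
  prior <- as_world_prior(prior)
  N <- max(prior$world)
  access <- assert_count(access, "access", min = 1L)
  observed <- assert_count(observed, "observed", min = 0L)
  if (access > N || observed > access) {
    abort("need 0 <= observed <= access <= N.", class = "altrsa_validation_error")
  }
  support <- observed:(observed + (N - access))
  lik <- dhyper(observed, support, N - support, access)
  w <- prior$prob[match(support, prior$world)] * lik
  if (sum(w) <= 0) {
    abort(sprintf("observation (access %d, observed %d) is inconsistent with the prior.",
                  access, observed),
          class = "altrsa_validation_error")
  }
  structure(
    list(N = N, access = access, observed = observed, support = support,
         belief = tibble(world = support, prob = w / sum(w))),
    class = "rsa_knowledge_state"
  )
}

#' @export
print.rsa_knowledge_state <- function(x, ...) {
  cat(sprintf("<knowledge state> examined %d of %d, saw %d with the property\n",
              x$access, x$N, x$observed))
  cat(sprintf("compatible worlds: {%s}; belief: %s\n",
              paste(x$support, collapse = ", "),
              paste(signif(x$belief$prob, 4), collapse = ", ")))
  invisible(x)
}

#' Speaker utility of an utterance
#'
#' Expected log-probability that the literal listener assigns to the worlds
#' the speaker believes in: `sum_w P(w | s) log L0(w | u)`. The utility is
#' `-Inf` exactly when the utterance is false in some world the speaker gives
#' positive belief (the speaker will not assert it), including the case where
#' the utterance has no prior mass at all.
#'
#' @param state An `rsa_knowledge_state` from [knowledge_state()].
#' @param utt An [utterance()] or integer meaning vector.
#' @inheritParams literal_listener
#' @return A single number in nats (possibly `-Inf`).
#' @examples
#' sp <- world_prior(3)
#' speaker_utility(knowledge_state(sp, 3, 3), utterance("some", 1:3), sp)
#' @export
speaker_utility <- function(state, utt, prior) {
  stopifnot(inherits(state, "rsa_knowledge_state"))
  prior <- as_world_prior(prior)
  l0 <- tryCatch(literal_listener(prior, utt),
                 altrsa_uninterpretable_utterance = function(e) NULL)
  if (is.null(l0)) return(-Inf)
  p_listener <- l0$prob[match(state$belief$world, l0$world)]
  b <- state$belief$prob
  if (any(b > 0 & p_listener == 0)) return(-Inf)
  keep <- b > 0
  sum(b[keep] * log(p_listener[keep]))
}

#' Speaker utterance distribution
#'
#' Softmax choice over the alternative set: probabilities proportional to
#' `exp(alpha * U1(u | s))`. Utterances with utility `-Inf` get probability 0
#' at every `alpha`, including `alpha = 0` (an indifferent speaker is still
#' truthful). A state in which every alternative has utility `-Inf` is a
#' *mute* state: all probabilities are 0 and the attribute `"mute"` is
#' `TRUE`; such states contribute nothing to the pragmatic listener's sum.
#'
#' @param state An `rsa_knowledge_state`.
#' @param alts An alternative set from [alt_set()] (tibble with `label`,
#'   `meaning`).
#' @inheritParams literal_listener
#' @param alpha Softmax rationality, `alpha >= 0`.
#' @return A tibble with columns `label`, `utility`, `prob`; attribute
#'   `"mute"` flags the all-unassertable case.
#' @examples
#' sp <- world_prior(3)
#' speaker_distribution(knowledge_state(sp, 3, 3), alt_set(3), sp, alpha = 1)
#' @export
speaker_distribution <- function(state, alts, prior, alpha = 1) {
  stopifnot(inherits(state, "rsa_knowledge_state"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0) {
    abort("`alpha` must be a single number >= 0.", class = "altrsa_validation_error")
  }
  prior <- as_world_prior(prior)
  utility <- map_dbl(alts$meaning, function(m) {
    speaker_utility(state, m, prior)
  })
  logw <- ifelse(is.finite(utility), alpha * utility, -Inf)
  mute <- all(!is.finite(logw))
  prob <- if (mute) rep(0, length(logw)) else exp(logw - logsumexp(logw))
  out <- tibble(label = alts$label, utility = utility, prob = prob)
  attr(out, "mute") <- mute
  out
}

#' Is a speaker distribution mute?
#'
#' @param x A tibble returned by [speaker_distribution()].
#' @return `TRUE` if no alternative was assertable in the state.
#' @export
is_mute <- function(x) isTRUE(attr(x, "mute"))

# log P(u chosen | access, observed) for one alternative set; -Inf if mute or
# u not in the set. Internal worker for the pragmatic listener.
log_speaker_prob <- function(prior, access, observed, alts, alpha, label) {
  # observations with zero prior probability (degenerate priors) never occur
  state <- tryCatch(knowledge_state(prior, access, observed),
                    altrsa_validation_error = function(e) NULL)
  if (is.null(state)) return(-Inf)
  sd1 <- speaker_distribution(state, alts, prior, alpha)
  if (is_mute(sd1)) return(-Inf)
  p <- sd1$prob[sd1$label == label]
  if (length(p) != 1L) return(-Inf)
  log(p)
}

#' Pragmatic listener
#'
#' Bayesian inversion of the knowledge-limited speaker, marginalizing over
#' the speaker's unobserved knowledge states and over which alternative set
#' the speaker is using:
#' `L1(w | u) ∝ sum_A P(A) sum_o P(w) P(o | w) S1(u | s(a, o), A)`.
#' All products are accumulated in log space and normalized by
#' log-sum-exp. Mute states contribute zero mass.
#'
#' @param config An [rsa_config()].
#' @param access Number of objects the speaker examined (defaults to
#'   `config$access_full`).
#' @param utt Utterance label; must belong to every alternative set with
#'   positive mixture weight (so a numeral requires `p_with_numerals = 1`).
#' @param p_with_numerals Optional override of the mixture weight in
#'   `config`.
#' @return A tibble with columns `world` and `prob` (the listener's
#'   posterior over world counts).
#' @examples
#' cfg <- rsa_config(alpha = 3)
#' pragmatic_listener(cfg, access = 3)            # full knowledge
#' pragmatic_listener(cfg, access = 2)            # partial knowledge
#' @export
pragmatic_listener <- function(config, access = config$access_full,
                               utt = "some", p_with_numerals = NULL) {
  stopifnot(inherits(config, "rsa_config"))
  access <- assert_count(access, "access", min = 1L)
  if (access > config$N) {
    abort("`access` must be at most N.", class = "altrsa_validation_error")
  }
  p_mix <- assert_prob(p_with_numerals %||% config$p_with_numerals, "p_with_numerals")
  prior <- config$prior
  N <- config$N

  sets <- list()
  if (p_mix < 1) sets[["no_numerals"]] <- list(w = 1 - p_mix, alts = alt_set(N, "no_numerals"))
  if (p_mix > 0) sets[["with_numerals"]] <- list(w = p_mix, alts = alt_set(N, "with_numerals"))
  for (s in sets) {
    if (!utt %in% s$alts$label) {
      abort(sprintf("utterance '%s' is not in the '%s' alternative set, which has positive weight.",
                    utt, attr(s$alts, "tag")),
            class = "altrsa_validation_error")
    }
  }

  # per alternative set: log S1(u | state(access, o)) for every observable o
  log_s1 <- lapply(sets, function(s) {
    vapply(0:access, function(o) {
      log_speaker_prob(prior, access, o, s$alts, config$alpha, utt)
    }, numeric(1))
  })

  log_score <- vapply(0:N, function(w) {
    obs <- observation_model(N, w, access)
    per_set <- vapply(seq_along(sets), function(i) {
      terms <- log(prior$prob[prior$world == w]) + log(obs$prob) +
        log_s1[[i]][obs$observed + 1L]
      logsumexp(terms)
    }, numeric(1))
    logsumexp(log(vapply(sets, `[[`, numeric(1), "w")) + per_set)
  }, numeric(1))

  if (all(!is.finite(log_score))) {
    abort(sprintf("unproducible utterance '%s': no knowledge state would produce it.", utt),
          class = "altrsa_unproducible_utterance")
  }
  tibble(world = 0:N, prob = exp(log_score - logsumexp(log_score)))
}

#' Probability that not all objects have the property
#'
#' Summary statistic of a listener posterior: the complement of the mass on
#' the all-world, i.e. the strength of the "some but not all" reading.
#'
#' @param posterior A tibble with columns `world`, `prob` (normalized).
#' @param N The all-world count; defaults to the largest world in
#'   `posterior`.
#' @return A single probability.
#' @examples
#' cfg <- rsa_config(alpha = 3)
#' prob_not_all(pragmatic_listener(cfg, access = 3))
#' @export
prob_not_all <- function(posterior, N = max(posterior$world)) {
  stopifnot(is.data.frame(posterior), all(c("world", "prob") %in% names(posterior)))
  1 - sum(posterior$prob[posterior$world == N])
}

#' Model predictions for the four experimental conditions
#'
#' Crosses knowledgeability (partial vs full access) with alternative
#' availability (mixture weight 0 vs 1 on the with-numerals set) and reports
#' the pragmatic listener's probability that not all objects have the
#' property given "some", both as a probability and as a percentage rounded
#' to the nearest integer (the reporting convention for condition tables).
#'
#' @param config An [rsa_config()].
#' @param utt Utterance label (default `"some"`).
#' @return A tibble of class `rsa_prediction_table` with columns
#'   `knowledgeability`, `alternatives`, `p_not_all`, `percent`; the
#'   generating config is attached as attribute `"config"`.
#' @examples
#' predict_condition_table(rsa_config(alpha = 3))
#' @export
predict_condition_table <- function(config, utt = "some") {
  stopifnot(inherits(config, "rsa_config"))
  grid <- expand_grid(
    knowledgeability = c("partial", "full"),
    alternatives = c("no_numerals", "with_numerals")
  )
  p <- map2(grid$knowledgeability, grid$alternatives, function(k, a) {
    acc <- if (k == "partial") config$access_partial else config$access_full
    post <- pragmatic_listener(config, access = acc, utt = utt,
                               p_with_numerals = if (a == "with_numerals") 1 else 0)
    prob_not_all(post, config$N)
  })
  out <- grid |>
    mutate(p_not_all = unlist(p), percent = round(100 * .data$p_not_all))
  class(out) <- c("rsa_prediction_table", class(out))
  attr(out, "config") <- config
  out
}

#' Sweep predictions over rationality and mixture grids
#'
#' Evaluates the partial- and full-knowledge "not all" probabilities for
#' every combination of `alpha` and `p_with_numerals`, e.g. to trace how the
#' prediction interpolates between the two alternative-set extremes.
#'
#' @param config Base [rsa_config()]; `alpha` and `p_with_numerals` in it are
#'   overridden by the grids.
#' @param alpha Numeric vector of rationality values.
#' @param p_with_numerals Numeric vector of mixture weights in `[0, 1]`.
#' @param utt Utterance label (default `"some"`).
#' @return A tibble of class `rsa_sweep`: one row per grid point and
#'   knowledgeability level, ordered by `alpha`, then `p_with_numerals`,
#'   then knowledgeability (partial before full).
#' @examples
#' rsa_sweep(rsa_config(), alpha = 3, p_with_numerals = c(0, 0.5, 1))
#' @export
rsa_sweep <- function(config, alpha = config$alpha,
                      p_with_numerals = config$p_with_numerals, utt = "some") {
  stopifnot(inherits(config, "rsa_config"))
  if (length(alpha) == 0L || length(p_with_numerals) == 0L) {
    abort("`alpha` and `p_with_numerals` grids must be nonempty.",
          class = "altrsa_validation_error")
  }
  grid <- expand_grid(alpha = as.numeric(alpha),
                      p_with_numerals = as.numeric(p_with_numerals),
                      knowledgeability = c("partial", "full"))
  rows <- purrr::pmap_dbl(grid, function(alpha, p_with_numerals, knowledgeability) {
    cfg <- rsa_config(N = config$N, prior = config$prior, alpha = alpha,
                      access_partial = config$access_partial,
                      access_full = config$access_full,
                      p_with_numerals = p_with_numerals)
    acc <- if (knowledgeability == "partial") cfg$access_partial else cfg$access_full
    prob_not_all(pragmatic_listener(cfg, access = acc, utt = utt), cfg$N)
  })
  out <- grid |> mutate(p_not_all = rows, percent = round(100 * rows))
  class(out) <- c("rsa_sweep", class(out))
  out
}
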