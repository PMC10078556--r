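#' Prior distribution over world states
#'
#' A world state is the number of objects (out of `N`) that carry the target
#' property, so the world space is `{0, 1, ..., N}`. The prior is returned as a
#' tibble with one row per world, which every listener/speaker function in the
#' package consumes.
#'
#' @param N Number of objects in the scenario (a single integer, `N >= 1`).
#' @param weights Either `"uniform"` or a numeric vector of `N + 1` nonnegative
#'   weights for worlds `0..N`. Weights must sum to 1 (within `1e-8`); they are
#'   renormalized exactly after validation.
#'
#' @return A tibble with columns `world` (integer, `0..N`) and `prob`.
#' @examples
#' world_prior(3)
#' world_prior(3, c(0.1, 0.2, 0.3, 0.4))
#' @export
world_prior <- function(N, weights = "uniform") {
  N <- assert_count(N, "N", min = 1L)
  if (identical(weights, "uniform")) {
    weights <- rep(1 / (N + 1), N + 1)
  }
  if (!is.numeric(weights) || length(weights) != N + 1) {
    abort(sprintf("`weights` must be \"uniform\" or a numeric vector of length N + 1 = %d.", N + 1),
          class = "altrsa_validation_error")
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    abort("prior: weights must be finite and nonnegative.",
          class = "altrsa_validation_error")
  }
  if (abs(sum(weights) - 1) > 1e-8) {
    abort(sprintf("prior: weights must sum to 1 (got %.6f).", sum(weights)),
          class = "altrsa_validation_error")
  }
  tibble(world = 0:N, prob = weights / sum(weights))
}

# validate / coerce a prior argument; returns tibble(world, prob)
as_world_prior <- function(prior, N = NULL) {
  if (is.data.frame(prior)) {
    if (!all(c("world", "prob") %in% names(prior))) {
      abort("`prior` must have columns `world` and `prob` (see `world_prior()`).",
            class = "altrsa_validation_error")
    }
    n_here <- max(prior$world)
    if (!is.null(N) && n_here != N) {
      abort(sprintf("`prior` is over worlds 0..%d but N = %d.", n_here, N),
            class = "altrsa_validation_error")
    }
    return(world_prior(n_here, prior$prob[order(prior$world)]))
  }
  if (is.null(N)) {
    abort("`N` is required when `prior` is not a data frame.",
          class = "altrsa_validation_error")
  }
  world_prior(N, prior)
}

english_numeral <- function(i) {
  words <- c("one", "two", "three", "four", "five", "six", "seven", "eight",
             "nine", "ten")
  ifelse(i >= 1 & i <= length(words), words[pmax(1, pmin(i, length(words)))],
         as.character(i))
}

#' Construct an utterance
#'
#' An utterance is a label plus a literal meaning: the set of world counts at
#' which it is true. Numerals carry lower-bounded semantics ("two" is true of
#' any world with at least two property-bearing objects); exact readings arise
#' pragmatically, not lexically.
#'
#' @param label Character label, e.g. `"some"` or `"two"`.
#' @param meaning Integer vector of world counts where the utterance is true;
#'   must be nonempty.
#' @return A list of class `rsa_utterance` with elements `label` and `meaning`.
#' @examples
#' utterance("two", 2:3)
#' @export
utterance <- function(label, meaning) {
  if (!is.character(label) || length(label) != 1L) {
    abort("`label` must be a single string.", class = "altrsa_validation_error")
  }
  meaning <- sort(unique(as.integer(meaning)))
  if (length(meaning) == 0L || any(meaning < 0)) {
    abort(sprintf("utterance '%s': meaning must be a nonempty set of world counts >= 0.", label),
          class = "altrsa_validation_error")
  }
  structure(list(label = label, meaning = meaning), class = "rsa_utterance")
}

#' @export
print.rsa_utterance <- function(x, ...) {
  cat(sprintf("<utterance '%s'> true in worlds {%s}\n",
              x$label, paste(x$meaning, collapse = ", ")))
  invisible(x)
}

#' Alternative sets of utterances
#'
#' Builds the inventory of utterances the speaker chooses among. The core set
#' is `{none, some, all}`; the with-numerals set adds the numerals `one..N`
#' under lower-bounded semantics. No numeral above `N` is consistent with the
#' scenario, so the inventory stops at `N`.
#'
#' @param N Number of objects in the scenario.
#' @param tag `"no_numerals"` (default) or `"with_numerals"`.
#' @return A tibble with columns `label` and `meaning` (a list-column of
#'   integer world sets), carrying the tag as attribute `"tag"`.
#' @examples
#' alt_set(3)
#' alt_set(3, "with_numerals")
#' @export
alt_set <- function(N, tag = c("no_numerals", "with_numerals")) {
  N <- assert_count(N, "N", min = 1L)
  tag <- match.arg(tag)
  labels <- c("none", "some", "all")
  meanings <- list(0L, seq_len(N), N)
  if (tag == "with_numerals") {
    labels <- c(labels, english_numeral(seq_len(N)))
    meanings <- c(meanings, lapply(seq_len(N), function(k) k:N))
  }
  if (anyDuplicated(labels)) {
    abort("alternative set: utterance labels must be unique.",
          class = "altrsa_validation_error")
  }
  out <- tibble(label = labels, meaning = meanings)
  attr(out, "tag") <- tag
  out
}
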