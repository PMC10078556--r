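#' Generator parameters for synthetic rating data
#'
#' The generator produces 0-100 "probability that ALL items have the
#' property" ratings as: cell mean + participant effect + item effect +
#' residual, truncated to `[0, 100]`. Cell means are on the probability-of-all
#' scale (the scale of the question participants answer); analyses usually run
#' on the complementary not-all scale after [transform_responses()].
#'
#' @param cell_means Named numeric vector of the four target-cell means on the
#'   0-100 probability-of-all scale; names `partial_no_numerals`,
#'   `partial_with_numerals`, `full_no_numerals`, `full_with_numerals`.
#' @param sd_participant,sd_item,sd_resid Standard deviations (rating points)
#'   of the additive Gaussian participant, item, and residual components.
#' @param comprehension_error_rate Probability that any single comprehension
#'   answer is wrong (two per trial), default 0.
#' @return A list of class `gen_params`.
#' @seealso [gen_params_exp2()] for defaults taken from the second rating
#'   study's observed cells; [gen_params_from_model()] to link the generator
#'   to model predictions.
#' @examples
#' gen_params(cell_means = c(partial_no_numerals = 55, partial_with_numerals = 48,
#'                           full_no_numerals = 35, full_with_numerals = 38),
#'            sd_participant = 21, sd_item = 11, sd_resid = 24)
#' @export
gen_params <- function(cell_means, sd_participant, sd_item, sd_resid,
                       comprehension_error_rate = 0) {
  need <- c("partial_no_numerals", "partial_with_numerals",
            "full_no_numerals", "full_with_numerals")
  if (!is.numeric(cell_means) || !all(need %in% names(cell_means))) {
    abort(paste0("`cell_means` must be a named numeric vector with names: ",
                 paste(need, collapse = ", "), "."),
          class = "altrsa_validation_error")
  }
  cell_means <- setNames(as.numeric(cell_means[need]), need)
  if (any(cell_means < 0 | cell_means > 100)) {
    abort("`cell_means` must lie in [0, 100].", class = "altrsa_validation_error")
  }
  for (s in c(sd_participant, sd_item, sd_resid)) {
    if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0) {
      abort("standard deviations must be single numbers >= 0.",
            class = "altrsa_validation_error")
    }
  }
  comprehension_error_rate <- assert_prob(comprehension_error_rate,
                                          "comprehension_error_rate")
  structure(
    list(cell_means = cell_means, sd_participant = as.numeric(sd_participant),
         sd_item = as.numeric(sd_item), sd_resid = as.numeric(sd_resid),
         comprehension_error_rate = comprehension_error_rate),
    class = "gen_params"
  )
}

#' @export
print.gen_params <- function(x, ...) {
  cat("<gen_params> cell means (probability-of-all scale):\n")
  print(round(x$cell_means, 2))
  cat(sprintf("sd participant %.2f, item %.2f, residual %.2f; comprehension error rate %.3f\n",
              x$sd_participant, x$sd_item, x$sd_resid, x$comprehension_error_rate))
  invisible(x)
}

#' Default generator calibrated to the second rating study
#'
#' Cell means are the observed condition means of that study on the not-all
#' scale (45.4, 52.3, 64.7, 62.0), converted back to the probability-of-all
#' scale for generation. The study reports only a total SD per cell
#' (30.7, 30.0, 37.1, 35.7); the generator needs a decomposition, so the
#' pooled variance is split 40% participant / 10% item / 50% residual — an
#' explicit assumption, exposed here as arguments.
#'
#' @param var_split Length-3 numeric vector of nonnegative shares (participant,
#'   item, residual) summing to 1.
#' @param comprehension_error_rate Passed to [gen_params()].
#' @return A `gen_params` object.
#' @examples
#' gen_params_exp2()
#' @export
gen_params_exp2 <- function(var_split = c(participant = 0.4, item = 0.1, resid = 0.5),
                            comprehension_error_rate = 0) {
  if (length(var_split) != 3L || any(var_split < 0) || abs(sum(var_split) - 1) > 1e-8) {
    abort("`var_split` must be three nonnegative shares summing to 1.",
          class = "altrsa_validation_error")
  }
  not_all <- c(partial_no_numerals = 45.4, partial_with_numerals = 52.3,
               full_no_numerals = 64.7, full_with_numerals = 62.0)
  total_var <- mean(c(30.7, 30.0, 37.1, 35.7)^2)
  gen_params(
    cell_means = 100 - not_all,
    sd_participant = sqrt(var_split[[1]] * total_var),
    sd_item = sqrt(var_split[[2]] * total_var),
    sd_resid = sqrt(var_split[[3]] * total_var),
    comprehension_error_rate = comprehension_error_rate
  )
}

#' Generator parameters linked to model predictions
#'
#' Uses a [predict_condition_table()] as the source of cell means: the
#' model's probability of the all-world, in percent, becomes the mean rating
#' of each cell.
#'
#' @param table An `rsa_prediction_table`.
#' @param sd_participant,sd_item,sd_resid,comprehension_error_rate Passed to
#'   [gen_params()].
#' @return A `gen_params` object.
#' @examples
#' gen_params_from_model(predict_condition_table(rsa_config(alpha = 3)),
#'                       sd_participant = 10, sd_item = 5, sd_resid = 10)
#' @export
gen_params_from_model <- function(table, sd_participant, sd_item, sd_resid,
                                  comprehension_error_rate = 0) {
  stopifnot(inherits(table, "rsa_prediction_table"))
  cm <- 100 * (1 - table$p_not_all)
  names(cm) <- paste(table$knowledgeability, table$alternatives, sep = "_")
  gen_params(cell_means = cm, sd_participant = sd_participant,
             sd_item = sd_item, sd_resid = sd_resid,
             comprehension_error_rate = comprehension_error_rate)
}

# mean of N(m, s) truncated to [0, 100]; vectorized over m. When m is far
# outside the window the normalizer underflows and the truncated mass sits
# essentially at the nearer bound.
truncnorm_mean <- function(m, s) {
  if (s == 0) return(pmin(pmax(m, 0), 100))
  a <- (0 - m) / s
  b <- (100 - m) / s
  z <- pnorm(b) - pnorm(a)
  out <- m + s * (dnorm(a) - dnorm(b)) / z
  bad <- !is.finite(out) | z <= 0
  out[bad] <- ifelse(m[bad] < 50, 0, 100)
  pmin(pmax(out, 0), 100)
}

#' Population cell means of the generator
#'
#' The generator truncates each rating to `[0, 100]`, so the population mean
#' of a cell is not the nominal (latent) cell mean when the scale bounds
#' bind. This function computes the exact population means: the
#' truncated-normal mean given the participant + item shift, integrated over
#' the Gaussian distribution of that shift. These are the quantities the
#' contrast estimator is consistent for.
#'
#' @param params A [gen_params()].
#' @return A tibble with columns `knowledgeability`, `exposure_condition`,
#'   `mean_rating` (probability-of-all scale) and `mean_not_all`
#'   (`100 - mean_rating`).
#' @examples
#' expected_cell_means(gen_params_exp2())
#' @export
expected_cell_means <- function(params) {
  stopifnot(inherits(params, "gen_params"))
  s_shift <- sqrt(params$sd_participant^2 + params$sd_item^2)
  cell_mean <- function(mu) {
    if (s_shift == 0) return(truncnorm_mean(mu, params$sd_resid))
    integrate(function(x) dnorm(x, 0, s_shift) * truncnorm_mean(mu + x, params$sd_resid),
              lower = -Inf, upper = Inf, rel.tol = 1e-10)$value
  }
  mr <- vapply(params$cell_means, cell_mean, numeric(1))
  tibble(
    knowledgeability = c("partial", "partial", "full", "full"),
    exposure_condition = rep(c("no_numerals", "with_numerals"), 2),
    mean_rating = unname(mr),
    mean_not_all = 100 - unname(mr)
  )
}

#' Population effects of the generator
#'
#' Contrasts of [expected_cell_means()] on the not-all scale, in the same
#' parameterization as [estimate_effects()]: grand mean, knowledgeability
#' (full minus partial), exposure (with minus without numerals) and their
#' interaction.
#'
#' @param params A [gen_params()].
#' @return A tibble with columns `term` and `value`.
#' @examples
#' expected_effects(gen_params_exp2())
#' @export
expected_effects <- function(params) {
  cm <- expected_cell_means(params)
  g <- function(k, e) cm$mean_not_all[cm$knowledgeability == k & cm$exposure_condition == e]
  tibble(
    term = c("intercept", "knowledgeability", "exposure", "interaction"),
    value = c(
      mean(cm$mean_not_all),
      ((g("full", "no_numerals") - g("partial", "no_numerals")) +
         (g("full", "with_numerals") - g("partial", "with_numerals"))) / 2,
      ((g("partial", "with_numerals") - g("partial", "no_numerals")) +
         (g("full", "with_numerals") - g("full", "no_numerals"))) / 2,
      (g("full", "with_numerals") - g("partial", "with_numerals")) -
        (g("full", "no_numerals") - g("partial", "no_numerals"))
    )
  )
}

#' Generate a synthetic rating dataset
#'
#' Simulates one complete experiment: participants are split into equal
#' between-subject exposure groups, trial orders come from [build_design()],
#' and each rating is cell mean + participant effect + item effect +
#' residual, truncated (not censored) to `[0, 100]` by sampling the residual
#' from its conditional distribution on the admissible window. Exposure
#' trials receive ratings centered on the grand mean of the four cell means;
#' they are generated for realism but are not analyzed downstream. Two
#' comprehension answers per trial are correct independently with
#' probability `1 - comprehension_error_rate`. Deterministic given `seed`.
#'
#' @param spec A [design_spec()].
#' @param params A [gen_params()].
#' @param seed Integer master seed.
#' @return A tibble with one row per trial: `participant`, `item`,
#'   `position`, `trial_type`, `knowledgeability`, `exposure_condition`,
#'   `rating`, `comp1_correct`, `comp2_correct`.
#' @examples
#' head(generate_dataset(design_spec(n_participants = 4), gen_params_exp2(), seed = 1))
#' @export
generate_dataset <- function(spec, params, seed) {
  stopifnot(inherits(spec, "design_spec"), inherits(params, "gen_params"))
  seed <- assert_count(seed, "seed", min = 0L)
  design <- build_design(spec, seed)
  n <- spec$n_participants
  total <- spec$n_target + spec$n_exposure
  streams <- derive_streams(seed, n)
  withr::local_preserve_seed()

  # between-subject exposure assignment, equal halves
  set.seed(streams$groups)
  with_idx <- sample.int(n, n %/% 2L)
  condition <- rep("no_numerals", n)
  condition[with_idx] <- "with_numerals"

  # item effects, shared by all participants (crossed design)
  items <- sort(unique(design$item))
  set.seed(streams$items)
  item_eff <- setNames(rnorm(length(items), 0, params$sd_item), items)

  exposure_mean <- mean(params$cell_means)
  cell_key <- names(params$cell_means)

  rating <- numeric(nrow(design))
  comp1 <- logical(nrow(design))
  comp2 <- logical(nrow(design))
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * total + 1L):(i * total)
    set.seed(streams$rating[i])
    p_eff <- rnorm(1, 0, params$sd_participant)
    is_target <- design$trial_type[rows] == "target"
    mu <- rep(exposure_mean, total)
    key <- paste(design$knowledgeability[rows][is_target], condition[i], sep = "_")
    mu[is_target] <- params$cell_means[match(key, cell_key)]
    m <- mu + p_eff + item_eff[design$item[rows]]
    if (params$sd_resid == 0) {
      rating[rows] <- pmin(pmax(m, 0), 100)
    } else {
      lo <- pnorm(0, m, params$sd_resid)
      hi <- pnorm(100, m, params$sd_resid)
      u <- lo + runif(total) * (hi - lo)
      rating[rows] <- pmin(pmax(qnorm(u, m, params$sd_resid), 0), 100)
    }
    err <- runif(2L * total) < params$comprehension_error_rate
    comp1[rows] <- !err[seq_len(total)]
    comp2[rows] <- !err[total + seq_len(total)]
  }

  design |>
    mutate(
      exposure_condition = condition[.data$participant],
      rating = rating,
      comp1_correct = comp1,
      comp2_correct = comp2
    ) |>
    select("participant", "item", "position", "trial_type",
           "knowledgeability", "exposure_condition", "rating",
           "comp1_correct", "comp2_correct")
}

#' Complement-transform probability ratings
#'
#' Adds `not_all_rating = 100 - rating`: a rating of the probability that
#' all items have the property becomes the probability that *not all* do,
#' the dependent variable of the analyses (a response of 80 becomes 20). The
#' original column is preserved, so applying the transform twice round-trips.
#'
#' @param data A dataset with a `rating` column in `[0, 100]`.
#' @return The input tibble with a `not_all_rating` column added (or
#'   recomputed).
#' @examples
#' transform_responses(tibble::tibble(rating = c(80, 0, 100)))
#' @export
transform_responses <- function(data) {
  stopifnot(is.data.frame(data))
  if (!"rating" %in% names(data)) {
    abort("`data` must have a `rating` column.", class = "altrsa_validation_error")
  }
  if (any(is.na(data$rating)) || any(data$rating < 0 | data$rating > 100)) {
    abort("`rating` must lie in [0, 100] with no missing values.",
          class = "altrsa_validation_error")
  }
  mutate(as_tibble(data), not_all_rating = 100 - .data$rating)
}

#' Apply comprehension-based exclusions
#'
#' Two-stage exclusion policy: participants whose overall comprehension
#' accuracy (both questions, all trials) falls below `accuracy_threshold`
#' are dropped entirely; optionally, individual target trials with any wrong
#' comprehension answer are dropped for the remaining participants.
#'
#' @param data A dataset with `comp1_correct`/`comp2_correct` columns.
#' @param accuracy_threshold Minimum participant-level accuracy (default
#'   0.875, the relaxed criterion of the fourth study).
#' @param scope `"both"` (participant and trial exclusions, default),
#'   `"participants"` or `"trials"`.
#' @return A list with `data` (the filtered tibble) and `report` (a one-row
#'   tibble counting dropped participants and dropped target trials).
#' @examples
#' d <- generate_dataset(design_spec(n_participants = 4), gen_params_exp2(), seed = 1)
#' exclusion_filter(d)$report
#' @export
exclusion_filter <- function(data, accuracy_threshold = 0.875,
                             scope = c("both", "participants", "trials")) {
  stopifnot(is.data.frame(data))
  scope <- match.arg(scope)
  if (!all(c("comp1_correct", "comp2_correct") %in% names(data))) {
    abort("`data` must have `comp1_correct` and `comp2_correct` columns.",
          class = "altrsa_validation_error")
  }
  accuracy_threshold <- assert_prob(accuracy_threshold, "accuracy_threshold")
  data <- as_tibble(data)

  dropped_participants <- 0L
  if (scope %in% c("both", "participants")) {
    acc <- data |>
      group_by(.data$participant) |>
      summarise(accuracy = mean(c(.data$comp1_correct, .data$comp2_correct)),
                .groups = "drop")
    bad <- acc$participant[acc$accuracy < accuracy_threshold]
    dropped_participants <- length(bad)
    data <- filter(data, !.data$participant %in% bad)
  }

  dropped_trials <- 0L
  if (scope %in% c("both", "trials")) {
    bad_trial <- data$trial_type == "target" &
      !(data$comp1_correct & data$comp2_correct)
    dropped_trials <- sum(bad_trial)
    data <- data[!bad_trial, , drop = FALSE]
  }

  list(
    data = data,
    report = tibble(
      accuracy_threshold = accuracy_threshold,
      scope = scope,
      participants_dropped = dropped_participants,
      target_trials_dropped = dropped_trials,
      participants_kept = length(unique(data$participant)),
      rows_kept = nrow(data)
    )
  )
}
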