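#' Add contrast-coded predictors
#'
#' Numeric sum-to-zero codes matching the analyses of the rating studies:
#' knowledgeability `k` (partial = -0.5, full = +0.5), exposure `e`
#' (no numerals = -0.5, with numerals = +0.5), and their product `ke`.
#'
#' @param data A dataset with `knowledgeability` and `exposure_condition`
#'   columns.
#' @return The input tibble with numeric columns `k`, `e`, `ke` added.
#' @examples
#' contrast_code(tibble::tibble(knowledgeability = "full",
#'                              exposure_condition = "no_numerals"))
#' @export
contrast_code <- function(data) {
  stopifnot(is.data.frame(data))
  if (!all(c("knowledgeability", "exposure_condition") %in% names(data))) {
    abort("`data` must have `knowledgeability` and `exposure_condition` columns.",
          class = "altrsa_validation_error")
  }
  kmap <- c(partial = -0.5, full = 0.5)
  emap <- c(no_numerals = -0.5, with_numerals = 0.5)
  if (!all(data$knowledgeability %in% names(kmap))) {
    abort("unknown `knowledgeability` level (expected 'partial' or 'full').",
          class = "altrsa_validation_error")
  }
  if (!all(data$exposure_condition %in% names(emap))) {
    abort("unknown `exposure_condition` level (expected 'no_numerals' or 'with_numerals').",
          class = "altrsa_validation_error")
  }
  as_tibble(data) |>
    mutate(k = unname(kmap[.data$knowledgeability]),
           e = unname(emap[.data$exposure_condition]),
           ke = .data$k * .data$e)
}

# per-participant cell means of not_all_rating on target trials ->
# list of per-group matrices with columns partial/full (NA = missing cell)
participant_cells <- function(data) {
  if (!"not_all_rating" %in% names(data) && "rating" %in% names(data)) {
    data <- transform_responses(data)
  }
  need <- c("participant", "knowledgeability", "exposure_condition", "not_all_rating")
  if (!all(need %in% names(data))) {
    abort(paste0("`data` must have columns: ", paste(need, collapse = ", "), "."),
          class = "altrsa_validation_error")
  }
  if ("trial_type" %in% names(data)) {
    data <- filter(data, .data$trial_type == "target")
  }
  pm <- data |>
    group_by(.data$participant, .data$exposure_condition, .data$knowledgeability) |>
    summarise(m = mean(.data$not_all_rating), .groups = "drop") |>
    pivot_wider(names_from = "knowledgeability", values_from = "m")
  for (col in c("partial", "full")) {
    if (!col %in% names(pm)) pm[[col]] <- NA_real_
  }
  groups <- split(pm, pm$exposure_condition)
  lapply(groups, function(g) cbind(partial = g$partial, full = g$full))
}

# cell averages and the four contrast statistics from per-group matrices
contrast_stats <- function(mats) {
  cell <- function(g, k) mean(mats[[g]][, k], na.rm = TRUE)
  pn <- cell("no_numerals", "partial"); fn <- cell("no_numerals", "full")
  pw <- cell("with_numerals", "partial"); fw <- cell("with_numerals", "full")
  c(intercept = (pn + fn + pw + fw) / 4,
    knowledgeability = ((fn - pn) + (fw - pw)) / 2,
    exposure = ((pw - pn) + (fw - fn)) / 2,
    interaction = (fw - pw) - (fn - pn))
}

# bootstrap the four statistics by resampling participants within exposure
# group; returns a 4 x n_boot matrix
bootstrap_stats <- function(mats, n_boot) {
  boots <- matrix(NA_real_, 4L, n_boot,
                  dimnames = list(c("intercept", "knowledgeability",
                                    "exposure", "interaction"), NULL))
  # precompute resampled column means per group: 2 columns x n_boot
  cellboot <- lapply(mats, function(M) {
    ng <- nrow(M)
    idx <- matrix(sample.int(ng, ng * n_boot, replace = TRUE), ng, n_boot)
    list(partial = colMeans(matrix(M[idx, "partial"], ng, n_boot), na.rm = TRUE),
         full = colMeans(matrix(M[idx, "full"], ng, n_boot), na.rm = TRUE))
  })
  pn <- cellboot$no_numerals$partial; fn <- cellboot$no_numerals$full
  pw <- cellboot$with_numerals$partial; fw <- cellboot$with_numerals$full
  boots["intercept", ] <- (pn + fn + pw + fw) / 4
  boots["knowledgeability", ] <- ((fn - pn) + (fw - pw)) / 2
  boots["exposure", ] <- ((pw - pn) + (fw - fn)) / 2
  boots["interaction", ] <- (fw - pw) - (fn - pn)
  boots
}

#' Estimate main effects and interaction from a rating dataset
#'
#' Fixed-effect contrasts on the not-all scale, estimated from
#' per-participant cell means: each participant is first reduced to their
#' mean not-all rating per knowledgeability level; the four design cells are
#' then averaged over participants, and the effects are the standard
#' contrast combinations (intercept = grand cell mean; knowledgeability =
#' full - partial; exposure = with - without numerals; interaction =
#' difference of the knowledgeability effect across exposure groups, i.e.
#' negative when numerals shrink it). Uncertainty comes from a nonparametric
#' bootstrap that resamples participants within exposure group (exposure is
#' between-subject). On balanced data these are the same fixed-effect
#' quantities a mixed-effects regression with +/-0.5 contrast coding targets;
#' no random-effect machinery is fitted.
#'
#' Participants missing a knowledgeability cell (possible after trial-level
#' exclusions) contribute their available cells only; the number of missing
#' participant-cells is reported in the result.
#'
#' @param data A dataset as produced by [generate_dataset()] (after optional
#'   [exclusion_filter()]); `not_all_rating` is computed from `rating` if
#'   absent. Non-target trials are ignored.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param conf_level Confidence level of the percentile intervals.
#' @param seed Optional seed for the bootstrap.
#' @return An object of class `rsa_fit`: see [tidy.rsa_fit()] and
#'   [glance.rsa_fit()].
#' @examples
#' d <- generate_dataset(design_spec(n_participants = 40), gen_params_exp2(), seed = 2)
#' fit <- estimate_effects(d, n_boot = 200, seed = 1)
#' tidy(fit)
#' @export
estimate_effects <- function(data, n_boot = 2000, conf_level = 0.95, seed = NULL) {
  n_boot <- assert_count(n_boot, "n_boot", min = 1L)
  stopifnot(conf_level > 0, conf_level < 1)
  mats <- participant_cells(data)
  if (!all(c("no_numerals", "with_numerals") %in% names(mats)) ||
      any(vapply(mats, nrow, 1L) < 2L)) {
    abort("need at least 2 participants in each exposure group.",
          class = "altrsa_validation_error")
  }
  missing_cells <- sum(vapply(mats, function(M) sum(is.na(M)), 1L))
  if (missing_cells > 0) {
    warn(sprintf("%d participant cell(s) missing; using available cells.", missing_cells))
  }
  est <- contrast_stats(mats)
  if (!is.null(seed)) withr::local_seed(seed)
  boots <- bootstrap_stats(mats, n_boot)
  alpha <- 1 - conf_level
  ci <- apply(boots, 1, quantile, probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
  structure(
    list(
      estimates = tibble(
        term = names(est),
        estimate = unname(est),
        se = unname(apply(boots, 1, sd)),
        conf.low = unname(ci[1, ]),
        conf.high = unname(ci[2, ])
      ),
      n_participants = sum(vapply(mats, nrow, 1L)),
      n_boot = n_boot,
      conf_level = conf_level,
      missing_cells = missing_cells
    ),
    class = "rsa_fit"
  )
}

#' @export
print.rsa_fit <- function(x, ...) {
  cat(sprintf("<rsa_fit> %d participants, %d bootstrap resamples, %.0f%% percentile CIs\n",
              x$n_participants, x$n_boot, 100 * x$conf_level))
  print(mutate(x$estimates,
               estimate = round(.data$estimate, 3), se = round(.data$se, 3),
               conf.low = round(.data$conf.low, 3),
               conf.high = round(.data$conf.high, 3)))
  if (x$missing_cells > 0) cat(sprintf("note: %d missing participant cell(s)\n", x$missing_cells))
  invisible(x)
}

#' Simple effect of numeral exposure within one knowledgeability level
#'
#' Difference between the exposure groups (with minus without numerals) of
#' participants' mean not-all ratings at the given knowledgeability level,
#' with a participant-resampling bootstrap interval.
#'
#' @inheritParams estimate_effects
#' @param within `"partial"` or `"full"`.
#' @return A one-row tibble with `term`, `estimate`, `se`, `conf.low`,
#'   `conf.high`, `n_participants`.
#' @examples
#' d <- generate_dataset(design_spec(n_participants = 40), gen_params_exp2(), seed = 3)
#' simple_effects(d, within = "partial", n_boot = 200, seed = 1)
#' @export
simple_effects <- function(data, within = c("partial", "full"), n_boot = 2000,
                           conf_level = 0.95, seed = NULL) {
  within <- match.arg(within)
  n_boot <- assert_count(n_boot, "n_boot", min = 1L)
  mats <- participant_cells(data)
  if (!all(c("no_numerals", "with_numerals") %in% names(mats)) ||
      any(vapply(mats, nrow, 1L) < 2L)) {
    abort("need at least 2 participants in each exposure group.",
          class = "altrsa_validation_error")
  }
  x_no <- mats$no_numerals[, within]
  x_with <- mats$with_numerals[, within]
  est <- mean(x_with, na.rm = TRUE) - mean(x_no, na.rm = TRUE)
  if (!is.null(seed)) withr::local_seed(seed)
  boot_mean <- function(x) {
    nx <- length(x)
    idx <- matrix(sample.int(nx, nx * n_boot, replace = TRUE), nx, n_boot)
    colMeans(matrix(x[idx], nx, n_boot), na.rm = TRUE)
  }
  boots <- boot_mean(x_with) - boot_mean(x_no)
  alpha <- 1 - conf_level
  ci <- quantile(boots, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
  tibble(
    term = paste0("exposure_within_", within),
    estimate = est,
    se = sd(boots),
    conf.low = ci[[1]],
    conf.high = ci[[2]],
    n_participants = length(x_no) + length(x_with)
  )
}

#' Monte-Carlo power analysis for the interaction test
#'
#' For each sample size in `n_grid`, simulates `n_sims` experiments from the
#' generator, fits [estimate_effects()], and counts the fraction of
#' simulations in which the bootstrap percentile interval for the
#' interaction (at level `1 - alpha_level`) excludes zero. With a
#' zero-interaction generator this fraction is the test's type-I error rate
#' and should sit near `alpha_level`.
#'
#' @param params A [gen_params()].
#' @param spec A [design_spec()]; its `n_participants` is overridden by the
#'   grid.
#' @param n_grid Integer vector of sample sizes.
#' @param n_sims Simulations per grid point (default 500).
#' @param alpha_level Nominal significance level (default 0.05).
#' @param n_boot Bootstrap resamples per fit (default 1000).
#' @param seed Master seed; simulation and bootstrap seeds are derived from
#'   it.
#' @return A tibble of class `rsa_power` with columns `n_participants`,
#'   `n_sims`, `alpha_level`, `power`, `mc_se`
#'   (`sqrt(power (1 - power) / n_sims)`).
#' @examples
#' \donttest{
#' power_analysis(gen_params_exp2(), design_spec(), n_grid = c(60, 120),
#'                n_sims = 50, seed = 1)
#' }
#' @export
power_analysis <- function(params, spec, n_grid, n_sims = 500,
                           alpha_level = 0.05, n_boot = 1000, seed = 1) {
  stopifnot(inherits(params, "gen_params"), inherits(spec, "design_spec"))
  n_sims <- assert_count(n_sims, "n_sims", min = 1L)
  alpha_level <- assert_prob(alpha_level, "alpha_level")
  n_grid <- vapply(n_grid, assert_count, integer(1), name = "n_grid", min = 4L)
  sim_seeds <- withr::with_seed(seed,
    matrix(sample.int(2147483646L, 2L * length(n_grid) * n_sims),
           nrow = 2L))
  out <- lapply(seq_along(n_grid), function(gi) {
    n <- n_grid[gi]
    spec_n <- design_spec(n_participants = n, n_target = spec$n_target,
                          n_exposure = spec$n_exposure,
                          first_trial_exposure = spec$first_trial_exposure,
                          no_adjacent_targets = spec$no_adjacent_targets)
    hits <- vapply(seq_len(n_sims), function(si) {
      j <- (gi - 1L) * n_sims + si
      d <- generate_dataset(spec_n, params, seed = sim_seeds[1L, j])
      fit <- estimate_effects(d, n_boot = n_boot, conf_level = 1 - alpha_level,
                              seed = sim_seeds[2L, j])
      int <- fit$estimates[fit$estimates$term == "interaction", ]
      int$conf.low > 0 || int$conf.high < 0
    }, logical(1))
    p <- mean(hits)
    tibble(n_participants = n, n_sims = n_sims, alpha_level = alpha_level,
           power = p, mc_se = sqrt(p * (1 - p) / n_sims))
  })
  res <- bind_rows(out)
  class(res) <- c("rsa_power", class(res))
  res
}
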