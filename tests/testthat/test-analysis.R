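# Contrast estimator, bootstrap intervals, simple effects, power machinery

noise_free_data <- function(cells, n = 8) {
  # cells named partial_no_numerals, ..., on the not-all scale
  params <- gen_params(cell_means = 100 - cells, sd_participant = 0,
                       sd_item = 0, sd_resid = 0)
  transform_responses(generate_dataset(design_spec(n_participants = n), params, seed = 1))
}

test_that("contrast coding matches the reported scheme", {
  d <- tibble::tibble(
    knowledgeability = c("partial", "full", "full", "partial"),
    exposure_condition = c("no_numerals", "with_numerals", "no_numerals", "with_numerals")
  )
  cc <- contrast_code(d)
  expect_identical(cc$k, c(-0.5, 0.5, 0.5, -0.5))
  expect_identical(cc$e, c(-0.5, 0.5, -0.5, 0.5))
  expect_identical(cc$ke, c(0.25, 0.25, -0.25, -0.25))
  expect_error(contrast_code(dplyr::mutate(d, knowledgeability = "half")),
               class = "altrsa_validation_error")
})

test_that("noise-free data reproduces the contrast algebra to machine precision", {
  cells <- c(partial_no_numerals = 40, partial_with_numerals = 52,
             full_no_numerals = 61, full_with_numerals = 58)
  fit <- estimate_effects(noise_free_data(cells), n_boot = 50, seed = 1)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  a <- cells[["partial_no_numerals"]]; b <- cells[["partial_with_numerals"]]
  cc <- cells[["full_no_numerals"]]; dd <- cells[["full_with_numerals"]]
  expect_equal(est[["intercept"]], (a + b + cc + dd) / 4, tolerance = 1e-12)
  expect_equal(est[["knowledgeability"]], ((cc - a) + (dd - b)) / 2, tolerance = 1e-12)
  expect_equal(est[["exposure"]], ((b - a) + (dd - cc)) / 2, tolerance = 1e-12)
  expect_equal(est[["interaction"]], (dd - b) - (cc - a), tolerance = 1e-12)
  # intervals collapse onto the point estimate without noise
  expect_equal(fit$estimates$conf.low, fit$estimates$estimate, tolerance = 1e-9)
  # all-equal cells: every effect zero
  fit0 <- estimate_effects(noise_free_data(c(partial_no_numerals = 50,
                                             partial_with_numerals = 50,
                                             full_no_numerals = 50,
                                             full_with_numerals = 50)),
                           n_boot = 50, seed = 1)
  expect_equal(fit0$estimates$estimate[-1], rep(0, 3), tolerance = 1e-12)
})

test_that("the estimator is linear in the response", {
  d <- transform_responses(generate_dataset(design_spec(n_participants = 30),
                                            gen_params_exp2(), seed = 6))
  fit <- estimate_effects(d, n_boot = 20, seed = 2)
  # scaling every rating scales every effect
  d_scaled <- dplyr::mutate(d, not_all_rating = 0.5 * not_all_rating)
  fit_s <- estimate_effects(d_scaled, n_boot = 20, seed = 2)
  expect_equal(fit_s$estimates$estimate, 0.5 * fit$estimates$estimate, tolerance = 1e-10)
  # shifting moves only the intercept
  d_shift <- dplyr::mutate(d, not_all_rating = not_all_rating + 7)
  fit_t <- estimate_effects(d_shift, n_boot = 20, seed = 2)
  expect_equal(fit_t$estimates$estimate[1], fit$estimates$estimate[1] + 7, tolerance = 1e-10)
  expect_equal(fit_t$estimates$estimate[-1], fit$estimates$estimate[-1], tolerance = 1e-10)
})

test_that("effects are recovered on synthetic data at moderate size", {
  params <- gen_params_exp2()
  truth <- setNames(expected_effects(params)$value, expected_effects(params)$term)
  d <- generate_dataset(design_spec(n_participants = 600), params, seed = 8)
  fit <- estimate_effects(d, n_boot = 1000, seed = 9)
  td <- tidy(fit)
  for (term in c("knowledgeability", "exposure", "interaction")) {
    row <- td[td$term == term, ]
    expect_lt(abs(row$estimate - truth[[term]]), 3 * row$se)
  }
  g <- glance(fit)
  expect_identical(g$n_participants, 600L)
  expect_identical(g$missing_cells, 0L)
})

test_that("missing participant cells are averaged available-case with a warning", {
  cells <- c(partial_no_numerals = 40, partial_with_numerals = 50,
             full_no_numerals = 60, full_with_numerals = 55)
  d <- noise_free_data(cells, n = 8)
  # drop every partial trial of one participant
  p1 <- d$participant[d$exposure_condition == "no_numerals"][1]
  d_miss <- d[!(d$participant == p1 & d$knowledgeability == "partial" &
                  d$trial_type == "target"), ]
  expect_warning(fit <- estimate_effects(d_miss, n_boot = 50, seed = 1),
                 "missing")
  expect_identical(fit$missing_cells, 1L)
  # balanced noise-free cells are unaffected by dropping one participant-cell
  expect_equal(fit$estimates$estimate[fit$estimates$term == "interaction"],
               (55 - 50) - (60 - 40), tolerance = 1e-12)
})

test_that("simple effects isolate the exposure contrast within one level", {
  cells <- c(partial_no_numerals = 40, partial_with_numerals = 52,
             full_no_numerals = 61, full_with_numerals = 58)
  d <- noise_free_data(cells)
  sp <- simple_effects(d, within = "partial", n_boot = 50, seed = 1)
  expect_equal(sp$estimate, 12, tolerance = 1e-12)
  sf <- simple_effects(d, within = "full", n_boot = 50, seed = 1)
  expect_equal(sf$estimate, -3, tolerance = 1e-12)
  # direction on study-calibrated noisy data: positive at partial knowledge
  d2 <- generate_dataset(design_spec(n_participants = 600), gen_params_exp2(), seed = 4)
  sp2 <- simple_effects(d2, within = "partial", n_boot = 500, seed = 5)
  expect_gt(sp2$estimate, 0)
})

test_that("simple-effect intervals cover a null exposure effect", {
  # no exposure effect in the generator at either knowledgeability level
  params <- gen_params(cell_means = c(partial_no_numerals = 52,
                                      partial_with_numerals = 52,
                                      full_no_numerals = 37,
                                      full_with_numerals = 37),
                       sd_participant = 21, sd_item = 10.5, sd_resid = 23.5)
  seeds <- withr::with_seed(31, sample.int(1e6, 100))
  covered <- vapply(seeds, function(s) {
    d <- generate_dataset(design_spec(n_participants = 240), params, seed = s)
    ci <- simple_effects(d, within = "partial", n_boot = 400, seed = s + 1)
    ci$conf.low <= 0 && ci$conf.high >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("power analysis is seeded, sized, and saturates for a huge effect", {
  params_big <- gen_params(cell_means = c(partial_no_numerals = 70,
                                          partial_with_numerals = 70,
                                          full_no_numerals = 70,
                                          full_with_numerals = 30),
                           sd_participant = 3, sd_item = 1, sd_resid = 5)
  pw <- power_analysis(params_big, design_spec(), n_grid = 100, n_sims = 100,
                       n_boot = 400, seed = 13)
  expect_s3_class(pw, "rsa_power")
  expect_gt(pw$power, 0.99)
  expect_equal(pw$mc_se, sqrt(pw$power * (1 - pw$power) / 100), tolerance = 1e-12)
  pw2 <- power_analysis(params_big, design_spec(), n_grid = 100, n_sims = 100,
                        n_boot = 400, seed = 13)
  expect_identical(pw, pw2)
})

test_that("power is nondecreasing in sample size up to Monte-Carlo slack", {
  pw <- power_analysis(gen_params_exp2(), design_spec(),
                       n_grid = c(60, 180, 420), n_sims = 120,
                       n_boot = 400, seed = 17)
  for (i in 2:nrow(pw)) {
    slack <- 2 * sqrt(pw$mc_se[i]^2 + pw$mc_se[i - 1]^2)
    expect_gte(pw$power[i], pw$power[i - 1] - slack)
  }
})
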