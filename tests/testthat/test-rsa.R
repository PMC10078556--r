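# Core listener/speaker operations on the N = 3 letters-and-checks scenario

up3 <- world_prior(3)

test_that("literal listener restricts and renormalizes the prior", {
  cases <- list(
    list(meaning = 3L, expected = c(0, 0, 0, 1)),          # "all"
    list(meaning = 1:3, expected = c(0, 1, 1, 1) / 3),     # "some"
    list(meaning = 2:3, expected = c(0, 0, 1, 1) / 2)      # lower-bounded "two"
  )
  for (cs in cases) {
    l0 <- literal_listener(up3, cs$meaning)
    expect_equal(l0$prob, cs$expected, tolerance = 1e-12)
    expect_equal(sum(l0$prob), 1, tolerance = 1e-12)
  }
  # nonuniform prior: weights proportional to prior inside the meaning
  skewed <- world_prior(3, c(0.1, 0.2, 0.3, 0.4))
  expect_equal(literal_listener(skewed, 1:3)$prob, c(0, 2, 3, 4) / 9)
})

test_that("utterances with no prior mass are uninterpretable", {
  all_world <- world_prior(3, c(0, 0, 0, 1))
  expect_error(literal_listener(all_world, 0L),
               class = "altrsa_uninterpretable_utterance")
  # ... but a compatible utterance still works under a degenerate prior
  expect_equal(literal_listener(all_world, 1:3)$prob, c(0, 0, 0, 1))
})

test_that("speaker utility is the belief-weighted log score of the literal listener", {
  s_full3 <- knowledge_state(up3, access = 3, observed = 3)
  expect_identical(speaker_utility(s_full3, utterance("all", 3L), up3), 0)
  expect_equal(speaker_utility(s_full3, utterance("some", 1:3), up3), log(1 / 3))
  # "all" is false at world 2, which the partial speaker entertains
  s_part <- knowledge_state(up3, access = 2, observed = 2)
  expect_identical(speaker_utility(s_part, utterance("all", 3L), up3), -Inf)
})

test_that("softmax speaker matches hand-renormalized weights", {
  s_full3 <- knowledge_state(up3, access = 3, observed = 3)
  # alpha = 1: weights 1 ("all") and 1/3 ("some"), "none" unassertable
  d1 <- speaker_distribution(s_full3, alt_set(3), up3, alpha = 1)
  expect_equal(d1$prob[d1$label == "all"], 3 / 4)
  expect_equal(d1$prob[d1$label == "some"], 1 / 4)
  expect_identical(d1$prob[d1$label == "none"], 0)
  expect_false(is_mute(d1))
  # alpha = 3: weights 1 and (1/3)^3
  d3 <- speaker_distribution(s_full3, alt_set(3), up3, alpha = 3)
  expect_equal(d3$prob[d3$label == "some"], 1 / 28)
  # alpha = 0: uniform over assertable utterances only
  d0 <- speaker_distribution(s_full3, alt_set(3), up3, alpha = 0)
  expect_equal(sort(d0$prob), c(0, 0.5, 0.5))
})

test_that("a state where nothing is assertable is flagged mute", {
  # examined 2 of 3, saw 0 with the property: "none" false at world 1,
  # "some" false at world 0, "all" false everywhere in the support
  s0 <- knowledge_state(up3, access = 2, observed = 0)
  d <- speaker_distribution(s0, alt_set(3), up3, alpha = 1)
  expect_true(is_mute(d))
  expect_identical(d$prob, rep(0, 3))
  # numerals do not help: they all exclude world 0 too
  expect_true(is_mute(speaker_distribution(s0, alt_set(3, "with_numerals"), up3, 1)))
})

test_that("observation model is hypergeometric subset sampling", {
  # all three objects have the property: both examined ones must show it
  o1 <- observation_model(3, world = 3, access = 2)
  expect_equal(o1$prob[o1$observed == 2], 1)
  # full access pins the observation to the world
  o2 <- observation_model(3, world = 2, access = 3)
  expect_identical(o2$observed, 2L)
  expect_equal(o2$prob, 1)
  # 1 of 3 objects has it, 2 examined: C(3,2) = 3 subsets, 2 contain it
  o3 <- observation_model(3, world = 1, access = 2)
  expect_equal(o3$prob[o3$observed == 1], 2 / 3)
  expect_equal(o3$prob[o3$observed == 0], 1 / 3)
  expect_equal(sum(o3$prob), 1, tolerance = 1e-12)
  expect_error(observation_model(3, world = 4, access = 2),
               class = "altrsa_validation_error")
})

test_that("knowledge states carry the Bayesian posterior over the support", {
  s1 <- knowledge_state(up3, access = 3, observed = 2)
  expect_identical(s1$support, 2L)
  expect_equal(s1$belief$prob, 1)
  # saw 2 of 2: worlds {2, 3} with likelihoods 1/3 and 1
  s2 <- knowledge_state(up3, access = 2, observed = 2)
  expect_identical(s2$support, 2:3)
  expect_equal(s2$belief$prob, c(1 / 4, 3 / 4))
  # saw 1 of 2: worlds {1, 2} with equal likelihood 2/3
  s3 <- knowledge_state(up3, access = 2, observed = 1)
  expect_equal(s3$belief$prob, c(1 / 2, 1 / 2))
})

test_that("pragmatic listener reproduces the hand-enumerated posteriors", {
  cfg <- rsa_config(alpha = 3)
  # full knowledge, no numerals: worlds 1,2 weight 1 each, world 3 weight 1/28
  expect_equal(prob_not_all(pragmatic_listener(cfg, access = 3)),
               56 / 57, tolerance = 1e-12)
  # partial knowledge, no numerals: "some" is the only assertable utterance
  # in every non-mute state, so the posterior is prior x reachability
  expect_equal(prob_not_all(pragmatic_listener(cfg, access = 2)),
               5 / 8, tolerance = 1e-12)
  # partial knowledge, numerals available: S1(some | saw 2 of 2) = 8/43
  expect_equal(prob_not_all(pragmatic_listener(cfg, access = 2, p_with_numerals = 1)),
               47 / 59, tolerance = 1e-12)
  # full knowledge, numerals available
  expect_equal(prob_not_all(pragmatic_listener(cfg, access = 3, p_with_numerals = 1)),
               0.9760387, tolerance = 1e-6)
})

test_that("unproducible utterances and mixture preconditions raise errors", {
  cfg <- rsa_config(alpha = 1)
  # a numeral can only be heard if the with-numerals set has weight 1
  expect_error(pragmatic_listener(cfg, access = 2, utt = "two", p_with_numerals = 0.5),
               class = "altrsa_validation_error")
  # under a prior with all mass on world 0, nobody would ever say "some"
  zero_cfg <- rsa_config(prior = c(1, 0, 0, 0))
  expect_error(pragmatic_listener(zero_cfg, access = 3, utt = "some"),
               class = "altrsa_unproducible_utterance")
})

test_that("prob_not_all is the complement of the all-world cell", {
  expect_equal(prob_not_all(tibble::tibble(world = 0:3, prob = c(0, 0, 0, 1))), 0)
  expect_equal(prob_not_all(tibble::tibble(world = 0:3, prob = c(1, 0, 0, 0))), 1)
  expect_equal(prob_not_all(tibble::tibble(world = 0:3, prob = c(0, 1, 1, 1) / 3)),
               2 / 3, tolerance = 1e-12)
})

test_that("condition table crosses knowledgeability with the two alternative sets", {
  tab <- predict_condition_table(rsa_config(alpha = 3))
  expect_s3_class(tab, "rsa_prediction_table")
  expect_identical(nrow(tab), 4L)
  cell <- function(k, a) tab$p_not_all[tab$knowledgeability == k & tab$alternatives == a]
  expect_equal(cell("partial", "no_numerals"), 5 / 8, tolerance = 1e-12)
  expect_equal(cell("partial", "with_numerals"), 47 / 59, tolerance = 1e-12)
  # both full-knowledge cells round to 98%
  expect_identical(tab$percent[tab$knowledgeability == "full"], c(98, 98))
  # partial cell with numerals exceeds the one without
  expect_gt(cell("partial", "with_numerals"), cell("partial", "no_numerals"))
})

test_that("sweep agrees with single-point predictions and orders rows deterministically", {
  cfg <- rsa_config(alpha = 3)
  sw <- rsa_sweep(cfg, alpha = 3, p_with_numerals = c(0, 1))
  tab <- predict_condition_table(cfg)
  for (k in c("partial", "full")) {
    for (p in c(0, 1)) {
      a <- if (p == 1) "with_numerals" else "no_numerals"
      expect_equal(
        sw$p_not_all[sw$knowledgeability == k & sw$p_with_numerals == p],
        tab$p_not_all[tab$knowledgeability == k & tab$alternatives == a],
        tolerance = 1e-12
      )
    }
  }
  sw2 <- rsa_sweep(cfg, alpha = 3, p_with_numerals = c(0, 1))
  expect_identical(sw, sw2)
  expect_error(rsa_sweep(cfg, alpha = numeric(0)), class = "altrsa_validation_error")
})
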