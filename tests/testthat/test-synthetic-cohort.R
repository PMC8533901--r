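test_that("trait generator reproduces the requested correlation structure", {
  set.seed(101)
  cfg_id <- cohort_config(n_subjects = 10000, trait_corr = diag(5))
  ph <- simulate_traits(cfg_id)
  dims <- neo_dimensions()
  C <- cor(as.matrix(ph[, dims]), method = "spearman")
  expect_lt(max(abs(C[upper.tri(C)])), 0.05)

  set.seed(102)
  ph2 <- simulate_traits(cohort_config(n_subjects = 10000))
  expect_equal(cor(ph2$extraversion, ph2$openness, method = "spearman"),
               0.48, tolerance = 0.03 / 0.48)
  # T-scale location and scale
  expect_equal(mean(ph2$neuroticism), 50, tolerance = 0.02)
  expect_equal(sd(ph2$neuroticism), 10, tolerance = 0.02)
})

test_that("facets load on their parent dimension", {
  set.seed(103)
  ph <- simulate_traits(cohort_config(n_subjects = 500, facet_loading = 1))
  expect_equal(cor(ph$n5_impulsiveness, ph$neuroticism, method = "spearman"), 1)
  expect_equal(cor(ph$o2_aesthetics, ph$openness, method = "spearman"), 1)

  set.seed(104)
  ph <- simulate_traits(cohort_config(n_subjects = 2000, facet_loading = 0.7))
  for (f in c("n1_anxiety", "e3_assertiveness", "c6_deliberation")) {
    parent <- switch(substr(f, 1, 1), n = "neuroticism", e = "extraversion",
                     c = "conscientiousness")
    expect_gt(cor(ph[[f]], ph[[parent]]), 0.5)
  }
})

test_that("degenerate chain parameters give an absorbing A1 course", {
  cfg <- cohort_config(
    n_segments = 300,
    markov = markov_params(p_down_base = 0, p_up_deep = 0, p_up_wake = 0,
                           drift_per_min = 0, start_p_wake = 0)
  )
  set.seed(105)
  s <- simulate_vigilance_course(0, cfg)
  expect_true(all(s$stage == "A1"))
  expect_equal(nrow(s), 300)
})

test_that("courses start awake and decline faster for higher propensities", {
  cfg <- cohort_config()
  set.seed(106)
  first_stage_wake <- replicate(200, {
    simulate_vigilance_course(rnorm(1), cfg)$vigilance[1] %in% 6:7
  })
  expect_gte(mean(first_stage_wake), 0.9)

  set.seed(107)
  declined <- replicate(200, {
    s <- simulate_vigilance_course(2, cfg)$vigilance
    mean(s[901:1200]) < mean(s[1:300])
  })
  expect_gte(mean(declined), 0.95)
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- cohort_config(n_subjects = 15, seed = 77, n_segments = 240)
  a <- simulate_cohort(cfg, features = TRUE)
  b <- simulate_cohort(cfg, features = TRUE)
  expect_identical(a$stages, b$stages)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$features, b$features)
  expect_identical(a$manifest$config_hash, b$manifest$config_hash)

  set.seed(41)
  c1 <- simulate_vigilance_course(0.5, cfg)
  set.seed(41)
  c2 <- simulate_vigilance_course(0.5, cfg)
  expect_identical(c1, c2)
})

test_that("null effects produce null trait-metric correlations", {
  cfg <- cohort_config(
    n_subjects = 10000, seed = 201,
    effect_vector = c(neuroticism = 0, extraversion = 0, openness = 0,
                      agreeableness = 0, conscientiousness = 0),
    age_effect = 0, daytime_effect = 0
  )
  co <- simulate_cohort(cfg)
  s <- summarize_cohort(co)
  for (tr in neo_dimensions()) {
    expect_lt(abs(cor(co$phenotypes[[tr]], s$slope_index,
                      method = "spearman")), 0.05)
  }
})

test_that("a configured effect shows up in the realised cohort", {
  co <- simulate_cohort(cohort_config(seed = 11))
  s <- summarize_cohort(co)
  rho <- cor(co$phenotypes$openness, s$slope_index, method = "spearman")
  expect_equal(rho, -0.17, tolerance = 0.09 / 0.17)
})

test_that("invalid configurations are rejected with informative errors", {
  bad_corr <- diag(5)
  bad_corr[1, 2] <- bad_corr[2, 1] <- 0.99
  bad_corr[1, 3] <- bad_corr[3, 1] <- 0.99
  bad_corr[2, 3] <- bad_corr[3, 2] <- -0.99
  expect_error(cohort_config(trait_corr = bad_corr), "positive semi-definite")
  expect_error(cohort_config(n_segments = 30), "at least 60")
  expect_error(cohort_config(effect_vector = rep(1.2, 5)), "inside \\(-1, 1\\)")
  # opposite-signed effects on two strongly correlated traits imply a
  # near-deterministic propensity model
  expect_error(
    simulate_cohort(cohort_config(
      n_subjects = 20,
      effect_vector = c(neuroticism = 0, extraversion = 0.6,
                        openness = -0.62, agreeableness = 0,
                        conscientiousness = 0),
      age_effect = 0, daytime_effect = 0,
      markov = markov_params(slope_attenuation = 1)
    )),
    "multiple correlation"
  )
})

test_that("default summary distributions stay in plausible cohort ranges", {
  # Bands are the observed Min/Max of a large reference cohort; the
  # generator should keep >= 99% of subjects inside each.
  co <- simulate_cohort(cohort_config(n_subjects = 5000, seed = 301))
  s <- summarize_cohort(co)
  expect_gte(mean(s$mean_vigilance >= 1.93 & s$mean_vigilance <= 6.76), 0.99)
  expect_gte(mean(s$slope_index >= -4.26 & s$slope_index <= 0.73), 0.99)
  expect_true(all(s$stability_score >= 1 & s$stability_score <= 14))
})

test_that("noise-free features satisfy their defining staging rules", {
  cfg <- cohort_config(feature_noise = 0)
  f <- simulate_features_from_stages(stage_to_vigilance(c("A1", "C")), cfg)
  # A1: occipital alpha dominant and at least twice its delta+theta
  expect_true(f$alpha_o[1] > max(f$alpha_p[1], f$alpha_t[1], f$alpha_f[1]))
  expect_gte(f$alpha_o[1], 2 * f$dt_o[1])
  # C: graph-element flag set
  expect_true(f$graph[2])
  expect_error(
    simulate_features_from_stages(
      1:7, cohort_config(feature_templates =
        default_feature_templates()[1:5, ])),
    "must contain all seven stages"
  )
})
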