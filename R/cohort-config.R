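#' Names of the Big Five dimensions and the thirty NEO facets
#'
#' Facet names follow the NEO-PI-R, prefixed with the parent dimension and
#' facet number (e.g. `n5_impulsiveness`, `o2_aesthetics`).
#'
#' @return Character vectors of column names used by the phenotype table.
#' @export
neo_dimensions <- function() {
  c("neuroticism", "extraversion", "openness", "agreeableness", "conscientiousness")
}

#' @rdname neo_dimensions
#' @export
neo_facets <- function() {
  facets <- list(
    n = c("anxiety", "angry_hostility", "depression", "self_consciousness",
          "impulsiveness", "vulnerability"),
    e = c("warmth", "gregariousness", "assertiveness", "activity",
          "excitement_seeking", "positive_emotions"),
    o = c("fantasy", "aesthetics", "feelings", "actions", "ideas", "values"),
    a = c("trust", "straightforwardness", "altruism", "compliance",
          "modesty", "tender_mindedness"),
    c = c("competence", "order", "dutifulness", "achievement_striving",
          "self_discipline", "deliberation")
  )
  unlist(lapply(names(facets), function(p) {
    paste0(p, seq_along(facets[[p]]), "_", facets[[p]])
  }))
}

#' Default correlation matrix of the Big Five dimension T-scores
#'
#' Extraversion-openness is set to 0.48, the dominant intercorrelation
#' observed in large adult cohorts; the remaining entries are modest values
#' typical of NEO-PI-R norm samples (neuroticism mildly negative with the
#' other four).
#'
#' @return A symmetric positive-definite 5x5 correlation matrix with
#'   dimnames from [neo_dimensions()].
#' @export
default_trait_correlations <- function() {
  dims <- neo_dimensions()
  R <- diag(5)
  dimnames(R) <- list(dims, dims)
  set_pair <- function(R, a, b, v) {
    R[a, b] <- v
    R[b, a] <- v
    R
  }
  R <- set_pair(R, "neuroticism", "extraversion", -0.25)
  R <- set_pair(R, "neuroticism", "openness", -0.05)
  R <- set_pair(R, "neuroticism", "agreeableness", -0.15)
  R <- set_pair(R, "neuroticism", "conscientiousness", -0.25)
  R <- set_pair(R, "extraversion", "openness", 0.48)
  R <- set_pair(R, "extraversion", "agreeableness", 0.15)
  R <- set_pair(R, "extraversion", "conscientiousness", 0.20)
  R <- set_pair(R, "openness", "agreeableness", 0.10)
  R <- set_pair(R, "openness", "conscientiousness", 0.05)
  R <- set_pair(R, "agreeableness", "conscientiousness", 0.15)
  R
}

#' Parameters of the arousal-decline Markov chain
#'
#' The generator models each recording as a discrete-time Markov chain over
#' the numeric vigilance codes 7..1 with single-step moves. Each second, a
#' segment moves one stage down with probability
#' `min(cap, p_down_base * exp(propensity_scale * squash(d)) * (1 + drift_per_min * minutes))`
#' where `d` is the subject's standardised decline propensity and
#' `squash(d) = squash_range * tanh(d / squash_range)` bounds the hazard
#' multiplier smoothly (strictly monotone, so subject ranks are preserved).
#' Recovery moves one stage up with probability `p_up_deep` from drowsiness
#' stages and `p_up_wake` from A1 into stage 0; post-task active wakefulness
#' decays with at least `wake_decay` per second. Recordings start in stage 0
#' with probability `start_p_wake` and otherwise in A1.
#'
#' `slope_attenuation` is the calibration constant linking requested effect
#' sizes to latent-scale correlations: the chain's stochasticity attenuates
#' the Spearman correlation between the latent propensity and the realised
#' slope index, so [simulate_cohort()] divides requested trait effects by
#' this constant. The default was estimated by large-scale simulation under
#' the default chain; re-estimate with [estimate_slope_attenuation()] if you
#' change the dynamics.
#'
#' @param p_down_base Baseline per-second downward transition probability.
#' @param propensity_scale Log-hazard scale of the decline propensity.
#' @param squash_range Soft bound (in SD units) on the propensity multiplier.
#' @param drift_per_min Linear growth rate of the downward hazard per elapsed
#'   minute.
#' @param p_up_deep Per-second recovery probability from stages B1 and below.
#' @param p_up_wake Per-second probability of re-entering stage 0 from A1.
#' @param cap Upper bound on the per-second downward hazard.
#' @param wake_decay Minimum per-second descent probability out of stage 0.
#' @param start_p_wake Probability of starting the recording in stage 0
#'   (otherwise A1).
#' @param slope_attenuation Calibration constant in (0, 1]; see Details.
#' @return A list of class `markov_params`.
#' @export
markov_params <- function(p_down_base = 0.0013,
                          propensity_scale = 0.9,
                          squash_range = 1.5,
                          drift_per_min = 0.15,
                          p_up_deep = 0.002,
                          p_up_wake = 2e-4,
                          cap = 0.01,
                          wake_decay = 0.01,
                          start_p_wake = 0.05,
                          slope_attenuation = 0.636) {
  p <- list(
    p_down_base = p_down_base, propensity_scale = propensity_scale,
    squash_range = squash_range, drift_per_min = drift_per_min,
    p_up_deep = p_up_deep, p_up_wake = p_up_wake, cap = cap,
    wake_decay = wake_decay, start_p_wake = start_p_wake,
    slope_attenuation = slope_attenuation
  )
  probs <- c("p_down_base", "p_up_deep", "p_up_wake", "cap", "wake_decay",
             "start_p_wake")
  for (nm in probs) {
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1) {
      stop("markov_params: `", nm, "` must be a probability in [0, 1]")
    }
  }
  if (p$propensity_scale < 0 || p$squash_range <= 0 || p$drift_per_min < 0) {
    stop("markov_params: scale and drift parameters must be non-negative")
  }
  if (p$slope_attenuation <= 0 || p$slope_attenuation > 1) {
    stop("markov_params: `slope_attenuation` must be in (0, 1]")
  }
  structure(p, class = "markov_params")
}

#' Per-stage feature templates for synthetic EEG current densities
#'
#' Mean regional alpha and delta+theta current densities (arbitrary units)
#' plus EOG / graph-element flags for each of the seven vigilance stages.
#' Templates are built to satisfy the staging rules exactly in the noise-free
#' limit: A1 occipital-dominant alpha, A2 parietal, A3 frontal; B2/3
#' delta-theta dominant; B1 low-voltage with slow eye movements; C flagged
#' with spindles/K-complexes. Active wakefulness (stage 0) is desynchronised
#' *low-amplitude* activity - its alpha sits below even the B1 level - which
#' keeps the 0/B1 distinction robust in recordings with little total alpha.
#'
#' @return A tibble with one row per stage and columns `stage`, `alpha_o`,
#'   `alpha_p`, `alpha_t`, `alpha_f`, `dt_o`, `dt_p`, `dt_t`, `dt_f`,
#'   `sem`, `graph`.
#' @export
default_feature_templates <- function() {
  tibble::tribble(
    ~stage, ~alpha_o, ~alpha_p, ~alpha_t, ~alpha_f, ~dt_o, ~dt_p, ~dt_t, ~dt_f, ~sem, ~graph,
    "0",    3.5, 3.5, 3.5, 3.5,   2,   2,   2,   2, FALSE, FALSE,
    "A1",    30, 12, 10,  8,   5,   5,   5,   5, FALSE, FALSE,
    "A2",    14, 28, 10,  7,   5,   5,   5,   5, FALSE, FALSE,
    "A3",    10, 12, 10, 22,   5,   5,   5,   5, FALSE, FALSE,
    "B1",     4,  4,  4,  4, 5.5, 5.5, 5.5, 5.5,  TRUE, FALSE,
    "B2/3",   3,  3,  3,  3,  12,  12,  12,  12, FALSE, FALSE,
    "C",      2,  2,  2,  2,  10,  10,  10,  10, FALSE,  TRUE
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles every tunable of the generator: cohort size, trait correlation
#' structure, the effect sizes linking traits and covariates to the latent
#' arousal-decline propensity, the recording length, the Markov chain
#' parameters and the per-stage feature templates.
#'
#' Effect sizes are expressed on the scale of the *realised* Spearman
#' correlation between the trait and the slope index at large n (negative =
#' higher trait, steeper vigilance decline). Defaults emulate a large adult
#' resting-EEG cohort: openness -0.17, extraversion -0.14, older age
#' shallower decline (0.168), later daytime steeper decline (-0.155).
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed recorded in the manifest and used by
#'   [simulate_cohort()].
#' @param trait_corr 5x5 correlation matrix of the dimension T-scores.
#' @param trait_mean,trait_sd Location/scale of the T-scores.
#' @param facet_loading Loading in (0, 1] of each facet on its parent
#'   dimension.
#' @param effect_vector Named vector of 5 trait effects in (-1, 1).
#' @param age_effect,daytime_effect,sex_effect Covariate effects in (-1, 1)
#'   on the same scale (sign = direction of association with vigilance
#'   metrics).
#' @param age_range Integer range of ages (years).
#' @param daytime_slots EEG assessment start times in hours.
#' @param prob_female Probability of `sex = "female"`.
#' @param n_segments Recording length in seconds (default 1200 = 20 min).
#' @param artifact_rate Per-second probability of an artifact segment.
#' @param markov A [markov_params()] object.
#' @param feature_templates Per-stage feature template tibble.
#' @param feature_noise Noise SD as a fraction of each template mean.
#' @param round_t_scores Round T-scores to integers (as normed inventories
#'   print them)? Default `FALSE` to preserve rank statistics.
#' @return A list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 50, seed = 7)
#' cfg$effect_vector
cohort_config <- function(n_subjects = 468,
                          seed = 1L,
                          trait_corr = default_trait_correlations(),
                          trait_mean = 50,
                          trait_sd = 10,
                          facet_loading = 0.7,
                          effect_vector = c(neuroticism = 0, extraversion = -0.14,
                                            openness = -0.17, agreeableness = 0,
                                            conscientiousness = 0),
                          age_effect = 0.168,
                          daytime_effect = -0.155,
                          sex_effect = 0,
                          age_range = c(40L, 79L),
                          daytime_slots = c(8.5, 11.0, 13.5),
                          prob_female = 0.526,
                          n_segments = 1200L,
                          artifact_rate = 0.02,
                          markov = markov_params(),
                          feature_templates = default_feature_templates(),
                          feature_noise = 0.2) {
  dims <- neo_dimensions()
  trait_corr <- as.matrix(trait_corr)
  if (!all(dim(trait_corr) == c(5, 5)) ||
      max(abs(trait_corr - t(trait_corr))) > 1e-8 ||
      any(abs(diag(trait_corr) - 1) > 1e-8)) {
    stop("`trait_corr` must be a symmetric 5x5 matrix with unit diagonal")
  }
  ev <- eigen(trait_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("`trait_corr` is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), "); offending matrix:\n",
         paste(utils::capture.output(print(round(trait_corr, 3))), collapse = "\n"))
  }
  if (is.null(names(effect_vector))) names(effect_vector) <- dims
  effect_vector <- effect_vector[dims]
  if (anyNA(effect_vector)) {
    stop("`effect_vector` must be named by the five NEO dimensions")
  }
  if (any(abs(effect_vector) >= 1) || abs(age_effect) >= 1 ||
      abs(daytime_effect) >= 1 || abs(sex_effect) >= 1) {
    stop("all effects must lie strictly inside (-1, 1)")
  }
  if (facet_loading <= 0 || facet_loading > 1) {
    stop("`facet_loading` must lie in (0, 1]")
  }
  if (n_segments < 60) stop("`n_segments` must be at least 60")
  if (artifact_rate < 0 || artifact_rate >= 0.5) {
    stop("`artifact_rate` must lie in [0, 0.5)")
  }
  if (!inherits(markov, "markov_params")) {
    stop("`markov` must be created by markov_params()")
  }
  needed <- c("stage", "alpha_o", "alpha_p", "alpha_t", "alpha_f",
              "dt_o", "dt_p", "dt_t", "dt_f", "sem", "graph")
  if (!all(needed %in% names(feature_templates)) ||
      !all(stage_levels() %in% feature_templates$stage)) {
    stop("`feature_templates` must contain all seven stages and columns: ",
         paste(needed, collapse = ", "))
  }
  structure(list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    trait_corr = trait_corr, trait_mean = trait_mean, trait_sd = trait_sd,
    facet_loading = facet_loading, effect_vector = effect_vector,
    age_effect = age_effect, daytime_effect = daytime_effect,
    sex_effect = sex_effect, age_range = as.integer(age_range),
    daytime_slots = daytime_slots, prob_female = prob_female,
    n_segments = as.integer(n_segments), artifact_rate = artifact_rate,
    markov = markov, feature_templates = feature_templates,
    feature_noise = feature_noise,
    round_t_scores = FALSE
  ), class = "cohort_config")
}

#' Read a cohort configuration from a YAML file
#'
#' Scalar fields of the YAML override the defaults of [cohort_config()];
#' `markov:` entries override [markov_params()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  mk <- do.call(markov_params, y$markov %||% list())
  y$markov <- NULL
  if (!is.null(y$effect_vector)) y$effect_vector <- unlist(y$effect_vector)
  if (!is.null(y$trait_corr)) y$trait_corr <- matrix(unlist(y$trait_corr), 5, 5)
  do.call(cohort_config, c(y, list(markov = mk)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
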