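#' Simulate correlated Big Five T-scores and covariates
#'
#' Dimension scores are drawn multivariate normal on the latent scale with
#' the configured correlation matrix, then affinely mapped to the T-scale
#' (nominal mean 50, SD 10). Each of the six facets per dimension loads on
#' its parent dimension's latent score with loading `facet_loading` plus
#' independent noise. Sex, age and the EEG daytime slot are drawn
#' independently of the traits.
#'
#' Uses the session RNG; call `set.seed()` (or use [simulate_cohort()], which
#' seeds from the config) for reproducibility.
#'
#' @param config A [cohort_config()] object.
#' @return A tibble with one row per subject: `subject_id`, `sex`, `age`,
#'   `daytime`, the five dimension T-scores and the thirty facet T-scores.
#' @export
#' @examples
#' set.seed(1)
#' ph <- simulate_traits(cohort_config(n_subjects = 100))
#' cor(ph$extraversion, ph$openness)
simulate_traits <- function(config) {
  sim_phenotypes(config)$phenotypes
}

# Internal: phenotypes plus the latent standard-normal scores needed to
# construct the decline propensity.
sim_phenotypes <- function(config) {
  n <- config$n_subjects
  dims <- neo_dimensions()
  z <- MASS::mvrnorm(n, mu = rep(0, 5), Sigma = config$trait_corr)
  if (n == 1) z <- matrix(z, nrow = 1)
  colnames(z) <- dims
  tscale <- function(x) config$trait_mean + config$trait_sd * x
  traits <- tibble::as_tibble(tscale(z))

  lam <- config$facet_loading
  facet_names <- neo_facets()
  parent <- rep(dims, each = 6)
  fz <- lam * z[, parent, drop = FALSE] +
    sqrt(1 - lam^2) * matrix(rnorm(n * 30), n, 30)
  colnames(fz) <- facet_names
  facets <- tibble::as_tibble(tscale(fz))

  if (isTRUE(config$round_t_scores)) {
    traits <- dplyr::mutate(traits, dplyr::across(dplyr::everything(), round))
    facets <- dplyr::mutate(facets, dplyr::across(dplyr::everything(), round))
  }

  sex <- ifelse(runif(n) < config$prob_female, "female", "male")
  age <- sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)
  daytime <- sample(config$daytime_slots, n, replace = TRUE)

  phenotypes <- dplyr::bind_cols(
    tibble::tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      sex = sex, age = age, daytime = daytime
    ),
    traits, facets
  )
  list(phenotypes = phenotypes, z_traits = z)
}

# Standardise a covariate empirically; constant vectors map to zero.
std0 <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Internal: latent decline propensity d ~ N(0,1) with the requested
# correlations to traits and covariates. Requested effects are on the
# realised trait-slope scale; division by the chain's slope_attenuation
# de-attenuates them to the latent scale.
sim_decline_propensity <- function(config, z_traits, phenotypes) {
  att <- config$markov$slope_attenuation
  # negative effect on vigilance metrics = positive loading on decline
  target <- c(-config$effect_vector,
              sex = -config$sex_effect,
              age = -config$age_effect,
              daytime = -config$daytime_effect) / att
  if (any(abs(target) >= 1)) {
    stop("de-attenuated effect |", signif(max(abs(target)), 3),
         "| >= 1; reduce effect sizes or use a less noisy chain")
  }
  S <- diag(8)
  S[1:5, 1:5] <- config$trait_corr
  w <- solve(S, target)
  r2 <- sum(target * w)
  if (r2 >= 0.95) {
    stop("effect_vector and covariate effects imply a multiple correlation ",
         "of ", signif(sqrt(r2), 3), " with the decline propensity; ",
         "the implied model is (nearly) deterministic")
  }
  n <- nrow(z_traits)
  zc <- cbind(
    std0(as.numeric(phenotypes$sex == "female")),
    std0(phenotypes$age),
    std0(phenotypes$daytime)
  )
  drop(cbind(z_traits, zc) %*% w) + sqrt(1 - r2) * rnorm(n)
}

# Internal: simulate the arousal-decline Markov chain for a vector of
# decline propensities. Returns an n x n_segments integer matrix of
# vigilance codes 7..1.
sim_stage_matrix <- function(d, config) {
  mk <- config$markov
  n <- length(d)
  T <- config$n_segments
  s <- ifelse(runif(n) < mk$start_p_wake, 7L, 6L)
  M <- matrix(0L, n, T)
  squash <- mk$squash_range * tanh(d / mk$squash_range)
  base <- mk$p_down_base * exp(mk$propensity_scale * squash)
  for (t in seq_len(T)) {
    m <- (t - 1) / 60
    pd <- pmin(mk$cap, base * (1 + mk$drift_per_min * m))
    pd <- ifelse(s == 7L, pmax(pd, mk$wake_decay), pd)
    pu <- ifelse(s >= 6L, mk$p_up_wake, mk$p_up_deep)
    u <- runif(n)
    down <- u < pd & s > 1L
    up <- u > 1 - pu & s < 7L
    s <- s - as.integer(down) + as.integer(up)
    M[, t] <- s
  }
  M
}

#' Simulate one recording's per-second vigilance course
#'
#' Runs the arousal-decline Markov chain (see [markov_params()]) for a single
#' subject with the given standardised decline propensity. The recording
#' starts in active or relaxed wakefulness (stage 0 or A1); higher decline
#' propensities produce stochastically lower late-course stages.
#'
#' Uses the session RNG.
#'
#' @param decline_propensity Standardised decline propensity (0 = cohort
#'   average; positive = steeper decline).
#' @param config A [cohort_config()] object.
#' @return A [stage_sequence()] tibble of length `config$n_segments`.
#' @export
#' @examples
#' set.seed(2)
#' seq <- simulate_vigilance_course(1.5, cohort_config(n_segments = 300))
#' table(seq$stage)
simulate_vigilance_course <- function(decline_propensity, config) {
  stopifnot(length(decline_propensity) == 1, is.finite(decline_propensity))
  codes <- sim_stage_matrix(decline_propensity, config)[1, ]
  stage_sequence(codes)
}

#' Simulate segment-level EEG features from a stage sequence
#'
#' Inverts the staging model: each segment's regional alpha and delta+theta
#' current densities are drawn around the per-stage template means with
#' Gaussian noise of SD `feature_noise` times the mean (truncated at zero);
#' slow-eye-movement and graph-element flags are taken from the template.
#' With `feature_noise = 0` the features satisfy the corresponding staging
#' rules exactly, so [stage_recording()] recovers every label.
#'
#' @param stages A [stage_sequence()] tibble or a vector of vigilance codes
#'   (7..1).
#' @param config A [cohort_config()] object (templates and noise level).
#' @return A feature tibble with columns `second`, `alpha_o`, `alpha_p`,
#'   `alpha_t`, `alpha_f`, `dt_o`, `dt_p`, `dt_t`, `dt_f`, `sem`, `graph`,
#'   `artifact`.
#' @export
simulate_features_from_stages <- function(stages, config) {
  v <- as_vigilance(stages)
  labels <- vigilance_to_stage(v$vigilance)
  tpl <- config$feature_templates
  idx <- match(labels, tpl$stage)
  if (any(is.na(idx) & !v$artifact)) {
    stop("no feature template defined for stage(s): ",
         paste(unique(labels[is.na(idx) & !v$artifact]), collapse = ", "))
  }
  # artifact segments still get (meaningless) feature rows from stage A1
  idx[is.na(idx)] <- match("A1", tpl$stage)
  dens_cols <- c("alpha_o", "alpha_p", "alpha_t", "alpha_f",
                 "dt_o", "dt_p", "dt_t", "dt_f")
  n <- length(idx)
  out <- lapply(dens_cols, function(cl) {
    mu <- tpl[[cl]][idx]
    pmax(mu + config$feature_noise * mu * rnorm(n), 0)
  })
  names(out) <- dens_cols
  tibble::tibble(
    second = seq_len(n) - 1L,
    !!!out,
    sem = tpl$sem[idx],
    graph = tpl$graph[idx],
    artifact = v$artifact
  )
}

#' Simulate a complete synthetic cohort
#'
#' Composition of the generator: correlated trait and facet T-scores,
#' covariates, a latent decline propensity with the configured trait and
#' covariate correlations, one per-second vigilance course per subject, and
#' (optionally) segment-level feature tables. Artifact segments are injected
#' at rate `config$artifact_rate`. Everything is seeded from `config$seed`
#' and the returned manifest records the seed and a hash of the
#' configuration, so identical configs yield identical cohorts.
#'
#' @param config A [cohort_config()] object.
#' @param features Also simulate per-subject feature tables? (Slower; only
#'   needed to exercise the staging classifier.)
#' @return An object of class `vigicor_cohort`: a list with elements
#'   `phenotypes` (tibble), `stages` (n_subjects x n_segments integer matrix
#'   of vigilance codes), `artifacts` (logical matrix of the same shape),
#'   `features` (list of feature tibbles or `NULL`), `decline_propensity`,
#'   and `manifest`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_subjects = 20, seed = 42))
#' dim(cohort$stages)
simulate_cohort <- function(config, features = FALSE) {
  set.seed(config$seed)
  ph <- sim_phenotypes(config)
  d <- sim_decline_propensity(config, ph$z_traits, ph$phenotypes)
  M <- sim_stage_matrix(d, config)
  A <- matrix(runif(length(M)) < config$artifact_rate,
              nrow(M), ncol(M))
  feats <- NULL
  if (features) {
    feats <- lapply(seq_len(nrow(M)), function(i) {
      simulate_features_from_stages(
        stage_sequence(M[i, ], artifact = A[i, ]), config
      )
    })
    names(feats) <- ph$phenotypes$subject_id
  }
  structure(list(
    phenotypes = ph$phenotypes,
    stages = M,
    artifacts = A,
    features = feats,
    decline_propensity = d,
    manifest = list(
      seed = config$seed,
      config_hash = rlang::hash(config),
      n_subjects = config$n_subjects,
      n_segments = config$n_segments,
      created = "simulate_cohort"
    )
  ), class = "vigicor_cohort")
}

#' @export
print.vigicor_cohort <- function(x, ...) {
  cat("<vigicor_cohort> ", nrow(x$stages), " subjects x ", ncol(x$stages),
      " s (seed ", x$manifest$seed, ")\n", sep = "")
  invisible(x)
}

#' Stage sequences of a cohort in long (tidy) format
#'
#' @param cohort A `vigicor_cohort`.
#' @return A tibble with columns `subject_id`, `second`, `stage`,
#'   `vigilance`, `artifact` (artifact segments have `NA` stage).
#' @export
cohort_stage_long <- function(cohort) {
  n <- nrow(cohort$stages)
  T <- ncol(cohort$stages)
  vig <- as.integer(t(cohort$stages))
  art <- as.logical(t(cohort$artifacts))
  vig[art] <- NA_integer_
  tibble::tibble(
    subject_id = rep(cohort$phenotypes$subject_id, each = T),
    second = rep(seq_len(T) - 1L, times = n),
    stage = vigilance_to_stage(vig),
    vigilance = vig,
    artifact = art
  )
}

#' Estimate the chain's slope attenuation constant
#'
#' Simulates subjects whose latent trait correlates with the decline
#' propensity at a reference value and measures the realised Spearman
#' correlation between trait and slope index; the ratio realised/reference
#' is the attenuation constant consumed by [markov_params()]. Use this if
#' you change the chain dynamics.
#'
#' @param config A [cohort_config()] object (only the chain and recording
#'   length matter).
#' @param n Number of simulated subjects.
#' @param reference Latent-scale reference correlation.
#' @return The estimated attenuation constant in (0, 1).
#' @export
estimate_slope_attenuation <- function(config, n = 20000, reference = 0.25) {
  z <- rnorm(n)
  d <- reference * z + sqrt(1 - reference^2) * rnorm(n)
  M <- sim_stage_matrix(d, config)
  sl <- slope_index_matrix(M)
  -cor(z, sl, method = "spearman") / reference
}
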