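#' Configuration of the vigilance stage classifier
#'
#' @param a_ratio Factor by which a candidate ROI's alpha current density
#'   must exceed its delta+theta density for an A-stage (default 2).
#' @param threshold_quantile Fraction of artifact-free segments excluded
#'   from the top set of the adaptive threshold (default 0.9 = top decile).
#' @param threshold_scale Multiplier applied to the top-set mean occipital
#'   alpha (default 0.25).
#' @param dt_dominance_factor Factor by which mean delta+theta must exceed
#'   mean alpha for stage B2/3 (default 2).
#' @param b1_context_window Seconds of preceding stage history consulted for
#'   the B1 drowsiness-context rule (default 60).
#' @return A list of class `staging_config`.
#' @export
staging_config <- function(a_ratio = 2,
                           threshold_quantile = 0.9,
                           threshold_scale = 0.25,
                           dt_dominance_factor = 2,
                           b1_context_window = 60) {
  if (a_ratio <= 0 || threshold_scale <= 0 || dt_dominance_factor <= 0) {
    stop("staging_config: all factors must be strictly positive")
  }
  if (threshold_quantile <= 0 || threshold_quantile >= 1) {
    stop("staging_config: `threshold_quantile` must lie in (0, 1)")
  }
  if (b1_context_window < 1) {
    stop("staging_config: `b1_context_window` must be at least 1 s")
  }
  structure(list(
    a_ratio = a_ratio, threshold_quantile = threshold_quantile,
    threshold_scale = threshold_scale,
    dt_dominance_factor = dt_dominance_factor,
    b1_context_window = b1_context_window
  ), class = "staging_config")
}

alpha_cols <- c("alpha_o", "alpha_p", "alpha_t", "alpha_f")
dt_cols <- c("dt_o", "dt_p", "dt_t", "dt_f")

check_features <- function(table) {
  need <- c(alpha_cols, dt_cols)
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("feature table lacks column(s): ", paste(miss, collapse = ", "))
  }
  dens <- as.matrix(table[, need])
  if (any(!is.finite(dens)) || any(dens < 0)) {
    stop("current densities must be finite and non-negative")
  }
  invisible(table)
}

#' Individual adaptive A-stage threshold
#'
#' The absolute current-density threshold that an ROI's alpha must exceed
#' for an A-stage is set per individual: the mean occipital alpha current
#' density over the top `1 - threshold_quantile` fraction (default: top
#' decile) of artifact-free segments, scaled by `threshold_scale` (default
#' 0.25). This adaptive stand-in tracks each individual's alpha amplitude;
#' it is homogeneous of degree one, so rescaling all densities rescales the
#' threshold identically and stage labels are scale-invariant.
#'
#' @param table A feature tibble (see [simulate_features_from_stages()] for
#'   the column contract).
#' @param config A [staging_config()].
#' @return The threshold, a positive scalar in current-density units.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 1, seed = 3, n_segments = 120)
#' f <- simulate_features_from_stages(rep(6, 120), cfg)
#' compute_adaptive_threshold(f)
compute_adaptive_threshold <- function(table, config = staging_config()) {
  check_features(table)
  art <- if ("artifact" %in% names(table)) table$artifact else FALSE
  x <- table$alpha_o[!art]
  if (length(x) < 60) {
    stop("QC: fewer than 60 artifact-free segments (", length(x),
         "); cannot set an adaptive threshold")
  }
  k <- max(1L, ceiling((1 - config$threshold_quantile) * length(x)))
  top <- sort(x, decreasing = TRUE)[seq_len(k)]
  thr <- config$threshold_scale * mean(top)
  if (!is.finite(thr) || thr <= 0) {
    stop("adaptive threshold is not strictly positive; ",
         "check the occipital alpha channel")
  }
  thr
}

# Vectorised context-free part of the rule cascade. Returns stage labels,
# with NA_character_ for artifact segments and "" for segments whose 0/B1
# resolution needs the causal context pass.
classify_rows <- function(table, theta, config) {
  n <- nrow(table)
  A <- as.matrix(table[, alpha_cols])
  D <- as.matrix(table[, dt_cols])
  lab <- rep("", n)

  art <- if ("artifact" %in% names(table)) table$artifact else rep(FALSE, n)
  graph <- if ("graph" %in% names(table)) table$graph else rep(FALSE, n)

  # A-candidacy: any ROI with alpha >= theta and alpha >= a_ratio * its own
  # delta+theta. Sub-classification by alpha topography: occipital strictly
  # greatest -> A1; frontal >= occipital (anteriorised) -> A3; else A2.
  cand <- (A >= theta) & (A >= config$a_ratio * D)
  is_a <- rowSums(cand) > 0
  occ_top <- A[, 1] > pmax(A[, 2], A[, 3], A[, 4])
  ant <- A[, 4] >= A[, 1]
  lab[is_a & occ_top] <- "A1"
  lab[is_a & !occ_top & ant] <- "A3"
  lab[is_a & !occ_top & !ant] <- "A2"

  # delta+theta dominance -> B2/3
  dt_dom <- rowMeans(D) >= config$dt_dominance_factor * rowMeans(A)
  lab[!is_a & dt_dom] <- "B2/3"

  # segments that are already B1 irrespective of context:
  # residual (non-dominant) alpha above threshold, or elevated delta+theta.
  b1_sure <- !is_a & !dt_dom &
    (apply(A, 1, max) >= theta | rowMeans(D) >= rowMeans(A))
  sem <- if ("sem" %in% names(table)) table$sem else rep(FALSE, n)
  b1_sure <- b1_sure | (!is_a & !dt_dom & sem)
  lab[b1_sure] <- "B1"

  lab[graph] <- "C"          # sleep-onset graph elements override
  lab[art] <- NA_character_  # artifact: no stage
  lab
}

#' Classify a single EEG segment
#'
#' Applies the rule cascade to one segment: (1) artifact segments get no
#' stage; (2) a spindle/K-complex graph element forces stage C; (3) if some
#' ROI's alpha exceeds the individual threshold `theta` and is at least
#' `a_ratio` times its own delta+theta, the segment is an A-stage - A1 when
#' occipital alpha is strictly greatest, A3 when frontal alpha reaches
#' occipital (anteriorisation), A2 otherwise; (4) mean delta+theta at least
#' `dt_dominance_factor` times mean alpha gives B2/3; (5) otherwise B1 when
#' slow eye movements are present, when residual alpha still reaches
#' `theta`, when delta+theta exceeds alpha on average, or when a drowsiness
#' stage (B1, B2/3 or C) occurred within the preceding context window;
#' otherwise stage 0. Rule (5) makes the cascade monotone: increasing
#' delta+theta can never move a segment towards higher arousal.
#'
#' @param features A one-row feature tibble, or a named list/vector with the
#'   density columns and optional `sem`, `graph`, `artifact` flags.
#' @param theta The individual A-stage threshold (see
#'   [compute_adaptive_threshold()]).
#' @param context Character vector of recently assigned stage labels (the
#'   preceding `b1_context_window` seconds); used only for the 0/B1 rule.
#' @param config A [staging_config()].
#' @return A stage label, or `NA` for an artifact segment.
#' @export
#' @examples
#' seg <- list(alpha_o = 20, alpha_p = 8, alpha_t = 8, alpha_f = 8,
#'             dt_o = 5, dt_p = 5, dt_t = 5, dt_f = 5)
#' classify_segment(seg, theta = 10)
classify_segment <- function(features, theta, context = character(),
                             config = staging_config()) {
  if (!is.data.frame(features)) features <- tibble::as_tibble(as.list(features))
  stopifnot(nrow(features) == 1, is.finite(theta), theta > 0)
  check_features(features)
  lab <- classify_rows(features, theta, config)
  if (identical(lab, "")) {
    drowsy <- any(context %in% c("B1", "B2/3", "C"), na.rm = TRUE)
    lab <- if (drowsy) "B1" else "0"
  }
  lab
}

#' Stage a full recording
#'
#' Computes the individual adaptive threshold, classifies every segment with
#' the context-free rules, then resolves the 0-versus-B1 segments in a
#' single causal left-to-right pass: a segment within
#' `b1_context_window` seconds after an assigned drowsiness stage (B1, B2/3
#' or C) becomes B1, otherwise stage 0. Artifact segments are excluded
#' (missing stage) and do not contribute context.
#'
#' @param table A feature tibble, one row per second.
#' @param config A [staging_config()].
#' @return A [stage_sequence()] tibble.
#' @export
#' @examples
#' cfg <- cohort_config(seed = 5, n_segments = 300, feature_noise = 0)
#' truth <- rep(c(6, 5, 3), each = 100)
#' f <- simulate_features_from_stages(truth, cfg)
#' out <- stage_recording(f)
#' all(out$vigilance == truth)
stage_recording <- function(table, config = staging_config()) {
  if (nrow(table) == 0) stop("empty feature table")
  check_features(table)
  art <- if ("artifact" %in% names(table)) table$artifact else rep(FALSE, nrow(table))
  if (all(art)) {
    return(stage_sequence(rep(NA_integer_, nrow(table)), artifact = TRUE))
  }
  theta <- compute_adaptive_threshold(table, config)
  lab <- classify_rows(table, theta, config)

  # Causal 0/B1 resolution. Only segments with direct drowsiness evidence
  # (B1 from SEM / residual alpha / elevated delta+theta, B2/3, C) refresh
  # the context window; context-inferred B1 does not, so an extended
  # desynchronised period after drowsiness returns to stage 0 once the
  # window expires.
  w <- config$b1_context_window
  last_drowsy <- -Inf
  for (i in seq_len(nrow(table))) {
    if (is.na(lab[i])) next
    if (lab[i] == "") {
      lab[i] <- if (i - last_drowsy <= w) "B1" else "0"
    } else if (lab[i] %in% c("B1", "B2/3", "C")) {
      last_drowsy <- i
    }
  }
  stage_sequence(stage_to_vigilance(lab), artifact = art)
}

#' Recording-level artifact quality control
#'
#' Recordings with substantial artifact burden - 15 percent or more of all
#' segments (boundary inclusive) - are excluded from analysis.
#'
#' @param seq A [stage_sequence()] tibble or vector of vigilance codes with
#'   `NA` for artifacts.
#' @return A list with `fraction_artifact` and logical `pass`.
#' @export
#' @examples
#' qc_artifact_filter(stage_sequence(rep(c(6, NA), c(1020, 180)),
#'                                   artifact = rep(c(FALSE, TRUE), c(1020, 180))))
qc_artifact_filter <- function(seq) {
  v <- as_vigilance(seq)
  if (length(v$vigilance) == 0) stop("empty stage sequence")
  frac <- mean(v$artifact)
  list(fraction_artifact = frac, pass = frac < 0.15)
}
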