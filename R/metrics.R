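#' Mean vigilance of a recording
#'
#' Arithmetic mean of the numeric vigilance codes (7..1) over artifact-free
#' segments; the standard estimate of the average arousal level during rest.
#'
#' @param seq A [stage_sequence()] tibble or vector of vigilance codes with
#'   `NA` for artifact segments.
#' @return Mean vigilance in `[1, 7]`.
#' @export
#' @examples
#' mean_vigilance(c(7, 6, NA, 5))  # artifact second excluded -> 6
mean_vigilance <- function(seq) {
  v <- as_vigilance(seq)
  x <- v$vigilance[!v$artifact]
  if (length(x) == 0) stop("QC: no artifact-free segments; mean vigilance undefined")
  mean(x)
}

# Per-minute block means over artifact-free seconds. Blocks with fewer than
# `min_valid` usable seconds are dropped. Returns midpoint time (10-min
# units) and mean per retained block.
minute_block_means <- function(vigilance, artifact, min_valid = 30) {
  T <- length(vigilance)
  nb <- T %/% 60
  if (nb < 1) stop("QC: recording shorter than one minute")
  block <- rep(seq_len(nb), each = 60)
  use <- seq_len(nb * 60)
  ok <- !artifact[use] & !is.na(vigilance[use])
  n_ok <- tapply(ok, block, sum)
  sums <- tapply(ifelse(ok, vigilance[use], 0), block, sum)
  keep <- n_ok >= min_valid
  tibble::tibble(
    minute = seq_len(nb)[keep],
    midpoint = (seq_len(nb)[keep] - 0.5) / 10,  # 10-minute units
    mean = as.numeric(sums[keep] / n_ok[keep])
  )
}

#' Slope index of a recording
#'
#' Ordinary least-squares slope of the per-minute mean vigilance against the
#' block midpoint time, expressed in stages per 10 minutes (negative =
#' declining arousal). Minute blocks need at least `min_valid` artifact-free
#' seconds to count; at least two usable blocks are required.
#'
#' @inheritParams mean_vigilance
#' @param min_valid Minimum artifact-free seconds per minute block.
#' @return The slope index (stages / 10 min).
#' @export
#' @examples
#' slope_index(rep(6, 1200))                      # constant -> 0
#' slope_index(rep(seq(6, 4.1, by = -0.1), each = 60))  # -0.1/min -> -1
slope_index <- function(seq, min_valid = 30) {
  v <- as_vigilance(seq)
  bm <- minute_block_means(v$vigilance, v$artifact, min_valid)
  if (nrow(bm) < 2) {
    stop("QC: fewer than two usable one-minute blocks; slope index undefined")
  }
  xc <- bm$midpoint - mean(bm$midpoint)
  sum(xc * bm$mean) / sum(xc^2)
}

# Internal vectorised slope index over the rows of a stage matrix with no
# artifacts (generator fast path).
slope_index_matrix <- function(M) {
  T <- ncol(M)
  nb <- T %/% 60
  pm <- vapply(seq_len(nb), function(b) {
    rowMeans(M[, ((b - 1) * 60 + 1):(b * 60), drop = FALSE])
  }, numeric(nrow(M)))
  if (nrow(M) == 1) pm <- matrix(pm, nrow = 1)
  x <- (seq_len(nb) - 0.5) / 10
  xc <- x - mean(x)
  as.vector(pm %*% xc) / sum(xc^2)
}

#' The 14-row stability rubric
#'
#' The stability score grades how stably high arousal is maintained on an
#' ordinal 1 (least stable) to 14 (most stable) scale. The rubric is a
#' first-match table over cumulative stage burdens: the proportion of
#' artifact-free segments at or below a depth class (`C`; `C`+`B2/3`;
#' `C`+`B2/3`+`B1`; any stage below A1) and, for the least stable row, how
#' early sleep onset first occurred. Scanning from row 1 (sleep onset early
#' and sustained) to row 13 (any segment below A1), the first matching row
#' gives the score; recordings containing only stages 0 and A1 score 14.
#' Because every condition is monotone in the cumulative burdens, deepening
#' any segment (or moving sleep onset earlier) can never increase the score.
#'
#' The rubric ships as a plain-text table
#' (`system.file("extdata", "stability_rubric.tsv", package = "vigicor")`)
#' and can be replaced wholesale via the `rubric` argument of
#' [stability_score()].
#'
#' @return A tibble with columns `score`, `burden_class`
#'   (`C`, `C_B23`, `C_B23_B1` or `BELOW_A1`), `min_prop` (minimum burden
#'   proportion; 0 means "any presence") and `max_first_minute` (latest
#'   allowed minute of first occurrence, `NA` = no timing condition).
#' @export
stability_rubric <- function() {
  path <- system.file("extdata", "stability_rubric.tsv", package = "vigicor")
  readr::read_tsv(path, col_types = readr::cols(
    score = readr::col_integer(),
    burden_class = readr::col_character(),
    min_prop = readr::col_double(),
    max_first_minute = readr::col_double()
  ))
}

burden_members <- list(
  "C" = 1L,
  "C_B23" = 1:2,
  "C_B23_B1" = 1:3,
  "BELOW_A1" = 1:5
)

#' Stability score of a recording
#'
#' Applies the first-match rubric of [stability_rubric()] to the artifact-free
#' segments of a stage sequence.
#'
#' @inheritParams mean_vigilance
#' @param rubric A rubric tibble; defaults to the shipped one.
#' @return An integer score in 1..14.
#' @export
#' @examples
#' stability_score(rep(c(7, 6), 600))   # only 0/A1 -> 14
#' stability_score(rep(c(6, 1), c(300, 900)))  # early, sustained sleep -> 1
stability_score <- function(seq, rubric = stability_rubric()) {
  v <- as_vigilance(seq)
  keep <- !v$artifact
  x <- v$vigilance[keep]
  minute <- (which(keep) - 1L) %/% 60L + 1L
  if (length(x) == 0) stop("QC: no artifact-free segments; stability undefined")
  stability_score_codes(x, minute, rubric)
}

# Core rubric scan on bare code/minute vectors (artifact-free only).
stability_score_codes <- function(x, minute, rubric) {
  for (i in seq_len(nrow(rubric))) {
    cls <- burden_members[[rubric$burden_class[i]]]
    if (is.null(cls)) stop("unknown burden class: ", rubric$burden_class[i])
    inside <- x <= max(cls)
    prop <- mean(inside)
    mp <- rubric$min_prop[i]
    hit <- if (mp > 0) prop >= mp else prop > 0
    mfm <- rubric$max_first_minute[i]
    if (hit && !is.na(mfm)) {
      hit <- any(inside) && min(minute[inside]) <= mfm
    }
    if (hit) return(rubric$score[i])
  }
  max(rubric$score) + 1L
}

#' Centred moving-average vigilance time course
#'
#' Simple centred moving average of the numeric vigilance codes over
#' artifact-free segments (window of `window` seconds, i.e. each point
#' averages the data point in time +/- (window-1)/2 s); the ends are
#' truncated to the available support. Used for group time-course figures.
#'
#' @inheritParams mean_vigilance
#' @param window Odd window length in seconds (default 61).
#' @return A tibble with columns `second` and `value` (`NA` where no
#'   artifact-free segment falls inside the window).
#' @export
moving_average_course <- function(seq, window = 61) {
  if (window < 1 || window %% 2 == 0) stop("`window` must be odd and >= 1")
  v <- as_vigilance(seq)
  x <- ifelse(v$artifact, NA_real_, v$vigilance)
  ok <- as.numeric(!is.na(x))
  x0 <- ifelse(is.na(x), 0, x)
  h <- (window - 1) / 2
  cs <- cumsum(c(0, x0))
  cn <- cumsum(c(0, ok))
  n <- length(x)
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  sums <- cs[hi + 1] - cs[lo]
  cnts <- cn[hi + 1] - cn[lo]
  tibble::tibble(
    second = seq_len(n) - 1L,
    value = ifelse(cnts > 0, sums / cnts, NA_real_)
  )
}

#' Summarise a recording as the three vigilance outcome variables
#'
#' @inheritParams slope_index
#' @param rubric Stability rubric (see [stability_rubric()]).
#' @return A one-row tibble: `mean_vigilance`, `stability_score`,
#'   `slope_index`, `fraction_artifact`, `qc_pass`.
#' @export
summarize_vigilance <- function(seq, rubric = stability_rubric(), min_valid = 30) {
  qc <- qc_artifact_filter(seq)
  tibble::tibble(
    mean_vigilance = mean_vigilance(seq),
    stability_score = stability_score(seq, rubric),
    slope_index = slope_index(seq, min_valid),
    fraction_artifact = qc$fraction_artifact,
    qc_pass = qc$pass
  )
}

#' Summarise every subject of a cohort
#'
#' Vectorised fast path over the stage matrix of a [simulate_cohort()]
#' result (or any long stage tibble with `subject_id`).
#'
#' @param cohort A `vigicor_cohort` object or a long stage tibble.
#' @param rubric Stability rubric.
#' @return A tibble with one row per subject: `subject_id`,
#'   `mean_vigilance`, `stability_score`, `slope_index`,
#'   `fraction_artifact`, `qc_pass`.
#' @export
summarize_cohort <- function(cohort, rubric = stability_rubric(),
                             min_valid = 30) {
  if (inherits(cohort, "vigicor_cohort")) {
    M <- cohort$stages
    A <- cohort$artifacts
    ids <- cohort$phenotypes$subject_id
  } else {
    stopifnot(is.data.frame(cohort), "subject_id" %in% names(cohort))
    ids <- unique(cohort$subject_id)
    T <- sum(cohort$subject_id == ids[1])
    M <- matrix(cohort$vigilance, nrow = length(ids), ncol = T, byrow = TRUE)
    A <- matrix(cohort$artifact, nrow = length(ids), ncol = T, byrow = TRUE)
  }
  n <- nrow(M)
  T <- ncol(M)
  nb <- T %/% 60
  ok <- !A
  V0 <- M
  V0[!ok] <- 0L
  mv <- rowSums(V0) / rowSums(ok)

  # per-minute block sums and valid counts (n x nb)
  bsum <- vapply(seq_len(nb), function(b) {
    cols <- ((b - 1) * 60 + 1):(b * 60)
    rowSums(V0[, cols, drop = FALSE])
  }, numeric(n))
  bok <- vapply(seq_len(nb), function(b) {
    cols <- ((b - 1) * 60 + 1):(b * 60)
    rowSums(ok[, cols, drop = FALSE])
  }, numeric(n))
  if (n == 1) { bsum <- matrix(bsum, 1); bok <- matrix(bok, 1) }
  x <- (seq_len(nb) - 0.5) / 10
  minute_of <- (seq_len(T) - 1L) %/% 60L + 1L

  slope <- stability <- frac_art <- numeric(n)
  for (i in seq_len(n)) {
    keep <- bok[i, ] >= min_valid
    if (sum(keep) < 2) {
      stop("QC: subject ", ids[i], " has fewer than two usable minute blocks")
    }
    bm <- bsum[i, keep] / bok[i, keep]
    xc <- x[keep] - mean(x[keep])
    slope[i] <- sum(xc * bm) / sum(xc^2)
    oki <- ok[i, ]
    stability[i] <- stability_score_codes(M[i, oki], minute_of[oki], rubric)
    frac_art[i] <- 1 - mean(oki)
  }
  tibble::tibble(
    subject_id = ids,
    mean_vigilance = mv,
    stability_score = as.integer(stability),
    slope_index = slope,
    fraction_artifact = frac_art,
    qc_pass = frac_art < 0.15
  )
}
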