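#' The seven EEG-vigilance stages
#'
#' EEG-vigilance operationalises brain arousal on an ordinal scale assigned to
#' each one-second eyes-closed EEG segment: active wakefulness (stage 0),
#' relaxed wakefulness with alpha dominance (A1 occipital, A2 intermediate,
#' A3 anteriorised), drowsiness (B1 low-voltage, B2/3 delta-theta dominant)
#' and sleep onset (C, marked by sleep spindles or K-complexes). Stages are
#' coded numerically from 7 (stage 0) down to 1 (stage C) so that higher
#' values mean higher arousal.
#'
#' @return A tibble with columns `stage` (label) and `vigilance`
#'   (numeric code 7..1).
#' @export
#' @examples
#' vigilance_stages()
vigilance_stages <- function() {
  tibble::tibble(
    stage = c("0", "A1", "A2", "A3", "B1", "B2/3", "C"),
    vigilance = 7:1
  )
}

#' @rdname vigilance_stages
#' @return `stage_levels()`: the stage labels ordered from highest to lowest
#'   arousal.
#' @export
stage_levels <- function() vigilance_stages()$stage

#' Convert between stage labels and numeric vigilance codes
#'
#' The mapping is bijective: `"0"` = 7, `"A1"` = 6, ..., `"C"` = 1.
#' `NA` (artifact-excluded segments) maps to `NA`.
#'
#' @param stage Character vector of stage labels.
#' @param vigilance Integer vector of codes in 1..7.
#' @return The corresponding codes (integer) or labels (character).
#' @export
#' @examples
#' stage_to_vigilance(c("A1", "C"))
#' vigilance_to_stage(c(7, 3))
stage_to_vigilance <- function(stage) {
  map <- vigilance_stages()
  bad <- !is.na(stage) & !(stage %in% map$stage)
  if (any(bad)) {
    stop("unknown stage label(s): ", paste(unique(stage[bad]), collapse = ", "))
  }
  map$vigilance[match(stage, map$stage)]
}

#' @rdname stage_to_vigilance
#' @export
vigilance_to_stage <- function(vigilance) {
  bad <- !is.na(vigilance) & !(vigilance %in% 1:7)
  if (any(bad)) {
    stop("vigilance codes must be integers in 1..7")
  }
  map <- vigilance_stages()
  map$stage[match(vigilance, map$vigilance)]
}

#' Construct a per-second stage sequence
#'
#' A stage sequence is the package's representation of one recording: one row
#' per one-second segment, with 0-based second index, stage label, numeric
#' vigilance code, and artifact flag. Artifact segments carry `NA` stage and
#' are excluded from every downstream metric.
#'
#' @param vigilance Integer vector of vigilance codes (7..1); values may be
#'   `NA` only where `artifact` is `TRUE`.
#' @param artifact Logical vector (recycled) flagging artifact segments.
#' @return A tibble with columns `second`, `stage`, `vigilance`, `artifact`.
#' @export
#' @examples
#' stage_sequence(c(7, 6, 6, 5), artifact = c(FALSE, FALSE, TRUE, FALSE))
stage_sequence <- function(vigilance, artifact = FALSE) {
  n <- length(vigilance)
  artifact <- rep_len(as.logical(artifact), n)
  vig <- as.integer(vigilance)
  vig[artifact] <- NA_integer_
  if (any(is.na(vig) & !artifact)) {
    stop("non-artifact segments must have a vigilance code in 1..7")
  }
  tibble::tibble(
    second = seq_len(n) - 1L,
    stage = vigilance_to_stage(vig),
    vigilance = vig,
    artifact = artifact
  )
}

# Extract (vigilance, artifact) from a stage_sequence tibble or a bare
# numeric vector. Internal normalisation used by all metric functions.
as_vigilance <- function(seq) {
  if (is.data.frame(seq)) {
    stopifnot(all(c("vigilance", "artifact") %in% names(seq)))
    list(vigilance = as.numeric(seq$vigilance), artifact = as.logical(seq$artifact))
  } else {
    v <- as.numeric(seq)
    list(vigilance = v, artifact = is.na(v))
  }
}
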