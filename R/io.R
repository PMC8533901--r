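#' Write a simulated cohort to plain-text tables
#'
#' Emits the generator's standard file set into `dir`: `phenotypes.tsv`
#' (one row per subject), `stages.tsv` (long format: `subject_id`, `second`,
#' `stage`, `vigilance`, `artifact`), optional per-subject feature tables
#' under `features/`, and `manifest.json` recording the seed and config
#' hash.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vigicor_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    phenotypes = file.path(dir, "phenotypes.tsv"),
    stages = file.path(dir, "stages.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  readr::write_tsv(cohort$phenotypes, paths["phenotypes"])
  readr::write_tsv(cohort_stage_long(cohort), paths["stages"])
  if (!is.null(cohort$features)) {
    fdir <- file.path(dir, "features")
    dir.create(fdir, showWarnings = FALSE)
    for (id in names(cohort$features)) {
      readr::write_tsv(cohort$features[[id]],
                       file.path(fdir, paste0(id, ".tsv")))
    }
    paths <- c(paths, features_dir = fdir)
  }
  jsonlite::write_json(cohort$manifest, paths["manifest"],
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Read pipeline tables from disk
#'
#' Readers for the TSV formats written by [write_cohort()] and
#' [run_pipeline()]; headers are required.
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_phenotypes
#' @export
read_stage_long <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    second = readr::col_integer(),
    stage = readr::col_character(),
    vigilance = readr::col_integer(),
    artifact = readr::col_logical()
  ))
}

#' @rdname read_phenotypes
#' @export
read_features <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
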