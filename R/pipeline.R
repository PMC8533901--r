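#' Run the full analysis pipeline on a synthetic cohort
#'
#' End-to-end orchestration mirroring the published analysis order:
#' simulate the cohort, summarise every recording (optionally routing
#' through feature simulation and the stage classifier), compute the
#' dimension- and facet-level Spearman association matrices with BH-FDR and
#' Bayes factors, build the structured permutation null and qq envelope for
#' each scope, repeat the dimension analysis with sex/age/daytime
#' adjustment, and run the power analysis. All stochastic steps are seeded
#' from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param B Permutation sets for the qq null.
#' @param use_classifier Route every subject through
#'   [simulate_features_from_stages()] + [stage_recording()] instead of
#'   consuming the generated stages directly (slower; exercises the full
#'   staging path).
#' @param scopes Which association scopes to run.
#' @param out_dir If non-`NULL`, write result tables (TSV), the result
#'   bundle (JSON) and figures (PNG) there.
#' @return A list of class `vigicor_results` with elements `cohort`,
#'   `summaries`, `associations` (per scope), `adjusted` (covariate-adjusted
#'   dimension matrix), `qq` (per scope), `exceedance`, `power`, `manifest`.
#' @export
#' @examples
#' res <- run_pipeline(cohort_config(n_subjects = 40, seed = 9,
#'                                   n_segments = 300), B = 200)
#' res$associations$dimensions
run_pipeline <- function(config = cohort_config(),
                         B = 10000,
                         use_classifier = FALSE,
                         scopes = c("dimensions", "facets"),
                         out_dir = NULL) {
  scopes <- match.arg(scopes, several.ok = TRUE)
  cohort <- simulate_cohort(config, features = use_classifier)
  if (use_classifier) {
    seqs <- lapply(cohort$features, stage_recording)
    summaries <- dplyr::bind_cols(
      tibble::tibble(subject_id = cohort$phenotypes$subject_id),
      dplyr::bind_rows(lapply(seqs, summarize_vigilance))
    )
  } else {
    summaries <- summarize_cohort(cohort)
  }
  n_qc_fail <- sum(!summaries$qc_pass)
  message("pipeline: ", nrow(summaries), " subjects summarised, ",
          n_qc_fail, " excluded by artifact QC")

  metrics <- c("mean_vigilance", "stability_score", "slope_index")
  keep <- summaries$qc_pass
  df <- dplyr::inner_join(cohort$phenotypes, summaries[keep, ],
                          by = "subject_id")
  associations <- list()
  qq <- list()
  exceedance <- NULL
  for (sc in scopes) {
    associations[[sc]] <- association_matrix(cohort$phenotypes, summaries,
                                             scope = sc)
    traits <- if (sc == "dimensions") neo_dimensions() else neo_facets()
    null <- permutation_pvalue_sets(as.matrix(df[, traits]),
                                    as.matrix(df[, metrics]), B = B)
    qq[[sc]] <- qq_envelope(null, associations[[sc]]$p)
    if (sc == "dimensions") {
      obs <- associations$dimensions$p
      exceedance <- exceedance_summaries(
        null, alpha = 0.05, k = sum(obs < 0.05), p0 = max(min(obs), 1e-12)
      )
    }
  }
  adjusted <- association_matrix(cohort$phenotypes, summaries,
                                 scope = "dimensions",
                                 covariates = c("sex", "age", "daytime"))
  power <- tibble::tibble(
    power = c(0.2, 0.5, 0.8),
    alpha = 0.05,
    detectable_r = vapply(c(0.2, 0.5, 0.8), detectable_r,
                          numeric(1), n = nrow(df))
  )
  res <- structure(list(
    cohort = cohort, summaries = summaries, associations = associations,
    adjusted = adjusted, qq = qq, exceedance = exceedance, power = power,
    manifest = c(cohort$manifest, list(B = B, scopes = scopes))
  ), class = "vigicor_results")
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' @export
print.vigicor_results <- function(x, ...) {
  cat("<vigicor_results> seed", x$manifest$seed, "-",
      x$manifest$n_subjects, "subjects\n")
  for (sc in names(x$associations)) {
    a <- x$associations[[sc]]
    cat("  ", sc, ": ", sum(a$p < 0.05), "/", nrow(a),
        " nominal, ", sum(a$p_fdr < 0.05), " FDR-significant\n", sep = "")
  }
  invisible(x)
}

# Write the result bundle: TSVs, JSON and figures.
write_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(res$summaries, file.path(out_dir, "summaries.tsv"))
  for (sc in names(res$associations)) {
    readr::write_tsv(res$associations[[sc]],
                     file.path(out_dir, paste0("associations_", sc, ".tsv")))
    readr::write_tsv(res$qq[[sc]], file.path(out_dir, paste0("qq_", sc, ".tsv")))
  }
  readr::write_tsv(res$adjusted, file.path(out_dir, "associations_adjusted.tsv"))
  bundle <- list(
    manifest = res$manifest,
    exceedance = res$exceedance,
    power = res$power
  )
  jsonlite::write_json(bundle, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (sc in names(res$qq)) {
    p <- plot_qq_envelope(res$qq[[sc]])
    ggplot2::ggsave(file.path(out_dir, paste0("qq_", sc, ".png")), p,
                    width = 5, height = 5, dpi = 150,
                    device = grDevices::png)
  }
  invisible(out_dir)
}

#' Group vigilance time-courses after a median split
#'
#' Moving-average vigilance time-courses (mean +/- standard error) for the
#' low- and high-scoring halves of a trait distribution, the standard
#' illustration of trait-linked arousal decline.
#'
#' @param cohort A `vigicor_cohort`.
#' @param trait Phenotype column to split on.
#' @param window Moving-average window in seconds (odd; default 61).
#' @return A ggplot object.
#' @export
plot_timecourse <- function(cohort, trait = "openness", window = 61) {
  stopifnot(inherits(cohort, "vigicor_cohort"))
  groups <- median_split_groups(cohort$phenotypes[[trait]])
  if (min(table(groups)) < 2) stop("each median-split group needs >= 2 subjects")
  M <- cohort$stages
  A <- cohort$artifacts
  courses <- lapply(seq_len(nrow(M)), function(i) {
    vig <- M[i, ]
    vig[A[i, ]] <- NA_integer_
    moving_average_course(stage_sequence(vig, A[i, ]), window)$value
  })
  C <- do.call(rbind, courses)
  df <- dplyr::bind_rows(lapply(levels(groups), function(g) {
    Cg <- C[groups == g, , drop = FALSE]
    mu <- colMeans(Cg, na.rm = TRUE)
    se <- apply(Cg, 2, function(col) sd(col, na.rm = TRUE) / sqrt(sum(!is.na(col))))
    tibble::tibble(second = seq_len(ncol(C)) - 1L, group = g, mean = mu, se = se)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$second / 60, y = .data$mean,
                                   colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "EEG-vigilance (7..1)",
                  colour = trait, fill = trait) +
    ggplot2::theme_minimal()
}

#' Slope-index boxplots by median-split group
#'
#' @param summaries Per-subject summary tibble.
#' @param phenotypes Phenotype tibble.
#' @param traits Traits to facet over (default the five dimensions).
#' @return A ggplot object.
#' @export
plot_slope_boxplots <- function(summaries, phenotypes,
                                traits = neo_dimensions()) {
  df <- dplyr::inner_join(phenotypes, summaries, by = "subject_id")
  long <- dplyr::bind_rows(lapply(traits, function(tr) {
    tibble::tibble(trait = tr,
                   group = median_split_groups(df[[tr]]),
                   slope_index = df$slope_index)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$slope_index)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.6) +
    ggplot2::facet_wrap(~trait, nrow = 1) +
    ggplot2::labs(x = NULL, y = "slope index (stages / 10 min)") +
    ggplot2::theme_minimal()
}

#' Permutation qq-plot with percentile envelope
#'
#' Observed -log10 p-values against the mean expected values under the
#' structured permutation null, with the 5th-95th percentile envelope as a
#' grey band.
#'
#' @param qq A [qq_envelope()] tibble.
#' @return A ggplot object.
#' @export
plot_qq_envelope <- function(qq) {
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$expected)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed),
                        colour = "steelblue") +
    ggplot2::labs(x = expression(expected ~ -log[10](p)),
                  y = expression(observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}
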