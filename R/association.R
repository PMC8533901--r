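#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked data (ties receive mean ranks).
#'
#' @param x,y Numeric vectors of equal length, n >= 4, finite.
#' @return The Spearman coefficient in `[-1, 1]`.
#' @export
#' @examples
#' spearman_rho(1:10, (1:10)^3)  # invariant under monotone transforms -> 1
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("inputs must be finite")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("Spearman correlation is undefined for a constant input vector")
  }
  cor(x, y, method = "spearman")
}

#' Two-sided p-value for a (partial) Spearman correlation
#'
#' Uses the t approximation `t = rho * sqrt((n - 2 - k) / (1 - rho^2))` on
#' `n - 2 - k` degrees of freedom (`k` = number of partialled covariates),
#' the standard large-sample treatment. For very small untied samples an
#' exact path (`exact = TRUE`, n <= 9, k = 0) enumerates the permutation
#' null distribution of the coefficient instead. For `|rho| = 1` the exact
#' path still applies; under the approximation the p-value is the limit 0
#' (with a warning).
#'
#' @param rho Correlation coefficient.
#' @param n Sample size (>= 4 + k).
#' @param k Number of covariates partialled out (default 0).
#' @param exact Use the exact permutation null (untied ranks, n <= 9)?
#' @return Two-sided p-value in `(0, 1]`.
#' @export
#' @examples
#' spearman_pvalue(-0.173, 468)  # ~ 2e-4
spearman_pvalue <- function(rho, n, k = 0, exact = FALSE) {
  stopifnot(abs(rho) <= 1, n >= 4 + k)
  if (exact) {
    if (k != 0) stop("the exact path does not support covariates")
    if (n > 9) stop("the exact path enumerates n! permutations; n must be <= 9")
    return(spearman_exact_pvalue(rho, n))
  }
  if (abs(rho) == 1) {
    warning("|rho| = 1: p-value is the degenerate limit 0")
    return(0)
  }
  df <- n - 2 - k
  t <- abs(rho) * sqrt(df / (1 - rho^2))
  2 * pt(t, df, lower.tail = FALSE)
}

# P(|rho*| >= |rho|) over all n! equally likely rank permutations
# (untied ranks). Enumerated once per call; n <= 9 keeps this instant.
spearman_exact_pvalue <- function(rho, n) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  ref <- seq_len(n)
  rhos <- vapply(perms(ref), function(p) {
    1 - 6 * sum((ref - p)^2) / (n * (n^2 - 1))
  }, numeric(1))
  mean(abs(rhos) >= abs(rho) - 1e-12)
}

#' Covariate-adjusted (partial) Spearman correlation
#'
#' Rank-transforms `x`, `y` and every covariate column (mean ranks for
#' ties), residualises the ranked `x` and `y` on the ranked covariates with
#' an intercept by least squares, and correlates the residuals; the p-value
#' is evaluated on `n - 2 - k` degrees of freedom. Ranking the covariates
#' keeps the whole procedure nonparametric, so a variable that equals a
#' covariate is absorbed completely. With no covariates this reduces
#' exactly to [spearman_rho()] + [spearman_pvalue()].
#'
#' @inheritParams spearman_rho
#' @param covariates A data frame / matrix of covariates (numeric; factors
#'   must be pre-coded), or `NULL`.
#' @return A list with `rho`, `p`, `n` and `k`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (is.null(covariates) || NCOL(covariates) == 0 || nrow(as.matrix(covariates)) == 0) {
    rho <- spearman_rho(x, y)
    return(list(rho = rho, p = spearman_pvalue(rho, n), n = n, k = 0L))
  }
  Z <- as.matrix(covariates)
  if (!is.numeric(Z)) stop("covariates must be numeric")
  k <- ncol(Z)
  if (k >= n - 3) stop("too many covariates (k must be < n - 3)")
  Z <- apply(Z, 2, rank)
  X <- cbind(1, Z)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dep <- colnames(Z)[qr_x$pivot[seq(qr_x$rank + 1, ncol(X))] - 1]
    stop("covariate matrix is rank deficient (linearly dependent: ",
         paste(dep, collapse = ", "), ")")
  }
  rx <- rank(x)
  ry <- rank(y)
  ex <- qr.resid(qr_x, rx)
  ey <- qr.resid(qr_x, ry)
  # a variable fully absorbed by the covariates leaves numerically-zero
  # residuals; report a null partial correlation rather than noise
  tol <- 1e-10 * n
  if (sd(ex) < tol || sd(ey) < tol) {
    warning("a variable is fully absorbed by the covariates; ",
            "partial correlation set to 0")
    return(list(rho = 0, p = 1, n = n, k = k))
  }
  rho <- cor(ex, ey)
  list(rho = rho, p = spearman_pvalue(rho, n, k), n = n, k = k)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment: the adjusted value of the i-th
#' smallest p is `min_{j >= i} p_(j) * m / j`, capped at 1. Input order is
#' preserved. Associations with adjusted p < 0.05 are conventionally called
#' significant after multiple testing.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order and length.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Trait-by-metric Spearman association matrix
#'
#' Correlates every trait column of the phenotype table with every vigilance
#' summary metric, producing the standard analysis table: Spearman rho,
#' two-sided p, BH-FDR-adjusted p (adjusted within the full scope - 15 tests
#' for the 5 dimensions, 90 for the 30 facets), and optionally the
#' stretched-beta-prior Bayes factor. Subjects failing artifact QC are
#' excluded; tables are matched by `subject_id`.
#'
#' @param phenotypes Phenotype tibble (see [simulate_traits()]).
#' @param summaries Per-subject summary tibble (see [summarize_cohort()]).
#' @param scope `"dimensions"` (5 traits) or `"facets"` (30 facets).
#' @param covariates Character vector drawn from `c("sex", "age",
#'   "daytime")`, or `NULL` for unadjusted correlations.
#' @param bayes Compute `bf10` per record?
#' @param kappa Stretched-beta prior width for the Bayes factors.
#' @return A tibble with one row per trait x metric pair: `trait`, `metric`,
#'   `rho`, `n`, `p`, `p_fdr` and (if requested) `bf10`; plus attribute
#'   `n_nominal` (count of p < 0.05).
#' @export
association_matrix <- function(phenotypes, summaries,
                               scope = c("dimensions", "facets"),
                               covariates = NULL,
                               bayes = TRUE, kappa = 1 / 3) {
  scope <- match.arg(scope)
  if (anyDuplicated(phenotypes$subject_id)) {
    stop("duplicate subject ids in phenotype table: ",
         paste(unique(phenotypes$subject_id[duplicated(phenotypes$subject_id)]),
               collapse = ", "))
  }
  if (anyDuplicated(summaries$subject_id)) {
    stop("duplicate subject ids in summary table")
  }
  unmatched <- setdiff(summaries$subject_id, phenotypes$subject_id)
  if (length(unmatched)) {
    stop("summary subjects missing from phenotype table: ",
         paste(head(unmatched, 5), collapse = ", "),
         if (length(unmatched) > 5) " ..." else "")
  }
  df <- dplyr::inner_join(phenotypes, summaries, by = "subject_id")
  if ("qc_pass" %in% names(df)) df <- df[df$qc_pass, ]
  traits <- if (scope == "dimensions") neo_dimensions() else neo_facets()
  metrics <- c("mean_vigilance", "stability_score", "slope_index")
  Z <- NULL
  if (!is.null(covariates)) {
    bad <- setdiff(covariates, c("sex", "age", "daytime"))
    if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
    Z <- sapply(covariates, function(cv) {
      if (cv == "sex") as.numeric(df$sex == "female") else as.numeric(df[[cv]])
    })
    Z <- matrix(Z, nrow = nrow(df), dimnames = list(NULL, covariates))
  }
  grid <- expand.grid(trait = traits, metric = metrics,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ps <- partial_spearman(df[[grid$trait[i]]], df[[grid$metric[i]]], Z)
    tibble::tibble(trait = grid$trait[i], metric = grid$metric[i],
                   rho = ps$rho, n = ps$n, p = ps$p)
  })
  out <- dplyr::bind_rows(res)
  out$p_fdr <- bh_adjust(out$p)
  if (bayes) {
    out$bf10 <- vapply(seq_len(nrow(out)), function(i) {
      correlation_bf10(out$rho[i], out$n[i], kappa)
    }, numeric(1))
  }
  attr(out, "n_nominal") <- sum(out$p < 0.05)
  out
}

#' Median-split group labels
#'
#' Splits scores into low and high groups at the median of the ascending
#' distribution: values strictly above the median are `"high"`; values at or
#' below it (including all median ties) are `"low"`. With an odd n the group
#' sizes differ by exactly one.
#'
#' @param scores Numeric vector (n >= 2).
#' @return A factor with levels `low`, `high`.
#' @export
#' @examples
#' median_split_groups(c(1, 2, 3, 4))
median_split_groups <- function(scores) {
  stopifnot(length(scores) >= 2)
  med <- median(scores)
  lab <- ifelse(scores > med, "high", "low")
  if (all(lab == "low")) {
    warning("all scores at or below the median; 'high' group is empty")
  }
  factor(lab, levels = c("low", "high"))
}
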