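#' Block permutation of a variable domain
#'
#' Applies one shared row permutation to an entire block of variables: all
#' columns move together, so every correlation *within* the block is
#' preserved exactly, while correlations *between* this block and any other
#' subject-aligned block are destroyed.
#'
#' @param Y Matrix or data frame, rows = subjects.
#' @param perm Integer permutation of the row indices (default: a uniform
#'   random permutation from the session RNG).
#' @return `Y` with permuted rows.
#' @export
block_permute <- function(Y, perm = sample(nrow(Y))) {
  stopifnot(length(perm) == nrow(Y), all(sort(perm) == seq_len(nrow(Y))))
  Y[perm, , drop = FALSE]
}

# Column-wise standardised mean ranks: crossprod of two such matrices /
# (n - 1) is exactly the Spearman correlation matrix (rank-then-Pearson,
# mean ranks for ties).
std_ranks <- function(X) {
  R <- apply(as.matrix(X), 2, rank)
  R <- scale(R)
  if (any(!is.finite(R))) stop("constant column: Spearman ranks undefined")
  R
}

#' Structured permutation null for cross-domain p-values
#'
#' Generates `B` sets of the `m = ncol(X) * ncol(Y)` cross-domain Spearman
#' p-values under the null of no trait-vigilance association: each set
#' permutes the subject rows of the vigilance block as one unit
#' ([block_permute()]), preserving all within-domain correlations while
#' severing cross-domain ones. Each set of p-values is sorted ascending.
#'
#' @param X Trait matrix (rows = subjects).
#' @param Y Vigilance-metric matrix (rows = subjects, aligned with `X`).
#' @param B Number of permutation sets (>= 100).
#' @return An object of class `permutation_null`: list with `p_sorted`
#'   (B x m matrix of ascending p-values), `B`, `m`, `n`.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(50 * 3), 50)
#' Y <- matrix(rnorm(50 * 2), 50)
#' null <- permutation_pvalue_sets(X, Y, B = 200)
#' dim(null$p_sorted)
permutation_pvalue_sets <- function(X, Y, B = 10000) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  if (B < 100) stop("B must be at least 100 for stable percentiles")
  n <- nrow(X)
  m <- ncol(X) * ncol(Y)
  Xs <- std_ranks(X)
  Ys <- std_ranks(Y)
  df <- n - 2
  P <- matrix(NA_real_, B, m)
  for (b in seq_len(B)) {
    rho <- crossprod(Xs, Ys[sample.int(n), , drop = FALSE]) / (n - 1)
    rho <- pmin(pmax(as.vector(rho), -1 + 1e-15), 1 - 1e-15)
    t <- abs(rho) * sqrt(df / (1 - rho^2))
    P[b, ] <- sort(2 * pt(t, df, lower.tail = FALSE))
  }
  structure(list(p_sorted = P, B = B, m = m, n = n),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("<permutation_null> B =", x$B, "sets of m =", x$m,
      "p-values (n =", x$n, "subjects)\n")
  invisible(x)
}

#' Quantile-quantile envelope of observed versus expected p-values
#'
#' For each rank of the sorted p-value set, summarises the permutation null
#' on the -log10 scale (mean = the diagonal of the qq-plot; 5th and 95th
#' percentile = the grey envelope) and aligns the observed p-values, sorted
#' from largest to smallest as in the conventional plot. Ranks whose
#' observed value exceeds the 95th percentile are flagged.
#'
#' @param null A [permutation_pvalue_sets()] result.
#' @param observed The `m` observed p-values.
#' @param probs Lower and upper envelope percentiles.
#' @return A tibble with one row per rank: `rank`, `expected`,
#'   `lower`, `upper`, `observed` (all -log10 p) and `exceeds`.
#' @export
qq_envelope <- function(null, observed, probs = c(0.05, 0.95)) {
  stopifnot(inherits(null, "permutation_null"))
  if (length(observed) != null$m) {
    stop("observed p-value set must have length m = ", null$m)
  }
  L <- -log10(null$p_sorted)  # column j = j-th smallest p across sets
  expected <- colMeans(L)
  lower <- apply(L, 2, quantile, probs = probs[1])
  upper <- apply(L, 2, quantile, probs = probs[2])
  obs_sorted <- -log10(sort(observed, decreasing = FALSE))
  # rank 1 = smallest p (largest -log10); plot orders largest p first
  m <- null$m
  tibble::tibble(
    rank = seq_len(m),
    expected = expected,
    lower = lower,
    upper = upper,
    observed = obs_sorted,
    exceeds = obs_sorted > upper
  )
}

#' Exceedance summaries of the permutation null
#'
#' Fractions of null sets that look at least as extreme as stated
#' thresholds: sets containing at least `k` p-values below `alpha`, and
#' sets whose minimum p-value falls below `p0`.
#'
#' @param null A [permutation_pvalue_sets()] result.
#' @param alpha Nominal significance threshold.
#' @param k Minimum count of p-values below `alpha`.
#' @param p0 Threshold for the smallest p-value of a set.
#' @return A list with `frac_k_below_alpha` and `frac_min_below_p0`.
#' @export
exceedance_summaries <- function(null, alpha = 0.05, k = 6, p0 = 2e-4) {
  stopifnot(inherits(null, "permutation_null"))
  if (alpha <= 0 || alpha > 1 || p0 <= 0 || p0 > 1) {
    stop("thresholds must lie in (0, 1]")
  }
  P <- null$p_sorted
  counts <- rowSums(P < alpha)
  list(
    frac_k_below_alpha = mean(counts >= k),
    frac_min_below_p0 = mean(P[, 1] < p0)
  )
}
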