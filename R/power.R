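#' Power of a two-sided correlation test
#'
#' Power to detect a true correlation `r` at sample size `n` and two-sided
#' level `alpha`, using the Fisher z transformation with small-sample bias
#' correction: the critical correlation `r_c` comes from the t criterion on
#' `n - 2` degrees of freedom, and
#' \deqn{1 - \beta = \Phi\left(\left(z_r - z_{r_c}\right)\sqrt{n-3}\right) +
#'   \Phi\left(\left(-z_r - z_{r_c}\right)\sqrt{n-3}\right)}
#' with `z_r = artanh(r) + r / (2(n-1))` and `z_{r_c} = artanh(r_c)`; both
#' rejection tails count, so the power tends to `alpha` as `r` tends to 0.
#' This mirrors the standard algorithm of correlation power calculators.
#'
#' @param r True correlation in `(0, 1)`.
#' @param n Sample size (>= 4).
#' @param alpha Two-sided significance level in `(0, 1)`.
#' @return The power `1 - beta`.
#' @export
#' @examples
#' correlation_power(0.129, 468)  # ~ 0.80
correlation_power <- function(r, n, alpha = 0.05) {
  stopifnot(r > 0, r < 1, n >= 4, alpha > 0, alpha < 1)
  tc <- qt(1 - alpha / 2, n - 2)
  rc <- tc / sqrt(n - 2 + tc^2)
  zr <- atanh(r) + r / (2 * (n - 1))
  zrc <- atanh(rc)
  pnorm((zr - zrc) * sqrt(n - 3)) + pnorm((-zr - zrc) * sqrt(n - 3))
}

#' Smallest detectable correlation at a given power
#'
#' Inverts [correlation_power()] in `r` by root-finding on (0, 0.999)
#' (tolerance 1e-6). Monotone in `power`.
#'
#' @param power Target power in `(alpha, 1)`.
#' @inheritParams correlation_power
#' @return The detectable effect size `r`.
#' @export
#' @examples
#' detectable_r(0.80, 468)  # ~ 0.129
detectable_r <- function(power, n, alpha = 0.05) {
  stopifnot(power > alpha, power < 1)
  f <- function(r) correlation_power(r, n, alpha) - power
  if (f(0.999) < 0) {
    stop("no detectable r below 0.999 reaches the requested power")
  }
  uniroot(f, c(1e-9, 0.999), tol = 1e-9)$root
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha Family-wise level.
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_alpha(0.05, 15)  # 0.0033
bonferroni_alpha <- function(alpha, m) {
  stopifnot(alpha > 0, alpha <= 1, m >= 1)
  alpha / m
}
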