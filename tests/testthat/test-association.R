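test_that("spearman_rho matches a rank-then-Pearson oracle and is monotone-invariant", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8)   # ties on both sides
  oracle <- cor(rank(x), rank(y))
  expect_equal(spearman_rho(x, y), oracle, tolerance = 1e-12)

  expect_equal(spearman_rho(1:10, 1:10), 1)
  expect_equal(spearman_rho(1:10, 10:1), -1)
  # invariance under strictly increasing transforms
  set.seed(30)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(spearman_rho(a, b), spearman_rho(exp(a), b^3 + 5 * b))
  expect_error(spearman_rho(rep(1, 10), 1:10), "constant")
})

test_that("the t approximation reproduces reference p-values", {
  expect_equal(spearman_pvalue(0, 468), 1)
  expect_equal(signif(spearman_pvalue(-0.173, 468), 1), 2e-4)
  expect_equal(round(spearman_pvalue(-0.150, 468), 3), 0.001)
  expect_equal(spearman_pvalue(0.3, 20), spearman_pvalue(-0.3, 20))
  w <- capture_warnings(p1 <- spearman_pvalue(1, 10))
  expect_match(w, "degenerate")
  expect_equal(p1, 0)
})

test_that("the exact small-n path matches the reference exact test", {
  set.seed(36)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    x <- sample(n)
    y <- sample(n)
    rho <- spearman_rho(x, y)
    got <- spearman_pvalue(rho, n, exact = TRUE)
    ref <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    )
    expect_equal(got, min(ref, 1), tolerance = 1e-8)
  }
  expect_error(spearman_pvalue(0.5, 50, exact = TRUE), "<= 9")
  expect_error(spearman_pvalue(0.5, 8, k = 1, exact = TRUE), "covariates")
})

test_that("type-I error of the t approximation is calibrated at n = 468", {
  set.seed(31)
  nsim <- 20000
  n <- 468
  X <- matrix(rnorm(n * nsim), n)
  Y <- matrix(rnorm(n * nsim), n)
  rho <- vapply(seq_len(nsim), function(i) {
    cor(X[, i], Y[, i], method = "spearman")
  }, numeric(1))
  p <- vapply(rho, spearman_pvalue, numeric(1), n = n)
  expect_gte(mean(p < 0.05), 0.045)
  expect_lte(mean(p < 0.05), 0.055)
})

test_that("partial spearman reduces, absorbs and matches its oracle", {
  set.seed(32)
  x <- rnorm(60); y <- rnorm(60)
  plain <- partial_spearman(x, y, NULL)
  expect_equal(plain$rho, spearman_rho(x, y))
  expect_equal(plain$p, spearman_pvalue(spearman_rho(x, y), 60))

  # y exactly equal to a covariate: full absorption of the ranked variable
  z <- rnorm(60)
  expect_warning(abs_res <- partial_spearman(x, z, cbind(z = z)), "absorbed")
  expect_equal(abs_res$rho, 0)
  # ... even when y is a monotone transform of the covariate
  expect_warning(abs_res2 <- partial_spearman(x, exp(z), cbind(z = z)),
                 "absorbed")
  expect_equal(abs_res2$rho, 0)

  # confounded triple vs explicit residualisation oracle (all ranked)
  u <- rnorm(200)
  x2 <- 0.6 * u + rnorm(200)
  y2 <- -0.5 * u + rnorm(200)
  got <- partial_spearman(x2, y2, cbind(u = u))
  ru <- rank(u)
  rx <- residuals(lm(rank(x2) ~ ru))
  ry <- residuals(lm(rank(y2) ~ ru))
  expect_equal(got$rho, cor(rx, ry), tolerance = 1e-10)
  expect_equal(got$p, spearman_pvalue(cor(rx, ry), 200, k = 1), tolerance = 1e-10)

  expect_error(partial_spearman(x2, y2, cbind(u = u, v = 2 * u)),
               "rank deficient")
})

test_that("BH adjustment matches the step-up construction", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    running <- Inf
    for (i in m:1) {
      running <- min(running, p[o[i]] * m / i)
      adj[o[i]] <- min(1, running)
    }
    adj
  }
  set.seed(33)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }

  # monotone: raising any input p never lowers any adjusted value
  for (i in 1:20) {
    p <- runif(12)
    j <- sample(12, 1)
    p2 <- p
    p2[j] <- min(1, p[j] + runif(1) * (1 - p[j]))
    expect_true(all(bh_adjust(p2) >= bh_adjust(p) - 1e-12))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("association matrices have the right shape, family and errors", {
  co <- simulate_cohort(cohort_config(n_subjects = 120, seed = 34))
  s <- summarize_cohort(co)
  am <- association_matrix(co$phenotypes, s, bayes = FALSE)
  expect_equal(nrow(am), 15)
  expect_true(all(am$p_fdr >= am$p))
  af <- association_matrix(co$phenotypes, s, scope = "facets", bayes = FALSE)
  expect_equal(nrow(af), 90)

  dup <- co$phenotypes[c(1, 1, 2:120), ]
  expect_error(association_matrix(dup, s, bayes = FALSE), "duplicate")
  expect_error(
    association_matrix(co$phenotypes[1:100, ], s, bayes = FALSE),
    "missing from phenotype table"
  )

  # covariate-adjusted matrix uses reduced degrees of freedom
  amc <- association_matrix(co$phenotypes, s, bayes = FALSE,
                            covariates = c("sex", "age", "daytime"))
  expect_equal(nrow(amc), 15)
  expect_error(association_matrix(co$phenotypes, s, covariates = "shoe_size"),
               "unknown covariate")
})

test_that("null cohorts produce ~5% nominal associations", {
  null_cfg <- function(seed) cohort_config(
    n_subjects = 150, seed = seed, n_segments = 600,
    effect_vector = c(neuroticism = 0, extraversion = 0, openness = 0,
                      agreeableness = 0, conscientiousness = 0),
    age_effect = 0, daytime_effect = 0
  )
  hits <- unlist(lapply(1:40, function(sd) {
    co <- simulate_cohort(null_cfg(sd))
    s <- summarize_cohort(co)
    am <- association_matrix(co$phenotypes, s, bayes = FALSE)
    am$p < 0.05
  }))
  expect_equal(mean(hits), 0.05, tolerance = 0.4)   # 600 tests, binomial noise
})

test_that("an injected openness effect typically surfaces as the strongest record", {
  tops <- sapply(35:42, function(sd) {
    co <- simulate_cohort(cohort_config(seed = sd))
    s <- summarize_cohort(co)
    am <- association_matrix(co$phenotypes, s, bayes = FALSE)
    top <- am[which.min(am$p), ]
    expect_lt(top$rho, 0)
    top$trait
  })
  expect_gte(mean(tops == "openness"), 0.5)
})

test_that("median split halves the ascending distribution", {
  g <- median_split_groups(c(1, 2, 3, 4))
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  g3 <- median_split_groups(c(5, 1, 9))
  expect_equal(abs(diff(as.integer(table(g3)))), 1L)
  expect_warning(ga <- median_split_groups(rep(2, 6)), "empty")
  expect_true(all(ga == "low"))
})
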