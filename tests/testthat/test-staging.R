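test_that("adaptive threshold follows the top-decile formula", {
  cfg <- cohort_config(feature_noise = 0)
  f <- simulate_features_from_stages(rep(6, 100), cfg)
  f[, c("alpha_o", "alpha_p", "alpha_t", "alpha_f")] <- 10
  expect_equal(compute_adaptive_threshold(f), 2.5)

  # homogeneity: scaling all densities scales the threshold
  set.seed(1)
  g <- features_for(balanced_codes(20), noise = 0.3)
  thr <- compute_adaptive_threshold(g)
  g2 <- g
  dens <- c("alpha_o", "alpha_p", "alpha_t", "alpha_f",
            "dt_o", "dt_p", "dt_t", "dt_f")
  g2[, dens] <- g2[, dens] * 3.7
  expect_equal(compute_adaptive_threshold(g2), 3.7 * thr)

  # independent sort-and-average oracle on lognormal input
  set.seed(2)
  h <- features_for(rep(6, 500), noise = 0)
  h$alpha_o <- exp(rnorm(500, 1, 0.6))
  k <- ceiling(0.1 * 500)
  oracle <- 0.25 * mean(rev(sort(h$alpha_o))[seq_len(k)])
  expect_equal(compute_adaptive_threshold(h), oracle, tolerance = 1e-12)

  # order invariance
  expect_equal(compute_adaptive_threshold(h[sample(500), ]),
               compute_adaptive_threshold(h))

  expect_error(compute_adaptive_threshold(h[1:40, ]), "fewer than 60")
})

test_that("the rule cascade classifies canonical segments", {
  th <- 10
  expect_equal(classify_segment(seg(c(50, 50, 50, 50), c(50, 50, 50, 50),
                                    graph = TRUE), th), "C")
  expect_equal(classify_segment(seg(c(20, 8, 8, 8), c(5, 5, 5, 5)), th), "A1")
  expect_equal(classify_segment(seg(c(8, 8, 8, 20), c(5, 5, 5, 5)), th), "A3")
  expect_equal(classify_segment(seg(c(14, 28, 10, 7), c(5, 5, 5, 5)), th), "A2")
  # frontal = occipital ties resolve to A3 (lower arousal)
  expect_equal(classify_segment(seg(c(20, 8, 8, 20), c(5, 5, 5, 5)), th), "A3")
  expect_equal(classify_segment(seg(c(2, 2, 2, 2), c(10, 10, 10, 10)), th), "B2/3")
  expect_equal(classify_segment(seg(c(5, 5, 5, 5), c(3, 3, 3, 3)), th), "0")
  expect_equal(classify_segment(seg(c(5, 5, 5, 5), c(3, 3, 3, 3), sem = TRUE),
                                th), "B1")
  expect_equal(classify_segment(seg(c(5, 5, 5, 5), c(3, 3, 3, 3)), th,
                                context = c("A1", "B2/3")), "B1")
  expect_equal(classify_segment(seg(c(5, 5, 5, 5), c(3, 3, 3, 3)), th,
                                context = c("A1", "A2")), "0")
})

test_that("labels are invariant to a common density rescaling", {
  set.seed(3)
  f <- features_for(balanced_codes(30), noise = 0.15)
  out1 <- stage_recording(f)
  dens <- c("alpha_o", "alpha_p", "alpha_t", "alpha_f",
            "dt_o", "dt_p", "dt_t", "dt_f")
  f2 <- f
  f2[, dens] <- f2[, dens] * 0.013
  out2 <- stage_recording(f2)
  expect_identical(out1$stage, out2$stage)
})

test_that("raising delta+theta never moves a segment to higher arousal", {
  set.seed(4)
  for (i in 1:200) {
    alpha <- exp(rnorm(4, 2, 1))
    dt <- exp(rnorm(4, 1.5, 1))
    th <- exp(rnorm(1, 2, 0.7))
    ctx <- sample(list(character(), c("A1"), c("B2/3")), 1)[[1]]
    sem <- runif(1) < 0.3
    before <- classify_segment(seg(alpha, dt, sem = sem), th, context = ctx)
    bump <- dt + stats::rexp(4, 1) * rbinom(4, 1, 0.6)
    after <- classify_segment(seg(alpha, bump, sem = sem), th, context = ctx)
    expect_lte(stage_to_vigilance(after), stage_to_vigilance(before))
  }
})

test_that("staging a recording is causal and handles artifacts", {
  set.seed(5)
  f <- features_for(balanced_codes(30), noise = 0.1)
  out <- stage_recording(f)
  # permuting tail segments leaves earlier labels unchanged
  f2 <- f
  tail_idx <- 151:210
  f2[tail_idx, ] <- f[sample(tail_idx), ]
  out2 <- stage_recording(f2)
  expect_identical(out$stage[1:150], out2$stage[1:150])

  # artifact segments are missing, not staged
  f3 <- f
  f3$artifact[c(10, 20)] <- TRUE
  out3 <- stage_recording(f3)
  expect_true(all(is.na(out3$stage[c(10, 20)])))
  expect_true(all(out3$artifact[c(10, 20)]))

  # an all-artifact table yields an all-missing sequence
  f4 <- f
  f4$artifact <- TRUE
  out4 <- stage_recording(f4)
  expect_true(all(is.na(out4$stage)))
  expect_equal(qc_artifact_filter(out4)$pass, FALSE)
})

test_that("artifact QC excludes recordings at the 15 percent boundary", {
  art <- function(k) stage_sequence(
    rep(c(6L, NA), c(1200 - k, k)), artifact = rep(c(FALSE, TRUE), c(1200 - k, k))
  )
  expect_false(qc_artifact_filter(art(180))$pass)   # exactly 15%: excluded
  expect_true(qc_artifact_filter(art(179))$pass)
  qc0 <- qc_artifact_filter(art(0))
  expect_true(qc0$pass)
  expect_equal(qc0$fraction_artifact, 0)
})

test_that("noise-free round-trip recovers every label exactly", {
  truth <- balanced_codes(40)
  out <- stage_recording(features_for(truth, noise = 0))
  expect_equal(out$vigilance, truth)
})

test_that("round-trip accuracy stays above 95 percent at 20 percent noise", {
  set.seed(6)
  truth <- balanced_codes(120)   # 840 segments, one block per stage
  acc <- replicate(5, {
    out <- stage_recording(features_for(truth, noise = 0.2))
    mean(out$vigilance == truth)
  })
  expect_gte(mean(acc), 0.95)

  # drowsiness context expires: wakefulness re-emerging >60 s after sleep
  # onset is staged 0 again, not B1
  wake_after_sleep <- c(rep(6, 100), rep(1, 100), rep(7, 200))
  out <- stage_recording(features_for(wake_after_sleep, noise = 0))
  expect_equal(out$stage[201:260], rep("B1", 60))   # within the window
  expect_equal(out$stage[261:400], rep("0", 140))   # after it expires
})
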