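test_that("the CAP score reproduces printed cohort values and is linear in
           its arguments", {
  expect_equal(cap_score(43, 46), 109.73, tolerance = 1e-4)
  expect_equal(round(cap_score(43, 46)), 110)
  expect_equal(cap_score(56, 40), 89.31, tolerance = 1e-3)
  expect_equal(round(cap_score(56, 40)), 89)
  expect_error(cap_score(50, 30), "exceed 30")
  expect_error(cap_score(-1, 42), "positive")
  # linear in age at fixed CAG, and in (CAG - 30) at fixed age
  expect_equal(cap_score(60, 42), 2 * cap_score(30, 42))
  expect_equal(cap_score(50, 42) - cap_score(50, 40),
               2 * (cap_score(50, 41) - cap_score(50, 40)))
  expect_lt(cap_score(50, 30 + 1e-9), 1e-6)
})

test_that("harmonization flips the timing measures and logs the right ones", {
  panel <- list(stroop_word_correct = 80, sdmt_correct = 35,
                circle_trace_annulus = 400, emotion_recog_correct = 20,
                iti = 0.28, sd_ioi = 0.05, sd_dmti = 0.06)
  h <- harmonize_measures(panel)
  # independent spreadsheet-style recomputation
  expect_equal(unname(h),
               c(80, 35, log(400), 20, -0.28, -log(0.05), -log(0.06)),
               tolerance = 1e-12)
  # larger ITI strictly decreases the harmonized value
  worse <- panel; worse$iti <- 0.4
  expect_lt(harmonize_measures(worse)["iti"], h["iti"])
  bad <- panel; bad$sd_ioi <- 0
  expect_error(harmonize_measures(bad), "positive before log")
  expect_error(harmonize_measures(panel[-1]), "missing")
})

test_that("the composite is zero at reference means, moves 1/7 per reference
           SD, and ignores measure order", {
  norms <- example_norms()
  at_mean <- list(stroop_word_correct = norms$mean[["stroop_word_correct"]],
                  sdmt_correct = norms$mean[["sdmt_correct"]],
                  circle_trace_annulus = exp(norms$mean[["circle_trace_annulus"]]),
                  emotion_recog_correct = norms$mean[["emotion_recog_correct"]],
                  iti = -norms$mean[["iti"]],
                  sd_ioi = exp(-norms$mean[["sd_ioi"]]),
                  sd_dmti = exp(-norms$mean[["sd_dmti"]]))
  expect_equal(composite_score(at_mean, norms), 0, tolerance = 1e-12)
  up <- at_mean
  up$sdmt_correct <- up$sdmt_correct + norms$sd[["sdmt_correct"]]
  expect_equal(composite_score(up, norms), 1 / 7, tolerance = 1e-12)
  # order invariance
  expect_equal(composite_score(rev(up), norms), composite_score(up, norms))
  # affine equivariance: shifting one reference mean by delta shifts the
  # composite by -delta / (7 * ref_sd)
  norms2 <- reference_norms(
    mean = replace(norms$mean, "sdmt_correct",
                   norms$mean[["sdmt_correct"]] + 2),
    sd = norms$sd)
  expect_equal(composite_score(at_mean, norms2) - composite_score(at_mean, norms),
               -2 / (7 * norms$sd[["sdmt_correct"]]), tolerance = 1e-12)
})

test_that("tapping measures follow their definitions on jittered sequences
           and guard degenerate input", {
  tp <- list(onsets = c(0, 0.5, 1.0), target_period = 0.5)
  expect_error(tapping_measures(tp), "zero inter-onset variance")
  set.seed(8)
  taps <- simulate_taps(50, jitter_sd = 0.03, seed = 8)
  tm <- tapping_measures(taps)
  ioi <- diff(taps$onsets)
  expect_equal(tm$iti, mean(ioi), tolerance = 1e-12)
  expect_equal(tm$log_sd_ioi, log(sd(ioi)), tolerance = 1e-12)
  # brute-force mid-tap deviation oracle
  p <- taps$target_period
  mid <- (taps$onsets[-50] + taps$onsets[-1]) / 2
  grid_mid <- taps$onsets[1] + (0:200 + 0.5) * p
  dev <- vapply(mid, function(m) m - grid_mid[which.min(abs(m - grid_mid))],
                numeric(1))
  expect_equal(tm$sd_dmti, sd(dev), tolerance = 1e-9)
  expect_error(tapping_measures(list(onsets = c(0, 1),
                                     target_period = 0.5)), "at least 3")
})

test_that("Spearman and partial Spearman behave like rank statistics", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, -x), -1)
  expect_equal(spearman_rho(x, exp(x)), 1)  # monotone invariance
  y <- c(2, 7, 1, 8, 2.8, 1.8)
  expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"))
  expect_error(spearman_rho(x, rep(1, 6)), "constant")
  set.seed(12)
  # control uncorrelated with both: partial matches marginal
  xx <- rnorm(400); yy <- xx + rnorm(400); cc <- rnorm(400)
  expect_lt(abs(partial_spearman(xx, yy, cc) - spearman_rho(xx, yy)), 0.05)
  # planted common driver: adjusting shrinks the correlation
  dd <- rnorm(200)
  x2 <- dd + rnorm(200, 0, 0.5); y2 <- dd + rnorm(200, 0, 0.5)
  expect_lt(abs(partial_spearman(x2, y2, dd)), abs(spearman_rho(x2, y2)))
  # constant control reduces to plain Spearman
  expect_equal(partial_spearman(x, y, rep(2, 6)), spearman_rho(x, y))
  expect_error(partial_spearman(x, y, x), "degenerate")
})

test_that("the packaged cohort table is consistent with the CAP formula and
           its printed correlations", {
  tab <- hd_cohort()
  expect_equal(nrow(tab), 10L)
  # participants whose printed CAP reproduces from integer age/CAG
  repro <- c(1, 2, 4, 5, 7, 10)
  expect_equal(round(cap_score(tab$age[repro], tab$cag[repro])),
               tab$cap[repro])
  expect_equal(round(spearman_rho(tab$caudate_pct_icv, tab$tms), 2), -0.77)
})
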