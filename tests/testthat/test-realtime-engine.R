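test_that("roi_mean, weighted_baseline and compute_psc match brute force", {
  set.seed(7)
  vol <- array(rnorm(6 * 6 * 4, 100), c(6, 6, 4))
  mask <- array(runif(6 * 6 * 4) < 0.3, c(6, 6, 4))
  expect_equal(roi_mean(vol, mask), sum(vol[mask]) / sum(mask))
  expect_equal(roi_mean(array(100, c(2, 2, 2)), array(TRUE, c(2, 2, 2))), 100)
  m2 <- array(FALSE, c(2, 2, 2)); m2[1:2] <- TRUE
  v2 <- array(0, c(2, 2, 2)); v2[1] <- 90; v2[2] <- 110
  expect_equal(roi_mean(v2, m2), 100)
  expect_error(roi_mean(vol, array(FALSE, c(6, 6, 4))), "empty")

  s <- rnorm(30, 100); w <- baseline_weights(30, 1)
  expect_equal(weighted_baseline(s, w), sum(s * w))
  expect_equal(weighted_baseline(rep(7, 30), w), 7)
  expect_equal(weighted_baseline(s, rep(1 / 30, 30)), mean(s))
  expect_error(weighted_baseline(s[1:10], w), "length")

  expect_equal(compute_psc(100, 100), 0)
  expect_equal(compute_psc(105, 100), 5)
  expect_equal(compute_psc(99, 100), -1)
  expect_error(compute_psc(100, 0), "positive")
})

test_that("shaping follows the previous block's maximum PSC with a floor,
           and the bar clips decreases and saturates", {
  st <- list(scale = 1, prev_block_max_psc = NA)
  st <- shaping_update(st, 0.8)
  expect_equal(st$scale, 0.8)
  st <- shaping_update(st, -0.2)
  expect_equal(st$scale, 0.1)   # all-decrease block floors at the minimum
  expect_equal(bar_fraction(-0.3, 1), 0)
  expect_equal(bar_fraction(2, 2), 1)
  expect_equal(bar_fraction(1, 2), 0.5)
  expect_equal(bar_fraction(5, 2), 1)  # saturation above scale
  # monotone nondecreasing in psc at fixed scale
  psc <- seq(-1, 3, by = 0.1)
  expect_true(all(diff(bar_fraction(psc, 1.5)) >= 0))
})

test_that("a constant-signal run yields zero PSC and an empty thermometer", {
  grid <- acquisition_grid(c(6, 6, 4))
  run <- make_clean_run(amplitude = 0, grid = grid)
  fb <- run_feedback(run, run$truth$roi_mask)
  expect_true(all(abs(fb$trace$psc) < 1e-9))
  expect_true(all(fb$trace$bar_fraction == 0))
})

test_that("the engine emits 20 display samples per 30 s upregulation block,
           applies 5 shaping updates, and replays against a scripted oracle", {
  run <- make_clean_run(amplitude = 1)
  cfg <- engine_config()
  fb <- run_feedback(run, run$truth$roi_mask, cfg)
  expect_equal(as.integer(table(fb$trace$block)), rep(20L, 5))
  expect_equal(nrow(fb$blocks), 5L)
  # scripted shaping oracle: S1 = S0, S_k = max(prev max, floor)
  s_oracle <- numeric(5)
  s_oracle[1] <- cfg$initial_scale
  for (k in 2:5)
    s_oracle[k] <- max(fb$blocks$max_psc[k - 1], cfg$scale_floor)
  expect_equal(fb$blocks$scale_used, s_oracle)
  expect_true(all(fb$trace$bar_fraction >= 0 & fb$trace$bar_fraction <= 1))
})

test_that("the engine agrees with a vectorized offline recomputation and the
           baseline is causal", {
  grid <- acquisition_grid(c(6, 6, 4))
  run <- make_clean_run(amplitude = 0.8, grid = grid, ar = 0.3,
                        noise_sd = 0.5, seed = 3)
  mask <- run$truth$roi_mask
  fb <- run_feedback(run, mask)
  # offline: recompute roi series, per-block weighted baselines, block means
  nvol <- run$design$n_volumes
  roi <- colMeans(matrix(run$bold, ncol = nvol)[as.vector(mask), ])
  times <- seq_len(nvol) - 1
  w <- baseline_weights(30, 1)
  blocks <- run$design$blocks
  base <- NA
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    vols <- which(times >= b$onset & times < b$onset + b$duration)
    if (b$kind == "baseline") base <- sum(roi[vols] * w)
    if (b$kind == "upregulate") {
      emitted <- fb$trace[fb$trace$block == i, ]
      offline_psc <- 100 * (roi[emitted$time + 1] - base) / base
      expect_equal(mean(emitted$psc), mean(offline_psc), tolerance = 1e-9)
      # causality: baseline equals the weighted mean of the immediately
      # preceding baseline block only
      expect_equal(unique(emitted$baseline), base, tolerance = 1e-12)
    }
  }
})

test_that("shaping makes a full bar strictly harder after a strong block", {
  run <- make_clean_run(amplitude = 1.5, seed = 2)
  fb <- run_feedback(run, run$truth$roi_mask)
  bl <- fb$blocks
  for (k in 2:nrow(bl)) {
    if (bl$max_psc[k - 1] > bl$scale_used[k - 1]) {
      expect_gt(bl$scale_used[k], bl$scale_used[k - 1])
    }
  }
})

test_that("a design starting with upregulation is rejected", {
  blocks <- data.frame(kind = c("upregulate", "baseline"),
                       onset = c(0, 30), duration = 30)
  d <- block_design(blocks, 1)
  grid <- acquisition_grid(c(4, 4, 3))
  truth <- simulation_truth(central_roi(grid, c(1, 1, 0)),
                            noise_sd = 0, ar_coefficient = 0)
  run <- simulate_run(truth, d, grid, seed = 1)
  expect_error(run_feedback(run, truth$roi_mask), "precedes")
})
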