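test_that("scan-to-scan displacement flags spikes strictly above threshold
           and is invariant to constant offsets", {
  motion <- matrix(0, 60, 6)
  expect_equal(ncol(spike_regressors(motion)$columns), 0L)
  motion[40:60, 1] <- 1.2
  sp <- spike_regressors(motion)
  expect_equal(sp$flagged, 40L)
  expect_equal(sum(sp$columns), 1)
  # exactly 1.0 mm is not flagged (strict inequality)
  m2 <- matrix(0, 60, 6); m2[40:60, 1] <- 1.0
  expect_equal(length(spike_regressors(m2)$flagged), 0L)
  # constant offsets leave the count unchanged
  m3 <- motion + 5
  expect_equal(spike_regressors(m3)$flagged, sp$flagged)
  # rotations are converted via the 50 mm head radius
  m4 <- matrix(0, 10, 6); m4[5:10, 4] <- 0.021  # 1.05 mm of arc
  expect_equal(spike_regressors(m4)$flagged, 5L)
  # run-level exclusion fires strictly above 2 mm
  m5 <- matrix(0, 10, 6); m5[5:10, 1] <- 2.0
  expect_false(exclude_run(m5))
  m5[5:10, 1] <- 2.1
  expect_true(exclude_run(m5))
})

test_that("the block contrast recovers a planted amplitude against a
           convolution oracle and averages over the mask linearly", {
  run <- make_clean_run(amplitude = 1)
  mask <- run$truth$roi_mask
  bc <- block_contrast(run, mask)
  # oracle: the planted series is amp * reg/plateau, so the regression
  # coefficient on the unnormalized regressor is amp / plateau
  h <- dgamma_hrf(0:32)
  plateau <- sum(h)
  expect_equal(bc$roi, 1 / plateau, tolerance = 0.02 / plateau)
  # ROI-mean contrast equals the mean of voxelwise contrasts over the mask
  expect_equal(bc$roi, mean(bc$map[mask]), tolerance = 1e-12)
  d <- block_design(data.frame(kind = "baseline", onset = 0, duration = 30), 1)
  run_nb <- run; run_nb$design <- d
  expect_error(block_contrast(run_nb, mask), "no 'upregulate'")
})

test_that("null runs produce contrasts centered on zero", {
  grid <- acquisition_grid(c(4, 4, 3))
  roi <- central_roi(grid, c(1, 1, 0))
  est <- vapply(1:60, function(i) {
    truth <- simulation_truth(roi, base_amplitude = 0, learning_slope = 0,
                              ar_coefficient = 0, noise_sd = 1)
    block_contrast(simulate_run(truth, nf_block_design(), grid, seed = i),
                   roi)$roi
  }, numeric(1))
  expect_lt(abs(mean(est)), 2 * sd(est) / sqrt(length(est)))
})

test_that("the mixed-model visit trend recovers planted slopes and reduces
           to OLS without a subject effect", {
  fit <- quiet_trend(make_trend_table(0.3, seed = 1))
  e <- trend_effect(fit)
  expect_lt(abs(e$estimate - 0.3), 3 * e$se)
  # identical responses: slope exactly 0
  d0 <- make_trend_table(0, seed = 2)
  d0$roi_contrast <- 1
  f0 <- quiet_trend(d0)
  expect_equal(trend_effect(f0)$estimate, 0, tolerance = 1e-10)
  # no between-subject variance: mixed slope agrees with plain OLS
  d1 <- make_trend_table(0.2, seed = 3, subj_sd = 0)
  f_mix <- quiet_trend(d1)
  f_ols <- visit_trend(d1, random = FALSE)
  expect_equal(trend_effect(f_mix)$estimate, trend_effect(f_ols)$estimate,
               tolerance = 1e-6)
  expect_error(visit_trend(make_trend_table(0, 1, visits = 1)), "2 visits")
})

test_that("PPI terms equal the centered elementwise product and centering is
           idempotent", {
  set.seed(9)
  d <- nf_block_design()
  cond <- as.numeric(convolve_design(d, "upregulate") > 0.5) # any boxcar
  seed_ts <- rnorm(d$n_volumes, 100)
  pp <- ppi_terms(seed_ts, cond)
  h <- dgamma_hrf(0:32)
  conv <- conv_oracle(cond, h)
  expect_equal(pp$interaction,
               (conv - mean(conv)) * (seed_ts - mean(seed_ts)),
               tolerance = 1e-12)
  pp2 <- ppi_terms(seed_ts - mean(seed_ts), cond)
  expect_equal(pp$interaction, pp2$interaction, tolerance = 1e-12)
  # constant seed: interaction identically 0
  pp0 <- ppi_terms(rep(5, d$n_volumes), cond)
  expect_true(all(abs(pp0$interaction) < 1e-12))
  expect_error(ppi_terms(1:5, 1:4), "equal length")
})

test_that("planted condition-dependent coupling yields a positive PPI beta
           and its growth across visits is detected", {
  d <- nf_block_design()
  cond <- as.numeric(
    convolve_design(d, "upregulate", normalize = "plateau") > 0.5)
  betas <- NULL
  set.seed(4)
  for (s in 1:6) for (v in 1:3) for (r in 1:2) {
    seed_ts <- rnorm(d$n_volumes)
    coupling <- 0.1 + 0.15 * (v - 1)
    pp_true <- ppi_terms(seed_ts, cond)
    target <- 0.3 * pp_true$seed + coupling * pp_true$interaction +
      rnorm(d$n_volumes, 0, 0.05)
    b <- fit_ppi(target, ppi_terms(seed_ts, cond))$beta
    betas <- rbind(betas, data.frame(subject = s, visit = v, run = r,
                                     beta = b))
  }
  expect_true(all(betas$beta > 0))
  tr <- suppressWarnings(suppressMessages(connectivity_change(betas)))
  e <- trend_effect(tr)
  expect_gt(e$estimate, 0)
  expect_lt(e$p, 0.05)
})

test_that("behaviour regression recovers a planted region and stays quiet
           under permutation or constant maps", {
  dims <- c(8, 8, 4)
  nvox <- prod(dims)
  region <- array(FALSE, dims); region[3:5, 3:5, 2:3] <- TRUE
  n <- 12
  hit <- perm_hit <- logical(10)
  for (i in 1:10) {
    set.seed(i)
    comp <- rnorm(n)
    covs <- data.frame(age = runif(n, 40, 65),
                       caudate_pct_icv = runif(n, 0.3, 0.55))
    maps <- matrix(rnorm(nvox * n, 0, 0.2), nvox, n)
    maps[as.vector(region), ] <- maps[as.vector(region), ] +
      matrix(rep(comp, each = sum(region)), sum(region), n)
    br <- behavior_regression(maps, comp, covs, dims)
    dice <- 2 * sum(br$sig & region) / (sum(br$sig) + sum(region))
    hit[i] <- dice >= 0.5
    brp <- behavior_regression(maps, sample(comp), covs, dims)
    perm_hit[i] <- sum(brp$sig & region) / max(sum(region), 1) > 0.5
  }
  expect_gte(mean(hit), 0.9)
  expect_lte(mean(perm_hit), 0.1)
  # constant maps: no clusters
  br0 <- behavior_regression(matrix(1, nvox, n), rnorm(n),
                             data.frame(age = runif(n, 40, 65),
                                        caudate_pct_icv = runif(n, .3, .5)),
                             dims)
  expect_length(br0$clusters$sizes, 0)
})

test_that("26-connected cluster labelling separates diagonal-touching and
           disjoint components", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE  # corner-diagonal: one cluster
  m[4, 4, 4] <- TRUE                       # far away: its own cluster
  cl <- label_clusters(m)
  expect_equal(sort(cl$sizes), c(1L, 2L))
  expect_equal(cl$labels[1, 1, 1], cl$labels[2, 2, 2])
  expect_true(cl$labels[4, 4, 4] != cl$labels[1, 1, 1])
})

test_that("tapping contrasts are identical for identical runs and detect a
           planted upregulation boost", {
  grid <- acquisition_grid(c(4, 4, 3))
  roi <- central_roi(grid, c(1, 1, 0))
  tap_design <- alternating_design("tap", n_cycles = 5, block_s = 20)
  make_tap_run <- function(amp, seed)
    simulate_run(simulation_truth(roi, base_amplitude = amp,
                                  learning_slope = 0, ar_coefficient = 0,
                                  noise_sd = 0.5),
                 tap_design, grid, signal_kind = "tap", seed = seed)
  subj <- paste0("s", 1:5)
  pre <- post_wo <- post_w <- setNames(vector("list", 5), subj)
  for (i in 1:5) {
    pre[[i]] <- make_tap_run(1, seed = 100 + i)
    post_wo[[i]] <- make_tap_run(1, seed = 200 + i)
    post_w[[i]] <- make_tap_run(1.6, seed = 300 + i)
  }
  res <- tapping_contrast_comparison(pre, post_wo, post_w, roi,
                                     active_kind = "tap")
  expect_gt(mean(res$contrasts$post_with - res$contrasts$post_without), 0)
  expect_lt(res$paired$p.value, 0.05)
  # identical runs across conditions -> zero differences
  same <- tapping_contrast_comparison(pre, pre, pre, roi, active_kind = "tap")
  expect_equal(same$contrasts$post_with, same$contrasts$pre, tolerance = 1e-12)
  expect_error(tapping_contrast_comparison(pre, post_wo, post_w[1:4], roi),
               "matched|missing")
})
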