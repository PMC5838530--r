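# Brute-force discrete convolution: out[t] = tr * sum_k h[k+1] * box[t-k]
conv_oracle <- function(box, h, tr = 1) {
  n <- length(box)
  out <- numeric(n)
  for (t in seq_len(n)) {
    for (k in 0:(length(h) - 1)) {
      if (t - k >= 1) out[t] <- out[t] + h[k + 1] * box[t - k]
    }
  }
  tr * out
}

# double-gamma HRF computed directly from gamma densities (independent of
# hrf_value); canonical defaults
dgamma_hrf <- function(t) dgamma(t, 6, 1) - dgamma(t, 16, 1) / 6

# a tiny noise-free run with a planted amplitude, shared by several tests
make_clean_run <- function(amplitude = 1, grid = acquisition_grid(c(6, 6, 4)),
                           design = nf_block_design(), seed = 1,
                           ar = 0, noise_sd = 0) {
  truth <- simulation_truth(central_roi(grid, c(1, 1, 1)),
                            base_amplitude = amplitude, learning_slope = 0,
                            ar_coefficient = ar, noise_sd = noise_sd,
                            drift_slope = 0)
  simulate_run(truth, design, grid, seed = seed)
}

# generator of ROI-contrast tables for mixed-model recovery tests
make_trend_table <- function(slope, seed, n_sub = 10, visits = 4, runs = 4,
                             subj_sd = 0.1, resid_sd = 0.3) {
  set.seed(seed)
  d <- expand.grid(subject = seq_len(n_sub), visit = seq_len(visits),
                   run = seq_len(runs))
  b <- rnorm(n_sub, 0, subj_sd)
  age <- runif(n_sub, 40, 65)
  caud <- runif(n_sub, 0.3, 0.55)
  d$age <- age[d$subject]
  d$caudate_pct_icv <- caud[d$subject]
  d$roi_contrast <- 0.2 + slope * d$visit + 0.02 * d$run + b[d$subject] +
    rnorm(nrow(d), 0, resid_sd)
  d
}

quiet_trend <- function(...) {
  suppressWarnings(suppressMessages(visit_trend(...)))
}
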