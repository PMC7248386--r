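# Shared fixtures: all synthetic, built in code.

# Deterministic config: no stroke jitter, no noise, short oscillations.
quiet_config <- function(osc_duration = 2.5) {
  cfg <- default_population_config()
  cfg$within_sd_fraction <- 0
  cfg$noise_snr_db <- Inf
  cfg$oscillation_duration_s <- osc_duration
  cfg
}

# Canonical agonist/antagonist parameter sets (pre-fatigue ER group means).
AGONIST <- c(t0 = 0.23, D = 214, mu = -1.42, sigma = 0.27)
ANTAGONIST <- c(t0 = 0.40, D = 30.6, mu = -1.78, sigma = 0.36)

make_simple_trial <- function(cfg = quiet_config(), agonist = AGONIST,
                              antagonist = ANTAGONIST, seed = 1) {
  set.seed(seed)
  params <- list(agonist = agonist)
  if (!is.null(antagonist)) params$antagonist <- antagonist
  generate_trial("simple", params, cfg)
}

# Match each ground-truth component to the nearest fitted one by t0 and
# return the per-component absolute errors.
recovery_errors <- function(fit_df, truth_df) {
  do.call(rbind, lapply(seq_len(nrow(truth_df)), function(j) {
    k <- which.min(abs(fit_df$t0 - truth_df$t0[j]))
    data.frame(dt0 = abs(fit_df$t0[k] - truth_df$t0[j]),
               dmu = abs(fit_df$mu[k] - truth_df$mu[j]),
               dsigma = abs(fit_df$sigma[k] - truth_df$sigma[j]),
               dD_rel = abs(fit_df$D[k] - truth_df$D[j]) / truth_df$D[j])
  }))
}

expect_recovered <- function(fit_df, truth_df,
                             tol = c(t0 = 0.005, mu = 0.02, sigma = 0.02, D = 0.02)) {
  err <- recovery_errors(fit_df, truth_df)
  expect_lte(max(err$dt0), tol[["t0"]])
  expect_lte(max(err$dmu), tol[["mu"]])
  expect_lte(max(err$dsigma), tol[["sigma"]])
  expect_lte(max(err$dD_rel), tol[["D"]])
}
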