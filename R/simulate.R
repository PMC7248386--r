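# Synthetic trial and session generation.
#
# Trials emulate four tablet tests executed at an audible stimulus (T = 0):
# simple strokes (an agonist/antagonist pair of neuromuscular components),
# triangles (three main strokes through virtual targets plus small corrective
# components), and 10 s of horizontal or vertical oscillations between two
# targets, produced as an alternating-direction train of lognormal commands
# spaced by the rhythm interval dt0.

new_trajectory <- function(t, x, y, meta, ground_truth = NULL) {
  structure(list(t = t, x = x, y = y, meta = meta, ground_truth = ground_truth),
            class = "sl_trajectory")
}

#' @export
print.sl_trajectory <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<trajectory> %s | participant %s | %s/%s | %d samples @ %g Hz | %.2f s\n",
              m$test_type %||% "?", m$participant %||% "?", m$fatigue %||% "?",
              m$condition %||% "?", length(x$t), m$sample_rate_hz %||% NA,
              max(x$t) - min(x$t)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw per-stroke parameters around participant means with clamped jitter.
jitter_params <- function(means, sds, frac) {
  out <- means
  for (p in names(means)) {
    sd_p <- if (p %in% names(sds)) sds[[p]] * frac else 0
    out[[p]] <- means[[p]] + stats::rnorm(1, 0, sd_p)
    if (p %in% names(PARAM_FLOOR)) out[[p]] <- max(out[[p]], PARAM_FLOOR[[p]])
  }
  out
}

trial_grid <- function(components, sr, margin = 0.1) {
  t_end <- max(components$t0 + exp(components$mu + 4 * components$sigma)) + margin
  seq(0, ceiling(t_end * sr) / sr, by = 1 / sr)
}

components_to_trajectory <- function(components, sr, meta, origin = c(0, 0)) {
  times <- trial_grid(components, sr)
  vel <- superpose(components, times)
  x <- origin[1L] + cumtrapz(times, vel$vx)
  y <- origin[2L] + cumtrapz(times, vel$vy)
  meta$sample_rate_hz <- sr
  meta$stimulus_time <- 0
  new_trajectory(times, x, y, meta, ground_truth = components)
}

#' Generate one synthetic trial
#'
#' @param test_type one of `"simple"`, `"triangle"`, `"h_osc"`, `"v_osc"`.
#' @param params participant-level parameter means: a list `role -> named
#'   vector` as returned by the population sampler (internally
#'   `participant_params()`); roles are `agonist`/`antagonist` for simple
#'   strokes, `stroke` for triangles, `oscillation` for oscillations.
#' @param config population configuration (for sampling rate, jitter, angles).
#' @param sds optional list of between-participant SDs per role (same shape as
#'   `params`) used to scale stroke-to-stroke jitter; 0 jitter when omitted.
#' @param meta named list merged into the trajectory metadata.
#' @param seed optional integer; when given, the trial is a pure function of
#'   its arguments.
#' @return an `sl_trajectory`: uniformly sampled `t` (s), `x`, `y` (mm),
#'   metadata and the ground-truth component table.
#' @export
generate_trial <- function(test_type, params, config = default_population_config(),
                           sds = NULL, meta = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sr <- config$sampling_rate_hz
  frac <- config$within_sd_fraction
  ang <- config$angles
  meta$test_type <- test_type
  comps <- switch(
    test_type,
    simple = {
      assert_that(all(c("agonist") %in% names(params)), "simple stroke needs agonist params")
      bearing <- ang$simple_bearing
      ag <- jitter_params(params$agonist, sds$agonist %||% numeric(), frac)
      rows <- list(data.frame(
        t0 = ag[["t0"]], D = ag[["D"]], mu = ag[["mu"]], sigma = ag[["sigma"]],
        theta_s = wrap_angle(bearing + stats::rnorm(1, 0, ang$agonist_jitter_sd * (frac > 0))),
        role = "agonist"))
      rows[[1L]]$theta_e <- rows[[1L]]$theta_s
      if ("antagonist" %in% names(params)) {
        an <- jitter_params(params$antagonist, sds$antagonist %||% numeric(), frac)
        th <- wrap_angle(bearing + pi + stats::rnorm(1, 0, ang$antagonist_jitter_sd * (frac > 0)))
        rows[[2L]] <- data.frame(t0 = an[["t0"]], D = an[["D"]], mu = an[["mu"]],
                                 sigma = an[["sigma"]], theta_s = th, theta_e = th,
                                 role = "antagonist")
      }
      meta$bearing <- bearing
      do.call(rbind, lapply(rows, function(r) r[c("t0", "D", "mu", "sigma", "theta_s", "theta_e", "role")]))
    },
    triangle = {
      assert_that("stroke" %in% names(params), "triangle needs stroke params")
      bearings <- ang$triangle_bearings
      gap <- config$triangle_stroke_gap
      rows <- list()
      t0_prev <- NA_real_
      for (k in 1:3) {
        st <- jitter_params(params$stroke, sds$stroke %||% numeric(), frac)
        t0_k <- if (k == 1L) st[["t0"]] else
          t0_prev + max(0.2, gap[[1L]] + stats::rnorm(1, 0, gap[[2L]] * (frac > 0)))
        t0_prev <- t0_k
        th <- wrap_angle(bearings[[k]] + stats::rnorm(1, 0, ang$triangle_jitter_sd * (frac > 0)))
        rows[[k]] <- data.frame(t0 = t0_k, D = st[["D"]], mu = st[["mu"]], sigma = st[["sigma"]],
                                theta_s = th, theta_e = th, role = paste0("stroke", k))
      }
      # small corrective components near the two corners (kept out of the three
      # main strokes; they raise Nblog toward the published ~5 per triangle)
      n_minor <- if (frac > 0) stats::rbinom(1, 2, 0.9) else 2L
      for (j in seq_len(n_minor)) {
        tc <- rows[[j]]$t0 + exp(rows[[j]]$mu) + 0.15
        th <- wrap_angle(bearings[[min(j + 1L, 3L)]] + stats::rnorm(1, 0, 0.5 * (frac > 0)))
        rows[[3L + j]] <- data.frame(t0 = tc, D = stats::runif(1, 8, 20), mu = -1.2,
                                     sigma = 0.2, theta_s = th, theta_e = th,
                                     role = "corrective")
      }
      meta$bearings <- bearings
      do.call(rbind, rows)
    },
    h_osc = ,
    v_osc = {
      assert_that("oscillation" %in% names(params), "oscillation needs oscillation params")
      base_dirs <- if (test_type == "h_osc") c(0, pi) else c(pi / 2, -pi / 2)
      dur <- config$oscillation_duration_s
      rows <- list()
      t0_k <- config$osc_first_t0
      k <- 0L
      while (t0_k <= dur) {
        k <- k + 1L
        os <- jitter_params(params$oscillation, sds$oscillation %||% numeric(), frac)
        ramp <- if (k <= 3L) c(0.5, 0.75, 0.9)[k] else 1
        th <- wrap_angle(base_dirs[[1L + (k - 1L) %% 2L]] +
                           stats::rnorm(1, 0, ang$osc_jitter_sd * (frac > 0)))
        rows[[k]] <- data.frame(t0 = t0_k, D = ramp * os[["D"]], mu = os[["mu"]],
                                sigma = os[["sigma"]], theta_s = th, theta_e = th,
                                role = "oscillation")
        t0_k <- t0_k + max(0.02, os[["dt0"]])
      }
      # stopping transients after the second stimulus
      for (j in 1:2) {
        k <- k + 1L
        os <- jitter_params(params$oscillation, sds$oscillation %||% numeric(), frac)
        th <- wrap_angle(base_dirs[[1L + (k - 1L) %% 2L]] +
                           stats::rnorm(1, 0, ang$osc_jitter_sd * (frac > 0)))
        rows[[k]] <- data.frame(t0 = t0_k, D = c(0.5, 0.25)[j] * os[["D"]], mu = os[["mu"]],
                                sigma = os[["sigma"]], theta_s = th, theta_e = th,
                                role = "oscillation")
        t0_k <- t0_k + max(0.02, os[["dt0"]])
      }
      meta$target_separation_mm <- config$target_separation_mm
      meta$orientation <- if (test_type == "h_osc") "horizontal" else "vertical"
      do.call(rbind, rows)
    },
    stop("unknown test type: ", test_type)
  )
  rownames(comps) <- NULL
  components_to_trajectory(comps, sr, meta)
}

#' Add measurement noise to a trajectory
#'
#' Zero-mean white noise is added to the central-difference velocity of the
#' trajectory and re-integrated into positions.  The noise is scaled so that
#' the realized velocity-domain SNR equals the target exactly (well within the
#' +/- 0.5 dB contract).
#'
#' @param trajectory an `sl_trajectory`.
#' @param target_snr_db target signal-to-noise ratio in dB; `Inf` returns the
#'   input unchanged. Must be positive and finite otherwise.
#' @param seed optional integer for reproducibility.
#' @return a noisy `sl_trajectory` (ground truth preserved; realized SNR in
#'   `meta$noise_snr_db`).
#' @export
add_noise <- function(trajectory, target_snr_db, seed = NULL) {
  assert_that(inherits(trajectory, "sl_trajectory"), "trajectory must be an sl_trajectory")
  if (is.infinite(target_snr_db)) return(trajectory)
  assert_that(is_number(target_snr_db) && target_snr_db > 0,
              "target SNR must be positive (dB) or Inf")
  if (!is.null(seed)) set.seed(seed)
  t <- trajectory$t
  n <- length(t)
  dt <- t[2L] - t[1L]
  vx <- c((trajectory$x[2L] - trajectory$x[1L]) / dt,
          (trajectory$x[3:n] - trajectory$x[1:(n - 2L)]) / (2 * dt),
          (trajectory$x[n] - trajectory$x[n - 1L]) / dt)
  vy <- c((trajectory$y[2L] - trajectory$y[1L]) / dt,
          (trajectory$y[3:n] - trajectory$y[1:(n - 2L)]) / (2 * dt),
          (trajectory$y[n] - trajectory$y[n - 1L]) / dt)
  ex <- stats::rnorm(n)
  ey <- stats::rnorm(n)
  # push the noise through the same position -> velocity route as the signal
  # (integrate to positions, differentiate back), so the realized SNR in the
  # measured-velocity domain equals the target exactly
  nx <- cumtrapz(t, ex)
  ny <- cumtrapz(t, ey)
  deriv <- function(z) {
    c((z[2L] - z[1L]) / dt,
      (z[3:n] - z[1:(n - 2L)]) / (2 * dt),
      (z[n] - z[n - 1L]) / dt)
  }
  es <- trapz(t, vx^2 + vy^2)
  en <- trapz(t, deriv(nx)^2 + deriv(ny)^2)
  assert_that(en > 0 && es > 0, "degenerate trajectory or noise draw")
  a <- sqrt(es / (en * 10^(target_snr_db / 10)))
  out <- trajectory
  out$x <- trajectory$x + a * nx
  out$y <- trajectory$y + a * ny
  out$meta$noise_snr_db <- target_snr_db
  out
}

#' Simulate a full session set
#'
#' Generates all trials for `n` participants, both conditions (pre/post) and
#' the requested fatigue sessions and test types, with the published-table
#' population structure and optional additive velocity noise.
#'
#' @param config population configuration.
#' @param seed integer seed; the whole session set is a pure function of
#'   (config, seed).
#' @param participants number of participants (default from config).
#' @param fatigues character subset of c("ER", "IR").
#' @param test_types character subset of the configured test types.
#' @param strokes_per_test repetitions for simple strokes/triangles (default
#'   from config; oscillations always yield one trial per cell).
#' @return a list with `trials` (list of `sl_trajectory`), `manifest` (data
#'   frame: trial_id, participant, fatigue, condition, test_type, trial_index),
#'   and `population` (the participant-level parameter draw).
#' @export
simulate_session <- function(config = default_population_config(), seed = 1L,
                             participants = config$n_participants,
                             fatigues = c("ER", "IR"),
                             test_types = names(config$tests),
                             strokes_per_test = config$strokes_per_test) {
  validate_population_config(config)
  pop <- sample_population(config, seed = seed, n_participants = participants)
  set.seed(seed + 1L)
  trials <- list()
  man <- list()
  id <- 0L
  for (i in seq_len(participants)) {
    for (fat in fatigues) {
      for (cond in c("pre", "post")) {
        for (test in test_types) {
          if (!fat %in% names(config$tests[[test]])) next
          n_rep <- if (test %in% c("h_osc", "v_osc")) 1L else strokes_per_test
          pp <- participant_params(pop, i, test, fat, cond)
          sds <- between_sds(config, test, fat, cond)
          for (r in seq_len(n_rep)) {
            id <- id + 1L
            tr <- generate_trial(test, pp, config, sds = sds,
                                 meta = list(participant = i, fatigue = fat,
                                             condition = cond, trial = r))
            tr <- add_noise(tr, config$noise_snr_db)
            trials[[id]] <- tr
            man[[id]] <- data.frame(trial_id = id, participant = i, fatigue = fat,
                                    condition = cond, test_type = test, trial_index = r,
                                    stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  list(trials = trials, manifest = do.call(rbind, man), population = pop)
}
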