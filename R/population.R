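# Population configuration for the synthetic-session generator.
#
# Defaults encode the published group means and between-participant SDs of the
# lognormal parameters for each test type (simple strokes, triangles,
# horizontal/vertical oscillations), each fatigue session (external/internal
# rotation) and each condition (pre/post fatigue).  Values are in s, mm and
# ln(s) as appropriate; each entry is c(mean, sd).

tbl <- function(mean, sd) c(mean = mean, sd = sd)

#' Default population configuration
#'
#' Returns the full configuration of the synthetic-data generator: parameter
#' means and between-participant SDs per test type, fatigue session (ER/IR,
#' external/internal shoulder rotation) and condition (pre/post fatigue),
#' together with sampling and noise settings.
#'
#' Structure of `$tests`: `tests[[test_type]][[fatigue]][[role]][[condition]]`
#' is a named list of `c(mean, sd)` entries for `t0` (or `dt0`, the command
#' interval, for oscillations), `D`, `mu` and `sigma`.
#'
#' Key scalar fields:
#' * `sampling_rate_hz` (200): tablet sampling rate emulated.
#' * `strokes_per_test` (30): simple strokes / triangles repetitions.
#' * `oscillation_duration_s` (10): commanded oscillation window.
#' * `target_separation_mm` (50): distance between the two oscillation targets.
#' * `noise_snr_db` (35): additive velocity-noise target; `Inf` disables noise.
#' * `within_sd_fraction` (0.5): stroke-to-stroke jitter SD as a fraction of the
#'   between-participant SD.
#' * `n_participants` (20).
#'
#' @return a list, see Details.
#' @export
default_population_config <- function() {
  simple_ER <- list(
    agonist = list(
      pre  = list(t0 = tbl(0.23, 0.08), D = tbl(214, 19.8), mu = tbl(-1.42, 0.18), sigma = tbl(0.27, 0.06)),
      post = list(t0 = tbl(0.25, 0.07), D = tbl(217, 21.6), mu = tbl(-1.41, 0.15), sigma = tbl(0.30, 0.06))),
    antagonist = list(
      pre  = list(t0 = tbl(0.40, 0.12), D = tbl(30.6, 6.94), mu = tbl(-1.78, 0.18), sigma = tbl(0.36, 0.11)),
      post = list(t0 = tbl(0.44, 0.12), D = tbl(33.0, 8.33), mu = tbl(-1.82, 0.20), sigma = tbl(0.39, 0.12))))
  simple_IR <- list(
    agonist = list(
      pre  = list(t0 = tbl(0.21, 0.08), D = tbl(208, 25.0), mu = tbl(-1.43, 0.18), sigma = tbl(0.27, 0.05)),
      post = list(t0 = tbl(0.24, 0.08), D = tbl(208, 23.7), mu = tbl(-1.46, 0.18), sigma = tbl(0.29, 0.05))),
    antagonist = list(
      pre  = list(t0 = tbl(0.40, 0.11), D = tbl(29.0, 6.66), mu = tbl(-1.86, 0.22), sigma = tbl(0.36, 0.08)),
      post = list(t0 = tbl(0.41, 0.11), D = tbl(30.4, 7.53), mu = tbl(-1.80, 0.16), sigma = tbl(0.36, 0.10))))
  triangle_ER <- list(
    stroke = list(
      pre  = list(t0 = tbl(0.23, 0.08), D = tbl(154.9, 9.29), mu = tbl(-0.80, 0.21), sigma = tbl(0.19, 0.03)),
      post = list(t0 = tbl(0.23, 0.06), D = tbl(158.0, 10.2), mu = tbl(-0.77, 0.18), sigma = tbl(0.19, 0.03))))
  # No published triangle table for the IR session (multivariate gate closed);
  # IR defaults reuse the pre-fatigue ER row for both conditions (no shift).
  triangle_IR <- list(
    stroke = list(
      pre  = triangle_ER$stroke$pre,
      post = triangle_ER$stroke$pre))
  h_osc <- list(
    ER = list(oscillation = list(
      pre  = list(dt0 = tbl(0.08, 0.01), D = tbl(124.8, 23.7), mu = tbl(-0.81, 0.07), sigma = tbl(0.06, 0.004)),
      post = list(dt0 = tbl(0.09, 0.01), D = tbl(126.2, 26.2), mu = tbl(-0.75, 0.10), sigma = tbl(0.06, 0.004)))),
    IR = list(oscillation = list(
      pre  = list(dt0 = tbl(0.09, 0.01), D = tbl(124.2, 24.5), mu = tbl(-0.81, 0.11), sigma = tbl(0.06, 0.004)),
      post = list(dt0 = tbl(0.09, 0.01), D = tbl(125.2, 28.8), mu = tbl(-0.75, 0.10), sigma = tbl(0.06, 0.004)))))
  v_osc <- list(
    ER = list(oscillation = list(
      pre  = list(dt0 = tbl(0.09, 0.01), D = tbl(118.4, 19.2), mu = tbl(-0.73, 0.11), sigma = tbl(0.06, 0.004)),
      post = list(dt0 = tbl(0.09, 0.01), D = tbl(123.9, 19.4), mu = tbl(-0.73, 0.14), sigma = tbl(0.06, 0.004)))),
    IR = list(oscillation = list(
      pre  = list(dt0 = tbl(0.09, 0.02), D = tbl(119.4, 26.0), mu = tbl(-0.74, 0.17), sigma = tbl(0.06, 0.004)),
      post = list(dt0 = tbl(0.10, 0.01), D = tbl(119.8, 21.6), mu = tbl(-0.69, 0.16), sigma = tbl(0.06, 0.004)))))

  list(
    sampling_rate_hz = 200,
    n_participants = 20,
    strokes_per_test = 30,
    oscillation_duration_s = 10,
    target_separation_mm = 50,
    noise_snr_db = 35,
    within_sd_fraction = 0.5,
    osc_first_t0 = 0.20,
    triangle_stroke_gap = tbl(0.55, 0.05),
    angles = list(
      simple_bearing = 0,
      # jitter SDs (rad) chosen so E|cos(theta_s - bearing)| matches the
      # published |cos(theta_s)| group means (~0.81 agonist, ~0.95 antagonist)
      agonist_jitter_sd = 0.6,
      antagonist_jitter_sd = 0.3,
      triangle_bearings = c(0, -2 * pi / 3, 2 * pi / 3),
      triangle_jitter_sd = 0.3,
      osc_jitter_sd = 0.15
    ),
    tests = list(
      simple = list(ER = simple_ER, IR = simple_IR),
      triangle = list(ER = triangle_ER, IR = triangle_IR),
      h_osc = h_osc,
      v_osc = v_osc
    )
  )
}

validate_population_config <- function(config) {
  assert_that(is.list(config) && !is.null(config$tests), "config must be a population config list")
  assert_that(config$sampling_rate_hz > 0, "config error: sampling rate must be > 0")
  assert_that(config$n_participants >= 1, "config error: need n >= 1 participants")
  assert_that(config$within_sd_fraction >= 0, "config error: negative jitter fraction")
  for (test in names(config$tests)) {
    for (fat in names(config$tests[[test]])) {
      for (role in names(config$tests[[test]][[fat]])) {
        for (cond in names(config$tests[[test]][[fat]][[role]])) {
          pars <- config$tests[[test]][[fat]][[role]][[cond]]
          for (p in names(pars)) {
            assert_that(length(pars[[p]]) == 2L && all(is.finite(pars[[p]])),
                        sprintf("config error: %s/%s/%s/%s/%s must be c(mean, sd)", test, fat, role, cond, p))
            assert_that(pars[[p]][[2L]] >= 0,
                        sprintf("config error: negative SD for %s/%s/%s/%s/%s", test, fat, role, cond, p))
          }
        }
      }
    }
  }
  invisible(TRUE)
}

# Parameters that must stay strictly positive when sampled.
POSITIVE_PARAMS <- c("t0", "dt0", "D", "sigma")
PARAM_FLOOR <- c(t0 = 0.01, dt0 = 0.02, D = 1, sigma = 0.02)

#' Draw participant-level parameter sets from a population configuration
#'
#' Each participant receives, for every test type, fatigue session and role, a
#' latent trait per parameter (a standard normal draw shared between the pre
#' and post conditions, so that a participant keeps their identity across the
#' fatigue intervention).  The participant-level mean under a condition is
#' `mean_cond + trait * sd_cond`; positive-only parameters (t0, dt0, D, sigma)
#' are redrawn until positive.
#'
#' @param config a population configuration, see [default_population_config()].
#' @param seed integer seed; draws are a pure function of (config, seed).
#' @param n_participants optional override of `config$n_participants`.
#' @return a long data frame with columns participant, test_type, fatigue,
#'   role, condition, parameter, value.
#' @export
sample_population <- function(config = default_population_config(), seed = 1L,
                              n_participants = config$n_participants) {
  validate_population_config(config)
  set.seed(seed)
  rows <- list()
  k <- 0L
  for (i in seq_len(n_participants)) {
    for (test in names(config$tests)) {
      for (fat in names(config$tests[[test]])) {
        for (role in names(config$tests[[test]][[fat]])) {
          conds <- config$tests[[test]][[fat]][[role]]
          params <- names(conds[[1L]])
          for (p in params) {
            # shared trait across pre/post; redraw if truncation violated
            for (try in 1:100) {
              z <- stats::rnorm(1)
              vals <- vapply(names(conds), function(cond) {
                ms <- conds[[cond]][[p]]
                ms[[1L]] + z * ms[[2L]]
              }, numeric(1))
              if (!(p %in% POSITIVE_PARAMS) || all(vals > 0)) break
            }
            if (p %in% POSITIVE_PARAMS) vals <- pmax(vals, PARAM_FLOOR[[p]])
            for (cond in names(conds)) {
              k <- k + 1L
              rows[[k]] <- data.frame(
                participant = i, test_type = test, fatigue = fat, role = role,
                condition = cond, parameter = p, value = vals[[cond]],
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Extract one participant's parameter means
#'
#' @param pop a population draw from [sample_population()].
#' @param participant,test_type,fatigue,condition cell selectors.
#' @return a list `role -> named numeric vector` of parameter means.
#' @export
participant_params <- function(pop, participant, test_type, fatigue, condition) {
  sel <- pop$participant == participant & pop$test_type == test_type &
    pop$fatigue == fatigue & pop$condition == condition
  sub <- pop[sel, , drop = FALSE]
  assert_that(nrow(sub) > 0L, "no such participant/test/fatigue/condition in population draw")
  out <- list()
  for (role in unique(sub$role)) {
    rr <- sub[sub$role == role, ]
    out[[role]] <- stats::setNames(rr$value, rr$parameter)
  }
  out
}

# Between-participant SDs for a given cell, role -> named vector (used to set
# within-participant stroke jitter).
between_sds <- function(config, test_type, fatigue, condition) {
  cell <- config$tests[[test_type]][[fatigue]]
  lapply(cell, function(role_cfg) {
    vapply(role_cfg[[condition]], function(ms) ms[[2L]], numeric(1))
  })
}
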