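# Closed-form Sigma-Lognormal forward model.
#
# A planar rapid movement is modelled as the vector sum of lognormal impulse
# responses.  Each neuromuscular component i contributes a speed profile
#
#   v_i(t) = D_i * Lambda(t; t0_i, mu_i, sigma_i^2)
#
# where Lambda is the 3-parameter (time-shifted) lognormal density, and the
# instantaneous direction sweeps a circle arc from theta_s to theta_e following
# the lognormal's cumulative distribution.

#' Construct a lognormal component
#'
#' One neuromuscular impulse response of the Sigma-Lognormal model.
#'
#' @param t0 command emission time in seconds, relative to the stimulus at T=0.
#' @param D command amplitude in mm (distance covered by the component).
#' @param mu log time delay, ln(s).
#' @param sigma log response time, ln(s); must be > 0.
#' @param theta_s,theta_e starting and ending angles in radians, counter
#'   clockwise from +x; wrapped to (-pi, pi].
#' @return an object of class `lognormal_component` (a named list).
#' @examples
#' lognormal_component(t0 = 0.23, D = 214, mu = -1.42, sigma = 0.27)
#' @export
lognormal_component <- function(t0, D, mu, sigma, theta_s = 0, theta_e = theta_s) {
  for (v in list(t0, D, mu, sigma, theta_s, theta_e)) {
    assert_that(is_number(v), "all component parameters must be finite scalars")
  }
  assert_that(sigma > 0, "invalid parameter: sigma must be > 0")
  assert_that(D > 0, "invalid parameter: D must be > 0")
  structure(
    list(t0 = t0, D = D, mu = mu, sigma = sigma,
         theta_s = wrap_angle(theta_s), theta_e = wrap_angle(theta_e)),
    class = "lognormal_component"
  )
}

#' @export
print.lognormal_component <- function(x, ...) {
  cat(sprintf(
    "<lognormal component> t0=%.4g s  D=%.4g mm  mu=%.4g  sigma=%.4g  theta=[%.3g -> %.3g] rad\n",
    x$t0, x$D, x$mu, x$sigma, x$theta_s, x$theta_e))
  invisible(x)
}

as_component_df <- function(components) {
  if (is.data.frame(components)) {
    need <- c("t0", "D", "mu", "sigma", "theta_s", "theta_e")
    assert_that(all(need %in% names(components)),
                paste("component table must have columns:", paste(need, collapse = ", ")))
    return(components)
  }
  if (inherits(components, "lognormal_component") ||
      (is.list(components) && all(c("t0", "D", "mu", "sigma") %in% names(components)))) {
    components <- list(components)
  }
  do.call(rbind, lapply(components, function(cc) {
    cc <- unclass(cc)
    cc$theta_s <- cc$theta_s %||% 0
    cc$theta_e <- cc$theta_e %||% cc$theta_s
    as.data.frame(cc[c("t0", "D", "mu", "sigma", "theta_s", "theta_e")])
  }))
}

#' Lognormal speed profile of one component
#'
#' Evaluates D * Lambda(t; t0, mu, sigma^2).  The support starts at t0: the
#' speed is exactly zero for all t <= t0.
#'
#' @param component a [lognormal_component()] (or a list/1-row data frame with
#'   the same fields).
#' @param times numeric vector of times (s), finite.
#' @return numeric vector of speeds (mm/s), non-negative.
#' @export
lognormal_speed <- function(component, times) {
  cc <- as_component_df(component)[1L, ]
  assert_that(is.numeric(times) && all(is.finite(times)), "times must be finite")
  assert_that(cc$sigma > 0 && cc$D > 0, "invalid parameter: sigma and D must be > 0")
  tau <- times - cc$t0
  out <- numeric(length(times))
  pos <- tau > 0
  lt <- log(tau[pos])
  out[pos] <- cc$D / (cc$sigma * sqrt(2 * pi) * tau[pos]) *
    exp(-((lt - cc$mu)^2) / (2 * cc$sigma^2))
  out
}

#' Angular profile of one component
#'
#' The direction of motion sweeps a circle arc from `theta_s` to `theta_e`,
#' following the lognormal cumulative distribution:
#' theta(t) = theta_s + (theta_e - theta_s)/2 * (1 + erf((ln(t - t0) - mu) / (sigma*sqrt(2)))).
#'
#' @inheritParams lognormal_speed
#' @return numeric vector of angles (rad); equals `theta_s` for t <= t0 and
#'   tends to `theta_e` as t grows.
#' @export
angular_profile <- function(component, times) {
  cc <- as_component_df(component)[1L, ]
  assert_that(is.numeric(times) && all(is.finite(times)), "times must be finite")
  assert_that(cc$sigma > 0 && cc$D > 0, "invalid parameter: sigma and D must be > 0")
  tau <- times - cc$t0
  out <- rep(cc$theta_s, length(times))
  pos <- tau > 0
  z <- (log(tau[pos]) - cc$mu) / (cc$sigma * sqrt(2))
  out[pos] <- cc$theta_s + (cc$theta_e - cc$theta_s) / 2 * (1 + erf(z))
  out
}

#' Superpose lognormal components into a planar velocity
#'
#' Vector summation of the component velocities:
#' v(t) = sum_i D_i * [cos(theta_i(t)), sin(theta_i(t))] * Lambda_i(t).
#'
#' @param components a list of [lognormal_component()]s or a data frame with
#'   columns t0, D, mu, sigma, theta_s, theta_e (one row per component).
#' @param times numeric vector of times (s).
#' @return a data frame with columns `t`, `vx`, `vy`, `speed` (mm/s).
#' @export
superpose <- function(components, times) {
  df <- as_component_df(components)
  assert_that(!is.null(df) && nrow(df) >= 1L, "component list must be non-empty")
  vx <- numeric(length(times))
  vy <- numeric(length(times))
  for (i in seq_len(nrow(df))) {
    sp <- lognormal_speed(df[i, ], times)
    th <- angular_profile(df[i, ], times)
    vx <- vx + sp * cos(th)
    vy <- vy + sp * sin(th)
  }
  data.frame(t = times, vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2))
}

#' Derived timing parameters of a lognormal component
#'
#' Motor-program execution descriptors of one impulse response, from standard
#' lognormal statistics:
#' * mode: `t0 + exp(mu - sigma^2)` -- time of the speed maximum (s);
#' * median: `t0 + exp(mu)` -- time at which half the distance is covered (s);
#' * time_delay: `t0 + exp(mu + sigma^2/2)` -- mean response latency (s);
#' * response_time: `exp(mu + sigma^2/2) * sqrt(exp(sigma^2) - 1)` -- spread of
#'   the impulse response (s);
#' * asymmetry: `(exp(sigma^2) + 2) * sqrt(exp(sigma^2) - 1)` -- skewness
#'   (dimensionless).
#'
#' For sigma > 0 the ordering mode < median < time_delay always holds.
#'
#' @param component a [lognormal_component()] (angles are ignored).
#' @return a named list with fields mode, median, time_delay, response_time,
#'   asymmetry.
#' @export
derived_parameters <- function(component) {
  cc <- as_component_df(component)[1L, ]
  assert_that(cc$sigma > 0 && cc$D > 0, "invalid parameter: sigma and D must be > 0")
  s2 <- cc$sigma^2
  list(
    mode = cc$t0 + exp(cc$mu - s2),
    median = cc$t0 + exp(cc$mu),
    time_delay = cc$t0 + exp(cc$mu + s2 / 2),
    response_time = exp(cc$mu + s2 / 2) * sqrt(expm1(s2)),
    asymmetry = (exp(s2) + 2) * sqrt(expm1(s2))
  )
}

# Vectorised version used on component tables; returns a data frame.
derived_parameters_df <- function(df) {
  s2 <- df$sigma^2
  data.frame(
    mode = df$t0 + exp(df$mu - s2),
    median = df$t0 + exp(df$mu),
    time_delay = df$t0 + exp(df$mu + s2 / 2),
    response_time = exp(df$mu + s2 / 2) * sqrt(expm1(s2)),
    asymmetry = (exp(s2) + 2) * sqrt(expm1(s2))
  )
}

#' Reaction time of a speed series
#'
#' First time at or after the stimulus at which the speed reaches 10% of its
#' maximum over the trial.
#'
#' @param times numeric vector of times (s), ascending.
#' @param speed numeric vector of speeds (mm/s), same length.
#' @param t_stimulus stimulus time (s), default 0.
#' @param fraction threshold fraction of the maximal speed, default 0.10.
#' @return reaction time in seconds.
#' @export
reaction_time <- function(times, speed, t_stimulus = 0, fraction = 0.10) {
  assert_that(length(times) == length(speed), "times and speed must align")
  keep <- times >= t_stimulus
  assert_that(any(keep), "no samples at or after the stimulus")
  vmax <- max(speed[keep])
  assert_that(is.finite(vmax) && vmax > 0, "undefined reaction time: speed has no positive maximum")
  idx <- which(keep & speed >= fraction * vmax)[1L]
  times[idx]
}

#' Command conduction duration
#'
#' Absolute difference between a component's command time and the trial's
#' reaction time, |t0 - RT|: an estimate of how long the motor command takes to
#' propagate to the end effector.
#'
#' @param t0 command emission time (s).
#' @param rt reaction time (s), see [reaction_time()].
#' @return conduction duration in seconds.
#' @export
conduction_time <- function(t0, rt) abs(t0 - rt)
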