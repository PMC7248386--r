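# Small numeric helpers shared across modules.

#' Trapezoidal integral
#' @param t abscissae (ascending)
#' @param y ordinates
#' @return scalar integral
#' @keywords internal
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum(diff(t) * (y[-1L] + y[-n]) / 2)
}

#' Cumulative trapezoidal integral, same length as input (starts at 0)
#' @keywords internal
cumtrapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum(diff(t) * (y[-1L] + y[-n]) / 2))
}

#' Error function
#' @keywords internal
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Wrap angles to (-pi, pi]
#' @keywords internal
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w <= -pi] <- pi
  w
}

# stopifnot-style check with a readable message
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# The discrete-differentiation operator implied by integrating a velocity to
# positions (trapezoid) and differentiating back (central differences,
# one-sided at the ends): interior samples become (v[i-1] + 2 v[i] + v[i+1])/4.
# Applying it to model velocities puts model and measured velocity estimates
# through the same linear filter, removing the estimation bias it would
# otherwise cause.  Works on vectors and on matrix columns.
blur_binomial <- function(v) {
  if (is.matrix(v)) {
    n <- nrow(v)
    if (n < 3L) return(v)
    out <- v
    out[1L, ] <- (v[1L, ] + v[2L, ]) / 2
    out[n, ] <- (v[n - 1L, ] + v[n, ]) / 2
    out[2:(n - 1L), ] <- (v[1:(n - 2L), , drop = FALSE] +
                            2 * v[2:(n - 1L), , drop = FALSE] +
                            v[3:n, , drop = FALSE]) / 4
    return(out)
  }
  n <- length(v)
  if (n < 3L) return(v)
  c((v[1L] + v[2L]) / 2,
    (v[1:(n - 2L)] + 2 * v[2:(n - 1L)] + v[3:n]) / 4,
    (v[n - 1L] + v[n]) / 2)
}
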