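# Levenberg-Marquardt refinement with analytic Jacobians.
#
# The planar model is v(t) = sum_i D_i * Lambda_i(t) * [cos theta_i(t),
# sin theta_i(t)] with Lambda the shifted lognormal density and theta an
# erf-shaped arc sweep.  All derivatives are closed-form, which makes
# Gauss-Newton steps cheap and precise where derivative-free optimisers crawl
# (the SSE valley is narrow and strongly parameter-correlated).

# Per-component model values and partial derivatives on a time grid.
# Returns list(vx, vy, Jx, Jy): Jx/Jy are n x 6 matrices with columns
# (t0, D, mu, sigma, theta_s, theta_e).
comp_grad <- function(cc, t) {
  n <- length(t)
  Jx <- matrix(0, n, 6L)
  Jy <- matrix(0, n, 6L)
  vx <- numeric(n); vy <- numeric(n)
  tau <- t - cc$t0
  pos <- tau > 0
  if (any(pos)) {
    tau <- tau[pos]
    P <- log(tau) - cc$mu
    s2 <- cc$sigma^2
    lam <- exp(-P^2 / (2 * s2)) / (cc$sigma * sqrt(2 * pi) * tau)
    z <- P / (cc$sigma * sqrt(2))
    ez <- exp(-z^2)
    Phi <- (1 + erf(z)) / 2
    th <- cc$theta_s + (cc$theta_e - cc$theta_s) * Phi
    cth <- cos(th); sth <- sin(th)
    dlam_dt0 <- lam * (1 + P / s2) / tau
    dlam_dmu <- lam * P / s2
    dlam_dsig <- lam * (P^2 / s2 - 1) / cc$sigma
    dPhi_dz <- ez / sqrt(pi)
    dth_scale <- (cc$theta_e - cc$theta_s) * dPhi_dz
    # z = (ln tau - mu)/(sigma sqrt2), tau = t - t0, so dz/dt0 = -1/(tau sigma sqrt2)
    dth_dt0 <- dth_scale * (-1 / (tau * cc$sigma * sqrt(2)))
    dth_dmu <- dth_scale * (-1 / (cc$sigma * sqrt(2)))
    dth_dsig <- dth_scale * (-z / cc$sigma)
    dth_dths <- 1 - Phi
    dth_dthe <- Phi
    D <- cc$D
    vx[pos] <- D * lam * cth
    vy[pos] <- D * lam * sth
    Jx[pos, 1L] <- D * (dlam_dt0 * cth - lam * sth * dth_dt0)
    Jy[pos, 1L] <- D * (dlam_dt0 * sth + lam * cth * dth_dt0)
    Jx[pos, 2L] <- lam * cth
    Jy[pos, 2L] <- lam * sth
    Jx[pos, 3L] <- D * (dlam_dmu * cth - lam * sth * dth_dmu)
    Jy[pos, 3L] <- D * (dlam_dmu * sth + lam * cth * dth_dmu)
    Jx[pos, 4L] <- D * (dlam_dsig * cth - lam * sth * dth_dsig)
    Jy[pos, 4L] <- D * (dlam_dsig * sth + lam * cth * dth_dsig)
    Jx[pos, 5L] <- -D * lam * sth * dth_dths
    Jy[pos, 5L] <- D * lam * cth * dth_dths
    Jx[pos, 6L] <- -D * lam * sth * dth_dthe
    Jy[pos, 6L] <- D * lam * cth * dth_dthe
  }
  list(vx = vx, vy = vy, Jx = Jx, Jy = Jy)
}

# `par` is the packed parameter vector (6 per component); keeping the hot
# path free of data.frame construction matters for the LM inner loop.
model_and_jacobian <- function(par, t, blur = TRUE) {
  n <- length(t)
  k <- length(par) %/% 6L
  vx <- numeric(n); vy <- numeric(n)
  J <- matrix(0, 2L * n, 6L * k)
  for (i in seq_len(k)) {
    o <- 6L * (i - 1L)
    g <- comp_grad(list(t0 = par[o + 1L], D = par[o + 2L], mu = par[o + 3L],
                        sigma = par[o + 4L], theta_s = par[o + 5L],
                        theta_e = par[o + 6L]), t)
    vx <- vx + g$vx
    vy <- vy + g$vy
    cols <- (o + 1L):(o + 6L)
    J[seq_len(n), cols] <- if (blur) blur_binomial(g$Jx) else g$Jx
    J[n + seq_len(n), cols] <- if (blur) blur_binomial(g$Jy) else g$Jy
  }
  if (blur) {
    vx <- blur_binomial(vx)
    vy <- blur_binomial(vy)
  }
  list(vx = vx, vy = vy, J = J)
}

# Box-constrained Levenberg-Marquardt on the planar velocity residual.
# df: component data frame; vx, vy: target velocity; lower/upper: vectors of
# length 6*k in component-major order (t0, D, mu, sigma, theta_s, theta_e).
lm_refine_planar <- function(df, t, vx, vy, lower, upper, max_iter = 60) {
  par <- comp_df_to_par(df)
  par <- pmin(pmax(par, lower), upper)
  k <- length(par) %/% 6L
  d_idx <- seq(2L, by = 6L, length.out = k)
  s_idx <- seq(4L, by = 6L, length.out = k)
  mj <- model_and_jacobian(par, t)
  r <- c(mj$vx - vx, mj$vy - vy)
  sse <- sum(r^2)
  lambda <- 1e-3
  for (it in seq_len(max_iter)) {
    J <- mj$J
    g <- crossprod(J, r)
    H <- crossprod(J)
    dH <- diag(H)
    dH[dH < 1e-12] <- 1e-12
    improved <- FALSE
    for (inner in 1:8) {
      A <- H + lambda * diag(dH, nrow = length(dH))
      delta <- tryCatch(solve(A, -g), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      trial <- pmin(pmax(par + as.vector(delta), lower), upper)
      if (any(trial[s_idx] <= 0) || any(trial[d_idx] <= 0)) { lambda <- lambda * 10; next }
      tmj <- model_and_jacobian(trial, t)
      tr <- c(tmj$vx - vx, tmj$vy - vy)
      tsse <- sum(tr^2)
      if (is.finite(tsse) && tsse < sse) {
        rel <- (sse - tsse) / max(sse, 1e-300)
        par <- trial; mj <- tmj; r <- tr; sse <- tsse
        lambda <- max(lambda / 3, 1e-12)
        improved <- TRUE
        if (rel < 1e-12) return(par_to_comp_df(par))
        break
      }
      lambda <- lambda * 10
    }
    if (!improved) break
  }
  par_to_comp_df(par)
}

# Magnitude-only variant: fit D * Lambda to a speed residual (angles unused).
lm_refine_speed <- function(par, t, r, lower, upper, max_iter = 50) {
  cc <- function(p) list(t0 = p[[1L]], D = p[[2L]], mu = p[[3L]], sigma = p[[4L]],
                         theta_s = 0, theta_e = 0)
  par <- pmin(pmax(par, lower), upper)
  g <- comp_grad(cc(par), t)
  res <- g$vx - r
  sse <- sum(res^2)
  lambda <- 1e-3
  for (it in seq_len(max_iter)) {
    J <- g$Jx[, 1:4, drop = FALSE]
    gr <- crossprod(J, res)
    H <- crossprod(J)
    dH <- diag(H); dH[dH < 1e-12] <- 1e-12
    improved <- FALSE
    for (inner in 1:8) {
      A <- H + lambda * diag(dH, nrow = 4L)
      delta <- tryCatch(solve(A, -gr), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      trial <- pmin(pmax(par + as.vector(delta), lower), upper)
      if (trial[[4L]] <= 0 || trial[[2L]] <= 0) { lambda <- lambda * 10; next }
      tg <- comp_grad(cc(trial), t)
      tres <- tg$vx - r
      tsse <- sum(tres^2)
      if (is.finite(tsse) && tsse < sse) {
        rel <- (sse - tsse) / max(sse, 1e-300)
        par <- trial; g <- tg; res <- tres; sse <- tsse
        lambda <- max(lambda / 3, 1e-12)
        improved <- TRUE
        if (rel < 1e-12) return(par)
        break
      }
      lambda <- lambda * 10
    }
    if (!improved) break
  }
  par
}
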