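# Forward Sigma-Lognormal model: speed profile, arc angles, superposition,
# derived timing parameters, reaction time.

test_that("lognormal_speed matches its closed forms on a dense grid", {
  cmp <- lognormal_component(t0 = 0.2, D = 200, mu = -1.4, sigma = 0.3)
  tt <- seq(0, 5, by = 1e-3)
  sp <- lognormal_speed(cmp, tt)

  expect_identical(lognormal_speed(cmp, 0.1), 0)           # support starts at t0
  expect_identical(sp[tt <= 0.2], rep(0, sum(tt <= 0.2)))
  expect_true(all(sp >= 0))

  # dense-grid argmax oracle vs t0 + exp(mu - sigma^2)
  expect_lt(abs(tt[which.max(sp)] - (0.2 + exp(-1.4 - 0.09))), 1e-3)
  # peak height closed form D * exp(sigma^2/2 - mu) / (sigma sqrt(2 pi))
  expect_equal(max(sp), 200 * exp(0.045 + 1.4) / (0.3 * sqrt(2 * pi)),
               tolerance = 1e-4)   # grid-sampled maximum vs analytic peak
  # quadrature oracle: area equals the command amplitude
  expect_equal(sum(diff(tt) * (sp[-1] + sp[-length(sp)]) / 2), 200,
               tolerance = 1e-3)
})

test_that("distance conservation holds across the sigma range", {
  tt <- seq(0, 20, by = 5e-4)
  for (sg in c(0.05, 0.1, 0.27, 0.45, 0.6)) {
    cmp <- lognormal_component(0.2, 150, -1.2, sg)
    sp <- lognormal_speed(cmp, tt)
    area <- sum(diff(tt) * (sp[-1] + sp[-length(sp)]) / 2)
    expect_lt(abs(area - 150) / 150, 1e-3)
  }
})

test_that("invalid parameters are rejected", {
  expect_error(lognormal_component(0.2, 100, -1.4, 0), "sigma")
  expect_error(lognormal_component(0.2, -5, -1.4, 0.3), "D")
  expect_error(lognormal_speed(list(t0 = 0, D = 1, mu = 0, sigma = 1), c(0, NA)),
               "finite")
})

test_that("angular_profile sweeps the arc through its characteristic points", {
  deg <- lognormal_component(0.2, 100, -1.4, 0.3, theta_s = 0.5, theta_e = 0.5)
  tt <- seq(0, 3, by = 0.01)
  expect_equal(angular_profile(deg, tt), rep(0.5, length(tt)))  # degenerate arc

  arc <- lognormal_component(0.2, 100, -1.4, 0.3, theta_s = 0.2, theta_e = 1.0)
  # erf(0) = 0 at the median time t0 + exp(mu)
  expect_equal(angular_profile(arc, 0.2 + exp(-1.4)), 0.6, tolerance = 1e-12)
  # erf tail: far beyond the median the angle is theta_e
  expect_lt(abs(angular_profile(arc, 0.2 + 100 * exp(-1.4)) - 1.0), 1e-6)
  expect_equal(angular_profile(arc, 0.1), 0.2)                 # before onset
})

test_that("superpose is linear and vector-sums components", {
  tt <- seq(0, 4, by = 1 / 200)
  a <- lognormal_component(0.2, 150, -1.4, 0.25, 0, 0)
  b <- lognormal_component(0.4, 40, -1.7, 0.35, pi, pi)

  # single component along +x has no y velocity
  va <- superpose(list(a), tt)
  expect_equal(va$vy, rep(0, length(tt)), tolerance = 1e-9)
  expect_equal(va$vx, lognormal_speed(a, tt))

  # equal-and-opposite pair: net displacement (0, 0)
  a2 <- lognormal_component(0.2, 150, -1.4, 0.25, pi, pi)
  v0 <- superpose(list(a, a2), tt)
  expect_lt(abs(sum(diff(tt) * (v0$vx[-1] + v0$vx[-length(tt)]) / 2)), 1e-9)

  # collinear opposed pair: speed is |D1 L1 - D2 L2| pointwise
  vab <- superpose(list(a, b), tt)
  expect_equal(vab$speed, abs(lognormal_speed(a, tt) - lognormal_speed(b, tt)),
               tolerance = 1e-9)

  # linearity: superpose(A u B) = superpose(A) + superpose(B)
  expect_equal(vab$vx, va$vx + superpose(list(b), tt)$vx, tolerance = 1e-12)
  expect_error(superpose(list(), tt), "non-empty")
})

test_that("derived parameters reproduce printed means and standard moments", {
  # printed group means (mu = -1.42, sigma = 0.27) give the printed 0.07 s
  dp <- derived_parameters(lognormal_component(0.23, 214, -1.42, 0.27))
  expect_equal(round(dp$response_time, 2), 0.07)

  # ordering invariant and degenerate limit
  expect_true(dp$mode < dp$median && dp$median < dp$time_delay)
  tiny <- derived_parameters(lognormal_component(0.3, 1, -1.0, 1e-9))
  expect_equal(tiny$mode, tiny$median, tolerance = 1e-6)
  expect_equal(tiny$median, tiny$time_delay, tolerance = 1e-6)
  expect_equal(tiny$median, 0.3 + exp(-1), tolerance = 1e-6)

  # asymmetry equals the third standardized moment of the impulse response
  cmp <- lognormal_component(0.1, 1, -1.3, 0.25)
  tt <- seq(0, 30, by = 1e-4)
  w <- lognormal_speed(cmp, tt)
  dt <- 1e-4
  m1 <- sum(tt * w) * dt
  v2 <- sum((tt - m1)^2 * w) * dt
  m3 <- sum((tt - m1)^3 * w) * dt
  expect_equal(derived_parameters(cmp)$asymmetry, m3 / v2^1.5, tolerance = 1e-4)
})

test_that("ordering gaps close as sigma shrinks", {
  gaps <- sapply(c(0.4, 0.2, 0.1, 0.05), function(sg) {
    dp <- derived_parameters(lognormal_component(0.2, 1, -1.4, sg))
    dp$time_delay - dp$mode
  })
  expect_true(all(diff(gaps) < 0))
})

test_that("reaction_time finds the 10% crossing", {
  tt <- seq(0, 1, by = 0.001)
  expect_equal(reaction_time(tt, 100 * tt), 0.1)   # linear ramp oracle

  cmp <- lognormal_component(0.2, 150, -1.4, 0.25)
  grid <- seq(0, 3, by = 0.001)
  sp <- lognormal_speed(cmp, grid)
  rt <- reaction_time(grid, sp)
  expect_equal(rt, grid[which(sp >= 0.1 * max(sp))[1]])  # grid-scan oracle
  expect_equal(conduction_time(cmp$t0, rt), abs(0.2 - rt))

  expect_error(reaction_time(tt, rep(0, length(tt))), "positive maximum")
})
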