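# Role classification, phase splitting, artifact/outlier filtering, rhythm.

comp_row <- function(t0, D, theta, mu = -1.4, sigma = 0.25) {
  data.frame(t0 = t0, D = D, mu = mu, sigma = sigma, theta_s = theta, theta_e = theta)
}

test_that("classify_simple_stroke follows the starting-angle rule", {
  # single component along the bearing -> agonist
  one <- classify_simple_stroke(comp_row(0.2, 100, 0), bearing = 0)
  expect_equal(one$role, "agonist")
  expect_true(one$retained)

  # opposite direction -> antagonist
  two <- classify_simple_stroke(rbind(comp_row(0.2, 100, 0), comp_row(0.4, 30, pi)),
                                bearing = 0)
  expect_equal(two$role, c("agonist", "antagonist"))

  # largest D wins within a side (brute-force max oracle)
  many <- rbind(comp_row(0.2, 80, 0.1), comp_row(0.3, 120, -0.2),
                comp_row(0.4, 60, 0.3), comp_row(0.5, 20, pi))
  cl <- classify_simple_stroke(many, bearing = 0)
  best <- which.max(ifelse(cos(many$theta_s) > 0, many$D, -Inf))
  expect_equal(which(cl$role == "agonist"), best)
  expect_equal(cl$reject_reason[is.na(cl$role)], rep("unassigned", 2))

  # strict inequality: just past perpendicular counts as antagonist
  perp <- classify_simple_stroke(rbind(comp_row(0.2, 100, pi / 2 + 0.01)), bearing = 0)
  expect_equal(perp$role, "agonist")  # single-component rule dominates
  perp2 <- classify_simple_stroke(rbind(comp_row(0.2, 100, pi / 2 + 0.01),
                                        comp_row(0.3, 50, 0)), bearing = 0)
  expect_equal(perp2$role, c("antagonist", "agonist"))

  expect_error(classify_simple_stroke(comp_row(0.2, 1, 0)[0, ], 0), "component")
})

test_that("assign_triangle_strokes maps the three largest and rejects misaligned", {
  b <- c(0, -2 * pi / 3, 2 * pi / 3)
  comps <- rbind(comp_row(0.2, 150, 0.1), comp_row(0.8, 160, b[2] + 0.1),
                 comp_row(1.4, 140, b[3] - 0.1), comp_row(0.5, 12, 1),
                 comp_row(1.1, 9, -1))
  res <- assign_triangle_strokes(comps, b)
  expect_false(res$rejected)
  expect_equal(res$components$role[1:3], c("stroke1", "stroke2", "stroke3"))
  expect_true(all(is.na(res$components$role[4:5])))

  # dominant component anti-aligned with its side -> trial rejected
  bad <- comps
  bad$theta_s[2] <- b[2] + pi
  expect_true(assign_triangle_strokes(bad, b)$rejected)

  # fewer than 3 components -> rejected
  expect_true(assign_triangle_strokes(comps[1:2, ], b)$rejected)
})

test_that("classification is invariant under global rotation", {
  rot <- 1.1
  comps <- rbind(comp_row(0.2, 100, 0.2), comp_row(0.4, 30, pi - 0.2))
  a <- classify_simple_stroke(comps, bearing = 0)
  comps2 <- comps
  comps2$theta_s <- comps$theta_s + rot
  comps2$theta_e <- comps$theta_e + rot
  b <- classify_simple_stroke(comps2, bearing = rot)
  expect_equal(a$role, b$role)
})

test_that("split_oscillation_phases bins, filters artifacts and labels direction", {
  comps <- rbind(comp_row(1.5, 120, 0.3), comp_row(5, 110, pi - 0.2),
                 comp_row(11, 100, 0.1), comp_row(6, 40, 0.2))
  out <- split_oscillation_phases(comps, "horizontal")
  expect_equal(out$phase, c("acceleration", "stable", "deceleration", "stable"))
  expect_equal(out$role, c("osc_ER", "osc_IR", "osc_ER", "osc_ER"))
  expect_false(out$retained[4])                       # D = 40 < 50 mm artifact
  expect_equal(out$reject_reason[4], "artifact")

  vert <- split_oscillation_phases(comp_row(3, 120, -pi / 3), "vertical")
  expect_equal(vert$role, "osc_IR")                   # sin < 0
  # boundary cases: left-closed bins
  expect_equal(split_oscillation_phases(comp_row(2, 120, 0), "horizontal")$phase, "stable")
  expect_equal(split_oscillation_phases(comp_row(10, 120, 0), "horizontal")$phase,
               "deceleration")
})

test_that("delta_t0 is sort-then-diff", {
  expect_equal(delta_t0(c(2.1, 2.19, 2.28)), c(0.09, 0.09))
  expect_equal(delta_t0(5), numeric(0))
  shuffled <- c(2.28, 2.1, 2.19)
  expect_equal(delta_t0(shuffled), diff(sort(shuffled)))  # sort+diff oracle
})

test_that("reject_outliers drops rows outside mean +/- 3 SD in any parameter", {
  set.seed(1)
  df <- data.frame(participant = 1, test_type = "simple", role = "agonist",
                   t0 = rnorm(30, 0.23, 0.02), D = rnorm(30, 214, 10),
                   mu = rnorm(30, -1.42, 0.05), sigma = rnorm(30, 0.27, 0.02))
  # identical rows -> nothing rejected
  same <- df; same[, c("t0", "D", "mu", "sigma")] <- rep(c(0.2, 200, -1.4, 0.25), each = 30)
  r0 <- reject_outliers(same, c("t0", "D", "mu", "sigma"),
                        c("participant", "test_type", "role"))
  expect_true(all(r0$data$retained))

  # one mu at mean + 5 SD -> exactly that row dropped (brute-force bound check)
  df2 <- df
  df2$mu[7] <- mean(df$mu) + 5 * sd(df$mu)
  r1 <- reject_outliers(df2, c("t0", "D", "mu", "sigma"),
                        c("participant", "test_type", "role"))
  m <- mean(df2$mu); s <- sd(df2$mu)
  expect_identical(which(!r1$data$retained), which(df2$mu < m - 3 * s | df2$mu > m + 3 * s))
  expect_identical(which(!r1$data$retained), 7L)

  # a single out-of-bounds parameter suffices
  df3 <- df
  df3$sigma[3] <- 10
  r2 <- reject_outliers(df3, c("t0", "D", "mu", "sigma"),
                        c("participant", "test_type", "role"))
  expect_false(r2$data$retained[3])
  expect_equal(r2$data$reject_reason[3], "outlier")

  # groups below 2 rows flagged, untouched
  solo <- df[1, ]
  r3 <- reject_outliers(solo, c("t0"), c("participant", "test_type", "role"))
  expect_true(r3$data$retained)
  expect_length(r3$flagged_groups, 1)
})

test_that("classify_trial assembles roles, derived parameters and rhythm", {
  tr <- make_simple_trial()
  rec <- decompose(tr)
  cl <- classify_trial(rec, tr)
  expect_setequal(cl$role, c("agonist", "antagonist"))
  expect_true(all(c("mode", "median", "time_delay", "response_time", "asymmetry",
                    "RT", "conduction", "abs_cos_theta_s", "nblog", "snr") %in% names(cl)))
  ag <- cl[cl$role == "agonist", ]
  expect_equal(ag$conduction, abs(ag$t0 - ag$RT))
  dp <- derived_parameters(lognormal_component(ag$t0, ag$D, ag$mu, ag$sigma))
  expect_equal(ag$mode, dp$mode)
})
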