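# Synthetic-session generator: population draws, trial construction, noise.

test_that("sample_population respects the configured moments", {
  cfg <- default_population_config()

  # default pre-ER agonist carries the published sigma moments
  ms <- cfg$tests$simple$ER$agonist$pre$sigma
  expect_equal(unname(ms), c(0.27, 0.06))

  # zero SDs -> every participant gets exactly the configured means
  cfg0 <- cfg
  for (test in names(cfg0$tests)) {
    for (fat in names(cfg0$tests[[test]])) {
      for (role in names(cfg0$tests[[test]][[fat]])) {
        for (cond in names(cfg0$tests[[test]][[fat]][[role]])) {
          for (p in names(cfg0$tests[[test]][[fat]][[role]][[cond]])) {
            cfg0$tests[[test]][[fat]][[role]][[cond]][[p]][2] <- 0
          }
        }
      }
    }
  }
  pop0 <- sample_population(cfg0, seed = 1, n_participants = 3)
  ag <- pop0[pop0$test_type == "simple" & pop0$fatigue == "ER" &
               pop0$role == "agonist" & pop0$condition == "pre" &
               pop0$parameter == "sigma", ]
  expect_equal(ag$value, rep(0.27, 3))

  # determinism
  expect_identical(sample_population(cfg, seed = 7, n_participants = 4),
                   sample_population(cfg, seed = 7, n_participants = 4))

  # negative SD rejected
  bad <- cfg
  bad$tests$simple$ER$agonist$pre$sigma[2] <- -1
  expect_error(sample_population(bad, seed = 1), "negative SD")
})

test_that("population draws match configured moments within 3 SE", {
  cfg <- default_population_config()
  pop <- sample_population(cfg, seed = 11, n_participants = 200)
  for (p in c("t0", "D", "mu", "sigma")) {
    sub <- pop[pop$test_type == "simple" & pop$fatigue == "ER" &
                 pop$role == "agonist" & pop$condition == "pre" &
                 pop$parameter == p, ]
    ms <- cfg$tests$simple$ER$agonist$pre[[p]]
    n <- nrow(sub)
    expect_lt(abs(mean(sub$value) - ms[1]), 3 * ms[2] / sqrt(n) + 1e-12)
    expect_lt(abs(sd(sub$value) - ms[2]), 3 * ms[2] / sqrt(2 * n) + 1e-12)
  }
})

test_that("pre and post draws are paired through a shared trait", {
  cfg <- default_population_config()
  pop <- sample_population(cfg, seed = 3, n_participants = 50)
  sub <- pop[pop$test_type == "simple" & pop$fatigue == "ER" &
               pop$role == "agonist" & pop$parameter == "sigma", ]
  pre <- sub$value[sub$condition == "pre"]
  post <- sub$value[sub$condition == "post"]
  expect_gt(cor(pre, post), 0.99)
  expect_equal(mean(post - pre), 0.03, tolerance = 1e-9)  # printed delta
})

test_that("collinear-opposed simple stroke covers the net distance", {
  tr <- make_simple_trial()
  disp <- sqrt((tr$x[length(tr$x)] - tr$x[1])^2 + (tr$y[length(tr$y)] - tr$y[1])^2)
  expect_lt(abs(disp - 183.4) / 183.4, 0.005)   # 214 - 30.6 mm vector oracle
  expect_equal(max(abs(diff(diff(tr$t)))), 0, tolerance = 1e-9)  # uniform grid
})

test_that("trial generation is a pure function of its seed", {
  cfg <- default_population_config()
  pp <- list(agonist = AGONIST, antagonist = ANTAGONIST)
  sds <- list(agonist = c(t0 = 0.08, D = 19.8, mu = 0.18, sigma = 0.06))
  t1 <- generate_trial("simple", pp, cfg, sds = sds, seed = 99)
  t2 <- generate_trial("simple", pp, cfg, sds = sds, seed = 99)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$ground_truth, t2$ground_truth)
  expect_error(generate_trial("spiral", pp, cfg), "unknown test type")
})

test_that("oscillation trials respect duration and target metadata", {
  cfg <- quiet_config(osc_duration = 10)
  pp <- list(oscillation = c(dt0 = 0.09, D = 124, mu = -0.81, sigma = 0.06))
  tr <- generate_trial("h_osc", pp, cfg)
  expect_gte(max(tr$t), 10)
  expect_equal(tr$meta$target_separation_mm, 50)
  expect_equal(tr$meta$orientation, "horizontal")
  # commands cover the window and alternate direction
  gt <- tr$ground_truth
  expect_gte(max(gt$t0), 10)
  expect_true(all(abs(abs(diff(sigmalog:::wrap_angle(gt$theta_s))) - pi) < 1e-9))
})

test_that("add_noise hits the target SNR in the measured-velocity domain", {
  tr <- make_simple_trial()
  expect_identical(add_noise(tr, Inf), tr)
  expect_error(add_noise(tr, -3), "positive")

  noisy <- add_noise(tr, 25, seed = 4)
  vc <- estimate_speed(tr, smooth = FALSE)
  vn <- estimate_speed(noisy, smooth = FALSE)
  es <- sigmalog:::trapz(vc$t, vc$vx^2 + vc$vy^2)
  en <- sigmalog:::trapz(vc$t, (vn$vx - vc$vx)^2 + (vn$vy - vc$vy)^2)
  expect_lt(abs(10 * log10(es / en) - 25), 0.5)

  expect_identical(add_noise(tr, 25, seed = 4)$x, noisy$x)  # seeded
})

test_that("simulate_session assembles a coherent manifest", {
  cfg <- quiet_config()
  sess <- simulate_session(cfg, seed = 2, participants = 2, fatigues = "ER",
                           test_types = c("simple", "h_osc"), strokes_per_test = 2)
  m <- sess$manifest
  expect_equal(nrow(m), length(sess$trials))
  expect_setequal(unique(m$test_type), c("simple", "h_osc"))
  expect_equal(sum(m$test_type == "simple"), 2 * 2 * 2)  # 2 participants x 2 cond x 2 strokes
  expect_equal(sum(m$test_type == "h_osc"), 2 * 2)       # one trial per cell
  # determinism of the whole session
  sess2 <- simulate_session(cfg, seed = 2, participants = 2, fatigues = "ER",
                            test_types = c("simple", "h_osc"), strokes_per_test = 2)
  expect_identical(sess$trials[[5]]$x, sess2$trials[[5]]$x)
})
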