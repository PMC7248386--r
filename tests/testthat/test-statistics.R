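# Statistical battery: thresholds, rank tests, multivariate gate, effect
# sizes, correlations, population summary.

test_that("bonferroni_threshold reproduces the printed thresholds", {
  expect_equal(signif(bonferroni_threshold(0.05, 12), 2), 0.0042)
  expect_equal(signif(bonferroni_threshold(0.05, 13), 3), 0.00385)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 16), 0.003125)
  expect_error(bonferroni_threshold(0.05, 0), "family size")
  expect_error(bonferroni_threshold(1.2, 4), "alpha")
})

test_that("mann_whitney U equals the exhaustive pair count", {
  # brute-force cross-pair wins
  brute_U <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mann_whitney(c(4, 5, 6), c(1, 2, 3))$U, 9)
  set.seed(5)
  for (rep in 1:10) {
    x <- sample(1:10, 5, replace = TRUE)
    y <- sample(1:10, 6, replace = TRUE)
    expect_equal(mann_whitney(x, y)$U, brute_U(x, y))
  }
  # identical samples: exact enumeration gives p = 1
  expect_equal(mann_whitney(c(2, 2, 2, 2), c(2, 2, 2, 2))$p, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("mann_whitney agrees with wilcox.test away from ties", {
  set.seed(8)
  x <- rnorm(30); y <- rnorm(30, 0.5)
  ours <- mann_whitney(x, y)
  ref <- wilcox.test(x, y, correct = TRUE, exact = FALSE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
})

test_that("mann_whitney null rejection rate is controlled", {
  # seeded null: p rarely below the oscillation Bonferroni threshold
  set.seed(123)
  hits <- 0L
  for (b in 1:500) {
    x <- rnorm(30); y <- rnorm(30)
    if (mann_whitney(x, y)$p < 0.0042) hits <- hits + 1L
  }
  expect_lte(hits, 5L)  # >= 99% of repeats stay above the threshold
})

test_that("wilcoxon_group handles shifts, ties and the degenerate case", {
  pre <- seq(1, 2, length.out = 20)
  # distinct positive shifts -> exact path, minimal two-sided p
  shift <- seq(0.2, 0.4, length.out = 20)
  res <- wilcoxon_group(pre, pre + shift)
  expect_lt(res$p, 0.001)
  expect_equal(res$p, 2 * (0.5^20), tolerance = 1e-12)    # all-positive ranks
  expect_equal(wilcoxon_group(pre, pre)$p, 1)
  # matches the exact signed-rank reference implementation
  set.seed(2)
  a <- rnorm(12); b <- a + rnorm(12, 0.3)
  ref <- wilcox.test(b, a, paired = TRUE, exact = TRUE)
  expect_equal(wilcoxon_group(a, b)$p, ref$p.value, tolerance = 1e-10)
})

test_that("hotelling_t2_paired gates correctly", {
  set.seed(4)
  pre <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(hotelling_t2_paired(pre, pre, n_perm = 200)$T2, 0)
  expect_equal(hotelling_t2_paired(pre, pre, n_perm = 200)$p, 1)

  post <- pre
  post[, 2] <- post[, 2] + 1.5        # 1.5 within-subject SDs
  r1 <- hotelling_t2_paired(pre, post, n_perm = 2000, seed = 9)
  expect_lt(r1$p, 0.05)
  # determinism under a fixed seed
  r2 <- hotelling_t2_paired(pre, post, n_perm = 2000, seed = 9)
  expect_identical(r1$p, r2$p)
  # shrinkage warning when n <= parameters
  wide <- matrix(rnorm(5 * 8), 5, 8)
  expect_warning(hotelling_t2_paired(wide, wide + rnorm(40, 0.1), n_perm = 50),
                 "shrinkage")
})

test_that("cohens_d and the verbal scale reproduce printed assignments", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3))$d, 0)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3))$magnitude, "very small")
  expect_equal(effect_magnitude(0.66), "medium")
  expect_equal(effect_magnitude(0.93), "large")
  expect_equal(effect_magnitude(-0.51), "medium")
  expect_equal(effect_magnitude(2.4), "huge")
  expect_equal(effect_magnitude(1.25), "very large")
  # hand computation: pooled SD 0.5, mean shift 1 -> d = 2 ("huge")
  pre <- c(-0.5, 0.5); post <- c(0.5, 1.5)   # sd = sqrt(0.5) each... build exact:
  pre <- c(0, 1) - 0.5; post <- c(1, 2) - 0.5
  sp <- sqrt(((1) * var(pre) + (1) * var(post)) / 2)
  d <- cohens_d(pre, post)
  expect_equal(d$d, (mean(post) - mean(pre)) / sp)
  expect_error(cohens_d(c(1, 1), c(2, 2)), "pooled SD")
})

test_that("spearman_matrix matches the rank formula", {
  x <- c(1, 2, 3, 4, 5, 6)
  up <- spearman_matrix(data.frame(a = x, b = 2 * x + 1))
  expect_equal(up$rho["a", "b"], 1)
  dn <- spearman_matrix(data.frame(a = x, b = rev(x)))
  expect_equal(dn$rho["a", "b"], -1)

  set.seed(3)
  a <- rnorm(6); b <- rnorm(6)
  got <- spearman_matrix(data.frame(a = a, b = b))$rho["a", "b"]
  dr <- rank(a) - rank(b)
  expect_equal(got, 1 - 6 * sum(dr^2) / (6 * 35))   # classic rank formula
  # constant column flagged as NA
  cc <- spearman_matrix(data.frame(a = a, b = rep(1, 6)))
  expect_true(is.na(cc$rho["a", "b"]))
})

test_that("summarize_population counts affected participants per category", {
  mk <- function(pid, param, sig) {
    data.frame(participant = pid, test_type = "simple", fatigue = "ER",
               role = "agonist", parameter = param, significant = sig)
  }
  # no significant flags -> all zeros
  none <- rbind(mk(1, "t0", FALSE), mk(2, "mu", FALSE))
  s0 <- summarize_population(none, n_participants = 20)
  expect_true(all(s0$percent == 0))

  # 7 of 20 with a central hit -> 35%
  flags <- do.call(rbind, lapply(1:20, function(i) {
    rbind(mk(i, "t0", i <= 7), mk(i, "mu", i %in% 5:8))
  }))
  s1 <- summarize_population(flags, n_participants = 20)
  cen <- s1$percent[s1$category == "central" & s1$role == "agonist"]
  per <- s1$percent[s1$category == "peripheral" & s1$role == "agonist"]
  both <- s1$percent[s1$category == "both" & s1$role == "agonist"]
  expect_equal(cen, 35)
  expect_equal(per, 20)
  expect_equal(both, 15)   # participants 5, 6, 7
  expect_lte(both, min(cen, per))   # set inclusion

  # random-flag property: both <= min(central, peripheral) in every cell
  set.seed(10)
  rnd <- do.call(rbind, lapply(1:20, function(i) {
    rbind(mk(i, "t0", runif(1) < 0.4), mk(i, "D", runif(1) < 0.4),
          mk(i, "mu", runif(1) < 0.4), mk(i, "sigma", runif(1) < 0.4))
  }))
  s2 <- summarize_population(rnd, n_participants = 20)
  expect_lte(s2$percent[s2$category == "both" & s2$role == "agonist"],
             min(s2$percent[s2$category %in% c("central", "peripheral") &
                              s2$role == "agonist"]))
})

test_that("parameter families have the declared sizes", {
  expect_length(parameter_family("simple", "individual"), 16)
  expect_length(parameter_family("h_osc", "individual"), 12)
  expect_length(parameter_family("triangle", "group"), 13)
  expect_length(parameter_family("v_osc", "group"), 12)
  expect_equal(parameter_category(c("t0", "mu", "mode", "nblog", "RT", "conduction")),
               c("central", "peripheral", "motor_program", "global", "rt", "conduction"))
})

test_that("compare_group gates per-parameter tests on the multivariate p", {
  set.seed(6)
  fam <- parameter_family("h_osc", "group")
  pre <- matrix(rnorm(20 * 12), 20, 12, dimnames = list(NULL, fam))
  # null: gate almost surely closed at these settings
  res0 <- compare_group(pre, pre + 0, "h_osc", n_perm = 300, seed = 2)
  expect_false(res0$gate_open)
  expect_null(res0$table)
  # strong shift on one parameter opens the gate and flags it
  post <- pre
  post[, "mu"] <- post[, "mu"] + 2
  res1 <- compare_group(pre, post, "h_osc", n_perm = 1000, seed = 2)
  expect_true(res1$gate_open)
  expect_true(res1$table$significant[res1$table$parameter == "mu"])
})
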