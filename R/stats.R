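# Statistical battery for pre- vs post-fatigue comparisons.
#
# Individual level: two-sample Mann-Whitney U tests on per-lognormal values
# with Bonferroni-corrected thresholds.  Group level: a permutation paired
# Hotelling T2 gate followed by Wilcoxon signed-rank tests on participant
# means, Cohen's d effect sizes on the Sawilowsky verbal scale, and Spearman
# correlation matrices.

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m family size (number of comparisons), >= 1.
#' @return alpha / m.
#' @examples
#' bonferroni_threshold(0.05, 12)  # 0.0042 at 2 s.f.
#' @export
bonferroni_threshold <- function(alpha, m) {
  assert_that(is_number(alpha) && alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  assert_that(is_number(m) && m >= 1, "family size m must be >= 1")
  alpha / m
}

#' Two-sample Mann-Whitney U test
#'
#' U is the number of (pre, post) pairs in which the pre value is larger
#' (ties count 1/2).  For samples of at most 8 per side the two-sided p-value
#' is computed by exhaustive enumeration of all group relabelings (exact even
#' under ties); otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y numeric samples (pre and post), each of size >= 2... size >= 1
#'   is rejected with an error for empty input.
#' @param exact_max per-side size limit for exhaustive enumeration.
#' @return list with `U`, `p`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  assert_that(length(x) >= 1 && length(y) >= 1, "empty sample")
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  assert_that(length(x) >= 2 && length(y) >= 2, "need >= 2 finite values per sample")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  w <- sum(rk[seq_len(n1)])
  U <- w - n1 * (n1 + 1) / 2              # pairs with x > y (+ ties/2)
  mu_U <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- utils::combn(n1 + n2, n1)
    ws <- colSums(matrix(rk[idx], nrow = n1))
    us <- ws - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu_U) >= abs(U - mu_U) - 1e-9)
    return(list(U = U, p = p, method = "exact enumeration"))
  }
  nt <- table(pooled)
  tie_term <- sum(nt^3 - nt) / ((n1 + n2) * (n1 + n2 - 1))
  sd_U <- sqrt(n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term))
  assert_that(sd_U > 0, "degenerate samples (all values tied)")
  z <- (U - mu_U - sign(U - mu_U) * 0.5) / sd_U
  p <- 2 * stats::pnorm(-abs(z))
  list(U = U, p = min(1, p), method = "normal approximation")
}

#' Paired Wilcoxon signed-rank test on participant means
#'
#' Two-sided; zero differences are dropped (all-zero input returns p = 1).
#' Exact null distribution for n <= 25 without ties in the absolute
#' differences, normal approximation with tie correction otherwise.
#'
#' @param pre,post numeric vectors of matched participant means.
#' @param exact_max size limit for the exact distribution.
#' @return list with `V` (positive-rank sum), `p`, `method`.
#' @export
wilcoxon_group <- function(pre, post, exact_max = 25) {
  assert_that(length(pre) == length(post), "pre and post must be matched")
  keep <- is.finite(pre) & is.finite(post)
  d <- post[keep] - pre[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(V = 0, p = 1, method = "all differences zero"))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max && !any(duplicated(abs(d)))) {
    p <- min(1, 2 * min(stats::psignrank(V, n), 1 - stats::psignrank(V - 1, n)))
    return(list(V = V, p = p, method = "exact"))
  }
  mu_V <- n * (n + 1) / 4
  nt <- table(abs(d))
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(nt^3 - nt) / 48
  assert_that(sig2 > 0, "degenerate paired differences")
  z <- (V - mu_V - sign(V - mu_V) * 0.5) / sqrt(sig2)
  list(V = V, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal approximation")
}

#' Nonparametric paired Hotelling T-squared test
#'
#' T2 is computed on the paired differences (post - pre) of the participant x
#' parameter matrices; the null distribution is generated by random sign
#' flips of the difference rows.  Rows with missing cells are removed first.
#' When n <= p (parameters), the covariance is shrunk toward its diagonal
#' with a warning.
#'
#' @param pre,post numeric matrices, participants x parameters, matched rows.
#' @param n_perm number of sign-flip permutations (default 10000).
#' @param seed integer seed for the permutation draw.
#' @return list with `T2`, `p`, `n`, `n_perm`, `seed`.
#' @export
hotelling_t2_paired <- function(pre, post, n_perm = 10000, seed = 1L) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  assert_that(all(dim(pre) == dim(post)), "pre and post must have matched dimensions")
  assert_that(ncol(pre) >= 2, "need at least 2 parameters")
  d <- post - pre
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]
  n <- nrow(d)
  p <- ncol(d)
  assert_that(n >= 3, "need at least 3 complete participant rows")
  shrink <- n < p + 1L
  if (shrink) warning("n < parameters + 1: using shrinkage-regularized covariance")
  t2_of <- function(dd) {
    if (all(dd == 0)) return(0)           # post identical to pre
    m <- colMeans(dd)
    S <- stats::cov(dd)
    if (shrink) S <- 0.9 * S + 0.1 * diag(diag(S), p)
    # ridge fallback for numerically singular covariance
    ridge <- max(mean(diag(S)), 1e-12) * 1e-8
    sol <- tryCatch(solve(S, m), error = function(e) {
      solve(S + diag(ridge, p), m)
    })
    n * sum(m * sol)
  }
  T2 <- t2_of(d)
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    signs <- sample(c(-1, 1), n, replace = TRUE)
    if (t2_of(d * signs) >= T2 - 1e-12) count <- count + 1L
  }
  list(T2 = T2, p = (1 + count) / (1 + n_perm), n = n, n_perm = n_perm, seed = seed)
}

# Sawilowsky verbal scale for |d|: largest scale point not exceeding |d|.
EFFECT_SCALE <- c("very small" = 0.01, "small" = 0.20, "medium" = 0.50,
                  "large" = 0.80, "very large" = 1.20, "huge" = 2.00)

#' Cohen's d with verbal magnitude label
#'
#' d = (mean(post) - mean(pre)) / pooled SD.  The label is the largest point
#' of the Sawilowsky scale (very small 0.01, small 0.2, medium 0.5, large
#' 0.8, very large 1.2, huge 2.0) that does not exceed |d|.
#'
#' @param pre,post numeric samples of size >= 2.
#' @return list with `d` and `magnitude`.
#' @export
cohens_d <- function(pre, post) {
  pre <- pre[is.finite(pre)]; post <- post[is.finite(post)]
  assert_that(length(pre) >= 2 && length(post) >= 2, "need >= 2 values per sample")
  n1 <- length(pre); n2 <- length(post)
  sp <- sqrt(((n1 - 1) * stats::var(pre) + (n2 - 1) * stats::var(post)) / (n1 + n2 - 2))
  assert_that(is.finite(sp) && sp > 0, "undefined effect size: zero pooled SD")
  d <- (mean(post) - mean(pre)) / sp
  list(d = d, magnitude = effect_magnitude(d))
}

#' @rdname cohens_d
#' @param d a Cohen's d value.
#' @export
effect_magnitude <- function(d) {
  pts <- EFFECT_SCALE[EFFECT_SCALE <= abs(d) + 1e-12]
  if (length(pts) == 0L) return(names(EFFECT_SCALE)[1L])
  names(pts)[length(pts)]
}

#' Spearman correlation matrix
#'
#' Pairwise Spearman rank correlations with tie handling and asymptotic
#' p-values; constant columns yield NA cells.
#'
#' @param df data frame or matrix of numeric columns (>= 4 rows).
#' @return list with `rho` and `p` matrices.
#' @export
spearman_matrix <- function(df) {
  m <- as.matrix(df)
  assert_that(nrow(m) >= 4, "need at least 4 paired observations")
  p <- ncol(m)
  rho <- matrix(NA_real_, p, p, dimnames = list(colnames(m), colnames(m)))
  pv <- rho
  for (i in seq_len(p)) {
    rho[i, i] <- 1
    pv[i, i] <- 0
    for (j in seq_len(p)) {
      if (j >= i) next
      ok <- stats::complete.cases(m[, c(i, j)])
      xi <- m[ok, i]; xj <- m[ok, j]
      if (sum(ok) < 4 || stats::sd(xi) == 0 || stats::sd(xj) == 0) next
      ct <- suppressWarnings(stats::cor.test(xi, xj, method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pv[i, j] <- pv[j, i] <- ct$p.value
    }
  }
  list(rho = rho, p = pv)
}

# --- parameter families and categories --------------------------------------

#' Parameter families and categories
#'
#' The individual-level family holds 16 parameters for simple strokes and
#' triangles and 12 for oscillations; the group-level family 13 and 12
#' respectively.  Categories follow the central / peripheral / motor-program /
#' global-state split, plus reaction time and conduction.
#'
#' @param test_type one of simple, triangle, h_osc, v_osc.
#' @param level "individual" or "group".
#' @return character vector of parameter (column) names.
#' @export
parameter_family <- function(test_type, level = c("individual", "group")) {
  level <- match.arg(level)
  osc <- test_type %in% c("h_osc", "v_osc")
  if (level == "individual") {
    if (osc) {
      c("delta_t0", "D", "abs_cos_theta_s", "abs_cos_theta_e", "mu", "sigma",
        "mode", "median", "time_delay", "response_time", "asymmetry", "conduction")
    } else {
      c("t0", "D", "abs_cos_theta_s", "abs_cos_theta_e", "mu", "sigma",
        "mode", "median", "time_delay", "response_time", "asymmetry",
        "nblog", "snr", "snr_per_nblog", "RT", "conduction")
    }
  } else {
    if (osc) {
      c("delta_t0", "D", "mu", "sigma", "mode", "median", "time_delay",
        "response_time", "asymmetry", "nblog", "snr", "snr_per_nblog")
    } else {
      c("t0", "D", "abs_cos_theta_s", "abs_cos_theta_e", "mu", "sigma",
        "mode", "median", "time_delay", "response_time",
        "nblog", "snr", "snr_per_nblog")
    }
  }
}

#' @rdname parameter_family
#' @param parameter parameter name(s).
#' @export
parameter_category <- function(parameter) {
  cats <- c(t0 = "central", delta_t0 = "central", D = "central",
            abs_cos_theta_s = "central", abs_cos_theta_e = "central",
            mu = "peripheral", sigma = "peripheral",
            mode = "motor_program", median = "motor_program",
            time_delay = "motor_program", response_time = "motor_program",
            asymmetry = "motor_program",
            nblog = "global", snr = "global", snr_per_nblog = "global",
            RT = "rt", conduction = "conduction")
  unname(cats[as.character(parameter)])
}

# per-trial parameters are constant within a trial; per-lognormal values vary
TRIAL_LEVEL_PARAMS <- c("nblog", "snr", "snr_per_nblog", "RT")

# Extract the vector of values for one parameter from a classified table.
parameter_values <- function(df, parameter) {
  if (parameter %in% TRIAL_LEVEL_PARAMS) {
    v <- df[[parameter]][!duplicated(df$trial)]
  } else {
    v <- df[[parameter]][df$retained]
  }
  v[is.finite(v)]
}

#' Individual-level pre/post comparison
#'
#' Mann-Whitney U per parameter on per-lognormal values (per-trial values for
#' Nblog, SNR, SNR/Nblog and RT), Bonferroni threshold alpha / family size,
#' and Cohen's d with verbal magnitude.
#'
#' @param pre_df,post_df classified-component tables for one participant,
#'   one test type (and one role for simple strokes), pre and post fatigue.
#' @param test_type test type string.
#' @param alpha nominal family-wise level (default 0.05).
#' @return data frame: parameter, category, n_pre, n_post, U, p, threshold,
#'   significant, d, magnitude.
#' @export
compare_individual <- function(pre_df, post_df, test_type, alpha = 0.05) {
  fam <- parameter_family(test_type, "individual")
  thr <- bonferroni_threshold(alpha, length(fam))
  rows <- lapply(fam, function(param) {
    x <- parameter_values(pre_df, param)
    y <- parameter_values(post_df, param)
    out <- data.frame(parameter = param, category = parameter_category(param),
                      n_pre = length(x), n_post = length(y),
                      U = NA_real_, p = NA_real_, threshold = thr,
                      significant = FALSE, d = NA_real_,
                      magnitude = NA_character_, stringsAsFactors = FALSE)
    if (length(x) >= 2 && length(y) >= 2) {
      mw <- tryCatch(mann_whitney(x, y), error = function(e) NULL)
      if (!is.null(mw)) {
        out$U <- mw$U
        out$p <- mw$p
        out$significant <- mw$p < thr
      }
      es <- tryCatch(cohens_d(x, y), error = function(e) NULL)
      if (!is.null(es)) {
        out$d <- es$d
        out$magnitude <- es$magnitude
      }
    }
    out
  })
  do.call(rbind, rows)
}

#' Group-level pre/post comparison
#'
#' A permutation paired Hotelling T2 on all parameters gates the
#' per-parameter Wilcoxon signed-rank tests (run only when the multivariate
#' p < `gate_alpha`).
#'
#' @param pre_mat,post_mat participant x parameter matrices of means (matched
#'   rows, columns named by parameter).
#' @param test_type test type string (sets the Bonferroni family size).
#' @param alpha nominal level for the per-parameter family (default 0.05).
#' @param gate_alpha threshold for the multivariate gate (default 0.05).
#' @param n_perm,seed permutation settings for the gate.
#' @return list with `hotelling` (test result), `gate_open`, and `table`
#'   (per-parameter data frame, NULL when the gate stays closed).
#' @export
compare_group <- function(pre_mat, post_mat, test_type, alpha = 0.05,
                          gate_alpha = 0.05, n_perm = 10000, seed = 1L) {
  fam <- parameter_family(test_type, "group")
  use <- intersect(fam, colnames(pre_mat))
  ht <- hotelling_t2_paired(pre_mat[, use, drop = FALSE],
                            post_mat[, use, drop = FALSE],
                            n_perm = n_perm, seed = seed)
  gate_open <- ht$p < gate_alpha
  thr <- bonferroni_threshold(alpha, length(fam))
  tab <- NULL
  if (gate_open) {
    rows <- lapply(use, function(param) {
      x <- pre_mat[, param]; y <- post_mat[, param]
      ok <- is.finite(x) & is.finite(y)
      out <- data.frame(parameter = param, category = parameter_category(param),
                        n = sum(ok), V = NA_real_, p = NA_real_, threshold = thr,
                        significant = FALSE, d = NA_real_,
                        magnitude = NA_character_, stringsAsFactors = FALSE)
      if (sum(ok) >= 6) {
        wt <- tryCatch(wilcoxon_group(x[ok], y[ok]), error = function(e) NULL)
        if (!is.null(wt)) {
          out$V <- wt$V
          out$p <- wt$p
          out$significant <- wt$p < thr
        }
        es <- tryCatch(cohens_d(x[ok], y[ok]), error = function(e) NULL)
        if (!is.null(es)) {
          out$d <- es$d
          out$magnitude <- es$magnitude
        }
      }
      out
    })
    tab <- do.call(rbind, rows)
  }
  list(hotelling = ht, gate_open = gate_open, table = tab)
}

#' Population summary of individual significance flags
#'
#' Reproduces the layout of a percent-affected table: for each test type,
#' fatigue type, stroke role and category, the percentage of participants
#' with at least one significant parameter in that category; a `Total` row
#' per test counts a participant once across roles.
#'
#' @param flags data frame with columns participant, test_type, fatigue,
#'   role, parameter, significant (one row per tested parameter).
#' @param n_participants denominator N (default: number of distinct
#'   participants in `flags`).
#' @return data frame: test_type, fatigue, role, category, percent.
#' @export
summarize_population <- function(flags, n_participants = length(unique(flags$participant))) {
  assert_that(n_participants >= 1, "need at least one participant")
  flags$category <- parameter_category(flags$parameter)
  out <- list()
  k <- 0L
  for (fat in unique(flags$fatigue)) {
    ff <- flags[flags$fatigue == fat, ]
    for (test in unique(ff$test_type)) {
      ft <- ff[ff$test_type == test, ]
      roles <- unique(ft$role)
      for (role in c(roles, "Total")) {
        fr <- if (role == "Total") ft else ft[ft$role == role, ]
        affected <- list()
        for (cat in unique(stats::na.omit(fr$category))) {
          fc <- fr[fr$category == cat & fr$significant, ]
          affected[[cat]] <- unique(fc$participant)
          k <- k + 1L
          out[[k]] <- data.frame(
            test_type = test, fatigue = fat, role = role, category = cat,
            percent = 100 * length(affected[[cat]]) / n_participants,
            stringsAsFactors = FALSE)
        }
        # "both systems": participants affected in the central AND the
        # peripheral category
        both <- intersect(affected[["central"]] %||% integer(0),
                          affected[["peripheral"]] %||% integer(0))
        k <- k + 1L
        out[[k]] <- data.frame(
          test_type = test, fatigue = fat, role = role, category = "both",
          percent = 100 * length(both) / n_participants, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
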