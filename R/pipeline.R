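# End-to-end orchestration: simulate -> extract -> format -> analyze -> report.

# Mean of each family parameter per participant, from a classified table.
# Per-lognormal parameters average retained rows (filtered by role when
# given); trial-level parameters average one value per trial.
participant_means <- function(df, test_type, role = NULL) {
  fam <- parameter_family(test_type, "group")
  participants <- sort(unique(df$participant))
  m <- matrix(NA_real_, length(participants), length(fam),
              dimnames = list(participants, fam))
  for (i in seq_along(participants)) {
    sub <- df[df$participant == participants[i], , drop = FALSE]
    roled <- if (!is.null(role)) sub[!is.na(sub$role) & sub$role == role, , drop = FALSE] else sub
    for (param in fam) {
      v <- if (param %in% TRIAL_LEVEL_PARAMS) {
        sub[[param]][!duplicated(sub$trial)]
      } else {
        roled[[param]][roled$retained]
      }
      v <- v[is.finite(v)]
      if (length(v) > 0L) m[i, param] <- mean(v)
    }
  }
  m
}

# Table-1-style row labels per test type.
roles_for_test <- function(test_type) {
  switch(test_type,
         simple = c("agonist", "antagonist"),
         triangle = c("stroke1", "stroke2", "stroke3"),
         h_osc = ,
         v_osc = c("osc_ER", "osc_IR"),
         "all")
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a session set, decomposes every trial into lognormal
#' components, classifies and filters them, and runs the individual and group
#' statistical batteries.  All artifacts are written under `out_dir`:
#' `trajectories/` (CSV), `manifest.json`, `ground_truth.csv`,
#' `components.csv`, `quality.csv`, `classified.csv`, `report.json`,
#' `run_log.txt`.
#'
#' @param out_dir output directory (created if missing).
#' @param config population configuration; see [default_population_config()].
#' @param seed integer master seed; the whole run is deterministic given
#'   (config, seed).
#' @param participants,fatigues,test_types,strokes_per_test forwarded to
#'   [simulate_session()].
#' @param decompose_cfg settings from [decompose_config()].
#' @param n_perm permutations for the multivariate gate.
#' @param manifest_path optional: analyze an existing session (skips
#'   simulation) from this manifest instead of simulating.
#' @param snr_target convenience override of `decompose_cfg$snr_target`.
#' @return a list with `classified`, `individual`, `group`, `population`,
#'   `correlations`, `retention`, `paths`.
#' @export
run_pipeline <- function(out_dir, config = default_population_config(), seed = 1L,
                         participants = config$n_participants,
                         fatigues = c("ER", "IR"),
                         test_types = names(config$tests),
                         strokes_per_test = config$strokes_per_test,
                         decompose_cfg = decompose_config(),
                         n_perm = 10000,
                         manifest_path = NULL,
                         snr_target = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(snr_target)) decompose_cfg$snr_target <- snr_target
  log_lines <- c(sprintf("run started: seed=%d participants=%s", seed,
                         paste(participants, collapse = ",")),
                 sprintf("R version: %s; package sigmalog %s", R.version.string,
                         as.character(utils::packageVersion("sigmalog"))),
                 sprintf("snr_target=%g dB, n_perm=%d", decompose_cfg$snr_target, n_perm))
  stage <- function(msg) {
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  # -- stage 1: simulate or load ---------------------------------------------
  if (is.null(manifest_path)) {
    stage("stage simulate: generating synthetic session")
    sess <- simulate_session(config, seed = seed, participants = participants,
                             fatigues = fatigues, test_types = test_types,
                             strokes_per_test = strokes_per_test)
    traj_dir <- file.path(out_dir, "trajectories")
    dir.create(traj_dir, showWarnings = FALSE)
    paths <- character(nrow(sess$manifest))
    for (i in seq_along(sess$trials)) {
      mrow <- sess$manifest[i, ]
      paths[i] <- file.path("trajectories",
                            sprintf("p%02d_%s_%s_%s_%03d.csv", mrow$participant,
                                    mrow$fatigue, mrow$condition, mrow$test_type,
                                    mrow$trial_index))
      write_trajectory(sess$trials[[i]], file.path(out_dir, paths[i]))
    }
    man <- cbind(sess$manifest, path = paths)
    write_manifest(man, file.path(out_dir, "manifest.json"),
                   seed = seed, config = NULL)
    gt <- do.call(rbind, lapply(seq_along(sess$trials), function(i) {
      g <- sess$trials[[i]]$ground_truth
      if (is.null(g)) return(NULL)
      cbind(sess$manifest[rep(i, nrow(g)), ], g)
    }))
    utils::write.csv(gt, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
    trials <- sess$trials
    man$path <- file.path(out_dir, paths)
  } else {
    stage(paste("stage load: reading manifest", manifest_path))
    mf <- read_manifest(manifest_path)
    man <- mf$trials
    trials <- lapply(man$path, read_trajectory)
  }

  # -- stage 2: extract ------------------------------------------------------
  stage(sprintf("stage extract: decomposing %d trials", length(trials)))
  classified <- list()
  quality <- list()
  comp_rows <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    for (field in c("participant", "fatigue", "condition", "test_type")) {
      if (is.null(tr$meta[[field]])) tr$meta[[field]] <- man[[field]][i]
    }
    if (is.null(tr$meta$trial)) tr$meta$trial <- man$trial_index[i]
    rec <- tryCatch(decompose(tr, decompose_cfg), error = function(e) {
      stop(sprintf("stage extract failed on trial %d (%s): %s", i,
                   man$path[i] %||% "?", conditionMessage(e)), call. = FALSE)
    })
    quality[[i]] <- data.frame(trial_id = i, participant = man$participant[i],
                               fatigue = man$fatigue[i], condition = man$condition[i],
                               test_type = man$test_type[i], trial = man$trial_index[i],
                               nblog = rec$nblog, snr = rec$snr_db,
                               snr_per_nblog = rec$snr_per_nblog,
                               low_quality = rec$low_quality)
    if (rec$nblog > 0L) {
      comp_rows[[i]] <- cbind(trial_id = i, man[rep(i, rec$nblog),
                                               c("participant", "fatigue", "condition",
                                                 "test_type", "trial_index")],
                              rec$components)
      cl <- classify_trial(rec, tr)
      if (!is.null(cl)) {
        cl$trial_id <- i
        classified[[i]] <- cl
      }
    }
  }
  quality <- do.call(rbind, quality)
  utils::write.csv(do.call(rbind, comp_rows), file.path(out_dir, "components.csv"),
                   row.names = FALSE)
  utils::write.csv(quality, file.path(out_dir, "quality.csv"), row.names = FALSE)
  classified <- do.call(rbind, classified)
  assert_that(!is.null(classified) && nrow(classified) > 0L,
              "stage format: no components survived extraction")

  # -- stage 3: outlier filtering --------------------------------------------
  stage("stage format: outlier filtering (mean +/- 3 SD per group)")
  filt <- reject_outliers(classified, OUTLIER_PARAMS,
                          c("participant", "test_type", "fatigue", "role"))
  classified <- filt$data
  utils::write.csv(classified, file.path(out_dir, "classified.csv"), row.names = FALSE)
  retention <- tapply(classified$retained, classified$test_type, mean)
  log_lines <- c(log_lines,
                 sprintf("retention by test: %s",
                         paste(names(retention), round(unlist(retention), 3),
                               sep = "=", collapse = ", ")))

  # -- stage 4: individual analyses ------------------------------------------
  stage("stage analyze: individual comparisons")
  individual <- list()
  flags <- list()
  k <- 0L
  for (fat in unique(classified$fatigue)) {
    for (test in unique(classified$test_type)) {
      sub <- classified[classified$fatigue == fat & classified$test_type == test, ]
      if (nrow(sub) == 0L) next
      for (pid in sort(unique(sub$participant))) {
        ps <- sub[sub$participant == pid, ]
        for (role in roles_for_test(test)) {
          rs <- if (role == "all") ps else ps[!is.na(ps$role) & ps$role == role, ]
          pre <- rs[rs$condition == "pre", ]
          post <- rs[rs$condition == "post", ]
          if (nrow(pre) == 0L || nrow(post) == 0L) next
          cmp <- compare_individual(pre, post, test)
          cmp$participant <- pid
          cmp$fatigue <- fat
          cmp$test_type <- test
          cmp$role <- role
          k <- k + 1L
          individual[[k]] <- cmp
        }
      }
    }
  }
  individual <- do.call(rbind, individual)
  pop_summary <- NULL
  if (!is.null(individual) && nrow(individual) > 0L) {
    pop_summary <- summarize_population(individual)
  }

  # -- stage 5: group analyses -----------------------------------------------
  stage("stage analyze: group comparisons (Hotelling gate + signed-rank)")
  group <- list()
  g <- 0L
  for (fat in unique(classified$fatigue)) {
    for (test in unique(classified$test_type)) {
      sub <- classified[classified$fatigue == fat & classified$test_type == test, ]
      if (nrow(sub) == 0L) next
      grp_roles <- if (test == "simple") c("agonist", "antagonist") else "all"
      for (role in grp_roles) {
        rrole <- if (role == "all") NULL else role
        pre <- participant_means(sub[sub$condition == "pre", ], test, rrole)
        post <- participant_means(sub[sub$condition == "post", ], test, rrole)
        common <- intersect(rownames(pre), rownames(post))
        if (length(common) < 6L) next
        res <- tryCatch(
          compare_group(pre[common, , drop = FALSE], post[common, , drop = FALSE],
                        test, n_perm = n_perm, seed = seed + g),
          error = function(e) NULL)
        if (is.null(res)) next
        g <- g + 1L
        group[[g]] <- list(fatigue = fat, test_type = test, role = role,
                           hotelling_p = res$hotelling$p, gate_open = res$gate_open,
                           table = res$table)
      }
    }
  }

  # -- stage 6: focal correlations -------------------------------------------
  stage("stage analyze: Spearman correlations (RT vs t0, t0 vs mu)")
  correlations <- list()
  cidx <- 0L
  for (fat in unique(classified$fatigue)) {
    for (test in c("simple", "triangle")) {
      sub <- classified[classified$fatigue == fat & classified$test_type == test, ]
      if (nrow(sub) == 0L) next
      for (role in roles_for_test(test)) {
        for (cond in c("pre", "post")) {
          sc <- sub[sub$condition == cond & !is.na(sub$role) & sub$role == role &
                      sub$retained, ]
          if (nrow(sc) == 0L) next
          agg <- stats::aggregate(sc[, c("t0", "mu", "RT")],
                                  by = list(participant = sc$participant), mean)
          if (nrow(agg) < 4L) next
          sp <- tryCatch(spearman_matrix(agg[, c("t0", "mu", "RT")]),
                         error = function(e) NULL)
          if (is.null(sp)) next
          cidx <- cidx + 1L
          correlations[[cidx]] <- list(
            fatigue = fat, test_type = test, role = role, condition = cond,
            rho_t0_RT = sp$rho["t0", "RT"], p_t0_RT = sp$p["t0", "RT"],
            rho_t0_mu = sp$rho["t0", "mu"], p_t0_mu = sp$p["t0", "mu"])
        }
      }
    }
  }

  # -- stage 7: report -------------------------------------------------------
  stage("stage report: writing report.json")
  report <- list(
    seed = seed,
    thresholds = list(
      individual = list(strokes = bonferroni_threshold(0.05, 16),
                        oscillations = bonferroni_threshold(0.05, 12)),
      group = list(strokes = bonferroni_threshold(0.05, 13),
                   oscillations = bonferroni_threshold(0.05, 12)),
      hotelling_gate = 0.05),
    retention = as.list(retention),
    quality = quality,
    individual = individual,
    population_summary = pop_summary,
    group = group,
    correlations = correlations)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  writeLines(c(log_lines, "run completed"), file.path(out_dir, "run_log.txt"))
  invisible(list(classified = classified, individual = individual, group = group,
                 population = pop_summary, correlations = correlations,
                 retention = retention, quality = quality,
                 paths = list(out_dir = out_dir,
                              report = file.path(out_dir, "report.json"))))
}
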