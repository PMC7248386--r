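# Data-formatting stage: role classification, oscillation phase splitting,
# artifact and outlier filtering, and rhythm (delta t0) computation.

#' Classify simple-stroke components into agonist and antagonist
#'
#' A component is on the agonist side iff the cosine of its starting angle
#' relative to the movement bearing is strictly positive (cos = 0 counts as
#' antagonist).  Within each side the largest-D component is retained; strokes
#' with a single component yield an agonist only.
#'
#' @param components data frame of components (t0, D, mu, sigma, theta_s,
#'   theta_e), one trial.
#' @param bearing direction of the net trial displacement (rad).
#' @return the data frame with `role` (`agonist`/`antagonist`/`NA`),
#'   `retained` and `reject_reason` columns; non-selected components carry
#'   reason `"unassigned"`.
#' @export
classify_simple_stroke <- function(components, bearing) {
  assert_that(is.data.frame(components) && nrow(components) >= 1L,
              "need at least one component")
  side_agonist <- cos(components$theta_s - bearing) > 0
  components$role <- NA_character_
  components$retained <- FALSE
  components$reject_reason <- "unassigned"
  if (nrow(components) == 1L) {
    components$role <- "agonist"
    components$retained <- TRUE
    components$reject_reason <- NA_character_
    return(components)
  }
  for (side in c(TRUE, FALSE)) {
    idx <- which(side_agonist == side)
    if (length(idx) == 0L) next
    pick <- idx[order(-components$D[idx], components$t0[idx])][1L]
    components$role[pick] <- if (side) "agonist" else "antagonist"
    components$retained[pick] <- TRUE
    components$reject_reason[pick] <- NA_character_
  }
  components
}

#' Assign triangle components to the three planned strokes
#'
#' The three largest-D components, ordered by t0, map to strokes 1-3.  The
#' trial is rejected when fewer than three components exist or when any
#' mapped component's starting angle does not point toward its side's bearing
#' (cosine of the angle difference <= 0).
#'
#' @param components data frame of components for one triangle trial.
#' @param bearings numeric length-3: planned bearings of sides 1-3 (rad).
#' @return a list with `components` (annotated data frame) and `rejected`
#'   (logical) plus `reason` when rejected.
#' @export
assign_triangle_strokes <- function(components, bearings) {
  assert_that(length(bearings) == 3L, "three side bearings required")
  components$role <- NA_character_
  components$retained <- FALSE
  components$reject_reason <- "unassigned"
  if (is.null(components) || nrow(components) < 3L) {
    if (!is.null(components) && nrow(components) > 0L) {
      components$reject_reason <- "invalid-reconstruction"
    }
    return(list(components = components, rejected = TRUE,
                reason = "invalid-reconstruction"))
  }
  main <- order(-components$D)[1:3]
  main <- main[order(components$t0[main])]
  ok <- TRUE
  for (k in 1:3) {
    if (cos(components$theta_s[main[k]] - bearings[k]) <= 0) ok <- FALSE
  }
  if (!ok) {
    components$reject_reason <- "unassigned"
    return(list(components = components, rejected = TRUE, reason = "unassigned"))
  }
  for (k in 1:3) {
    components$role[main[k]] <- paste0("stroke", k)
    components$retained[main[k]] <- TRUE
    components$reject_reason[main[k]] <- NA_character_
  }
  list(components = components, rejected = FALSE)
}

#' Split oscillation components into phases and rotation directions
#'
#' Phases by command time t0 (left-closed bins): acceleration `[0, 2)` s,
#' stable `[2, 10)` s, deceleration `[10, Inf)` s.  Components with amplitude
#' D < 50 mm are rejected as artifacts.  Direction: for horizontal
#' oscillations a positive cosine of the starting angle marks an external
#' rotation movement (`osc_ER`), otherwise internal (`osc_IR`); for vertical
#' oscillations the sine is used.
#'
#' @param components data frame of components for one oscillation trial.
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param artifact_min_mm artifact amplitude threshold (default 50 mm).
#' @param phase_bounds phase boundaries in s (default `c(2, 10)`).
#' @return the data frame with `phase`, `role`, `retained`, `reject_reason`.
#' @export
split_oscillation_phases <- function(components, orientation = c("horizontal", "vertical"),
                                     artifact_min_mm = 50, phase_bounds = c(2, 10)) {
  orientation <- match.arg(orientation)
  if (is.null(components) || nrow(components) == 0L) {
    return(cbind(components,
                 data.frame(phase = character(0), role = character(0),
                            retained = logical(0), reject_reason = character(0))))
  }
  components$phase <- ifelse(components$t0 < phase_bounds[1L], "acceleration",
                             ifelse(components$t0 < phase_bounds[2L], "stable", "deceleration"))
  trig <- if (orientation == "horizontal") cos(components$theta_s) else sin(components$theta_s)
  components$role <- ifelse(trig > 0, "osc_ER", "osc_IR")
  artifact <- components$D < artifact_min_mm
  components$retained <- !artifact
  components$reject_reason <- ifelse(artifact, "artifact", NA_character_)
  components
}

#' Rhythm intervals between successive commands
#'
#' Successive differences of ascending-sorted t0 values; used on the
#' stable-phase components of one oscillation trial.
#'
#' @param t0 numeric vector of command times (s).
#' @return numeric vector of intervals (s); empty when fewer than 2 values.
#' @export
delta_t0 <- function(t0) {
  if (length(t0) < 2L) return(numeric(0))
  diff(sort(t0))
}

#' Reject outliers by the mean +/- 3 SD rule
#'
#' Within each group, a row is dropped iff any monitored parameter lies
#' outside that group's mean +/- 3 SD.  Bounds come from the unfiltered group
#' in a single pass.  Groups with fewer than 2 rows are kept unchanged and
#' flagged.
#'
#' @param df data frame of per-component rows.
#' @param params character, columns to monitor.
#' @param group_cols character, grouping columns (e.g. participant, test type,
#'   role).
#' @param k SD multiplier (default 3).
#' @return a list: `data` (df with `retained` updated; dropped rows get
#'   `reject_reason = "outlier"`), `retention` (per-group fraction retained),
#'   `flagged_groups` (too small to filter).
#' @export
reject_outliers <- function(df, params, group_cols, k = 3) {
  assert_that(all(params %in% names(df)), "missing monitored parameter columns")
  assert_that(all(group_cols %in% names(df)), "missing grouping columns")
  key <- interaction(df[group_cols], drop = TRUE)
  out <- rep(FALSE, nrow(df))
  flagged <- character(0)
  retention <- list()
  for (g in levels(key)) {
    idx <- which(key == g)
    if (length(idx) < 2L) {
      flagged <- c(flagged, g)
      retention[[g]] <- 1
      next
    }
    bad <- rep(FALSE, length(idx))
    for (p in params) {
      v <- df[[p]][idx]
      m <- mean(v)
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) next
      bad <- bad | v < m - k * s | v > m + k * s
    }
    out[idx] <- bad
    retention[[g]] <- 1 - mean(bad)
  }
  if ("retained" %in% names(df)) df$retained <- df$retained & !out else df$retained <- !out
  if (!"reject_reason" %in% names(df)) df$reject_reason <- NA_character_
  df$reject_reason[out] <- "outlier"
  list(data = df, retention = unlist(retention), flagged_groups = flagged)
}

# Parameters monitored by the outlier filter (per-lognormal scales).
OUTLIER_PARAMS <- c("t0", "D", "mu", "sigma")

#' Classify one reconstructed trial
#'
#' Runs the appropriate role/phase classification for the trial's test type,
#' attaches derived timing parameters, the trial reaction time, conduction
#' time, and reconstruction-quality fields.
#'
#' @param recon an `sl_reconstruction` from [decompose()].
#' @param trajectory the source `sl_trajectory` (for bearings and metadata).
#' @return a data frame, one row per component, or `NULL` for an empty
#'   reconstruction.
#' @export
classify_trial <- function(recon, trajectory) {
  if (is.null(recon$components) || recon$nblog == 0L) return(NULL)
  comps <- recon$components
  meta <- trajectory$meta
  test <- meta$test_type
  if (test == "simple") {
    disp <- c(trajectory$x[length(trajectory$x)] - trajectory$x[1L],
              trajectory$y[length(trajectory$y)] - trajectory$y[1L])
    bearing <- atan2(disp[2L], disp[1L])
    comps <- classify_simple_stroke(comps, bearing)
    comps$phase <- NA_character_
  } else if (test == "triangle") {
    res <- assign_triangle_strokes(comps, meta$bearings)
    comps <- res$components
    comps$phase <- NA_character_
    if (res$rejected) comps$retained <- FALSE
  } else if (test %in% c("h_osc", "v_osc")) {
    comps <- split_oscillation_phases(comps, meta$orientation)
  } else {
    stop("unknown test type: ", test)
  }
  comps <- cbind(comps, derived_parameters_df(comps))
  rt <- tryCatch(reaction_time(recon$velocity$t, recon$velocity$speed,
                               t_stimulus = meta$stimulus_time %||% 0),
                 error = function(e) NA_real_)
  comps$RT <- rt
  comps$conduction <- abs(comps$t0 - rt)
  comps$abs_cos_theta_s <- abs(cos(comps$theta_s))
  comps$abs_cos_theta_e <- abs(cos(comps$theta_e))
  # rhythm intervals: successive differences across stable-phase commands
  comps$delta_t0 <- NA_real_
  if (test %in% c("h_osc", "v_osc")) {
    st <- which(comps$phase == "stable" & comps$retained)
    if (length(st) >= 2L) {
      ord <- st[order(comps$t0[st])]
      comps$delta_t0[ord[-1L]] <- diff(comps$t0[ord])
      comps$conduction[ord[-1L]] <- abs(comps$delta_t0[ord[-1L]] - rt)
    }
  }
  comps$nblog <- recon$nblog
  comps$snr <- recon$snr_db
  comps$snr_per_nblog <- recon$snr_per_nblog
  for (field in c("participant", "fatigue", "condition", "trial", "test_type")) {
    comps[[field]] <- meta[[field]] %||% NA
  }
  comps
}
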