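# Trajectory CSV dialect and session manifest handling.
#
# Trajectories are comma-separated files with '#'-prefixed metadata lines
# (key: value) followed by a t,x,y header.  Required metadata: units_time=s,
# units_xy=mm, sample_rate_hz.  Manifests are JSON.

#' Write a trajectory CSV
#'
#' @param trajectory an `sl_trajectory`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  meta <- trajectory$meta
  meta$units_time <- "s"
  meta$units_xy <- "mm"
  keep <- vapply(meta, function(v) is.character(v) || is.numeric(v) || is.logical(v),
                 logical(1))
  meta <- meta[keep]
  lines <- vapply(names(meta), function(k) {
    sprintf("# %s: %s", k, paste(format(meta[[k]], digits = 15), collapse = " "))
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  writeLines("t,x,y", con)
  utils::write.table(
    data.frame(t = trajectory$t, x = trajectory$x, y = trajectory$y),
    con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' Validates the metadata (time in s, coordinates in mm, a sampling rate),
#' the column set, and that timestamps are strictly increasing on a uniform
#' grid; errors carry the first offending line number.
#'
#' @param path file path.
#' @return an `sl_trajectory`.
#' @export
read_trajectory <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  raw <- readLines(path)
  meta_lines <- grep("^#", raw)
  if (length(meta_lines) > 0L) {
    assert_that(identical(meta_lines, seq_along(meta_lines)),
                "metadata lines must be a leading block")
  }
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(raw[ln], regexec("^#\\s*([^:]+):\\s*(.*)$", raw[ln]))[[1L]]
    assert_that(length(m) == 3L, sprintf("line %d: malformed metadata", ln))
    key <- trimws(m[2L])
    val <- trimws(m[3L])
    nv <- suppressWarnings(as.numeric(strsplit(val, "\\s+")[[1L]]))
    meta[[key]] <- if (!anyNA(nv)) nv else val
  }
  hdr_ln <- length(meta_lines) + 1L
  assert_that(hdr_ln <= length(raw) && grepl("^t,x,y", raw[hdr_ln]),
              sprintf("line %d: expected header 't,x,y'", hdr_ln))
  assert_that(identical(meta$units_time %||% "s", "s"),
              "unit mismatch: units_time must be 's'")
  assert_that(identical(meta$units_xy %||% "mm", "mm"),
              "unit mismatch: units_xy must be 'mm'")
  df <- utils::read.csv(text = raw[(hdr_ln + 1L):length(raw)], header = FALSE,
                        col.names = c("t", "x", "y"))
  assert_that(nrow(df) >= 2L, "trajectory needs at least 2 samples")
  assert_that(all(is.finite(as.matrix(df))), "non-finite sample values")
  dt <- diff(df$t)
  bad <- which(dt <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("line %d: non-monotone time", hdr_ln + bad[1L] + 1L), call. = FALSE)
  }
  step <- (df$t[nrow(df)] - df$t[1L]) / (nrow(df) - 1L)
  off <- which(abs(dt - step) > 1e-6 * step + 1e-9)
  if (length(off) > 0L) {
    stop(sprintf("line %d: non-uniform sampling grid", hdr_ln + off[1L] + 1L), call. = FALSE)
  }
  if (is.null(meta$sample_rate_hz)) meta$sample_rate_hz <- 1 / step
  new_trajectory(df$t, df$x, df$y, meta)
}

#' Write a session manifest (JSON)
#'
#' @param manifest data frame with per-trial rows (must include `path`,
#'   `participant`, `fatigue`, `condition`, `test_type`, `trial_index`).
#' @param path output path.
#' @param study_id study identifier string.
#' @param seed integer seed used for the session.
#' @param config population configuration snapshot (stored verbatim).
#' @return the path, invisibly.
#' @export
write_manifest <- function(manifest, path, study_id = "synthetic", seed = NA,
                           config = NULL) {
  obj <- list(study_id = study_id, seed = seed,
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              trials = manifest, config = config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read and validate a session manifest
#'
#' Checks that every referenced trajectory file exists and that the
#' (participant, fatigue, condition, test type, trial index) keys are unique.
#'
#' @param path manifest JSON path.
#' @return a list with `study_id`, `seed`, `trials` (data frame), `config`.
#' @export
read_manifest <- function(path) {
  assert_that(file.exists(path), paste0("no such manifest: ", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- obj$trials
  assert_that(is.data.frame(tr) && nrow(tr) >= 1L, "manifest has no trials")
  need <- c("path", "participant", "fatigue", "condition", "test_type", "trial_index")
  assert_that(all(need %in% names(tr)),
              paste("manifest trials need columns:", paste(need, collapse = ", ")))
  base <- dirname(path)
  full <- ifelse(grepl("^/", tr$path), tr$path, file.path(base, tr$path))
  missing <- full[!file.exists(full)]
  assert_that(length(missing) == 0L,
              paste0("manifest references missing file(s): ", missing[1L]))
  key <- interaction(tr$participant, tr$fatigue, tr$condition, tr$test_type,
                     tr$trial_index, drop = TRUE)
  assert_that(!anyDuplicated(key), "duplicate trial keys in manifest")
  tr$path <- full
  list(study_id = obj$study_id, seed = obj$seed, trials = tr, config = obj$config)
}

#' Read a configuration file (JSON or YAML)
#'
#' Values found in the file override the defaults from
#' [default_population_config()] (shallow merge on the top level, full
#' replacement below).
#'
#' @param path config path ending in .json, .yaml or .yml.
#' @return a population configuration list.
#' @export
read_config <- function(path) {
  assert_that(file.exists(path), paste0("no such config: ", path))
  user <- if (grepl("\\.(yaml|yml)$", path)) {
    assert_that(requireNamespace("yaml", quietly = TRUE),
                "the yaml package is required for YAML configs; use JSON otherwise")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  config <- default_population_config()
  for (k in names(user)) config[[k]] <- user[[k]]
  validate_population_config(config)
  config
}
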