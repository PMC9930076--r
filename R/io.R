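#' Write joint-angle trials as long-format CSV
#'
#' The CSV dialect has columns `participant_id`, `condition`, `task`,
#' `trial`, `time_s`, `joint`, `angle_deg` (plus
#' `measured_completion_time_s` when available), UTF-8 with a header row.
#'
#' @param trials list of [JointAngleTrial-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAngleData <- function(trials, path) {
  rows <- lapply(trials, function(tr) {
    n <- nrow(tr@angles)
    data.frame(
      participant_id = tr@participant_id,
      condition = tr@condition,
      task = tr@task,
      trial = tr@trial_index,
      time_s = (seq_len(n) - 1L) / tr@sample_rate_hz,
      joint = rep(colnames(tr@angles), each = n),
      angle_deg = as.vector(tr@angles),
      measured_completion_time_s = tr@measured_completion_time_s,
      stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read joint-angle trials from long-format CSV
#'
#' Reads the dialect written by [writeAngleData()] and reassembles
#' [JointAngleTrial-class] objects, inferring the sampling rate from the
#' time column. Malformed files (missing columns, unequal series lengths)
#' raise errors naming the problem.
#'
#' @param path CSV file.
#' @return List of [JointAngleTrial-class].
#' @export
readAngleData <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("participant_id", "condition", "task", "trial", "time_s",
           "joint", "angle_deg")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("angle CSV is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  key <- interaction(df$participant_id, df$condition, df$task, df$trial,
                     drop = TRUE)
  lapply(split(df, key), function(d) {
    lens <- table(d$joint)
    if (!setequal(names(lens), ULP_JOINTS) ||
        length(unique(as.integer(lens))) != 1L)
      stop(sprintf(
        "trial %s/%s/%s/%s: the 7 joint series must be present with equal length",
        d$participant_id[1], d$condition[1], d$task[1], d$trial[1]))
    d <- d[order(d$joint, d$time_s), ]
    n <- as.integer(lens[1])
    ts <- sort(unique(d$time_s))
    fs <- 1 / stats::median(diff(ts))
    ang <- matrix(NA_real_, n, 7L,
                  dimnames = list(NULL, sort(ULP_JOINTS)))
    for (j in sort(ULP_JOINTS))
      ang[, j] <- d$angle_deg[d$joint == j]
    mt <- if ("measured_completion_time_s" %in% names(d))
      d$measured_completion_time_s[1] else NA_real_
    jointAngleTrial(d$participant_id[1], d$condition[1], d$task[1],
                    d$trial[1], fs, ang[, ULP_JOINTS],
                    measured_completion_time_s = mt)
  })
}

#' Write / read a kinematic-summary table
#'
#' One row per participant x condition x task x joint, the tabular output of
#' [summarizeParticipant()] across a study.
#'
#' @param summary data.frame (the `summary` element(s) bound together).
#' @param path CSV file.
#' @return `path` / the data.frame.
#' @export
writeKinematicSummary <- function(summary, path) {
  write.csv(summary, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeKinematicSummary
#' @export
readKinematicSummary <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("participant_id", "condition", "task", "joint", "rom_mean_deg",
           "kv_deg", "kr")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("kinematic summary CSV is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  df
}

#' Read a tidy score table
#'
#' Expected columns: `participant_id`, `group`, `measure`, `value`
#' (long format), or a wide table with `participant_id`, `group` and one
#' column per measure, which is returned as-is.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
readScoreTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("participant_id", "group") %in% names(df)))
    stop("score CSV must have participant_id and group columns")
  df
}

#' Build and validate a run configuration
#'
#' Collects the analysis settings shared by [runWithinComparison()] and
#' [runBetweenComparison()]; every threshold must be positive and `alpha` in
#' (0, 1).
#'
#' @param alpha significance level (0.01 in the reference analysis).
#' @param variance_policy `"auto"`, `"pooled"` or `"welch"` for independent t.
#' @param n_steps normalized trial length.
#' @param max_step_deg,angle_bounds_deg artifact screen settings.
#' @param onset_velocity_threshold_deg_s,sustain_ms,return_tolerance_deg,baseline_window_s
#'   segmentation settings.
#' @param indeterminate_band_deg coordination-rule indeterminate band.
#' @param seed RNG seed recorded with the run.
#' @return A validated `RunConfig` (S3) list.
#' @export
runConfig <- function(alpha = 0.01,
                      variance_policy = c("auto", "pooled", "welch"),
                      n_steps = 500L,
                      max_step_deg = 30,
                      angle_bounds_deg = c(-180, 180),
                      onset_velocity_threshold_deg_s = 5,
                      sustain_ms = 100,
                      return_tolerance_deg = 2,
                      baseline_window_s = 0.5,
                      indeterminate_band_deg = 1,
                      seed = 1L) {
  variance_policy <- match.arg(variance_policy)
  cfg <- list(alpha = alpha, variance_policy = variance_policy,
              n_steps = as.integer(n_steps), max_step_deg = max_step_deg,
              angle_bounds_deg = angle_bounds_deg,
              onset_velocity_threshold_deg_s = onset_velocity_threshold_deg_s,
              sustain_ms = sustain_ms,
              return_tolerance_deg = return_tolerance_deg,
              baseline_window_s = baseline_window_s,
              indeterminate_band_deg = indeterminate_band_deg,
              seed = as.integer(seed))
  if (!(alpha > 0 && alpha < 1)) stop("alpha: must lie in (0, 1)")
  pos <- c("n_steps", "max_step_deg", "onset_velocity_threshold_deg_s",
           "sustain_ms", "return_tolerance_deg", "baseline_window_s",
           "indeterminate_band_deg")
  for (f in pos)
    if (cfg[[f]] <= 0) stop(sprintf("%s: must be positive", f))
  structure(cfg, class = "RunConfig")
}

#' Load a run configuration from YAML or JSON
#'
#' @param path file whose extension selects the parser (`.yaml`/`.yml` or
#'   `.json`); fields are validated by [runConfig()].
#' @return A `RunConfig` list.
#' @export
loadRunConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop(sprintf("unsupported config format '%s' (use yaml or json)", ext)))
  allowed <- names(formals(runConfig))
  bad <- setdiff(names(vals), allowed)
  if (length(bad))
    stop(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")))
  do.call(runConfig, vals)
}
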