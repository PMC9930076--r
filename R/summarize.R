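#' Summarize the trials of one participant x condition x task
#'
#' Runs the full per-trial chain: artifact screen, movement-bound detection,
#' raw-segment RoM, time-normalization, then kinematic variability (KV) and
#' repeatability (KR) across the included trials. Trials failing the artifact
#' screen (or in which no movement is detected) are excluded and counted;
#' completion-time mean and SD (denominator n - 1) are computed over included
#' trials. KV/KR require at least 2 included trials and are `NA` otherwise.
#'
#' @param trials list of [JointAngleTrial-class] sharing participant,
#'   condition and task.
#' @param n_steps number of normalized time steps (default 500).
#' @param max_step_deg,angle_bounds_deg artifact-screen settings, see
#'   [screenArtifacts()].
#' @param onset_velocity_threshold_deg_s,sustain_ms,return_tolerance_deg,baseline_window_s,detect_cutoff_hz
#'   segmentation settings, see [detectTrialBounds()].
#' @param bounds `"detect"` (default) segments each trial by the velocity
#'   rule; `"ground_truth"` uses generator metadata (synthetic data only),
#'   which isolates the KV/KR estimators from detection jitter.
#' @return A `KinematicSummary` (S3) list with elements
#'   \describe{
#'     \item{summary}{data.frame, one row per joint: `participant_id`,
#'       `condition`, `task`, `joint`, `rom_mean_deg`, `kv_deg`, `kr`,
#'       `n_trials_included`, `n_trials_excluded`, `completion_time_mean_s`,
#'       `completion_time_sd_s`.}
#'     \item{qc}{data.frame, one row per trial: bounds, end source,
#'       completion time, exclusion flag and reason.}
#'     \item{normalized}{list of included normalized-trial matrices.}
#'   }
#' @export
summarizeParticipant <- function(trials, n_steps = 500L,
                                 max_step_deg = 30,
                                 angle_bounds_deg = c(-180, 180),
                                 onset_velocity_threshold_deg_s = 5,
                                 sustain_ms = 100,
                                 return_tolerance_deg = 2,
                                 baseline_window_s = 0.5,
                                 detect_cutoff_hz = 2,
                                 bounds = c("detect", "ground_truth")) {
  bounds <- match.arg(bounds)
  stopifnot(length(trials) >= 1L)
  ids <- unique(vapply(trials, function(t) paste(
    t@participant_id, t@condition, t@task), character(1)))
  if (length(ids) != 1L)
    stop("trials must share participant, condition and task")

  qc <- vector("list", length(trials))
  normalized <- list()
  roms <- list()
  times <- numeric(0)
  reports <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    rep_i <- screenArtifacts(tr, max_step_deg, angle_bounds_deg)
    reports[[i]] <- rep_i
    row <- data.frame(
      participant_id = tr@participant_id, condition = tr@condition,
      task = tr@task, trial_index = tr@trial_index,
      excluded = rep_i$excluded,
      reason = if (rep_i$excluded)
        paste(unique(rep_i$reasons$type), collapse = ";") else "",
      start_index = NA_integer_, end_index = NA_integer_,
      end_source = NA_character_, completion_time_s = NA_real_,
      stringsAsFactors = FALSE)
    if (!rep_i$excluded) {
      bd <- tryCatch({
        if (bounds == "ground_truth") groundTruthBounds(tr) else
          detectTrialBounds(tr, onset_velocity_threshold_deg_s, sustain_ms,
                            return_tolerance_deg, baseline_window_s,
                            detect_cutoff_hz)
      }, error = function(e) e)
      if (inherits(bd, "error")) {
        row$excluded <- TRUE
        row$reason <- conditionMessage(bd)
      } else {
        row$start_index <- bd$start_index
        row$end_index <- bd$end_index
        row$end_source <- bd$end_source
        row$completion_time_s <- bd$completion_time_s
        roms[[length(roms) + 1L]] <- computeRom(tr, bd)
        normalized[[length(normalized) + 1L]] <-
          timeNormalize(tr, bd, n_steps)
        times <- c(times, bd$completion_time_s)
      }
    }
    qc[[i]] <- row
  }
  qc <- do.call(rbind, qc)
  n_inc <- sum(!qc$excluded)
  n_exc <- sum(qc$excluded)
  if (n_inc == 0L) {
    err <- simpleError("no analyzable trials: all trials excluded")
    err$artifact_reports <- reports
    stop(err)
  }
  rom_mat <- do.call(rbind, roms)
  rom_mean <- colMeans(rom_mat)
  if (n_inc >= 2L) {
    kv <- computeKv(normalized)
    kr <- suppressWarnings(computeKr(normalized))
  } else {
    kv <- stats::setNames(rep(NA_real_, length(ULP_JOINTS)), ULP_JOINTS)
    kr <- kv
  }
  tr1 <- trials[[1L]]
  summary <- data.frame(
    participant_id = tr1@participant_id,
    condition = tr1@condition,
    task = tr1@task,
    joint = ULP_JOINTS,
    rom_mean_deg = as.numeric(rom_mean[ULP_JOINTS]),
    kv_deg = as.numeric(kv[ULP_JOINTS]),
    kr = as.numeric(kr[ULP_JOINTS]),
    n_trials_included = n_inc,
    n_trials_excluded = n_exc,
    completion_time_mean_s = mean(times),
    completion_time_sd_s = if (n_inc >= 2L) sd(times) else NA_real_,
    stringsAsFactors = FALSE)
  structure(list(summary = summary, qc = qc, normalized = normalized),
            class = "KinematicSummary")
}

#' @export
print.KinematicSummary <- function(x, ...) {
  s <- x$summary[1L, ]
  cat(sprintf("KinematicSummary %s | %s | %s: %d included, %d excluded\n",
              s$participant_id, s$condition, s$task,
              s$n_trials_included, s$n_trials_excluded))
  print(x$summary[, c("joint", "rom_mean_deg", "kv_deg", "kr")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

## Signed mean excursion of one channel over the segmented movement,
## relative to the trial's initial value (mean of the baseline window).
trialExcursion <- function(trial, channel, bd, baseline_window_s = 0.5) {
  fs <- trial@sample_rate_hz
  x <- trial@angles[, channel]
  nb <- max(2L, min(length(x), as.integer(round(baseline_window_s * fs))))
  init <- mean(x[seq_len(nb)])
  mean(x[bd$start_index:bd$end_index] - init)
}

#' Classify a participant's shoulder coordination pattern
#'
#' Compares, between the MHP and SHP conditions, the signed mean excursions
#' of shoulder internal(+)/external(-) rotation and abduction(+)/adduction(-)
#' over the clothespin-relocation (RCRT) trials. A participant is labelled
#' `JC_DIFF` (different joint coordination) when both excursion signs flip
#' between conditions, and `JC_SIM` otherwise. Excursions within
#' `indeterminate_band_deg` of zero are treated as sign-indeterminate and
#' resolve conservatively to `JC_SIM`.
#'
#' @param trials list of [JointAngleTrial-class] for one participant, both
#'   conditions (RCRT tasks are used; others ignored).
#' @param indeterminate_band_deg half-width of the indeterminate band (deg).
#' @param bounds see [summarizeParticipant()].
#' @param ... further arguments passed to [screenArtifacts()] /
#'   [detectTrialBounds()] defaults are used.
#' @return A `CoordinationAssessment` (S3) list: `participant_id`, `label`
#'   (`"JC_SIM"` or `"JC_DIFF"`), `excursions` (data.frame condition x
#'   channel with the audit metrics), `rule_version`.
#' @export
classifyCoordination <- function(trials, indeterminate_band_deg = 1,
                                 bounds = c("detect", "ground_truth"), ...) {
  bounds <- match.arg(bounds)
  pid <- unique(vapply(trials, participantId, character(1)))
  if (length(pid) != 1L)
    stop("trials must belong to a single participant")
  rcrt <- Filter(function(t) t@task %in% c("RCRT_up", "RCRT_down"), trials)
  conds <- unique(vapply(rcrt, condition, character(1)))
  if (!all(ULP_CONDITIONS %in% conds))
    stop("incomparable participant: both MHP and SHP conditions are required")
  channels <- c(rotation = "shoulder_internal_external_rotation",
                abduction = "shoulder_abduction_adduction")
  rows <- list()
  exc <- matrix(NA_real_, 2L, 2L,
                dimnames = list(ULP_CONDITIONS, names(channels)))
  for (cond in ULP_CONDITIONS) {
    sel <- Filter(function(t) t@condition == cond, rcrt)
    vals <- matrix(NA_real_, 0L, 2L)
    for (tr in sel) {
      if (screenArtifacts(tr)$excluded) next
      bd <- tryCatch({
        if (bounds == "ground_truth") groundTruthBounds(tr) else
          detectTrialBounds(tr)
      }, error = function(e) NULL)
      if (is.null(bd)) next
      vals <- rbind(vals, vapply(channels, trialExcursion, numeric(1),
                                 trial = tr, bd = bd))
    }
    if (nrow(vals) == 0L)
      stop(sprintf("incomparable participant: no analyzable RCRT trials in %s",
                   cond))
    exc[cond, ] <- colMeans(vals)
  }
  determinate <- abs(exc) > indeterminate_band_deg
  flips <- vapply(names(channels), function(ch)
    all(determinate[, ch]) &&
      sign(exc["MHP", ch]) != sign(exc["SHP", ch]), logical(1))
  label <- if (all(flips)) "JC_DIFF" else "JC_SIM"
  structure(list(
    participant_id = pid,
    label = label,
    excursions = as.data.frame(exc),
    rule_version = "sign-flip/1.0"
  ), class = "CoordinationAssessment")
}

#' @export
print.CoordinationAssessment <- function(x, ...) {
  cat(sprintf("CoordinationAssessment %s: %s (rule %s)\n",
              x$participant_id, x$label, x$rule_version))
  print(round(x$excursions, 2))
  invisible(x)
}
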