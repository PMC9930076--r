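## Group trials into a nested list participant -> condition -> task.
splitTrials <- function(trials) {
  keys <- vapply(trials, function(t)
    paste(t@participant_id, t@condition, t@task, sep = "\r"), character(1))
  split(trials, keys)
}

#' Within-group comparison: MHP vs SHP kinematics in the cross-over arm
#'
#' For every participant with trials in both conditions, per task:
#' completion-time means and SDs are compared across conditions with a
#' paired t test; range of motion, kinematic variability and kinematic
#' repeatability are each compared with the 2 (hand) x 7 (joint)
#' fully-within repeated-measures ANOVA; and each participant's shoulder
#' coordination pattern is classified as `JC_SIM`/`JC_DIFF`. Participants
#' missing a condition are excluded with a logged reason.
#'
#' @param trials list of [JointAngleTrial-class] covering both conditions.
#' @param config a [runConfig()].
#' @param bounds segmentation mode passed to [summarizeParticipant()].
#' @return A `ComparisonReport` (S3) list: `kinematic_summary` (full-precision
#'   table), `qc`, `completion_tests` (per task), `anova` (per task x metric),
#'   `coordination` (per participant labels), `exclusions`.
#' @export
runWithinComparison <- function(trials, config = runConfig(),
                                bounds = c("detect", "ground_truth")) {
  bounds <- match.arg(bounds)
  stopifnot(inherits(config, "RunConfig"))
  pids <- unique(vapply(trials, participantId, character(1)))
  exclusions <- data.frame(participant_id = character(),
                           reason = character(), stringsAsFactors = FALSE)
  summaries <- list()
  qcs <- list()
  coords <- list()
  for (pid in pids) {
    ptrials <- Filter(function(t) t@participant_id == pid, trials)
    conds <- unique(vapply(ptrials, condition, character(1)))
    if (!all(ULP_CONDITIONS %in% conds)) {
      exclusions <- rbind(exclusions, data.frame(
        participant_id = pid,
        reason = sprintf("missing condition: %s",
                         paste(setdiff(ULP_CONDITIONS, conds),
                               collapse = ", ")),
        stringsAsFactors = FALSE))
      next
    }
    ok <- TRUE
    for (cond in ULP_CONDITIONS) for (tk in ULP_TASKS) {
      sel <- Filter(function(t) t@condition == cond && t@task == tk, ptrials)
      if (!length(sel)) next
      sm <- tryCatch(summarizeParticipant(
        sel, n_steps = config$n_steps,
        max_step_deg = config$max_step_deg,
        angle_bounds_deg = config$angle_bounds_deg,
        onset_velocity_threshold_deg_s =
          config$onset_velocity_threshold_deg_s,
        sustain_ms = config$sustain_ms,
        return_tolerance_deg = config$return_tolerance_deg,
        baseline_window_s = config$baseline_window_s,
        bounds = bounds), error = function(e) e)
      if (inherits(sm, "error")) {
        exclusions <- rbind(exclusions, data.frame(
          participant_id = pid,
          reason = sprintf("%s/%s: %s", cond, tk, conditionMessage(sm)),
          stringsAsFactors = FALSE))
        ok <- FALSE
      } else {
        summaries[[length(summaries) + 1L]] <- sm$summary
        qcs[[length(qcs) + 1L]] <- sm$qc
      }
    }
    if (ok) {
      ca <- tryCatch(
        classifyCoordination(ptrials,
                             indeterminate_band_deg =
                               config$indeterminate_band_deg,
                             bounds = bounds),
        error = function(e) e)
      if (!inherits(ca, "error"))
        coords[[length(coords) + 1L]] <- data.frame(
          participant_id = pid, label = ca$label,
          rot_mhp = ca$excursions["MHP", "rotation"],
          rot_shp = ca$excursions["SHP", "rotation"],
          abd_mhp = ca$excursions["MHP", "abduction"],
          abd_shp = ca$excursions["SHP", "abduction"],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(summaries))
    stop("no participant provided analyzable trials in both conditions")
  summary_tab <- do.call(rbind, summaries)
  qc_tab <- do.call(rbind, qcs)
  rownames(summary_tab) <- rownames(qc_tab) <- NULL

  ## Completion-time paired t per task (participant-level means).
  ct <- unique(summary_tab[, c("participant_id", "condition", "task",
                               "completion_time_mean_s",
                               "completion_time_sd_s")])
  completion_tests <- list()
  for (tk in intersect(ULP_TASKS, unique(ct$task))) {
    d <- ct[ct$task == tk, ]
    wide <- merge(d[d$condition == "MHP",
                    c("participant_id", "completion_time_mean_s",
                      "completion_time_sd_s")],
                  d[d$condition == "SHP",
                    c("participant_id", "completion_time_mean_s",
                      "completion_time_sd_s")],
                  by = "participant_id", suffixes = c("_mhp", "_shp"))
    if (nrow(wide) >= 2L) {
      completion_tests[[tk]] <- list(
        mean = pairedT(wide$completion_time_mean_s_mhp,
                       wide$completion_time_mean_s_shp,
                       alpha = config$alpha),
        sd = if (all(!is.na(wide$completion_time_sd_s_mhp)) &&
                 all(!is.na(wide$completion_time_sd_s_shp)))
          pairedT(wide$completion_time_sd_s_mhp,
                  wide$completion_time_sd_s_shp, alpha = config$alpha)
        else NULL,
        n = nrow(wide))
    }
  }

  ## 2 x 7 RM-ANOVA per task and metric.
  anova <- list()
  for (tk in intersect(ULP_TASKS, unique(summary_tab$task))) {
    anova[[tk]] <- list()
    for (metric in c("rom_mean_deg", "kv_deg", "kr")) {
      d <- summary_tab[summary_tab$task == tk,
                       c("participant_id", "condition", "joint", metric)]
      names(d) <- c("subject", "hand", "joint", "value")
      d <- d[complete.cases(d), ]
      counts <- table(d$subject)
      full <- names(counts)[counts == 2L * length(ULP_JOINTS)]
      d <- d[d$subject %in% full, ]
      if (length(full) >= 3L)
        anova[[tk]][[metric]] <- rmAnovaHandByJoint(
          d, alpha = config$alpha)
    }
  }

  coordination <- if (length(coords)) do.call(rbind, coords) else
    data.frame(participant_id = character(), label = character())
  structure(list(
    kinematic_summary = summary_tab,
    qc = qc_tab,
    completion_tests = completion_tests,
    anova = anova,
    coordination = coordination,
    exclusions = exclusions,
    config = config
  ), class = "ComparisonReport")
}

#' Between-group comparison: questionnaire scores of MHP vs SHP users
#'
#' Per numeric measure: each group is checked for normality (Shapiro-Wilk,
#' alpha 0.05); when both groups pass, a Levene-routed unpaired t test is
#' used, otherwise the Mann-Whitney test. Character/factor measures are
#' cross-tabulated and tested with Pearson chi-squared plus Cramer's V.
#' Measures that are constant in both groups, or present in only one, are
#' flagged and skipped.
#'
#' @param scores data.frame with `participant_id`, `group`, and one column
#'   per measure (wide), or long format with `measure`/`value` columns.
#' @param config a [runConfig()].
#' @return A `ComparisonReport` (S3) list with `between_table` (one row per
#'   measure: group descriptives, test, statistic, df, p, effect size,
#'   label, significance) and `tests` (the [StatTestResult-class] objects).
#' @export
runBetweenComparison <- function(scores, config = runConfig()) {
  stopifnot(inherits(config, "RunConfig"))
  if (all(c("measure", "value") %in% names(scores))) {
    wide <- stats::reshape(
      scores[, c("participant_id", "group", "measure", "value")],
      idvar = c("participant_id", "group"), timevar = "measure",
      direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    scores <- wide
  }
  if (!all(c("participant_id", "group") %in% names(scores)))
    stop("scores must have participant_id and group columns")
  groups <- sort(unique(scores$group))
  if (length(groups) != 2L)
    stop("exactly two groups are required")
  measures <- setdiff(names(scores), c("participant_id", "group"))
  rows <- list()
  tests <- list()
  for (m in measures) {
    v1 <- scores[scores$group == groups[1], m]
    v2 <- scores[scores$group == groups[2], m]
    v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
    row <- data.frame(
      measure = m, group1 = groups[1], group2 = groups[2],
      n1 = length(v1), n2 = length(v2),
      mean1 = NA_real_, sd1 = NA_real_, median1 = NA_real_, iqr1 = NA_real_,
      mean2 = NA_real_, sd2 = NA_real_, median2 = NA_real_, iqr2 = NA_real_,
      test = NA_character_, statistic = NA_real_, df = NA_real_,
      p_value = NA_real_, effect_size = NA_real_,
      effect_label = NA_character_, significant = NA,
      flag = "", stringsAsFactors = FALSE)
    if (!length(v1) || !length(v2)) {
      row$flag <- "present in one group only; skipped"
      rows[[m]] <- row
      next
    }
    if (is.numeric(scores[[m]])) {
      row$mean1 <- mean(v1); row$sd1 <- sd(v1)
      row$median1 <- median(v1); row$iqr1 <- stats::IQR(v1)
      row$mean2 <- mean(v2); row$sd2 <- sd(v2)
      row$median2 <- median(v2); row$iqr2 <- stats::IQR(v2)
      if (sd(v1) == 0 && sd(v2) == 0) {
        row$flag <- "degenerate: constant in both groups"
        rows[[m]] <- row
        next
      }
      parametric <- tryCatch(
        checkNormality(v1)$parametric && checkNormality(v2)$parametric,
        error = function(e) FALSE)
      res <- if (parametric)
        independentT(v1, v2, variance_policy = config$variance_policy,
                     alpha = config$alpha)
      else mannWhitney(v1, v2, alpha = config$alpha)
    } else {
      tab <- table(scores$group, scores[[m]])
      res <- tryCatch(chiSquared(tab, alpha = config$alpha),
                      error = function(e) e)
      if (inherits(res, "error")) {
        row$flag <- sprintf("degenerate: %s", conditionMessage(res))
        rows[[m]] <- row
        next
      }
    }
    row$test <- res@method
    row$statistic <- res@statistic
    row$df <- res@df
    row$p_value <- res@p_value
    row$effect_size <- res@effect_size
    row$effect_label <- res@effect_label
    row$significant <- res@significant
    rows[[m]] <- row
    tests[[m]] <- res
  }
  structure(list(
    between_table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    tests = tests,
    config = config
  ), class = "ComparisonReport")
}

#' Round a comparison table for presentation
#'
#' Applies the reporting convention of the reference tables: statistics and
#' effect sizes to 1 decimal, p-values to 2 decimals. Rounding is
#' presentation-only; the full-precision tables remain in the report.
#'
#' @param report a `ComparisonReport` from [runBetweenComparison()].
#' @return The `between_table` with rounded columns.
#' @export
formatBetweenTable <- function(report) {
  tab <- report$between_table
  for (col in c("statistic", "effect_size", "mean1", "sd1", "mean2", "sd2",
                "median1", "iqr1", "median2", "iqr2"))
    tab[[col]] <- round(tab[[col]], 1)
  tab$df <- round(tab$df, 1)
  tab$p_value <- round(tab$p_value, 2)
  tab
}

#' @export
print.ComparisonReport <- function(x, ...) {
  if (!is.null(x$between_table)) {
    cat("Between-group comparison report\n")
    print(formatBetweenTable(x), row.names = FALSE)
  } else {
    cat(sprintf(
      "Within-group comparison report: %d participants, %d excluded\n",
      length(unique(x$kinematic_summary$participant_id)),
      nrow(x$exclusions)))
    if (nrow(x$coordination)) {
      cat("Coordination labels:\n")
      print(table(x$coordination$label))
    }
    for (tk in names(x$completion_tests)) {
      ct <- x$completion_tests[[tk]]
      cat(sprintf(
        "%s completion time: t = %.2f, df = %g, p = %.3f, r = %.2f\n",
        tk, ct$mean@statistic, ct$mean@df, ct$mean@p_value,
        ct$mean@effect_size))
    }
  }
  invisible(x)
}
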