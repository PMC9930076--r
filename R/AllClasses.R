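#' JointAngleTrial: one recorded trial of 7 joint-angle series
#'
#' Container for a single task execution: a numeric matrix of joint angles in
#' degrees (rows are samples at a fixed rate, columns the seven joints named
#' by [jointNames()]), together with participant, condition, task and trial
#' labels. An optional stopwatch completion time serves as a fallback when
#' movement-offset detection fails, and `meta` carries generator ground truth
#' for synthetic trials.
#'
#' @slot participant_id character scalar.
#' @slot condition `"MHP"` or `"SHP"`.
#' @slot task one of `"RCRT_up"`, `"RCRT_down"`, `"TRAY"`.
#' @slot trial_index positive integer.
#' @slot sample_rate_hz sampling rate in Hz (60 in the reference protocol).
#' @slot angles numeric matrix, samples x 7 joints, degrees.
#' @slot measured_completion_time_s stopwatch time in seconds, or `NA`.
#' @slot meta list of free-form metadata (e.g. synthetic ground truth).
#'
#' @export
setClass("JointAngleTrial",
  representation(
    participant_id = "character",
    condition = "character",
    task = "character",
    trial_index = "integer",
    sample_rate_hz = "numeric",
    angles = "matrix",
    measured_completion_time_s = "numeric",
    meta = "list"
  ),
  prototype(
    measured_completion_time_s = NA_real_,
    meta = list()
  )
)

setValidity("JointAngleTrial", function(object) {
  msgs <- character()
  if (length(object@participant_id) != 1L || is.na(object@participant_id))
    msgs <- c(msgs, "participant_id must be a single non-missing string")
  if (length(object@condition) != 1L || !object@condition %in% ULP_CONDITIONS)
    msgs <- c(msgs, sprintf("condition must be one of: %s",
                            paste(ULP_CONDITIONS, collapse = ", ")))
  if (length(object@task) != 1L || !object@task %in% ULP_TASKS)
    msgs <- c(msgs, sprintf("task must be one of: %s",
                            paste(ULP_TASKS, collapse = ", ")))
  if (length(object@trial_index) != 1L || is.na(object@trial_index) ||
      object@trial_index < 1L)
    msgs <- c(msgs, "trial_index must be a positive integer")
  if (length(object@sample_rate_hz) != 1L || is.na(object@sample_rate_hz) ||
      object@sample_rate_hz <= 0)
    msgs <- c(msgs, "sample_rate_hz must be a positive number")
  a <- object@angles
  if (!is.numeric(a) || is.null(colnames(a)))
    msgs <- c(msgs, "angles must be a numeric matrix with joint column names")
  else {
    if (!setequal(colnames(a), ULP_JOINTS) || anyDuplicated(colnames(a)))
      msgs <- c(msgs, "angles must have exactly the 7 joint columns (see jointNames())")
    if (nrow(a) < 2L)
      msgs <- c(msgs, "angles must contain at least 2 samples")
    if (anyNA(a))
      msgs <- c(msgs, "angles must not contain missing values")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a JointAngleTrial
#'
#' @param participant_id,condition,task,trial_index trial labels.
#' @param sample_rate_hz sampling rate in Hz.
#' @param angles numeric matrix (samples x 7 joints, columns named as
#'   [jointNames()]) of angles in degrees.
#' @param measured_completion_time_s optional stopwatch time in seconds.
#' @param meta optional metadata list.
#' @return A [JointAngleTrial-class] object.
#' @examples
#' ang <- matrix(0, 120, 7, dimnames = list(NULL, jointNames()))
#' tr <- jointAngleTrial("P01", "MHP", "RCRT_up", 1, 60, ang)
#' sampleRate(tr)
#' @export
jointAngleTrial <- function(participant_id, condition, task, trial_index,
                            sample_rate_hz, angles,
                            measured_completion_time_s = NA_real_,
                            meta = list()) {
  angles <- angles[, ULP_JOINTS, drop = FALSE]
  new("JointAngleTrial",
      participant_id = as.character(participant_id),
      condition = as.character(condition),
      task = as.character(task),
      trial_index = as.integer(trial_index),
      sample_rate_hz = as.numeric(sample_rate_hz),
      angles = angles,
      measured_completion_time_s = as.numeric(measured_completion_time_s),
      meta = meta)
}

#' @describeIn jointAngleTrial angle matrix accessor (samples x joints, degrees)
#' @param object,x a `JointAngleTrial`.
#' @export
setGeneric("angles", function(object) standardGeneric("angles"))

#' @rdname jointAngleTrial
#' @export
setMethod("angles", "JointAngleTrial", function(object) object@angles)

#' @rdname jointAngleTrial
#' @export
setGeneric("participantId", function(object) standardGeneric("participantId"))

#' @rdname jointAngleTrial
#' @export
setMethod("participantId", "JointAngleTrial",
          function(object) object@participant_id)

#' @rdname jointAngleTrial
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))

#' @rdname jointAngleTrial
#' @export
setMethod("condition", "JointAngleTrial", function(object) object@condition)

#' @rdname jointAngleTrial
#' @export
setGeneric("task", function(object) standardGeneric("task"))

#' @rdname jointAngleTrial
#' @export
setMethod("task", "JointAngleTrial", function(object) object@task)

#' @rdname jointAngleTrial
#' @export
setGeneric("trialIndex", function(object) standardGeneric("trialIndex"))

#' @rdname jointAngleTrial
#' @export
setMethod("trialIndex", "JointAngleTrial", function(object) object@trial_index)

#' @rdname jointAngleTrial
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))

#' @rdname jointAngleTrial
#' @export
setMethod("sampleRate", "JointAngleTrial",
          function(object) object@sample_rate_hz)

#' @rdname jointAngleTrial
#' @export
setGeneric("measuredCompletionTime",
           function(object) standardGeneric("measuredCompletionTime"))

#' @rdname jointAngleTrial
#' @export
setMethod("measuredCompletionTime", "JointAngleTrial",
          function(object) object@measured_completion_time_s)

setMethod("show", "JointAngleTrial", function(object) {
  cat(sprintf(
    "JointAngleTrial %s | %s | %s | trial %d\n  %d samples @ %g Hz (%.2f s), 7 joints\n",
    object@participant_id, object@condition, object@task, object@trial_index,
    nrow(object@angles), object@sample_rate_hz,
    nrow(object@angles) / object@sample_rate_hz))
  invisible(object)
})

#' StatTestResult: one statistical test with its effect size
#'
#' Result container for the between/within-comparison test battery. Holds the
#' test statistic, degrees of freedom, p-value, the associated effect size
#' (Pearson r, Cramer's V or generalized eta squared), its magnitude label,
#' and the significance flag at the analysis alpha (0.01 by default, chosen
#' against multiple testing).
#'
#' @slot method tag: `paired_t`, `pooled_t`, `welch_t`, `mann_whitney`,
#'   `chi_squared`, `levene`, `shapiro_wilk`, or `ks`.
#' @slot statistic test statistic value.
#' @slot df,df2 degrees of freedom (df2 is `NA` unless two are needed).
#' @slot p_value two-sided p-value.
#' @slot effect_size effect-size value (`NA` for audit-only tests).
#' @slot effect_metric `pearson_r`, `cramers_v`, `eta_g_sq`, or `none`.
#' @slot effect_label `negligible`, `small`, `medium`, `large`, or `NA`.
#' @slot alpha significance level used for `significant`.
#' @slot significant logical, `p_value < alpha`.
#' @slot details list of auxiliary quantities (ranks, U statistics, the
#'   routing Levene test, expected counts, ...).
#' @export
setClass("StatTestResult",
  representation(
    method = "character",
    statistic = "numeric",
    df = "numeric",
    df2 = "numeric",
    p_value = "numeric",
    effect_size = "numeric",
    effect_metric = "character",
    effect_label = "character",
    alpha = "numeric",
    significant = "logical",
    details = "list"
  ),
  prototype(df2 = NA_real_, effect_size = NA_real_, effect_metric = "none",
            effect_label = NA_character_, alpha = 0.01, details = list())
)

setValidity("StatTestResult", function(object) {
  msgs <- character()
  if (!is.na(object@p_value) &&
      (object@p_value < 0 || object@p_value > 1))
    msgs <- c(msgs, "p_value must lie in [0, 1]")
  if (object@effect_metric == "pearson_r" && !is.na(object@effect_size) &&
      abs(object@effect_size) > 1 + 1e-12)
    msgs <- c(msgs, "|pearson_r| must be <= 1")
  if (object@effect_metric == "cramers_v" && !is.na(object@effect_size) &&
      (object@effect_size < -1e-12 || object@effect_size > 1 + 1e-12))
    msgs <- c(msgs, "cramers_v must lie in [0, 1]")
  if (!is.na(object@p_value) && !is.na(object@significant) &&
      object@significant != (object@p_value < object@alpha))
    msgs <- c(msgs, "significant must equal p_value < alpha")
  if (length(msgs)) msgs else TRUE
})

## Internal constructor; computes label + significance consistently.
newStatResult <- function(method, statistic, df, p_value,
                          effect_size = NA_real_, effect_metric = "none",
                          df2 = NA_real_, alpha = 0.01, details = list(),
                          effect_df = NULL) {
  label <- NA_character_
  if (!identical(effect_metric, "none") && !is.na(effect_size))
    label <- classifyEffect(effect_size, effect_metric, df = effect_df)
  new("StatTestResult",
      method = method, statistic = as.numeric(statistic),
      df = as.numeric(df), df2 = as.numeric(df2),
      p_value = as.numeric(p_value),
      effect_size = as.numeric(effect_size),
      effect_metric = effect_metric, effect_label = label,
      alpha = alpha, significant = as.numeric(p_value) < alpha,
      details = details)
}

#' @describeIn StatTestResult p-value accessor
#' @param object a `StatTestResult`.
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname StatTestResult-class
#' @export
setMethod("pValue", "StatTestResult", function(object) object@p_value)

#' @rdname StatTestResult-class
#' @export
setGeneric("effectSize", function(object) standardGeneric("effectSize"))

#' @rdname StatTestResult-class
#' @export
setMethod("effectSize", "StatTestResult", function(object) object@effect_size)

#' @rdname StatTestResult-class
#' @export
setGeneric("effectLabel", function(object) standardGeneric("effectLabel"))

#' @rdname StatTestResult-class
#' @export
setMethod("effectLabel", "StatTestResult", function(object) object@effect_label)

#' @rdname StatTestResult-class
#' @export
setGeneric("testStatistic", function(object) standardGeneric("testStatistic"))

#' @rdname StatTestResult-class
#' @export
setMethod("testStatistic", "StatTestResult", function(object) object@statistic)

#' @rdname StatTestResult-class
#' @export
setGeneric("isSignificant", function(object) standardGeneric("isSignificant"))

#' @rdname StatTestResult-class
#' @export
setMethod("isSignificant", "StatTestResult", function(object) object@significant)

setMethod("show", "StatTestResult", function(object) {
  dfs <- if (is.na(object@df2)) sprintf("%.4g", object@df) else
    sprintf("%.4g, %.4g", object@df, object@df2)
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              object@method, object@statistic, dfs, object@p_value))
  if (!identical(object@effect_metric, "none"))
    cat(sprintf("  effect (%s) = %.4g [%s]\n", object@effect_metric,
                object@effect_size, object@effect_label))
  cat(sprintf("  %ssignificant at alpha = %g\n",
              if (isTRUE(object@significant)) "" else "not ", object@alpha))
  invisible(object)
})
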