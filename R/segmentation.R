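## Zero-phase low-pass for detection only; falls back to the raw series when
## the cutoff is not below Nyquist. The series is reflection-padded before
## filtering so that the filter's zero initial conditions do not create
## spurious edge transients (a series starting at a non-zero baseline would
## otherwise look like a step).
detectSmooth <- function(x, fs, cutoff) {
  n <- length(x)
  if (cutoff >= fs / 2 || n < 12L) return(x)
  bf <- signal::butter(2, cutoff / (fs / 2))
  k <- min(n - 1L, as.integer(round(2 * fs)))
  ## constant-level padding of the offset-removed series: the filter's zero
  ## initial conditions then match the padded level exactly at the start,
  ## and the end transient decays inside the padding
  x0 <- x - x[1L]
  xp <- c(rep(0, k), x0, rep(x0[n], k))
  y <- signal::filtfilt(bf, xp)
  as.numeric(y[(k + 1L):(k + n)]) + x[1L]
}

## Central-difference angular velocity (deg/s), one-sided at the ends.
angularVelocity <- function(x, fs) {
  n <- length(x)
  v <- numeric(n)
  if (n >= 3L) v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
  v[1L] <- (x[2L] - x[1L]) * fs
  v[n] <- (x[n] - x[n - 1L]) * fs
  v
}

#' Detect movement start and end of a trial
#'
#' The start is the first sample at which the angular velocity of either
#' shoulder detection channel (flexion/extension or abduction/adduction)
#' exceeds `onset_velocity_threshold_deg_s` for at least `sustain_ms`.
#' The end is the first sample after the last sustained suprathreshold
#' movement at
#' which both shoulder channels are back within `return_tolerance_deg` of
#' their pre-start baseline (the mean of the first `baseline_window_s` of the
#' recording). When no such return exists, the end falls back to
#' `start + measured completion time`. Velocities are computed on a
#' zero-phase low-pass (2 Hz) copy of the angles so that sensor-level noise
#' does not trigger spurious onsets.
#'
#' Candidate onsets are confirmed by requiring the velocity to reach
#' `confirm_factor` times the threshold within `confirm_window_s` of the run
#' start; slow noise ramps that momentarily cross the onset threshold are
#' thereby rejected, while a genuine reach (whose peak velocity is an order
#' of magnitude above threshold) confirms immediately. If no run confirms,
#' the earliest sustained run is used.
#'
#' @param trial a [JointAngleTrial-class].
#' @param onset_velocity_threshold_deg_s onset threshold (deg/s).
#' @param sustain_ms minimum supra-threshold duration (ms).
#' @param return_tolerance_deg baseline-return tolerance (deg).
#' @param baseline_window_s window defining the starting value (s).
#' @param detect_cutoff_hz low-pass cutoff for detection (Hz).
#' @param confirm_factor,confirm_window_s onset-confirmation rule (see
#'   above).
#' @return A `SegmentBounds` (S3) list: `start_index`, `end_index`,
#'   `completion_time_s`, `end_source` (`"detected"` or
#'   `"fallback_measured_time"`).
#' @export
detectTrialBounds <- function(trial,
                              onset_velocity_threshold_deg_s = 5,
                              sustain_ms = 100,
                              return_tolerance_deg = 2,
                              baseline_window_s = 0.5,
                              detect_cutoff_hz = 1.5,
                              confirm_factor = 3,
                              confirm_window_s = 0.5) {
  stopifnot(is(trial, "JointAngleTrial"))
  if (onset_velocity_threshold_deg_s <= 0 || sustain_ms <= 0 ||
      return_tolerance_deg <= 0)
    stop("detection thresholds must be positive")
  fs <- trial@sample_rate_hz
  a <- trial@angles[, SHOULDER_DETECT_JOINTS, drop = FALSE]
  n <- nrow(a)
  sm <- apply(a, 2L, detectSmooth, fs = fs, cutoff = detect_cutoff_hz)
  vel <- apply(sm, 2L, angularVelocity, fs = fs)
  supra <- abs(vel) > onset_velocity_threshold_deg_s
  k <- max(1L, as.integer(round(sustain_ms / 1000 * fs)))
  runs <- do.call(rbind, lapply(seq_len(ncol(supra)), function(j) {
    r <- rle(supra[, j])
    ends <- cumsum(r$lengths)
    keep <- r$values & r$lengths >= k
    cbind(start = (ends - r$lengths + 1L)[keep], end = ends[keep])
  }))
  run_starts <- sort(unique(runs[, "start"]))
  if (!length(run_starts))
    stop("no movement detected in the shoulder angles")
  vmax <- pmax(abs(vel[, 1L]), abs(vel[, 2L]))
  w <- max(1L, as.integer(round(confirm_window_s * fs)))
  confirmed <- vapply(run_starts, function(s)
    max(vmax[s:min(s + w, n)]) >=
      confirm_factor * onset_velocity_threshold_deg_s, logical(1))
  start_index <- if (any(confirmed)) run_starts[which(confirmed)[1L]] else
    run_starts[1L]

  nb <- max(2L, min(n, as.integer(round(baseline_window_s * fs))))
  baseline <- colMeans(a[seq_len(nb), , drop = FALSE])

  last_supra <- max(runs[, "end"])
  end_index <- NA_integer_
  if (last_supra < n) {
    cand <- (last_supra + 1L):n
    back <- abs(a[cand, 1L] - baseline[1L]) <= return_tolerance_deg &
      abs(a[cand, 2L] - baseline[2L]) <= return_tolerance_deg
    if (any(back)) end_index <- cand[which(back)[1L]]
  }
  end_source <- "detected"
  if (is.na(end_index)) {
    mt <- trial@measured_completion_time_s
    if (is.na(mt))
      stop("end undeterminable: no baseline return and no measured completion time")
    end_index <- start_index + as.integer(round(mt * fs))
    end_index <- min(end_index, n)
    end_source <- "fallback_measured_time"
  }
  if (end_index <= start_index)
    stop("end undeterminable: detected end precedes start")
  structure(list(
    start_index = start_index,
    end_index = end_index,
    completion_time_s = (end_index - start_index) / fs,
    end_source = end_source
  ), class = "SegmentBounds")
}

## Ground-truth bounds for generator trials, same shape as detectTrialBounds().
groundTruthBounds <- function(trial) {
  m <- trial@meta
  if (is.null(m$gt_start_index) || is.null(m$gt_end_index))
    stop("trial carries no generator ground-truth bounds")
  structure(list(
    start_index = m$gt_start_index,
    end_index = min(m$gt_end_index, nrow(trial@angles)),
    completion_time_s = (min(m$gt_end_index, nrow(trial@angles)) -
                           m$gt_start_index) / trial@sample_rate_hz,
    end_source = "ground_truth"
  ), class = "SegmentBounds")
}

#' Screen a trial for gimbal-lock-like artifacts
#'
#' Flags a trial for exclusion when any joint series contains a
#' sample-to-sample jump larger than `max_step_deg` or a sample outside
#' `angle_bounds_deg`. Euler-angle discontinuities near gimbal lock show up
#' as exactly such unaccountable single-sample peaks.
#'
#' @param trial a [JointAngleTrial-class].
#' @param max_step_deg maximum plausible per-sample step (deg); the default
#'   30 deg/sample at 60 Hz corresponds to 1800 deg/s.
#' @param angle_bounds_deg plausible angle interval (deg).
#' @return An `ArtifactReport` (S3) list: `participant_id`, `condition`,
#'   `task`, `trial_index`, `excluded` (TRUE iff any reason), and `reasons`,
#'   a data.frame with columns `joint`, `type` (`"spike"` or
#'   `"out_of_range"`), `index`, `value`.
#' @export
screenArtifacts <- function(trial, max_step_deg = 30,
                            angle_bounds_deg = c(-180, 180)) {
  stopifnot(is(trial, "JointAngleTrial"))
  if (max_step_deg <= 0) stop("max_step_deg must be positive")
  reasons <- list()
  for (j in colnames(trial@angles)) {
    x <- trial@angles[, j]
    st <- which(abs(diff(x)) > max_step_deg)
    if (length(st))
      reasons[[length(reasons) + 1L]] <- data.frame(
        joint = j, type = "spike", index = st + 1L,
        value = abs(diff(x))[st], stringsAsFactors = FALSE)
    oo <- which(x < angle_bounds_deg[1] | x > angle_bounds_deg[2])
    if (length(oo))
      reasons[[length(reasons) + 1L]] <- data.frame(
        joint = j, type = "out_of_range", index = oo, value = x[oo],
        stringsAsFactors = FALSE)
  }
  reasons <- if (length(reasons)) do.call(rbind, reasons) else
    data.frame(joint = character(), type = character(),
               index = integer(), value = numeric(), stringsAsFactors = FALSE)
  structure(list(
    participant_id = trial@participant_id,
    condition = trial@condition,
    task = trial@task,
    trial_index = trial@trial_index,
    excluded = nrow(reasons) > 0L,
    reasons = reasons
  ), class = "ArtifactReport")
}
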