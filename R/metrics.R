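#' Time-normalize a trial segment to a fixed number of steps
#'
#' Resamples each joint series of the segmented movement to exactly `n_steps`
#' points at equally spaced normalized times in \[0, 1\], by cubic-spline
#' interpolation through the original samples. Both segment endpoints are
#' included, so the first and last output samples equal the original values
#' at the bound indices.
#'
#' @param trial a [JointAngleTrial-class].
#' @param bounds a `SegmentBounds` from [detectTrialBounds()].
#' @param n_steps number of output samples (500 in the reference analysis).
#' @return A numeric matrix `n_steps` x 7 (joints in columns), with
#'   attributes `participant_id`, `condition`, `task`, `trial_index`.
#' @export
timeNormalize <- function(trial, bounds, n_steps = 500L) {
  stopifnot(is(trial, "JointAngleTrial"))
  s <- bounds$start_index
  e <- bounds$end_index
  n <- nrow(trial@angles)
  if (s < 1L || e > n || s >= e)
    stop("bounds are invalid for this trial")
  len <- e - s + 1L
  if (len < 4L)
    stop("segment too short for cubic spline (need >= 4 samples)")
  x <- seq(0, 1, length.out = len)
  xout <- seq(0, 1, length.out = n_steps)
  out <- matrix(NA_real_, n_steps, ncol(trial@angles),
                dimnames = list(NULL, colnames(trial@angles)))
  for (j in seq_len(ncol(out)))
    out[, j] <- spline(x, trial@angles[s:e, j], xout = xout,
                       method = "fmm")$y
  attr(out, "participant_id") <- trial@participant_id
  attr(out, "condition") <- trial@condition
  attr(out, "task") <- trial@task
  attr(out, "trial_index") <- trial@trial_index
  out
}

#' Per-trial range of motion
#'
#' RoM of each joint is max minus min of the raw (un-normalized) angle series
#' within the segmented movement.
#'
#' @inheritParams timeNormalize
#' @return Named numeric vector of RoM in degrees (always >= 0).
#' @export
computeRom <- function(trial, bounds) {
  stopifnot(is(trial, "JointAngleTrial"))
  s <- bounds$start_index
  e <- bounds$end_index
  if (s < 1L || e > nrow(trial@angles) || s >= e)
    stop("bounds are invalid for this trial")
  seg <- trial@angles[s:e, , drop = FALSE]
  apply(seg, 2L, function(x) max(x) - min(x))
}

## Stack a list of normalized-trial matrices into a T x M matrix per joint.
stackNormalized <- function(normalized) {
  if (length(normalized) < 2L)
    stop("insufficient trials: at least 2 normalized trials are required")
  dims <- vapply(normalized, nrow, integer(1))
  if (length(unique(dims)) != 1L)
    stop("normalized trials must share the same number of time steps")
  joints <- colnames(normalized[[1L]])
  lapply(stats::setNames(joints, joints), function(j)
    vapply(normalized, function(m) m[, j], numeric(dims[1L])))
}

#' Kinematic variability (KV)
#'
#' For each joint, the across-trial sample standard deviation (denominator
#' M - 1) is computed at every normalized time point and averaged over all
#' time points. KV is in degrees; 0 means sample-for-sample identical trials.
#'
#' @param normalized list of normalized-trial matrices from [timeNormalize()]
#'   for one participant x condition x task (>= 2 trials).
#' @return Named numeric vector, KV per joint (degrees).
#' @export
computeKv <- function(normalized) {
  mats <- stackNormalized(normalized)
  M <- length(normalized)
  vapply(mats, function(Y) {
    mu <- rowMeans(Y)
    mean(sqrt(rowSums((Y - mu)^2) / (M - 1)))
  }, numeric(1))
}

#' Kinematic repeatability (KR): adjusted coefficient of multiple determination
#'
#' With `Y[m, t]` the angle of trial m (of M) at normalized time t (of T),
#' `Ybar_t` the across-trial mean at t and `Ybar` the grand mean:
#' \deqn{KR = 1 - \frac{\sum_{m,t} (Y_{mt} - \bar Y_t)^2 / (T(M-1))}
#'                    {\sum_{m,t} (Y_{mt} - \bar Y)^2 / (TM - 1)}}
#' KR is 1 for identical non-constant waveforms, near 0 for trials sharing no
#' common waveform, and may be negative; negative values are reported
#' unclamped with a warning. A set of sample-for-sample identical constant
#' trials has zero total variance and yields `NA` with a
#' "degenerate waveform" warning.
#'
#' @inheritParams computeKv
#' @return Named numeric vector, KR per joint (dimensionless, <= 1).
#' @export
computeKr <- function(normalized) {
  mats <- stackNormalized(normalized)
  M <- length(normalized)
  out <- vapply(mats, function(Y) {
    Tn <- nrow(Y)
    mu_t <- rowMeans(Y)
    within <- sum((Y - mu_t)^2) / (Tn * (M - 1))
    total <- sum((Y - mean(Y))^2) / (Tn * M - 1)
    if (total <= .Machine$double.eps) return(NA_real_)
    1 - within / total
  }, numeric(1))
  if (anyNA(out))
    warning(sprintf("degenerate waveform (zero total variance) for: %s",
                    paste(names(out)[is.na(out)], collapse = ", ")))
  if (any(!is.na(out) & out < 0))
    warning("negative kinematic repeatability reported unclamped")
  out
}
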