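# Shared fixtures, all generated in code.

# Toy "normalized" matrix: one waveform replicated over the 7 joints.
mkNormalized <- function(v) {
  matrix(rep(v, 7), ncol = 7, dimnames = list(NULL, jointNames()))
}

# A trial with identical series in all joints.
mkTrial <- function(x, fs = 60, participant = "P01", cond = "MHP",
                    task = "RCRT_up", trial = 1, mt = NA_real_) {
  ang <- matrix(rep(x, 7), ncol = 7, dimnames = list(NULL, jointNames()))
  jointAngleTrial(participant, cond, task, trial, fs, ang,
                  measured_completion_time_s = mt)
}

# Small, fast generator configuration: short movements, one value per knob.
quickConfig <- function(n_participants = 1,
                        trials = c(RCRT_up = 3L, RCRT_down = 3L, TRAY = 3L),
                        dur_mean = 5, dur_sd = 0, ...) {
  dur <- data.frame(
    task = rep(taskNames(), each = 2L),
    condition = rep(c("MHP", "SHP"), times = 3L),
    mean_s = dur_mean, sd_s = dur_sd, stringsAsFactors = FALSE)
  syntheticConfig(n_participants = n_participants, trials_per_task = trials,
                  task_duration_s = dur, ...)
}

pickTrials <- function(trials, cond = NULL, tk = NULL, pid = NULL) {
  Filter(function(t) {
    (is.null(cond) || condition(t) == cond) &&
      (is.null(tk) || task(t) %in% tk) &&
      (is.null(pid) || participantId(t) == pid)
  }, trials)
}
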