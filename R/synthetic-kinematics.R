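#' SyntheticConfig: parameters of the kinematic trial generator
#'
#' Describes the study conditions emulated by [generateKinematicDataset()]:
#' the measurement protocol (participants, conditions, trials per task,
#' 60 Hz sampling), per-condition task durations, smooth per-joint reach
#' profiles, trial-to-trial noise sources, the coordination mode, and
#' gimbal-lock-like spike artifacts. See [syntheticConfig()] for defaults.
#'
#' @slot n_participants number of participants.
#' @slot conditions condition labels (subset of `MHP`, `SHP`).
#' @slot trials_per_task named integer vector (`RCRT_up`, `RCRT_down`, `TRAY`).
#' @slot sample_rate_hz sampling rate in Hz.
#' @slot task_duration_s data.frame (`task`, `condition`, `mean_s`, `sd_s`)
#'   of movement durations; the SD is the between-participant scatter, shared
#'   across conditions within a participant to reflect the paired design.
#' @slot pad_s quiescent padding (s) before and after the movement.
#' @slot base_profiles data.frame (`joint`, `baseline_deg`, `amplitude_deg`,
#'   `rise_s`) of reach-hold-return angle profiles.
#' @slot amp_noise_sd relative trial-to-trial amplitude scatter.
#' @slot time_warp_sd relative trial-to-trial duration scatter.
#' @slot additive_noise_sd degrees; marginal SD of smooth additive noise.
#' @slot noise_cutoff_hz low-pass cutoff of the additive noise (Hz).
#' @slot coordination_mode `"JC_SIM"` or `"JC_DIFF"`.
#' @slot artifact_prob per-trial probability of an injected spike.
#' @slot spike_magnitude_deg spike excursion in degrees.
#' @slot spike_width_samples spike width (1 = single sample, gimbal-lock-like).
#' @slot seed master RNG seed; participants use derived substreams.
#' @export
setClass("SyntheticConfig",
  representation(
    n_participants = "integer",
    conditions = "character",
    trials_per_task = "integer",
    sample_rate_hz = "numeric",
    task_duration_s = "data.frame",
    pad_s = "numeric",
    base_profiles = "data.frame",
    amp_noise_sd = "numeric",
    time_warp_sd = "numeric",
    additive_noise_sd = "numeric",
    noise_cutoff_hz = "numeric",
    coordination_mode = "character",
    artifact_prob = "numeric",
    spike_magnitude_deg = "numeric",
    spike_width_samples = "integer",
    seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msgs <- character()
  chk <- function(cond, msg) if (!cond) msgs <<- c(msgs, msg)
  chk(length(object@n_participants) == 1L && object@n_participants >= 1L,
      "n_participants: must be >= 1")
  chk(length(object@conditions) >= 1L &&
        all(object@conditions %in% ULP_CONDITIONS),
      "conditions: must be a non-empty subset of {MHP, SHP}")
  chk(setequal(names(object@trials_per_task), ULP_TASKS) &&
        all(object@trials_per_task >= 1L),
      "trials_per_task: must name all tasks with counts >= 1")
  chk(object@sample_rate_hz > 0, "sample_rate_hz: must be positive")
  chk(all(c("task", "condition", "mean_s", "sd_s") %in%
            names(object@task_duration_s)) &&
        all(object@task_duration_s$mean_s > 0) &&
        all(object@task_duration_s$sd_s >= 0),
      "task_duration_s: needs task/condition/mean_s/sd_s with mean_s > 0, sd_s >= 0")
  chk(object@pad_s >= 0, "pad_s: must be >= 0")
  chk(setequal(object@base_profiles$joint, ULP_JOINTS) &&
        all(c("baseline_deg", "amplitude_deg", "rise_s") %in%
              names(object@base_profiles)) &&
        all(object@base_profiles$rise_s > 0),
      "base_profiles: must cover the 7 joints with baseline/amplitude/rise_s")
  chk(object@amp_noise_sd >= 0, "amp_noise_sd: must be >= 0")
  chk(object@time_warp_sd >= 0, "time_warp_sd: must be >= 0")
  chk(object@additive_noise_sd >= 0, "additive_noise_sd: must be >= 0")
  chk(object@noise_cutoff_hz > 0, "noise_cutoff_hz: must be positive")
  chk(object@coordination_mode %in% c("JC_SIM", "JC_DIFF"),
      "coordination_mode: must be JC_SIM or JC_DIFF")
  chk(object@artifact_prob >= 0 && object@artifact_prob <= 1,
      "artifact_prob: must lie in [0, 1]")
  chk(object@spike_magnitude_deg >= 0, "spike_magnitude_deg: must be >= 0")
  chk(object@spike_width_samples >= 1L, "spike_width_samples: must be >= 1")
  if (length(msgs)) msgs else TRUE
})

## Default movement durations: per-condition completion-time summaries of the
## three tasks in the reference protocol (seconds).
defaultTaskDurations <- function() {
  data.frame(
    task = rep(ULP_TASKS, each = 2L),
    condition = rep(c("MHP", "SHP"), times = 3L),
    mean_s = c(23.8, 16.3, 22.4, 17.7, 15.6, 14.5),
    sd_s = c(6.8, 5.6, 8.8, 7.9, 3.8, 4.8),
    stringsAsFactors = FALSE
  )
}

## Default reach-hold-return profiles. Amplitudes are signed excursions from
## baseline; shoulder rotation is negative (external) and abduction positive
## in the reference coordination pattern.
defaultBaseProfiles <- function() {
  data.frame(
    joint = ULP_JOINTS,
    baseline_deg = c(5, 0, 0, 10, -5, 10, 70),
    amplitude_deg = c(10, 8, 6, 40, -15, 20, 30),
    rise_s = rep(1.0, 7L),
    stringsAsFactors = FALSE
  )
}

#' Create a synthetic-data generator configuration
#'
#' Defaults reproduce the reference protocol: 14 participants, both
#' conditions, 5 + 5 + 10 trials for the clothespin-relocation (up/down) and
#' tray tasks, 60 Hz sampling, and per-condition task durations matching the
#' study's completion times. Noise defaults (10% amplitude scatter, 10%
#' duration scatter, 0.5 deg smooth additive noise low-passed at 6 Hz, 5%
#' spike probability) are documented in the methods vignette.
#'
#' @param n_participants,conditions,trials_per_task,sample_rate_hz,task_duration_s,pad_s,base_profiles,amp_noise_sd,time_warp_sd,additive_noise_sd,noise_cutoff_hz,coordination_mode,artifact_prob,spike_magnitude_deg,spike_width_samples,seed
#'   see [SyntheticConfig-class].
#' @return A validated [SyntheticConfig-class] object; invalid settings raise
#'   a configuration error naming the offending field.
#' @examples
#' cfg <- syntheticConfig(n_participants = 2, seed = 1)
#' cfg
#' @export
syntheticConfig <- function(n_participants = 14,
                            conditions = c("MHP", "SHP"),
                            trials_per_task = c(RCRT_up = 5L, RCRT_down = 5L,
                                                TRAY = 10L),
                            sample_rate_hz = 60,
                            task_duration_s = defaultTaskDurations(),
                            pad_s = 1.0,
                            base_profiles = defaultBaseProfiles(),
                            amp_noise_sd = 0.1,
                            time_warp_sd = 0.1,
                            additive_noise_sd = 0.5,
                            noise_cutoff_hz = 6,
                            coordination_mode = c("JC_SIM", "JC_DIFF"),
                            artifact_prob = 0.05,
                            spike_magnitude_deg = 90,
                            spike_width_samples = 1L,
                            seed = 1L) {
  coordination_mode <- match.arg(coordination_mode)
  tp <- as.integer(round(trials_per_task))
  names(tp) <- names(trials_per_task)
  new("SyntheticConfig",
      n_participants = as.integer(n_participants),
      conditions = conditions,
      trials_per_task = tp,
      sample_rate_hz = as.numeric(sample_rate_hz),
      task_duration_s = task_duration_s,
      pad_s = as.numeric(pad_s),
      base_profiles = base_profiles,
      amp_noise_sd = as.numeric(amp_noise_sd),
      time_warp_sd = as.numeric(time_warp_sd),
      additive_noise_sd = as.numeric(additive_noise_sd),
      noise_cutoff_hz = as.numeric(noise_cutoff_hz),
      coordination_mode = coordination_mode,
      artifact_prob = as.numeric(artifact_prob),
      spike_magnitude_deg = as.numeric(spike_magnitude_deg),
      spike_width_samples = as.integer(spike_width_samples),
      seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d participants x {%s} x trials (%s), %g Hz\n",
    object@n_participants, paste(object@conditions, collapse = ", "),
    paste(sprintf("%s: %d", names(object@trials_per_task),
                  object@trials_per_task), collapse = ", "),
    object@sample_rate_hz))
  cat(sprintf(
    "  noise: amp %.3g, warp %.3g, additive %.3g deg (<%g Hz); spikes p = %.3g (%g deg)\n",
    object@amp_noise_sd, object@time_warp_sd, object@additive_noise_sd,
    object@noise_cutoff_hz, object@artifact_prob, object@spike_magnitude_deg))
  cat(sprintf("  coordination: %s, seed %d\n",
              object@coordination_mode, object@seed))
  invisible(object)
})

## Reach-hold-return unit profile: raised-cosine rise over `rise`, plateau,
## mirrored return; 0 outside [0, dur].
plateauProfile <- function(t, dur, rise) {
  rise <- min(rise, dur / 2)
  y <- numeric(length(t))
  up <- t >= 0 & t < rise
  hold <- t >= rise & t <= dur - rise
  down <- t > dur - rise & t <= dur
  y[up] <- 0.5 * (1 - cos(pi * t[up] / rise))
  y[hold] <- 1
  y[down] <- 0.5 * (1 - cos(pi * (dur - t[down]) / rise))
  y
}

## Variance gain of the zero-phase low-pass used for additive noise; cached
## per (rate, cutoff) so every trial pays only the filtering cost.
.noiseGainCache <- new.env(parent = emptyenv())

smoothNoiseGain <- function(fs, cutoff) {
  key <- sprintf("%.6g_%.6g", fs, cutoff)
  if (!is.null(.noiseGainCache[[key]])) return(.noiseGainCache[[key]])
  bf <- signal::butter(2, cutoff / (fs / 2))
  imp <- c(rep(0, 512), 1, rep(0, 512))
  h <- signal::filtfilt(bf, imp)
  g <- sqrt(sum(h^2))
  .noiseGainCache[[key]] <- g
  g
}

## Smooth additive noise with marginal SD `sd`: low-pass filtered white noise
## rescaled by the filter's stationary gain; edge transients trimmed.
smoothNoise <- function(n, fs, cutoff, sd) {
  if (sd == 0 || n == 0L) return(numeric(n))
  if (cutoff >= fs / 2) return(rnorm(n, 0, sd))
  pad <- 120L
  w <- rnorm(n + 2L * pad)
  bf <- signal::butter(2, cutoff / (fs / 2))
  y <- signal::filtfilt(bf, w)[(pad + 1L):(pad + n)]
  y * (sd / smoothNoiseGain(fs, cutoff))
}

## Deterministic per-participant substream seed: adding participants never
## perturbs earlier ones.
participantSeed <- function(master, p) {
  as.integer((as.numeric(master) + as.numeric(p) * 7919) %% 2147483647)
}

#' Generate a synthetic kinematic dataset
#'
#' Simulates every trial of the measurement protocol for each participant,
#' condition and task: smooth reach-hold-return joint-angle waveforms
#' bracketed by quiescent padding, with trial-to-trial amplitude and duration
#' scatter, smooth additive noise, and occasional single-sample spike
#' artifacts. In `JC_DIFF` mode the signs of the shoulder internal/external
#' rotation and abduction/adduction excursions are flipped in the MHP
#' condition only, emulating participants who switch coordination strategy
#' between hands. Output is deterministic in the seed, and each trial's
#' `meta` slot records the ground-truth movement bounds and any injected
#' spike.
#'
#' @param config a [SyntheticConfig-class].
#' @return A list of [JointAngleTrial-class] objects.
#' @examples
#' cfg <- syntheticConfig(n_participants = 1, trials_per_task = c(
#'   RCRT_up = 2L, RCRT_down = 2L, TRAY = 2L), seed = 7)
#' trials <- generateKinematicDataset(cfg)
#' length(trials)  # 1 participant x 2 conditions x 6 trials
#' @export
generateKinematicDataset <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  fs <- config@sample_rate_hz
  prof <- config@base_profiles
  rownames(prof) <- prof$joint
  flip_joints <- c("shoulder_internal_external_rotation",
                   "shoulder_abduction_adduction")
  out <- vector("list", 0L)
  for (p in seq_len(config@n_participants)) {
    pid <- sprintf("P%02d", p)
    set.seed(participantSeed(config@seed, p))
    ## Participant-level duration offsets, shared across conditions (paired
    ## design: fast participants are fast with either hand).
    dur_u <- stats::setNames(rnorm(length(ULP_TASKS)), ULP_TASKS)
    for (cond in config@conditions) {
      for (tk in ULP_TASKS) {
        dd <- config@task_duration_s
        row <- dd[dd$task == tk & dd$condition == cond, , drop = FALSE]
        if (nrow(row) != 1L)
          stop(sprintf("task_duration_s: no unique entry for %s/%s", tk, cond))
        dur_p <- max(row$mean_s + dur_u[[tk]] * row$sd_s, row$mean_s * 0.25)
        for (tr in seq_len(config@trials_per_task[[tk]])) {
          d <- dur_p * max(1 + rnorm(1, 0, config@time_warp_sd), 0.25)
          n <- as.integer(round((d + 2 * config@pad_s) * fs))
          tgrid <- (seq_len(n) - 1L) / fs
          ang <- matrix(0, n, length(ULP_JOINTS),
                        dimnames = list(NULL, ULP_JOINTS))
          shape <- plateauProfile(tgrid - config@pad_s, d,
                                  min(prof$rise_s[1], d / 4))
          for (j in ULP_JOINTS) {
            amp <- prof[j, "amplitude_deg"]
            if (config@coordination_mode == "JC_DIFF" && cond == "MHP" &&
                j %in% flip_joints)
              amp <- -amp
            amp <- amp * (1 + rnorm(1, 0, config@amp_noise_sd))
            sh <- if (prof[j, "rise_s"] == prof$rise_s[1]) shape else
              plateauProfile(tgrid - config@pad_s, d,
                             min(prof[j, "rise_s"], d / 4))
            ang[, j] <- prof[j, "baseline_deg"] + amp * sh +
              smoothNoise(n, fs, config@noise_cutoff_hz,
                          config@additive_noise_sd)
          }
          spike <- NULL
          if (config@artifact_prob > 0 &&
              stats::runif(1) < config@artifact_prob) {
            sj <- ULP_JOINTS[sample.int(length(ULP_JOINTS), 1L)]
            lo <- as.integer(round(config@pad_s * fs)) + 1L
            hi <- max(lo, n - as.integer(round(config@pad_s * fs)))
            si <- lo + sample.int(max(hi - lo, 1L), 1L) - 1L
            w <- min(config@spike_width_samples, n - si + 1L)
            sgn <- sample(c(-1, 1), 1L)
            ang[si:(si + w - 1L), sj] <-
              ang[si:(si + w - 1L), sj] + sgn * config@spike_magnitude_deg
            spike <- list(joint = sj, index = si, width = w,
                          magnitude_deg = sgn * config@spike_magnitude_deg)
          }
          out[[length(out) + 1L]] <- jointAngleTrial(
            pid, cond, tk, tr, fs, ang,
            measured_completion_time_s = d,
            meta = list(
              gt_start_index = as.integer(round(config@pad_s * fs)) + 1L,
              gt_end_index = as.integer(round((config@pad_s + d) * fs)),
              gt_duration_s = d,
              coordination_mode = config@coordination_mode,
              spike = spike))
        }
      }
    }
  }
  out
}
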