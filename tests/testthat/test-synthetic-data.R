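test_that("generator produces the protocol's trial structure", {
  cfg <- syntheticConfig(n_participants = 2, seed = 1)
  expect_equal(unname(cfg@trials_per_task[taskNames()]), c(5L, 5L, 10L))
  trials <- generateKinematicDataset(quickConfig(
    n_participants = 2, trials = c(RCRT_up = 2L, RCRT_down = 2L, TRAY = 3L),
    dur_mean = 4, seed = 1))
  expect_length(trials, 2 * 2 * 7)
  t1 <- trials[[1]]
  expect_s4_class(t1, "JointAngleTrial")
  expect_identical(colnames(angles(t1)), jointNames())
  counts <- table(vapply(trials, function(t)
    paste(participantId(t), condition(t), task(t)), character(1)))
  expect_true(all(counts[grepl("TRAY", names(counts))] == 3))
  expect_true(all(counts[grepl("RCRT", names(counts))] == 2))
})

test_that("generator configuration errors name the offending field", {
  expect_error(quickConfig(n_participants = 0, seed = 1), "n_participants")
  expect_error(quickConfig(artifact_prob = 1.5, seed = 1), "artifact_prob")
  expect_error(quickConfig(additive_noise_sd = -1, seed = 1),
               "additive_noise_sd")
  expect_error(syntheticConfig(trials_per_task = c(RCRT_up = 5L), seed = 1),
               "trials_per_task")
  expect_error(quickConfig(coordination_mode = "JC_MAYBE", seed = 1))
})

test_that("zero noise makes trials of a participant-task identical", {
  cfg <- quickConfig(trials = c(RCRT_up = 3L, RCRT_down = 1L, TRAY = 1L),
                     amp_noise_sd = 0, time_warp_sd = 0,
                     additive_noise_sd = 0, artifact_prob = 0, seed = 2)
  tr <- pickTrials(generateKinematicDataset(cfg), cond = "MHP",
                   tk = "RCRT_up")
  expect_length(tr, 3L)
  expect_identical(angles(tr[[1]]), angles(tr[[2]]))
  expect_identical(angles(tr[[1]]), angles(tr[[3]]))
})

test_that("the dataset is deterministic in the seed", {
  cfg <- quickConfig(trials = c(RCRT_up = 2L, RCRT_down = 1L, TRAY = 1L),
                     seed = 7)
  a <- generateKinematicDataset(cfg)
  b <- generateKinematicDataset(cfg)
  expect_identical(lapply(a, angles), lapply(b, angles))
  cfg2 <- quickConfig(trials = c(RCRT_up = 2L, RCRT_down = 1L, TRAY = 1L),
                      seed = 8)
  c <- generateKinematicDataset(cfg2)
  expect_false(identical(angles(a[[1]]), angles(c[[1]])))
})

test_that("adding participants does not perturb earlier ones", {
  trials2 <- generateKinematicDataset(quickConfig(
    n_participants = 2, trials = c(RCRT_up = 1L, RCRT_down = 1L, TRAY = 1L),
    seed = 3))
  trials3 <- generateKinematicDataset(quickConfig(
    n_participants = 3, trials = c(RCRT_up = 1L, RCRT_down = 1L, TRAY = 1L),
    seed = 3))
  a2 <- lapply(pickTrials(trials2, pid = "P02"), angles)
  a3 <- lapply(pickTrials(trials3, pid = "P02"), angles)
  expect_identical(a2, a3)
})

test_that("JC_DIFF flips shoulder rotation/abduction signs in MHP only", {
  for (mode in c("JC_SIM", "JC_DIFF")) {
    cfg <- quickConfig(trials = c(RCRT_up = 2L, RCRT_down = 1L, TRAY = 1L),
                       amp_noise_sd = 0, time_warp_sd = 0,
                       additive_noise_sd = 0, artifact_prob = 0,
                       coordination_mode = mode, seed = 4)
    tr <- generateKinematicDataset(cfg)
    exc <- function(cond, joint) {
      t1 <- pickTrials(tr, cond = cond, tk = "RCRT_up")[[1]]
      a <- angles(t1)[, joint]
      mean(a - a[1])
    }
    rot <- c(exc("MHP", "shoulder_internal_external_rotation"),
             exc("SHP", "shoulder_internal_external_rotation"))
    abd <- c(exc("MHP", "shoulder_abduction_adduction"),
             exc("SHP", "shoulder_abduction_adduction"))
    if (mode == "JC_SIM") {
      expect_identical(sign(rot[1]), sign(rot[2]))
      expect_identical(sign(abd[1]), sign(abd[2]))
    } else {
      expect_identical(sign(rot[1]), -sign(rot[2]))
      expect_identical(sign(abd[1]), -sign(abd[2]))
    }
  }
})

test_that("artifact injection produces single-sample spikes of set magnitude", {
  cfg <- quickConfig(trials = c(RCRT_up = 4L, RCRT_down = 1L, TRAY = 1L),
                     artifact_prob = 1, spike_magnitude_deg = 90, seed = 5)
  tr <- pickTrials(generateKinematicDataset(cfg), cond = "MHP",
                   tk = "RCRT_up")
  for (t1 in tr) {
    sp <- t1@meta$spike
    expect_false(is.null(sp))
    expect_equal(sp$width, 1L)
    expect_equal(abs(sp$magnitude_deg), 90)
    # the spike is visible as a step jump at the recorded joint/index
    steps <- abs(diff(angles(t1)[, sp$joint]))
    expect_gt(max(steps), 60)
  }
})

test_that("group scores follow the two-group specification", {
  spec <- groupScoreSpec(list(
    age = list(dist = "normal", mean = c(MHP = 48.6, SHP = 58.1),
               sd = c(MHP = 12.4, SHP = 15.7), range = c(18, 95))))
  gs <- generateGroupScores(spec, seed = 1)
  expect_equal(nrow(gs), 33L)
  expect_equal(unname(table(gs$group)[c("MHP", "SHP")]), c(14L, 19L),
               ignore_attr = TRUE)
  expect_true(all(gs$age >= 18 & gs$age <= 95))

  # SD = 0 collapses to the mean
  spec0 <- groupScoreSpec(list(
    x = list(dist = "normal", mean = c(A = 3, B = 5), sd = c(A = 0, B = 0))),
    n = c(A = 4L, B = 4L))
  gs0 <- generateGroupScores(spec0, seed = 2)
  expect_equal(gs0$x, rep(c(3, 5), each = 4))
})

test_that("empirical moments converge to the specification (LLN)", {
  spec <- groupScoreSpec(list(
    z = list(dist = "normal", mean = c(A = 0, B = 0), sd = c(A = 1, B = 1))),
    n = c(A = 10000L, B = 10000L))
  gs <- generateGroupScores(spec, seed = 3)
  expect_lt(abs(mean(gs$z)), 0.05)
  expect_lt(abs(sd(gs$z) - 1), 0.05)
})

test_that("ordinal measures and invalid specs are handled", {
  spec <- groupScoreSpec(list(
    sex = list(dist = "ordinal", levels = c("m", "f"),
               prob = list(A = c(0.5, 0.5), B = c(1, 0)))),
    n = c(A = 50L, B = 20L))
  gs <- generateGroupScores(spec, seed = 4)
  expect_true(all(gs$sex[gs$group == "B"] == "m"))
  expect_error(groupScoreSpec(list(
    x = list(dist = "cauchy", location = 0))), "unknown distribution")
  expect_error(groupScoreSpec(list(
    x = list(dist = "normal", mean = c(A = 1), sd = c(A = -1))),
    n = c(A = 3L)), "named per group|sd")
})
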