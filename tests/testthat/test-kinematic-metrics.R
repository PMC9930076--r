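seg <- function(s, e) structure(
  list(start_index = s, end_index = e, completion_time_s = (e - s) / 60,
       end_source = "detected"), class = "SegmentBounds")

test_that("RoM is max minus min of the raw segment", {
  t1 <- mkTrial(c(0, 12, 20, 5))
  expect_equal(unname(computeRom(t1, seg(1L, 4L))["elbow_flexion_extension"]),
               20)
  expect_equal(unname(computeRom(mkTrial(rep(3, 10)), seg(1L, 10L))[1]), 0)
})

test_that("RoM agrees with a brute-force oracle on random segments", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(50:200, 1)
    x <- cumsum(rnorm(n))
    s <- sample(1:(n - 10), 1); e <- sample((s + 5):n, 1)
    t1 <- mkTrial(x)
    oracle <- max(x[s:e]) - min(x[s:e])   # direct enumeration
    expect_equal(unname(computeRom(t1, seg(s, e))[1]), oracle)
  }
})

test_that("noiseless generated trials recover the configured amplitude", {
  cfg <- quickConfig(trials = c(RCRT_up = 1L, RCRT_down = 1L, TRAY = 1L),
                     amp_noise_sd = 0, time_warp_sd = 0,
                     additive_noise_sd = 0, artifact_prob = 0, seed = 12)
  t1 <- pickTrials(generateKinematicDataset(cfg), tk = "RCRT_up")[[1]]
  rom <- computeRom(t1, detectTrialBounds(t1))
  expect_equal(unname(rom["shoulder_flexion_extension"]), 40, tolerance = 0.5 / 40)
  expect_equal(unname(rom["elbow_flexion_extension"]), 30, tolerance = 0.5 / 30)
})

test_that("KV matches the hand-computed toy oracle", {
  # SDs per time point are (0, sqrt(2), 0) -> KV = sqrt(2)/3
  nt <- list(mkNormalized(c(0, 10, 20)), mkNormalized(c(0, 12, 20)))
  expect_equal(unname(computeKv(nt)[1]), sqrt(2) / 3, tolerance = 1e-12)
  expect_equal(round(unname(computeKv(nt)[1]), 4), 0.4714)
})

test_that("KV is zero for identical trials and shift-invariant", {
  a <- mkNormalized(sin(seq(0, 3, length.out = 40)))
  expect_equal(unname(computeKv(list(a, a))[1]), 0)
  b <- mkNormalized(sin(seq(0, 3, length.out = 40)) + 0.3)
  kv1 <- computeKv(list(a, b))
  kv2 <- computeKv(list(a + 7, b + 7))
  expect_equal(kv1, kv2)
})

test_that("KV and KR demand at least two trials", {
  a <- mkNormalized(1:10)
  expect_error(computeKv(list(a)), "insufficient trials")
  expect_error(computeKr(list(a)), "insufficient trials")
})

test_that("KR matches the hand-evaluated formula on the toy instance", {
  nt <- list(mkNormalized(c(0, 10, 20)), mkNormalized(c(0, 12, 20)))
  # within mean square: ((0)^2*2 + 1 + 1 + 0 + 0)/(3*(2-1)) = 2/3
  # total mean square: sum((y - 62/6)^2) / (3*2 - 1)
  y <- c(0, 10, 20, 0, 12, 20)
  oracle <- 1 - (2 / 3) / (sum((y - mean(y))^2) / 5)
  kr <- unname(computeKr(nt)[1])
  expect_equal(kr, oracle, tolerance = 1e-12)
  expect_equal(round(kr, 4), 0.9917)
})

test_that("KR is exactly 1 for identical non-constant trials", {
  a <- mkNormalized(c(1, 5, 2, 8))
  expect_equal(unname(computeKr(list(a, a, a))[1]), 1)
})

test_that("KR of pure independent noise is near zero under the null", {
  set.seed(31)
  nt <- replicate(40, mkNormalized(rnorm(200)), simplify = FALSE)
  expect_lt(abs(unname(computeKr(nt)[1])), 0.05)
})

test_that("KR warns and returns NA on degenerate constant waveforms", {
  a <- mkNormalized(rep(2, 10))
  expect_warning(kr <- computeKr(list(a, a)), "degenerate waveform")
  expect_true(all(is.na(kr)))
})

test_that("KV and KR are invariant under common affine maps", {
  set.seed(32)
  base <- sin(seq(0, 4, length.out = 60))
  nt <- replicate(5, mkNormalized(base + rnorm(60, 0, 0.3)),
                  simplify = FALSE)
  kv0 <- computeKv(nt); kr0 <- computeKr(nt)
  a <- -2.5; b <- 13
  nt2 <- lapply(nt, function(m) a * m + b)
  expect_equal(computeKv(nt2), abs(a) * kv0, tolerance = 1e-10)
  expect_equal(computeKr(nt2), kr0, tolerance = 1e-10)
})

test_that("KR decreases monotonically with additive noise (Monte Carlo)", {
  set.seed(33)
  base <- 20 * sin(seq(0, pi, length.out = 150))
  krs <- vapply(c(0.5, 1, 2, 4, 8), function(s) {
    nt <- replicate(12, mkNormalized(base + rnorm(150, 0, s)),
                    simplify = FALSE)
    unname(computeKr(nt)[1])
  }, numeric(1))
  expect_true(all(diff(krs) < 0))
})

test_that("KV recovers the generator's additive noise SD", {
  for (sig in c(0.5, 2)) {
    cfg <- quickConfig(trials = c(RCRT_up = 50L, RCRT_down = 1L, TRAY = 1L),
                       conditions = "MHP", amp_noise_sd = 0, time_warp_sd = 0,
                       additive_noise_sd = sig, artifact_prob = 0,
                       seed = round(100 * sig))
    tr <- pickTrials(generateKinematicDataset(cfg), tk = "RCRT_up")
    nm <- lapply(tr, function(t) timeNormalize(t, ulpkin:::groundTruthBounds(t)))
    kv <- computeKv(nm)
    expect_true(all(abs(kv / sig - 1) < 0.1))
  }
})
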