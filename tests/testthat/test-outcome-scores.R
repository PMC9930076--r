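tariffPath <- function() system.file("extdata", "eq5d5l_tariff_synthetic.csv",
                                     package = "ulpkin")
weightsPath <- function() system.file("extdata",
                                      "puf_ulp_weights_synthetic.csv",
                                      package = "ulpkin")

test_that("OPUS-UEFS sums span 0-57 and match an oracle sum", {
  expect_equal(scoreOpusUefs(rep(0, 19))$score, 0)
  expect_equal(scoreOpusUefs(rep(3, 19))$score, 57)
  set.seed(51)
  items <- sample(0:3, 19, replace = TRUE)
  rec <- scoreOpusUefs(items, "P01")
  expect_equal(rec$score, sum(items))
  expect_false(rec$out_of_range)
  expect_error(scoreOpusUefs(c(rep(1, 18), NA)), "missing")
  expect_error(scoreOpusUefs(rep(1, 18)), "19 item")
  expect_error(scoreOpusUefs(c(rep(1, 18), 7)), "range")
})

test_that("TAPES-upper subscale sums hit the documented endpoints", {
  lo <- scoreTapes(rep(1, 23))
  expect_equal(lo$score, c(9, 3, 4, 5, 2))
  hi <- scoreTapes(rep(5, 23))
  expect_equal(hi$score, c(45, 15, 20, 25, 10))
  expect_equal(lo$range_min, c(9, 3, 4, 5, 2))
  expect_equal(hi$range_max, c(45, 15, 20, 25, 10))
  set.seed(52)
  items <- sample(1:5, 23, replace = TRUE)
  recs <- scoreTapes(items)
  expect_equal(recs$score[recs$subscale == "prosthesis_satisfaction"],
               sum(items[1:9]))
  expect_equal(recs$score[recs$subscale == "optimal_adjustment"],
               sum(items[22:23]))
  # named-list input is equivalent
  as_list <- list(prosthesis_satisfaction = items[1:9],
                  general_adjustment = items[10:12],
                  social_adjustment = items[13:16],
                  adjustment_to_limitation = items[17:21],
                  optimal_adjustment = items[22:23])
  expect_equal(scoreTapes(as_list)$score, recs$score)
})

test_that("scores are invariant to item order within a subscale", {
  set.seed(53)
  items <- sample(1:5, 23, replace = TRUE)
  shuffled <- items
  shuffled[1:9] <- sample(items[1:9])      # permute within satisfaction
  expect_equal(scoreTapes(items)$score, scoreTapes(shuffled)$score)
  d <- sample(1:5, 12, replace = TRUE)
  d2 <- c(sample(d[1:8]), sample(d[9:12]))
  expect_equal(scoreDquest(d)$score, scoreDquest(d2)$score)
})

test_that("RAND-36 subscales are min-max transformed onto 0-100", {
  key <- readRand36Key()
  # responses at the recoded minimum of every item
  worst <- ifelse(key$reverse, key$n_levels, 1)
  names(worst) <- key$item
  expect_equal(scoreRand36(worst, key)$score, rep(0, 9))
  best <- ifelse(key$reverse, 1, key$n_levels)
  names(best) <- key$item
  expect_equal(scoreRand36(best, key)$score, rep(100, 9))

  # the transform is affine: independent oracle on random responses
  set.seed(54)
  v <- vapply(key$n_levels, function(k) sample.int(k, 1), integer(1))
  names(v) <- key$item
  recs <- scoreRand36(v, key)
  rec <- ifelse(key$reverse, key$n_levels + 1 - v, v)
  for (i in seq_len(nrow(recs))) {
    sel <- key$subscale == recs$subscale[i]
    oracle <- 100 * (sum(rec[sel]) - sum(sel)) /
      (sum(key$n_levels[sel]) - sum(sel))
    expect_equal(recs$score[i], oracle)
  }
  expect_true(all(recs$score >= 0 & recs$score <= 100))
  expect_error(scoreRand36(v[-1], key), "match the scoring key")
})

test_that("EQ-5D-5L valuation follows the tariff", {
  tariff <- readEq5dTariff(tariffPath())
  full <- scoreEq5d5l(c(1, 1, 1, 1, 1), tariff)
  expect_equal(full$score[full$subscale == "utility"], 1.0)

  # hand-computed decrement sum for a mixed profile
  prof <- c(2, 1, 3, 5, 4)
  rec <- scoreEq5d5l(prof, tariff, vas = 75)
  expect_equal(rec$score[rec$subscale == "utility"],
               1.0 - (0.05 + 0.07 + 0.35 + 0.22))
  expect_equal(rec$score[rec$subscale == "vas"], 75)

  # all-zero decrements value every profile at full health
  zero <- tariff
  zero$decrements$decrement <- 0
  expect_equal(scoreEq5d5l(c(5, 5, 5, 5, 5), zero)$score[1], 1.0)

  expect_error(scoreEq5d5l(c(1, 1, 1, 1, 1), NULL), "tariff required")
  expect_error(scoreEq5d5l(c(1, 1, 1, 6, 1), tariff), "1..5")
  expect_error(scoreEq5d5l(c(1, 1, 1, 1, 1), tariff, vas = 120), "0..100")
})

test_that("PUF-ULP endpoints follow the weight table plus 12", {
  w <- readPufUlpWeights(weightsPath())
  worst <- scorePufUlp(rep(4L, 9), w)
  expect_equal(worst$score, 0)
  best <- scorePufUlp(rep(1L, 9), w)
  expect_equal(best$score, 12.1)
  expect_equal(c(worst$range_min[1], worst$range_max[1]), c(0, 12.1))

  # merged worst levels: level 4 falls back to the level-3 weight
  merged <- scorePufUlp(c(1, 1, 1, 1, 4, 1, 1, 1, 3), w)
  expect_equal(merged$score, 12 + 0.1 - 1.1 - 1.1)

  zeros <- w; zeros$weight <- 0
  expect_equal(scorePufUlp(rep(2L, 9), zeros)$score, 12)
  expect_error(scorePufUlp(rep(1L, 9), NULL), "weight table required")
  expect_error(scorePufUlp(rep(5L, 9), w), "1..4")
})

test_that("D-QUEST means land in 1-5 and match oracle means", {
  expect_equal(scoreDquest(rep(5, 12))$score, c(5, 5, 5))
  expect_equal(scoreDquest(rep(1, 12))$score, c(1, 1, 1))
  set.seed(55)
  r <- sample(1:5, 12, replace = TRUE)
  recs <- scoreDquest(r)
  expect_equal(recs$score, c(mean(r[1:8]), mean(r[9:12]), mean(r)))
  expect_error(scoreDquest(c(rep(3, 11), 6)), "range")
  expect_error(scoreDquest(rep(3, 11)), "12 item")
})
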