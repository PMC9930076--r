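## One ScoreRecord row; out_of_range flags scores outside the declared range.
scoreRecord <- function(participant_id, instrument, subscale, score,
                        range) {
  data.frame(
    participant_id = as.character(participant_id),
    instrument = instrument,
    subscale = subscale,
    score = as.numeric(score),
    range_min = range[1], range_max = range[2],
    out_of_range = score < range[1] | score > range[2],
    stringsAsFactors = FALSE)
}

checkItems <- function(items, n, lo, hi, instrument) {
  items <- as.numeric(items)
  if (length(items) != n)
    stop(sprintf("%s requires exactly %d item responses (got %d)",
                 instrument, n, length(items)))
  if (anyNA(items))
    stop(sprintf("%s: missing responses at item(s) %s; no imputation is applied",
                 instrument, paste(which(is.na(items)), collapse = ", ")))
  if (any(items < lo | items > hi))
    stop(sprintf("%s: responses outside the %g..%g item range at item(s) %s",
                 instrument, lo, hi,
                 paste(which(items < lo | items > hi), collapse = ", ")))
  items
}

#' Score the OPUS-UEFS (ease of ADL execution)
#'
#' Sum of the 19 upper-extremity functional status items (each 0-3); total
#' range 0-57, higher = easier execution of activities of daily living.
#'
#' @param items numeric vector of 19 responses in 0..3.
#' @param participant_id optional identifier.
#' @return A one-row ScoreRecord data.frame.
#' @export
scoreOpusUefs <- function(items, participant_id = NA_character_) {
  items <- checkItems(items, 19L, 0, 3, "OPUS-UEFS")
  scoreRecord(participant_id, "OPUS-UEFS", "total", sum(items), c(0, 57))
}

## TAPES-upper subscale structure: item counts, all items rated 1-5.
TAPES_SUBSCALES <- list(
  prosthesis_satisfaction = 9L,
  general_adjustment = 3L,
  social_adjustment = 4L,
  adjustment_to_limitation = 5L,
  optimal_adjustment = 2L
)

#' Score the TAPES-upper subscales
#'
#' Subscale sums of the prosthesis-satisfaction (9 items, range 9-45) and
#' four psychosocial subscales: general adjustment (3 items, 3-15), social
#' adjustment (4 items, 4-20), adjustment to limitation (5 items, 5-25) and
#' optimal adjustment (2 items, 2-10). All items are rated 1-5; higher =
#' better adjustment/satisfaction.
#'
#' @param items numeric vector of 23 responses in 1..5, ordered by subscale
#'   (satisfaction, general, social, limitation, optimal), or a named list
#'   with one numeric vector per subscale.
#' @param participant_id optional identifier.
#' @return A five-row ScoreRecord data.frame.
#' @export
scoreTapes <- function(items, participant_id = NA_character_) {
  ns <- unlist(TAPES_SUBSCALES)
  if (is.list(items)) {
    if (!setequal(names(items), names(ns)))
      stop(sprintf("TAPES-upper: expected subscales %s",
                   paste(names(ns), collapse = ", ")))
    items <- unlist(items[names(ns)], use.names = FALSE)
  }
  items <- checkItems(items, sum(ns), 1, 5, "TAPES-upper")
  splits <- rep(names(ns), ns)
  out <- lapply(names(ns), function(sc) {
    v <- items[splits == sc]
    scoreRecord(participant_id, "TAPES-upper", sc, sum(v),
                c(ns[[sc]] * 1, ns[[sc]] * 5))
  })
  do.call(rbind, out)
}

#' Read a RAND-36 scoring key
#'
#' The key (shipped as an editable CSV, `rand36_scoring_key.csv` under the
#' package's `extdata`) declares, per item, the subscale it belongs to, its
#' number of response levels, and whether it is reverse-coded.
#'
#' @param path CSV path; default is the shipped key.
#' @return data.frame with columns `item`, `subscale`, `n_levels`, `reverse`.
#' @export
readRand36Key <- function(path = system.file("extdata",
                                             "rand36_scoring_key.csv",
                                             package = "ulpkin")) {
  key <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("item", "subscale", "n_levels", "reverse")
  if (!all(req %in% names(key)))
    stop(sprintf("RAND-36 key must have columns: %s",
                 paste(req, collapse = ", ")))
  key$reverse <- as.logical(key$reverse)
  key
}

#' Score the RAND-36 subscales on a 0-100 scale
#'
#' Items are recoded per the scoring key (reverse-coded items flipped within
#' their response range), summed per subscale, and min-max transformed:
#' `100 * (raw - min) / (max - min)`, so each subscale lies in 0-100 with
#' higher = better health.
#'
#' @param items named numeric vector of raw responses; names must match the
#'   key's `item` column, values in `1..n_levels` per item.
#' @param key scoring key, see [readRand36Key()].
#' @param participant_id optional identifier.
#' @return One ScoreRecord row per subscale in the key.
#' @export
scoreRand36 <- function(items, key = readRand36Key(),
                        participant_id = NA_character_) {
  if (is.null(names(items)) || !setequal(names(items), key$item))
    stop("RAND-36: item names must match the scoring key exactly")
  if (anyNA(items))
    stop(sprintf("RAND-36: missing responses for %s; no imputation is applied",
                 paste(names(items)[is.na(items)], collapse = ", ")))
  v <- items[key$item]
  if (any(v < 1 | v > key$n_levels))
    stop(sprintf("RAND-36: responses out of range for %s",
                 paste(key$item[v < 1 | v > key$n_levels], collapse = ", ")))
  rec <- ifelse(key$reverse, key$n_levels + 1 - v, v)
  out <- lapply(unique(key$subscale), function(sc) {
    sel <- key$subscale == sc
    raw <- sum(rec[sel])
    lo <- sum(sel)                # every item's minimum recoded value is 1
    hi <- sum(key$n_levels[sel])
    scoreRecord(participant_id, "RAND-36", sc,
                100 * (raw - lo) / (hi - lo), c(0, 100))
  })
  do.call(rbind, out)
}

EQ5D_DIMENSIONS <- c("mobility", "self_care", "usual_activities",
                     "pain_discomfort", "anxiety_depression")

#' Read an EQ-5D-5L tariff table
#'
#' A tariff CSV has columns `dimension`, `level`, `decrement`: one row per
#' dimension x level 2..5 utility decrement (level 1 implies no decrement)
#' plus a `full_health` row whose `decrement` column holds the full-health
#' utility (1.0 for the Dutch value set). National tariff coefficients are
#' licensed externally and must be supplied by the user; the package ships
#' only a synthetic example table for testing
#' (`eq5d5l_tariff_synthetic.csv`).
#'
#' @param path CSV path.
#' @return List with `full_health` (numeric) and `decrements` (data.frame).
#' @export
readEq5dTariff <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("dimension", "level", "decrement")
  if (!all(req %in% names(tab)))
    stop(sprintf("tariff must have columns: %s", paste(req, collapse = ", ")))
  fh <- tab$decrement[tab$dimension == "full_health"]
  if (length(fh) != 1L)
    stop("tariff required: table must contain one full_health row")
  dec <- tab[tab$dimension != "full_health", , drop = FALSE]
  if (!all(dec$dimension %in% EQ5D_DIMENSIONS))
    stop(sprintf("tariff dimensions must be among: %s",
                 paste(EQ5D_DIMENSIONS, collapse = ", ")))
  list(full_health = fh, decrements = dec)
}

#' Score the EQ-5D-5L health profile and VAS
#'
#' The five-dimension profile (levels 1..5 for mobility, self-care, usual
#' activities, pain/discomfort, anxiety/depression) is valued with a national
#' tariff: utility = full-health value minus the tariff decrements of the
#' reported levels. The 0-100 VAS rating is passed through unchanged.
#'
#' @param profile named (or ordered) integer vector of 5 levels in 1..5.
#' @param tariff a tariff from [readEq5dTariff()]; required, since tariff
#'   coefficients are external.
#' @param vas optional 0-100 perceived-health rating.
#' @param participant_id optional identifier.
#' @return ScoreRecord rows for `utility` (and `vas` when supplied).
#' @export
scoreEq5d5l <- function(profile, tariff, vas = NA_real_,
                        participant_id = NA_character_) {
  if (missing(tariff) || is.null(tariff))
    stop("tariff required: supply a value set via readEq5dTariff()")
  profile <- as.integer(profile)
  if (length(profile) != 5L || anyNA(profile) ||
      any(profile < 1L | profile > 5L))
    stop("EQ-5D-5L profile must be 5 levels, each in 1..5")
  dec <- tariff$decrements
  total_dec <- 0
  for (i in seq_along(EQ5D_DIMENSIONS)) {
    if (profile[i] == 1L) next
    row <- dec[dec$dimension == EQ5D_DIMENSIONS[i] &
                 dec$level == profile[i], "decrement"]
    if (length(row) != 1L)
      stop(sprintf("tariff has no entry for %s level %d",
                   EQ5D_DIMENSIONS[i], profile[i]))
    total_dec <- total_dec + row
  }
  worst <- sum(vapply(EQ5D_DIMENSIONS, function(d) {
    v <- dec[dec$dimension == d, "decrement"]
    if (length(v)) max(v) else 0
  }, numeric(1)))
  util <- tariff$full_health - total_dec
  out <- scoreRecord(participant_id, "EQ-5D-5L", "utility", util,
                     c(tariff$full_health - worst, tariff$full_health))
  if (!is.na(vas)) {
    if (vas < 0 || vas > 100) stop("EQ-5D-5L VAS must lie in 0..100")
    out <- rbind(out, scoreRecord(participant_id, "EQ-5D-5L", "vas", vas,
                                  c(0, 100)))
  }
  out
}

PUF_ULP_ITEMS <- c("wearing_comfort", "functionality", "independence",
                   "work_hobby_household", "user_friendliness",
                   "life_like_appearance", "phantom_limb_pain",
                   "overuse_complaints", "reliability")
## Items whose two worst answer levels share one estimated weight.
PUF_ULP_MERGED <- c("user_friendliness", "reliability")

#' Read a PUF-ULP weight table
#'
#' Columns `item`, `level`, `weight`: the estimated weight of each answer
#' level (1 = best .. 4 = worst) of the nine usage-feature items. For the
#' `user_friendliness` and `reliability` items the two worst levels are
#' merged (a level-4 row may be omitted; level 3's weight is then used).
#' The study's weight values are not published; the package ships only a
#' synthetic example (`puf_ulp_weights_synthetic.csv`) whose worst/best
#' level sums are -12.0 and 0.1, matching the instrument's documented
#' endpoints.
#'
#' @param path CSV path.
#' @return data.frame with columns `item`, `level`, `weight`.
#' @export
readPufUlpWeights <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("item", "level", "weight")
  if (!all(req %in% names(tab)))
    stop(sprintf("weight table must have columns: %s",
                 paste(req, collapse = ", ")))
  missing_items <- setdiff(PUF_ULP_ITEMS, tab$item)
  if (length(missing_items))
    stop(sprintf("weight table lacks item(s): %s",
                 paste(missing_items, collapse = ", ")))
  tab
}

#' Score the PUF-ULP (preferred usage features of upper-limb prostheses)
#'
#' The weights of the nine answered levels are summed and 12 is added, so
#' that with the study's weight table (worst-level sum -12.0, best-level sum
#' 0.1) scores range from 0 to 12.1; higher = better match between the
#' prosthesis and the user's preferred usage features.
#'
#' @param answers named (or ordered) integer vector of 9 levels in 1..4
#'   (1 = best answer level).
#' @param weights a weight table from [readPufUlpWeights()]; required, since
#'   the estimated weights are external.
#' @param participant_id optional identifier.
#' @return A one-row ScoreRecord data.frame.
#' @export
scorePufUlp <- function(answers, weights, participant_id = NA_character_) {
  if (missing(weights) || is.null(weights))
    stop("weight table required: supply one via readPufUlpWeights()")
  answers <- as.integer(answers)
  if (length(answers) != 9L || anyNA(answers) ||
      any(answers < 1L | answers > 4L))
    stop("PUF-ULP requires 9 answer levels, each in 1..4")
  lookup <- function(item, level) {
    w <- weights$weight[weights$item == item & weights$level == level]
    if (!length(w) && item %in% PUF_ULP_MERGED && level == 4L)
      w <- weights$weight[weights$item == item & weights$level == 3L]
    if (length(w) != 1L)
      stop(sprintf("weight table has no entry for %s level %d", item, level))
    w
  }
  total <- sum(mapply(lookup, PUF_ULP_ITEMS, answers)) + 12
  lo <- sum(vapply(PUF_ULP_ITEMS, lookup, numeric(1), level = 4L)) + 12
  hi <- sum(vapply(PUF_ULP_ITEMS, lookup, numeric(1), level = 1L)) + 12
  scoreRecord(participant_id, "PUF-ULP", "total", total, sort(c(lo, hi)))
}

#' Score the D-QUEST satisfaction ratings
#'
#' Means of the eight device items, the four service items, and all twelve
#' items; each score lies in 1-5, higher = more satisfied.
#'
#' @param ratings numeric vector of 12 ratings in 1..5 (device items first).
#' @param participant_id optional identifier.
#' @return A three-row ScoreRecord data.frame (`device`, `service`, `total`).
#' @export
scoreDquest <- function(ratings, participant_id = NA_character_) {
  ratings <- checkItems(ratings, 12L, 1, 5, "D-QUEST")
  rbind(
    scoreRecord(participant_id, "D-QUEST", "device",
                mean(ratings[1:8]), c(1, 5)),
    scoreRecord(participant_id, "D-QUEST", "service",
                mean(ratings[9:12]), c(1, 5)),
    scoreRecord(participant_id, "D-QUEST", "total",
                mean(ratings), c(1, 5))
  )
}
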