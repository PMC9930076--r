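#' Specify a two-group questionnaire dataset
#'
#' A `GroupScoreSpec` names, per measure, either a normal distribution
#' (group-specific mean and SD, values resampled into the declared valid
#' range) or an ordinal distribution (level labels with group-specific
#' probabilities). Group sizes default to the reference cohorts (14 MHP and
#' 19 SHP users).
#'
#' @param measures named list; each element is a list with `dist = "normal"`
#'   (`mean`, `sd`: named per-group numerics; `range`: length-2 numeric) or
#'   `dist = "ordinal"` (`levels`: character; `prob`: named list of per-group
#'   probability vectors).
#' @param n named integer vector of group sizes, e.g. `c(MHP = 14, SHP = 19)`.
#' @return A `GroupScoreSpec` (S3) object.
#' @examples
#' spec <- groupScoreSpec(list(
#'   age = list(dist = "normal", mean = c(MHP = 48.6, SHP = 58.1),
#'              sd = c(MHP = 12.4, SHP = 15.7), range = c(18, 95))))
#' @export
groupScoreSpec <- function(measures, n = c(MHP = 14L, SHP = 19L)) {
  if (!is.list(measures) || is.null(names(measures)) ||
      any(names(measures) == ""))
    stop("measures must be a named list")
  if (is.null(names(n)) || any(n < 1))
    stop("n must be a named vector of group sizes >= 1")
  for (m in names(measures)) {
    e <- measures[[m]]
    if (is.null(e$dist) || !e$dist %in% c("normal", "ordinal"))
      stop(sprintf("measure '%s': unknown distribution kind '%s'",
                   m, as.character(e$dist)))
    if (e$dist == "normal") {
      if (!all(names(n) %in% names(e$mean)) ||
          !all(names(n) %in% names(e$sd)))
        stop(sprintf("measure '%s': mean/sd must be named per group", m))
      if (any(e$sd < 0))
        stop(sprintf("measure '%s': sd must be >= 0", m))
      if (!is.null(e$range) && (length(e$range) != 2L ||
                                e$range[1] > e$range[2]))
        stop(sprintf("measure '%s': range must be (lo, hi)", m))
    } else {
      if (is.null(e$levels) || length(e$levels) < 2L)
        stop(sprintf("measure '%s': ordinal needs >= 2 levels", m))
      for (g in names(n)) {
        pr <- e$prob[[g]]
        if (is.null(pr) || length(pr) != length(e$levels) || any(pr < 0))
          stop(sprintf("measure '%s': prob for group '%s' must match levels",
                       m, g))
      }
    }
  }
  structure(list(measures = measures, n = n), class = "GroupScoreSpec")
}

#' Generate two-group questionnaire scores
#'
#' Draws one row per synthetic participant with a group label and one column
#' per measure. Normal measures are resampled into their declared valid range
#' (so empirical moments converge to the specified values as n grows for
#' ranges that are wide relative to the SD); ordinal measures are sampled
#' from the per-group level probabilities.
#'
#' @param spec a [groupScoreSpec()].
#' @param seed integer RNG seed.
#' @return A data.frame with columns `participant_id`, `group`, and the
#'   measures.
#' @export
generateGroupScores <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "GroupScoreSpec"))
  set.seed(as.integer(seed))
  groups <- rep(names(spec$n), times = spec$n)
  out <- data.frame(
    participant_id = sprintf("S%03d", seq_along(groups)),
    group = groups,
    stringsAsFactors = FALSE)
  for (m in names(spec$measures)) {
    e <- spec$measures[[m]]
    col <- vector(if (e$dist == "normal") "numeric" else "character",
                  nrow(out))
    for (g in names(spec$n)) {
      idx <- which(out$group == g)
      if (e$dist == "normal") {
        v <- rnorm(length(idx), e$mean[[g]], e$sd[[g]])
        if (!is.null(e$range)) {
          bad <- which(v < e$range[1] | v > e$range[2])
          tries <- 0L
          while (length(bad) && tries < 1000L) {
            v[bad] <- rnorm(length(bad), e$mean[[g]], e$sd[[g]])
            bad <- which(v < e$range[1] | v > e$range[2])
            tries <- tries + 1L
          }
          v <- pmin(pmax(v, e$range[1]), e$range[2])
        }
        col[idx] <- v
      } else {
        col[idx] <- sample(e$levels, length(idx), replace = TRUE,
                           prob = e$prob[[g]])
      }
    }
    out[[m]] <- col
  }
  out
}

#' Reference-study group-score specification
#'
#' Encodes the between-group study conditions used throughout the package's
#' simulations: participant characteristics (age, prosthesis experience, sex,
#' side of limb absence) and a selection of instrument scores, each with the
#' cohort means/SDs or category proportions of the 14 MHP and 19 SHP users.
#'
#' @return A [groupScoreSpec()].
#' @export
defaultGroupScoreSpec <- function() {
  groupScoreSpec(list(
    age = list(dist = "normal", mean = c(MHP = 48.6, SHP = 58.1),
               sd = c(MHP = 12.4, SHP = 15.7), range = c(18, 95)),
    experience_current_y = list(dist = "normal",
                                mean = c(MHP = 3.1, SHP = 29.4),
                                sd = c(MHP = 2.8, SHP = 19.8),
                                range = c(0, 70)),
    sex = list(dist = "ordinal", levels = c("male", "female"),
               prob = list(MHP = c(9, 5) / 14, SHP = c(13, 6) / 19)),
    side = list(dist = "ordinal", levels = c("left", "right"),
                prob = list(MHP = c(9, 5) / 14, SHP = c(13, 6) / 19)),
    tapes_satisfaction = list(dist = "normal",
                              mean = c(MHP = 35.9, SHP = 38.7),
                              sd = c(MHP = 5.6, SHP = 5.9), range = c(9, 45)),
    dquest_total = list(dist = "normal", mean = c(MHP = 3.9, SHP = 4.1),
                        sd = c(MHP = 0.5, SHP = 0.4), range = c(1, 5)),
    puf_ulp = list(dist = "normal", mean = c(MHP = 8.9, SHP = 10.6),
                   sd = c(MHP = 2.1, SHP = 1.3), range = c(0, 12.1)),
    eq5d_vas = list(dist = "normal", mean = c(MHP = 83.6, SHP = 83.6),
                    sd = c(MHP = 12.8, SHP = 15.6), range = c(0, 100))
  ))
}
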