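#' Effect-size magnitude thresholds
#'
#' The magnitude bands used by [classifyEffect()]: Pearson r (0.1, 0.3, 0.5),
#' generalized eta squared (0.02, 0.13, 0.26), and Cramer's V for 1 df
#' (0.1, 0.3, 0.5) and 3 df (0.06, 0.17, 0.29).
#'
#' @return Named list of strictly increasing threshold triples.
#' @export
effectThresholds <- function() {
  list(
    pearson_r = c(0.1, 0.3, 0.5),
    eta_g_sq = c(0.02, 0.13, 0.26),
    cramers_v_df1 = c(0.1, 0.3, 0.5),
    cramers_v_df3 = c(0.06, 0.17, 0.29)
  )
}

#' Label an effect size as negligible/small/medium/large
#'
#' Magnitudes are compared against the metric's threshold triple; boundary
#' values are assigned to the higher category (e.g. r = 0.3 is `medium`).
#' Pearson r is classified by absolute value. For Cramer's V the
#' df-appropriate thresholds are used (1 df and 3 df bands are defined; other
#' df yield `NA` with a warning).
#'
#' @param value effect-size value.
#' @param metric `"pearson_r"`, `"eta_g_sq"`, or `"cramers_v"`.
#' @param df contingency-table degrees of freedom, required for Cramer's V.
#' @return One of `"negligible"`, `"small"`, `"medium"`, `"large"`.
#' @examples
#' classifyEffect(0.8, "pearson_r")          # "large"
#' classifyEffect(0.17, "cramers_v", df = 3) # "medium"
#' @export
classifyEffect <- function(value,
                           metric = c("pearson_r", "eta_g_sq", "cramers_v"),
                           df = NULL) {
  metric <- match.arg(metric)
  th <- effectThresholds()
  cuts <- switch(metric,
    pearson_r = th$pearson_r,
    eta_g_sq = th$eta_g_sq,
    cramers_v = {
      if (is.null(df)) stop("df is required to classify Cramer's V")
      if (df == 1) th$cramers_v_df1
      else if (df == 3) th$cramers_v_df3
      else {
        warning(sprintf("no Cramer's V thresholds defined for df = %g", df))
        return(NA_character_)
      }
    })
  v <- abs(value)
  c("negligible", "small", "medium", "large")[findInterval(v, cuts) + 1L]
}

#' Pearson r from a t statistic
#'
#' `r = sign(t) * sqrt(t^2 / (t^2 + df))`; the conventional effect size for
#' paired and independent t tests.
#'
#' @param t t statistic.
#' @param df its degrees of freedom (> 0).
#' @return Signed r in \[-1, 1\].
#' @examples
#' rFromT(4.1, 12)  # 0.76, a large effect
#' @export
rFromT <- function(t, df) {
  if (any(df <= 0)) stop("df must be positive")
  sign(t) * sqrt(t^2 / (t^2 + df))
}

#' Effect size r from a standardized z statistic
#'
#' `r = z / sqrt(N)` with N the total sample size; the conversion used for
#' Mann-Whitney tests.
#'
#' @param z standardized test statistic.
#' @param n_total total number of observations (>= 2).
#' @return Signed r.
#' @examples
#' rFromZ(-3.7, 33)  # -0.64
#' @export
rFromZ <- function(z, n_total) {
  if (any(n_total < 2)) stop("n_total must be >= 2")
  z / sqrt(n_total)
}
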