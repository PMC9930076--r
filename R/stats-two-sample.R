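#' Normality check with Shapiro-Wilk routing
#'
#' Runs Shapiro-Wilk (the routing authority at `alpha`) and a classical
#' Kolmogorov-Smirnov test against a normal with the sample's moments
#' (reported for audit only). A sample routed non-normal should be analyzed
#' with the nonparametric branch of the battery.
#'
#' @param x numeric sample (n >= 3, non-degenerate).
#' @param alpha routing significance level (0.05).
#' @return List with `shapiro` and `ks` [StatTestResult-class] objects and
#'   `parametric` (TRUE when Shapiro-Wilk does not reject).
#' @export
checkNormality <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  if (length(x) < 3L || sd(x) == 0)
    stop("sample too small or degenerate for a normality check (need n >= 3, non-constant)")
  sw <- shapiro.test(x)
  ks <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  list(
    shapiro = newStatResult("shapiro_wilk", sw$statistic, NA_real_,
                            sw$p.value, alpha = alpha),
    ks = newStatResult("ks", ks$statistic, NA_real_, ks$p.value,
                       alpha = alpha),
    parametric = sw$p.value >= alpha
  )
}

#' Paired t test with Pearson r effect size
#'
#' `t = mean(d) / (sd(d)/sqrt(n))` on the within-participant differences,
#' df = n - 1, effect size `r = sqrt(t^2/(t^2+df))` signed by t.
#'
#' @param x,y paired numeric vectors of equal length (n >= 2).
#' @param alpha significance level (0.01 in the reference analysis).
#' @return A [StatTestResult-class] with method `paired_t`.
#' @examples
#' pairedT(c(1, 2, 3), c(2, 3, 5))  # t = -4, df = 2, r = -0.94
#' @export
pairedT <- function(x, y, alpha = 0.01) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (var(d) == 0) stop("degenerate differences: zero variance")
  ht <- t.test(x, y, paired = TRUE)
  tval <- unname(ht$statistic); df <- unname(ht$parameter)
  newStatResult("paired_t", tval, df, ht$p.value,
                effect_size = rFromT(tval, df), effect_metric = "pearson_r",
                alpha = alpha,
                details = list(mean_diff = mean(d), sd_diff = sd(d),
                               n = length(x)))
}

#' Independent-samples t test with Levene routing
#'
#' With `variance_policy = "auto"`, Levene's test (center = mean, the SPSS
#' default, at alpha 0.05) selects the pooled-variance t (df = n1 + n2 - 2)
#' or Welch's t (Welch-Satterthwaite df). Effect size r as in [pairedT()].
#'
#' @param x,y numeric samples (each n >= 2).
#' @param variance_policy `"auto"`, `"pooled"`, or `"welch"`.
#' @param alpha significance level for the test itself.
#' @param levene_alpha routing level for Levene's test.
#' @return A [StatTestResult-class] with method `pooled_t` or `welch_t`; the
#'   routing Levene test is in `details$levene`.
#' @export
independentT <- function(x, y, variance_policy = c("auto", "pooled", "welch"),
                         alpha = 0.01, levene_alpha = 0.05) {
  variance_policy <- match.arg(variance_policy)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples need n >= 2")
  if (var(x) == 0 && var(y) == 0)
    stop("degenerate samples: zero variance in both groups")
  lev <- NULL
  if (variance_policy == "auto") {
    lt <- car::leveneTest(c(x, y),
                          factor(rep(c("x", "y"), c(length(x), length(y)))),
                          center = mean)
    lev <- newStatResult("levene", lt[1, "F value"], lt[1, "Df"],
                         lt[1, "Pr(>F)"], df2 = lt[2, "Df"],
                         alpha = levene_alpha)
    variance_policy <- if (lt[1, "Pr(>F)"] < levene_alpha) "welch" else
      "pooled"
  }
  ht <- t.test(x, y, var.equal = (variance_policy == "pooled"))
  tval <- unname(ht$statistic); df <- unname(ht$parameter)
  newStatResult(paste0(variance_policy, "_t"), tval, df, ht$p.value,
                effect_size = rFromT(tval, df), effect_metric = "pearson_r",
                alpha = alpha,
                details = list(levene = lev, n1 = length(x), n2 = length(y)))
}

#' t test from printed summary statistics
#'
#' Pooled or Welch t computed from group means, SDs and sizes; the
#' validation path for published summary tables.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @param method `"pooled"` or `"welch"`.
#' @param alpha significance level.
#' @return A [StatTestResult-class].
#' @examples
#' tFromSummary(48.6, 12.4, 14, 58.1, 15.7, 19)  # t = -1.87, df = 31
#' @export
tFromSummary <- function(m1, s1, n1, m2, s2, n2,
                         method = c("pooled", "welch"), alpha = 0.01) {
  method <- match.arg(method)
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (s1 < 0 || s2 < 0) stop("SDs must be >= 0")
  if (s1 == 0 && s2 == 0) stop("degenerate: zero variance in both groups")
  if (method == "pooled") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tval <- (m1 - m2) / se
  p <- 2 * pt(-abs(tval), df)
  newStatResult(paste0(method, "_t"), tval, df, p,
                effect_size = rFromT(tval, df), effect_metric = "pearson_r",
                alpha = alpha, details = list(n1 = n1, n2 = n2))
}

#' Mann-Whitney U test with normal approximation
#'
#' U is reported with the smaller-value convention, `U = min(U1, U2)` with
#' `U1` the statistic of the first sample. The z statistic uses the normal
#' approximation with tie-corrected variance and no continuity correction
#' (the convention of mainstream statistical packages for this battery), so
#' z is always <= 0; the direction is recoverable from `details$U1`. Effect
#' size `r = z / sqrt(N)`.
#'
#' @param x,y numeric samples (each n >= 1).
#' @param alpha significance level.
#' @return A [StatTestResult-class] with method `mann_whitney`; `statistic`
#'   is U, `details$z` the z statistic.
#' @examples
#' mannWhitney(c(1, 2), c(3, 4))  # U = 0, z = -1.55, r = -0.77
#' @export
mannWhitney <- function(x, y, alpha = 0.01) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples need n >= 1")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    stop("degenerate samples: all values identical")
  rk <- rank(pooled)
  R1 <- sum(rk[seq_len(n1)])
  U1 <- R1 - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  N <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - tie_term)
  if (sigma2 <= 0) stop("degenerate samples: zero rank variance")
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  p <- 2 * pnorm(-abs(z))
  newStatResult("mann_whitney", U, NA_real_, p,
                effect_size = rFromZ(z, N), effect_metric = "pearson_r",
                alpha = alpha,
                details = list(z = z, U1 = U1, U2 = U2, R1 = R1,
                               n1 = n1, n2 = n2))
}

#' Pearson chi-squared test with Cramer's V
#'
#' Pearson chi-squared on a contingency table (no Yates correction by
#' default), with `V = sqrt(chi2 / (N * (min(rows, cols) - 1)))` labelled by
#' the df-appropriate thresholds.
#'
#' @param table matrix of counts (2 x 2 or 2 x k).
#' @param correction `"none"` (default) or `"yates"`.
#' @param alpha significance level.
#' @return A [StatTestResult-class] with method `chi_squared` and Cramer's V
#'   as the effect size.
#' @examples
#' chiSquared(matrix(c(9, 13, 5, 6), 2))  # chi2 = 0.06, V = 0.04
#' @export
chiSquared <- function(table, correction = c("none", "yates"), alpha = 0.01) {
  correction <- match.arg(correction)
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: a margin is zero")
  ht <- suppressWarnings(
    chisq.test(table, correct = (correction == "yates")))
  chi2 <- unname(ht$statistic)
  df <- unname(ht$parameter)
  N <- sum(table)
  V <- sqrt(chi2 / (N * (min(dim(table)) - 1)))
  newStatResult("chi_squared", chi2, df, ht$p.value,
                effect_size = V, effect_metric = "cramers_v",
                alpha = alpha, effect_df = df,
                details = list(expected = ht$expected, n = N))
}
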