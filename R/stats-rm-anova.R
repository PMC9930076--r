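## Orthonormal contrast matrix (k x (k-1)), columns orthonormal and
## orthogonal to the unit vector.
orthonormalContrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2L, sqrt(colSums(C^2)), "/")
}

## Mauchly's W and Greenhouse-Geisser epsilon for one within effect.
## Y: n x d matrix of orthonormal-contrast scores for the effect.
sphericityStats <- function(Y) {
  n <- nrow(Y); d <- ncol(Y)
  S <- stats::cov(Y)
  eps <- sum(diag(S))^2 / (d * sum(S^2))
  eps <- min(max(eps, 1 / d), 1)
  W <- NA_real_; p <- NA_real_
  if (n - 1 >= d) {
    dt <- det(S)
    if (is.finite(dt) && dt > 0) {
      W <- dt / (sum(diag(S)) / d)^d
      f <- 1 - (2 * d^2 + d + 2) / (6 * d * (n - 1))
      chi <- -(n - 1) * f * log(W)
      p <- pchisq(chi, d * (d + 1) / 2 - 1, lower.tail = FALSE)
    }
  }
  list(W = W, p = p, epsilon = eps)
}

#' Two-way fully-within repeated-measures ANOVA (hand x joint)
#'
#' Full sum-of-squares decomposition for a balanced design with two
#' within-subject factors: prosthetic hand (2 levels) and joint angle
#' (7 levels), each effect tested against its own subject-interaction error
#' term. For within factors with more than 2 levels, Mauchly's W is computed
#' on the orthonormal-contrast covariance and the Greenhouse-Geisser epsilon
#' is applied to the degrees of freedom when sphericity is rejected
#' (`mauchly_p < sphericity_alpha`; epsilon = 1 is reported for the 2-level
#' hand factor). When too few subjects make Mauchly's test undefined, the
#' correction is applied unconditionally (conservative). The effect size is
#' the generalized eta squared for fully-within designs:
#' `SS_effect / (SS_effect + SS_subject + sum of all error SS)`.
#'
#' @param data data.frame with columns `subject`, `hand`, `joint`, `value`;
#'   one observation per cell, complete and balanced (no imputation).
#' @param alpha significance level (0.01).
#' @param sphericity_alpha level of Mauchly's test gating the correction.
#' @return An `AnovaTable` data.frame with one row per effect (`hand`,
#'   `joint`, `hand:joint`): uncorrected `df_num`/`df_den`, `F`,
#'   `mauchly_w`, `mauchly_p`, `epsilon_gg`, `gg_applied`, corrected
#'   `df_num_adj`/`df_den_adj`, `p_value`, `eta_g_sq`, `significant`.
#'   Attribute `"ss"` carries the full SS decomposition.
#' @export
rmAnovaHandByJoint <- function(data, alpha = 0.01, sphericity_alpha = 0.05) {
  req <- c("subject", "hand", "joint", "value")
  if (!all(req %in% names(data)))
    stop(sprintf("data must have columns: %s", paste(req, collapse = ", ")))
  data$subject <- as.character(data$subject)
  data$hand <- as.character(data$hand)
  data$joint <- as.character(data$joint)
  subjects <- sort(unique(data$subject))
  hands <- sort(unique(data$hand))
  joints <- unique(data$joint)
  n <- length(subjects); a <- length(hands); b <- length(joints)
  if (n < 3L) stop("need at least 3 subjects")
  if (a < 2L || b < 2L) stop("both factors need at least 2 levels")
  if (nrow(data) != n * a * b ||
      anyNA(data$value) ||
      any(table(data$subject, data$hand, data$joint) != 1L))
    stop("unbalanced design: each subject x hand x joint cell must appear exactly once")

  ## cell array Y[subject, hand, joint]
  Y <- array(NA_real_, c(n, a, b), dimnames = list(subjects, hands, joints))
  Y[cbind(match(data$subject, subjects), match(data$hand, hands),
          match(data$joint, joints))] <- data$value

  gm <- mean(Y)
  m_s <- apply(Y, 1L, mean)
  m_h <- apply(Y, 2L, mean)
  m_j <- apply(Y, 3L, mean)
  m_sh <- apply(Y, c(1L, 2L), mean)
  m_sj <- apply(Y, c(1L, 3L), mean)
  m_hj <- apply(Y, c(2L, 3L), mean)

  ss_subj <- a * b * sum((m_s - gm)^2)
  ss_hand <- n * b * sum((m_h - gm)^2)
  ss_joint <- n * a * sum((m_j - gm)^2)
  ss_hj <- n * sum((m_hj - outer(m_h, rep(1, b)) -
                      outer(rep(1, a), m_j) + gm)^2)
  ss_err_hand <- b * sum((m_sh - outer(m_s, rep(1, a)) -
                            outer(rep(1, n), m_h) + gm)^2)
  ss_err_joint <- a * sum((m_sj - outer(m_s, rep(1, b)) -
                             outer(rep(1, n), m_j) + gm)^2)
  ss_total <- sum((Y - gm)^2)
  ss_err_int <- ss_total - ss_subj - ss_hand - ss_joint - ss_hj -
    ss_err_hand - ss_err_joint

  df <- list(hand = a - 1, joint = b - 1, hj = (a - 1) * (b - 1),
             err_hand = (a - 1) * (n - 1), err_joint = (b - 1) * (n - 1),
             err_int = (a - 1) * (b - 1) * (n - 1))

  ## Sphericity: contrast scores per effect on the subject x cell matrix.
  cells <- matrix(aperm(Y, c(1L, 3L, 2L)), n, a * b)  # joint fastest
  Ch <- orthonormalContrasts(a)
  Cj <- orthonormalContrasts(b)
  ones_h <- matrix(1 / a, a, 1L)
  ones_j <- matrix(1 / b, b, 1L)
  ## cells columns ordered hand-major, joint fastest -> kron(hand, joint)
  M_joint <- kronecker(ones_h, Cj)
  M_hj <- kronecker(Ch, Cj)
  sph <- list(
    hand = list(W = NA_real_, p = NA_real_, epsilon = 1),
    joint = sphericityStats(cells %*% M_joint),
    hj = sphericityStats(cells %*% M_hj)
  )

  err_denom <- ss_subj + ss_err_hand + ss_err_joint + ss_err_int
  mk <- function(name, ss_eff, df_num, ss_err, df_den, sp) {
    Fv <- (ss_eff / df_num) / (ss_err / df_den)
    ggap <- FALSE
    eps <- sp$epsilon
    if (df_num > 1) {
      ggap <- if (is.na(sp$p)) TRUE else sp$p < sphericity_alpha
    }
    d1 <- if (ggap) df_num * eps else df_num
    d2 <- if (ggap) df_den * eps else df_den
    p <- pf(Fv, d1, d2, lower.tail = FALSE)
    data.frame(
      effect = name, df_num = df_num, df_den = df_den, F = Fv,
      mauchly_w = sp$W, mauchly_p = sp$p, epsilon_gg = eps,
      gg_applied = ggap, df_num_adj = d1, df_den_adj = d2,
      p_value = p,
      eta_g_sq = ss_eff / (ss_eff + err_denom),
      significant = p < alpha,
      stringsAsFactors = FALSE)
  }
  out <- rbind(
    mk("hand", ss_hand, df$hand, ss_err_hand, df$err_hand, sph$hand),
    mk("joint", ss_joint, df$joint, ss_err_joint, df$err_joint, sph$joint),
    mk("hand:joint", ss_hj, df$hj, ss_err_int, df$err_int, sph$hj)
  )
  attr(out, "ss") <- c(subject = ss_subj, hand = ss_hand, joint = ss_joint,
                       `hand:joint` = ss_hj, err_hand = ss_err_hand,
                       err_joint = ss_err_joint, err_int = ss_err_int,
                       total = ss_total)
  attr(out, "n_subjects") <- n
  class(out) <- c("AnovaTable", "data.frame")
  out
}

#' @export
print.AnovaTable <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%d subjects)\n",
              attr(x, "n_subjects")))
  df <- as.data.frame(x)
  df$F <- round(df$F, 3)
  df$p_value <- signif(df$p_value, 3)
  df$eta_g_sq <- round(df$eta_g_sq, 4)
  df$epsilon_gg <- round(df$epsilon_gg, 3)
  print(df[, c("effect", "F", "df_num_adj", "df_den_adj", "p_value",
               "epsilon_gg", "eta_g_sq", "significant")], row.names = FALSE)
  invisible(x)
}
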