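#' Mean functional connectivity of a network
#'
#' Mean of the strict upper triangle of the full (unmasked) epoch-mean
#' matrix: the average of all connections, including inter-hemispheric ones.
#' This is deliberately different from node strength, which is
#' intra-hemispheric only.
#'
#' @param fc Square symmetric connectivity matrix (>= 2 regions).
#' @return Scalar mean connectivity.
#' @export
mean_fc <- function(fc) {
  if (!is.matrix(fc) || nrow(fc) < 2L || nrow(fc) != ncol(fc))
    stop("fc must be a square matrix of size >= 2")
  vals <- fc[upper.tri(fc)]
  if (anyNA(vals))
    stop("fc contains NA off-diagonals; mean_fc uses the unmasked matrix")
  mean(vals)
}

#' Outcome-group AUC for D_RS values
#'
#' `AUC = P(D_RS of a random not-seizure-free subject > D_RS of a random
#' seizure-free subject) + 0.5 P(tie)`, computed by midranks (identical to
#' all-pairs enumeration). Values above 0.5 mean seizure-free patients have
#' lower D_RS, i.e. their resections captured relatively stronger nodes.
#'
#' @param drs_values Numeric vector of per-subject D_RS values.
#' @param outcome Parallel vector with levels `"ILAE1"` and `"ILAE_gt1"`.
#' @return List with `auc`, `n1` (ILAE1 count) and `n2` (ILAE_gt1 count).
#' @export
group_auc <- function(drs_values, outcome) {
  if (length(drs_values) != length(outcome))
    stop("drs_values and outcome lengths differ")
  if (!all(outcome %in% c("ILAE1", "ILAE_gt1")))
    stop("outcome must be 'ILAE1' or 'ILAE_gt1'")
  x <- drs_values[outcome == "ILAE1"]   # hypothesized lower
  y <- drs_values[outcome == "ILAE_gt1"]
  if (length(x) == 0L || length(y) == 0L)
    stop("both outcome groups must be nonempty")
  r <- rank(c(y, x))
  u_y <- sum(r[seq_along(y)]) - length(y) * (length(y) + 1) / 2
  list(auc = u_y / (length(x) * length(y)), n1 = length(x), n2 = length(y))
}

#' Logit-transformed Hanley-McNeil confidence interval for an AUC
#'
#' Standard error from the Hanley-McNeil formula with
#' `Q1 = A / (2 - A)` and `Q2 = 2 A^2 / (1 + A)`:
#' `SE^2 = [A(1-A) + (n1-1)(Q1-A^2) + (n2-1)(Q2-A^2)] / (n1 n2)`.
#' The interval is constructed on the logit scale,
#' `logit(A) +/- z * SE / (A(1-A))`, and back-transformed, which keeps both
#' bounds inside (0, 1).
#'
#' @param auc Observed AUC, strictly between 0 and 1.
#' @param n1,n2 Group sizes (n1 paired with the Q1 term, n2 with Q2).
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(ci_low, ci_high)`.
#' @export
auc_logit_ci <- function(auc, n1, n2, level = 0.95) {
  if (!(auc > 0 && auc < 1))
    stop("auc must be strictly inside (0, 1); degenerate AUCs have no logit interval")
  if (n1 < 1 || n2 < 1) stop("group sizes must be >= 1")
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  A <- auc
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + (n1 - 1) * (Q1 - A^2) + (n2 - 1) * (Q2 - A^2)) /
               (n1 * n2))
  z <- qnorm((1 + level) / 2)
  half <- z * se / (A * (1 - A))
  c(ci_low = plogis(qlogis(A) - half), ci_high = plogis(qlogis(A) + half))
}

#' One-tailed Mann-Whitney rank-sum p-value
#'
#' Tests the alternative that `x` is stochastically smaller than `y` (the
#' seizure-free group having lower D_RS). Exact enumeration is used for small
#' tie-free samples (`n1 + n2 <= 12`); otherwise the normal approximation
#' with tie and continuity corrections, which is what the cohort-scale
#' comparison (12 vs 19) uses.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `p` and `method` (`"exact"` or `"normal_approx"`).
#' @export
ranksum_one_tailed <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 12L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "less", exact = exact,
                       correct = TRUE)
  )
  list(p = wt$p.value, method = if (exact) "exact" else "normal_approx")
}

#' Outcome discrimination summary for one segment
#'
#' Composes [group_auc()], [auc_logit_ci()] and [ranksum_one_tailed()] into
#' the per-segment outcome analysis. If the AUC is degenerate (0 or 1) the
#' interval is reported as the degenerate point pair rather than through the
#' logit construction.
#'
#' @inheritParams group_auc
#' @param level Confidence level for the AUC interval.
#' @return A `group_auc_result` list: `auc`, `ci_low`, `ci_high`, `level`,
#'   `n1`, `n2`, `p_one_tailed`, `p_method`.
#' @export
group_outcome_test <- function(drs_values, outcome, level = 0.95) {
  a <- group_auc(drs_values, outcome)
  ci <- if (a$auc > 0 && a$auc < 1) {
    auc_logit_ci(a$auc, a$n1, a$n2, level)
  } else c(ci_low = a$auc, ci_high = a$auc)
  pr <- ranksum_one_tailed(drs_values[outcome == "ILAE1"],
                           drs_values[outcome == "ILAE_gt1"])
  structure(list(auc = a$auc, ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 level = level, n1 = a$n1, n2 = a$n2,
                 p_one_tailed = pr$p, p_method = pr$method),
            class = "group_auc_result")
}

#' @export
print.group_auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.2f, %d%%CI = %.2f-%.2f (n = %d vs %d), one-tailed rank-sum p = %.3g [%s]\n",
              x$auc, round(100 * x$level), x$ci_low, x$ci_high,
              x$n1, x$n2, x$p_one_tailed, x$p_method))
  invisible(x)
}

# Gaussian log-likelihood of residuals at the MLE scale; used to compare
# nested robust fits. This is a quasi-likelihood: bisquare M-estimation has
# no canonical likelihood, so the Gaussian one is evaluated at the robust
# parameter estimates.
.gauss_loglik <- function(residuals) {
  n <- length(residuals)
  s2 <- mean(residuals^2)
  -n / 2 * (log(2 * pi) + log(s2) + 1)
}

#' Robust (bisquare) regression of mean connectivity on log10 duration
#'
#' Fits `mean_fc ~ 1 + log10(duration_years)` by iteratively reweighted least
#' squares with the Tukey bisquare psi (tuning constant 4.685), and compares
#' it with the intercept-only model via a likelihood-ratio test on Gaussian
#' quasi-likelihoods evaluated at the robust estimates (chi-square, 1 df).
#' Adjusted R-squared comes from bisquare-weighted sums of squares:
#' `1 - (1 - R2_w)(n - 1)/(n - 2)`.
#'
#' @param cohort data.frame with columns `mean_fc` and `duration_years`
#'   (rows of a single segment).
#' @return A `duration_fit` list: `slope`, `intercept`, `adjusted_r2`,
#'   `lrt_p`, `model_kind = "robust_ols"`, `n`, plus `se_slope` and the
#'   underlying `fit`.
#' @export
fit_duration_robust <- function(cohort) {
  req <- c("mean_fc", "duration_years")
  if (!all(req %in% names(cohort))) stop("cohort needs columns mean_fc, duration_years")
  n <- nrow(cohort)
  if (n < 3L) stop("need at least 3 subjects")
  if (any(cohort$duration_years <= 0)) stop("durations must be > 0")
  dur <- log10(cohort$duration_years)
  if (stats::var(dur) == 0) stop("zero variance in log10 duration")
  y <- cohort$mean_fc
  fit <- MASS::rlm(y ~ dur, psi = MASS::psi.bisquare, maxit = 100)
  fit0 <- MASS::rlm(y ~ 1, psi = MASS::psi.bisquare, maxit = 100)
  lrt <- max(0, 2 * (.gauss_loglik(resid(fit)) - .gauss_loglik(resid(fit0))))
  w <- fit$w
  ybar_w <- sum(w * y) / sum(w)
  r2_w <- 1 - sum(w * resid(fit)^2) / sum(w * (y - ybar_w)^2)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    se_slope = unname(sqrt(diag(stats::vcov(fit)))[2]),
    adjusted_r2 = 1 - (1 - r2_w) * (n - 1) / (n - 2),
    lrt_p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
    model_kind = "robust_ols",
    likelihood = "gaussian_quasi",
    n = n,
    fit = fit
  ), class = "duration_fit")
}

#' Mixed-effects duration model across segments
#'
#' Maximum-likelihood fit of `mean_fc ~ 1 + log10(duration) + (1 | segment)`
#' against the null without the duration term; the p-value is a
#' likelihood-ratio chi-square with 1 df. Requires at least two distinct
#' segments (otherwise the random intercept is unidentifiable; use
#' [fit_duration_robust()] on the single segment instead).
#'
#' @param cohort data.frame with columns `mean_fc`, `duration_years` and
#'   `segment` (all segments, one row per subject-segment).
#' @return A `duration_fit` list with `model_kind = "lme_random_intercept"`,
#'   fixed-effect `slope`/`intercept`, `se_slope`, random-intercept variance
#'   `segment_var`, and `lrt_p`.
#' @export
fit_duration_lme <- function(cohort) {
  req <- c("mean_fc", "duration_years", "segment")
  if (!all(req %in% names(cohort))) stop("cohort needs columns mean_fc, duration_years, segment")
  if (length(unique(cohort$segment)) < 2L)
    stop("only one segment: random intercept unidentifiable; use fit_duration_robust()")
  if (nrow(cohort) < 3L) stop("need at least 3 rows")
  dat <- data.frame(y = cohort$mean_fc, dur = log10(cohort$duration_years),
                    segment = factor(cohort$segment))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  full <- lme4::lmer(y ~ 1 + dur + (1 | segment), data = dat, REML = FALSE,
                     control = ctrl)
  null <- lme4::lmer(y ~ 1 + (1 | segment), data = dat, REML = FALSE,
                     control = ctrl)
  lrt <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))))
  fe <- lme4::fixef(full)
  vc <- as.data.frame(lme4::VarCorr(full))
  structure(list(
    slope = unname(fe["dur"]),
    intercept = unname(fe["(Intercept)"]),
    se_slope = unname(sqrt(diag(as.matrix(stats::vcov(full))))[2]),
    segment_var = vc$vcov[vc$grp == "segment"],
    lrt_p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
    model_kind = "lme_random_intercept",
    n = nrow(dat),
    fit = full
  ), class = "duration_fit")
}

#' @export
print.duration_fit <- function(x, ...) {
  cat(sprintf("%s: slope = %.4g (SE %.3g), LRT p = %.3g%s\n",
              x$model_kind, x$slope, x$se_slope, x$lrt_p,
              if (!is.null(x$adjusted_r2))
                sprintf(", adjusted R2 = %.3g", x$adjusted_r2) else ""))
  invisible(x)
}
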