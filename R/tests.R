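## Classical two-sample tests for competing risks data, each labelled by
## the null hypothesis it targets:
##   H0lambda_k   : no effect on the cause-k cause-specific intensity
##   H0lambda12   : no effect on either intensity (global null)
##   H0F1         : equal CIFs for the event of interest
##   H0F1F2       : equal CIFs for both event types

.cr_test <- function(name, hypothesis, statistic, df, p.value,
                     estimate = NULL, se = NULL) {
  structure(list(name = name, hypothesis = hypothesis,
                 statistic = statistic, df = df, p.value = p.value,
                 estimate = estimate, se = se), class = "cr_test")
}

#' @export
print.cr_test <- function(x, ...) {
  cat(x$name, "  [null: ", x$hypothesis, "]\n", sep = "")
  if (!is.null(x$estimate))
    cat(sprintf("  estimate = %.4f (se %.4f)\n", x$estimate, x$se))
  cat(sprintf("  statistic = %.4f, df = %d, p = %.4g\n", x$statistic,
              x$df, x$p.value))
  invisible(x)
}

#' Cause-specific log-rank test
#'
#' Standard two-sample log-rank test for the cause-`cause` hazard, treating
#' events of the other cause as censored at their event time.
#'
#' @param data observed dataset (`time`, `status`, `x`).
#' @param cause 1 or 2.
#' @return a `cr_test` (df = 1) targeting the cause-specific-hazard null.
#' @export
logrank_cause_specific <- function(data, cause = 1) {
  ev <- as.integer(data$status == cause)
  if (!any(ev)) stop("no events of cause ", cause)
  sd <- survival::survdiff(survival::Surv(data$time, ev) ~ data$x)
  .cr_test(sprintf("Log-rank test, cause %d", cause),
           sprintf("H0lambda%d", cause), sd$chisq, 1,
           stats::pchisq(sd$chisq, 1, lower.tail = FALSE))
}

#' Cause-specific Cox Wald test
#'
#' Fits the cause-specific proportional hazards model
#' \eqn{\lambda_{0k}(t \mid x) = \lambda_k(t) e^{\gamma_k x}} (other-cause
#' events censored) and returns the Wald test of \eqn{\gamma_k = 0}.
#'
#' @inheritParams logrank_cause_specific
#' @return a `cr_test` with the estimate \eqn{\hat\gamma_k} attached.
#' @export
cox_cause_specific_wald <- function(data, cause = 1) {
  ev <- as.integer(data$status == cause)
  if (!any(ev)) stop("no events of cause ", cause)
  fit <- survival::coxph(survival::Surv(data$time, ev) ~ data$x)
  g <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  if (!is.finite(g) || abs(g) > 15)
    warning("monotone partial likelihood: no cause-", cause,
            " events in one arm?")
  z2 <- (g / se)^2
  .cr_test(sprintf("Cox cause-specific Wald test, cause %d", cause),
           sprintf("H0lambda%d", cause), z2, 1,
           stats::pchisq(z2, 1, lower.tail = FALSE), estimate = g, se = se)
}

#' Joint two-degree-of-freedom Cox Wald test of the global null
#'
#' Sums the squared Wald z statistics of the two cause-specific Cox models;
#' the two are asymptotically independent, giving a chi-squared reference
#' with 2 df for the hypothesis of no effect on either intensity.
#'
#' @param data observed dataset.
#' @return a `cr_test` with df = 2.
#' @export
joint_cox_wald <- function(data) {
  t1 <- cox_cause_specific_wald(data, 1)
  t2 <- cox_cause_specific_wald(data, 2)
  stat <- t1$statistic + t2$statistic
  .cr_test("Joint Cox Wald test (both causes)", "H0lambda1lambda2",
           stat, 2, stats::pchisq(stat, 2, lower.tail = FALSE))
}

#' Gray's test for equality of cumulative incidence functions
#'
#' Two-sample log-rank-type test of equal CIFs for the chosen cause
#' (rho = 0 weighting), computed by [cmprsk::cuminc()].
#'
#' @inheritParams logrank_cause_specific
#' @return a `cr_test` (df = 1) targeting the CIF null.
#' @export
gray_test <- function(data, cause = 1) {
  if (!any(data$status == cause)) stop("no events of cause ", cause)
  ci <- cmprsk::cuminc(data$time, data$status, data$x, cencode = 0)
  row <- rownames(ci$Tests) == as.character(cause)
  .cr_test(sprintf("Gray's test, cause %d", cause),
           if (cause == 1) "H0F1" else "H0F2",
           ci$Tests[row, "stat"], as.integer(ci$Tests[row, "df"]),
           ci$Tests[row, "pv"])
}

#' Wald tests of no treatment effect from FG / DB fits
#'
#' Convenience wrappers turning a robust-variance model fit into a
#' `cr_test` of the CIF null \eqn{\beta = 0}.
#'
#' @param fit an [fg_fit()] or [db_fit()] result with a robust SE.
#' @return a `cr_test` (df = 1).
#' @export
wald_test <- function(fit) {
  if (inherits(fit, "fg_fit")) {
    z2 <- (fit$coef[["beta"]] / fit$se_robust)^2
    .cr_test("Fine-Gray robust Wald test", "H0F1", z2, 1,
             stats::pchisq(z2, 1, lower.tail = FALSE),
             estimate = fit$coef[["beta"]], se = fit$se_robust)
  } else if (inherits(fit, "db_fit")) {
    z2 <- (fit$coef[["beta"]] / fit$se_robust)^2
    .cr_test(sprintf("Direct binomial robust Wald test (R = %d)",
                     length(fit$grid)), "H0F1", z2, 1,
             stats::pchisq(z2, 1, lower.tail = FALSE),
             estimate = fit$coef[["beta"]], se = fit$se_robust)
  } else stop("`fit` must be an fg_fit or db_fit")
}

#' Sample size for the Fine-Gray Wald test
#'
#' Schoenfeld-type formula for the number of subjects needed so a
#' two-sided Wald test of \eqn{\beta = 0} at level `alpha` has the given
#' power against \eqn{\beta = \beta_1}:
#' \deqn{n = \frac{1}{P(T_1 \le C)} \cdot
#'   \frac{(z_{1-\alpha/2} + z_{power})^2}
#'        {\beta_1^2 \, P(X{=}1) P(X{=}0)},}
#' where \eqn{P(T_1 \le C)} is the proportion of observed events of
#' interest by the end of follow-up.  Derived under complete data (no
#' IPCW), so it is an approximation with random loss to follow-up.
#'
#' @param beta1 alternative log subdistribution hazard ratio (nonzero).
#' @param p_obs proportion of subjects with an observed event of interest.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param p_x randomization probability P(X = 1).
#' @return a list with `n` (ceiling) and `n_exact` (unrounded).
#' @examples
#' latouche_sample_size(log(0.75), p_obs = 0.5)  # n = 759
#' @export
latouche_sample_size <- function(beta1, p_obs, alpha = 0.05, power = 0.8,
                                 p_x = 0.5) {
  if (beta1 == 0) stop("`beta1` must be nonzero")
  stopifnot(p_obs > 0, p_obs <= 1, alpha > 0, alpha < 1, power > 0,
            power < 1, p_x > 0, p_x < 1)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n_exact <- z^2 / (p_obs * beta1^2 * p_x * (1 - p_x))
  list(n = ceiling(n_exact), n_exact = n_exact)
}
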