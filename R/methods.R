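## S3 methods for fitted CIF regression objects.

#' @export
coef.cif_fit <- function(object, ...) object$coef

#' @export
vcov.fg_fit <- function(object, ...) {
  matrix(object$se_robust^2, 1, 1, dimnames = list("beta", "beta"))
}

#' @export
vcov.db_fit <- function(object, ...) object$vcov

#' @export
print.fg_fit <- function(x, digits = 4, ...) {
  cat("Fine-Gray cloglog CIF regression (", x$weights, " IPCW weights)\n",
      sep = "")
  cat(sprintf("  n = %d, events of interest = %d, tau = %g\n", x$n,
              nrow(x$gamma_hat), x$tau))
  cat(sprintf("  beta = %.*f  (robust se %.*f, naive se %.*f)\n", digits,
              x$coef[["beta"]], digits, x$se_robust, digits, x$se_naive))
  if (!x$convergence$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
print.db_fit <- function(x, digits = 4, ...) {
  R <- length(x$grid)
  cat(sprintf("Direct binomial cloglog CIF regression (R = %d, %s variant)\n",
              R, x$variant))
  cat(sprintf("  n = %d, tau = %g, grid: %s\n", x$n, x$tau,
              paste(signif(x$grid, 3), collapse = ", ")))
  cat(sprintf("  beta = %.*f  (robust se %.*f)\n", digits,
              x$coef[["beta"]], digits, x$se_robust))
  if (!x$convergence$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
summary.fg_fit <- function(object, conf.level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  b <- object$coef[["beta"]]; se <- object$se_robust
  out <- list(fit = object,
              table = data.frame(
                estimate = b, exp_estimate = exp(b), se_robust = se,
                z = b / se,
                p.value = 2 * stats::pnorm(-abs(b / se)),
                lower = b - z * se, upper = b + z * se,
                row.names = "beta"),
              conf.level = conf.level)
  class(out) <- "summary.cif_fit"
  out
}

#' @export
summary.db_fit <- function(object, conf.level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  b <- object$coef[["beta"]]; se <- object$se_robust
  out <- list(fit = object,
              table = data.frame(
                estimate = b, exp_estimate = exp(b), se_robust = se,
                z = b / se,
                p.value = 2 * stats::pnorm(-abs(b / se)),
                lower = b - z * se, upper = b + z * se,
                row.names = "beta"),
              conf.level = conf.level)
  class(out) <- "summary.cif_fit"
  out
}

#' @export
print.summary.cif_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\n  %g%% Wald interval (robust):\n", 100 * x$conf.level))
  print(signif(x$table, 4))
  invisible(x)
}

#' Predicted cumulative incidence from a fitted CIF regression
#'
#' For a Fine-Gray fit, \eqn{\hat F_1(t \mid x) = 1 -
#' \exp(-\hat\Gamma(t) e^{\hat\beta x})} with the Breslow step function
#' \eqn{\hat\Gamma}; for a direct binomial fit,
#' \eqn{h(\hat\alpha_r + \hat\beta x)} at the grid times.
#'
#' @param object an `fg_fit` or `db_fit`.
#' @param times evaluation times (FG only; DB fits predict on their grid).
#' @param x treatment indicator, 0 or 1 (vectorized).
#' @param ... unused.
#' @return a data frame with columns `t`, `x`, `F1`.
#' @export
predict.fg_fit <- function(object, times = NULL, x = c(0, 1), ...) {
  if (is.null(times)) times <- object$gamma_hat$time
  step <- stats::stepfun(object$gamma_hat$time, c(0, object$gamma_hat$Gamma))
  out <- do.call(rbind, lapply(x, function(xi)
    data.frame(t = times, x = xi,
               F1 = 1 - exp(-step(times) * exp(object$coef[["beta"]] * xi)))))
  rownames(out) <- NULL
  out
}

#' @rdname predict.fg_fit
#' @export
predict.db_fit <- function(object, times = NULL, x = c(0, 1), ...) {
  R <- length(object$grid)
  alpha <- object$coef[seq_len(R)]
  if (!is.null(times)) {
    idx <- match(times, object$grid)
    if (anyNA(idx)) stop("DB fits predict only at their grid times")
  } else idx <- seq_len(R)
  out <- do.call(rbind, lapply(x, function(xi)
    data.frame(t = object$grid[idx], x = xi,
               F1 = cloglog_inv(alpha[idx] + object$coef[["beta"]] * xi))))
  rownames(out) <- NULL
  out
}

#' Plot fitted cumulative incidence curves
#'
#' @param x an `fg_fit` or `db_fit`.
#' @param ... passed to plotting primitives.
#' @return invisibly, the plotted prediction frame.
#' @export
plot.cif_fit <- function(x, ...) {
  pr <- predict(x)
  is_fg <- inherits(x, "fg_fit")
  plot(NULL, xlim = c(0, max(pr$t)), ylim = c(0, min(1, max(pr$F1) * 1.2)),
       xlab = "time", ylab = "cumulative incidence", ...)
  for (xi in unique(pr$x)) {
    d <- pr[pr$x == xi, ]
    if (is_fg) graphics::lines(stats::stepfun(d$t, c(0, d$F1)),
                               do.points = FALSE, col = xi + 1)
    else graphics::points(d$t, d$F1, col = xi + 1, pch = 16 + xi)
  }
  graphics::legend("topleft", legend = c("control", "treatment"),
                   col = 1:2, lty = 1, bty = "n")
  invisible(pr)
}

#' Residuals of a direct binomial fit
#'
#' IPCW-weighted response residuals \eqn{\tilde N_{1i}(s_r) -
#' h(\hat\alpha_r + \hat\beta x_i)}, one column per grid time.
#'
#' @param object a `db_fit`.
#' @param data the dataset the model was fitted to.
#' @param ... unused.
#' @return an n x R matrix.
#' @export
residuals.db_fit <- function(object, data, ...) {
  tau <- object$tau
  ghat <- km_censoring(data, "none", tau)
  R <- length(object$grid)
  Nt <- sapply(object$grid, function(sr)
    weighted_response(data, sr, ghat, tau))
  if (R == 1) Nt <- matrix(Nt, ncol = 1)
  mu <- sapply(seq_len(R), function(r)
    cloglog_inv(object$coef[r] + object$coef[["beta"]] * data$x))
  Nt - mu
}
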