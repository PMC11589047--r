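## Deterministic probability limits (estimands) of the FG and DB
## treatment-effect estimators under an arbitrary true competing risks
## process, assuming independent censoring and a correctly specified
## censoring model.

#' Expected Fine-Gray pseudo-score per subject
#'
#' Evaluates the large-sample limit of the (scaled) FG pseudo-score at a
#' candidate beta,
#' \deqn{\int_0^\tau G_w(t)\Big[s^{(1)}(t) -
#'   \frac{s_b^{(1)}(t,\beta)}{s_b^{(0)}(t,\beta)} s^{(0)}(t)\Big] dt,}
#' where \eqn{s^{(l)}(t) = \sum_x P(X{=}x) x^l f_1(t \mid x)} and
#' \eqn{s_b^{(l)}(t,\beta) = \sum_x P(X{=}x) x^l e^{\beta x}
#' (1 - F_1(t^- \mid x))}, by adaptive quadrature.
#'
#' The factor \eqn{G_w(t)} depends on the weight style whose estimand is
#' wanted.  For standard IPCW weights every weight has unit conditional
#' expectation and censoring drops out (\eqn{G_w \equiv 1}, `rho = 0`).
#' For stabilized weights (the `cmprsk::crr` convention and the package
#' default in [fg_fit()]) each subject's expected contribution at t is
#' proportional to the withdrawal survivor \eqn{G(t) = e^{-\rho t}}, so
#' the estimand depends on the censoring law; pass the withdrawal rate
#' `rho` (e.g. from [calibrate_censoring_rate()]) to obtain it.
#'
#' @param process a `cr_process`.
#' @param beta candidate log effect.
#' @param p_x randomization probability P(X = 1).
#' @param rho exponential withdrawal rate entering the stabilized-weight
#'   estimand; 0 (default) gives the standard-weight estimand.
#' @param tau upper integration limit; defaults to the process horizon.
#' @return the expected per-subject score (a number).
#' @export
expected_fg_score <- function(process, beta, p_x = 0.5, rho = 0,
                              tau = NULL) {
  if (is.null(tau)) tau <- process$tau
  integrand <- function(t) {
    f10 <- proc_f1(process, t, 0); f11 <- proc_f1(process, t, 1)
    s1 <- p_x * f11
    s0 <- (1 - p_x) * f10 + s1
    s1b <- p_x * exp(beta) * (1 - proc_F1(process, t, 1))
    s0b <- (1 - p_x) * (1 - proc_F1(process, t, 0)) + s1b
    r <- ifelse(s0b > 0, s1b / s0b, 0)   # nobody at risk: define as 0
    gw <- if (rho > 0) exp(-rho * t) else 1
    gw * (s1 - r * s0)
  }
  stats::integrate(integrand, 0, tau, rel.tol = 1e-12,
                   abs.tol = 1e-14)$value
}

#' Probability limit of the Fine-Gray estimator
#'
#' Solves the expected pseudo-score equation for the limiting value
#' \eqn{\beta^\star_{FG}} by Brent's method on [-5, 5], and accumulates the
#' limiting baseline cumulative subdistribution hazard
#' \deqn{\Gamma^\star(t) = \int_0^t
#'   \frac{\sum_x P(x) f_1(u \mid x)}
#'        {\sum_x P(x) e^{\beta^\star x}(1 - F_1(u^- \mid x))}\,du}
#' on a fine grid (this increment is the same for both weight styles).
#' When the cloglog model for \eqn{F_1} actually holds the limit equals
#' the generating beta; under an intensity-based truth it is a functional
#' of all process intensities.
#'
#' @inheritParams expected_fg_score
#' @param grid_n number of grid points for the baseline-limit curve.
#' @return an object of class `fg_limit`: `beta_star`, `curve` (a data
#'   frame `t`, `Gamma_star`, `alpha_star`), solver `diagnostics`.
#' @seealso [db_limit()], [limit_cif()]
#' @export
fg_limit <- function(process, p_x = 0.5, rho = 0, grid_n = 400) {
  es <- function(b) expected_fg_score(process, b, p_x, rho)
  lo <- es(-5); hi <- es(5)
  if (sign(lo) == sign(hi))
    stop("expected score has no sign change on [-5, 5]; score at -5: ",
         signif(lo, 4), ", at 5: ", signif(hi, 4))
  sol <- stats::uniroot(es, c(-5, 5), tol = 1e-12)
  bs <- sol$root
  tg <- seq(0, process$tau, length.out = grid_n + 1)
  dint <- function(t) {
    num <- (1 - p_x) * proc_f1(process, t, 0) + p_x * proc_f1(process, t, 1)
    den <- (1 - p_x) * (1 - proc_F1(process, t, 0)) +
      p_x * exp(bs) * (1 - proc_F1(process, t, 1))
    num / den
  }
  mid <- (tg[-1] + tg[-length(tg)]) / 2
  Gam <- c(0, cumsum(dint(mid) * diff(tg)))
  structure(list(beta_star = bs,
                 curve = data.frame(t = tg, Gamma_star = Gam,
                                    alpha_star = log(pmax(Gam, 1e-300))),
                 p_x = p_x, rho = rho,
                 diagnostics = list(residual = es(bs), iter = sol$iter,
                                    estim.prec = sol$estim.prec)),
            class = "fg_limit")
}

#' Probability limit of the direct binomial estimator
#'
#' Solves the R + 1 expected estimating equations
#' \deqn{\sum_x P(x) \frac{h'(\alpha_r + \beta x)}
#'   {h(\cdot)(1 - h(\cdot))}\{F_1(s_r \mid x) - h(\alpha_r + \beta x)\} = 0,}
#' \deqn{\sum_r P(X{=}1) \frac{h'(\alpha_r + \beta)}
#'   {h(\cdot)(1 - h(\cdot))}\{F_1(s_r \mid 1) - h(\alpha_r + \beta)\} = 0}
#' for \eqn{(\alpha^\star, \beta^\star)} by Newton iteration with a
#' numerical Jacobian, initialized at the true control-arm transforms
#' \eqn{\alpha_r = g(F_1(s_r \mid 0))} and beta = 0.  The weighted
#' responses are conditionally unbiased for \eqn{F_1(s_r \mid x)} under a
#' correct censoring model, so the DB estimand does not involve the
#' censoring law.
#'
#' @inheritParams expected_fg_score
#' @param grid evaluation times; defaults to [db_grid()] with `R` points.
#' @param R number of grid points when `grid` is not given.
#' @return an object of class `db_limit`: `beta_star`, `alpha_star`,
#'   `grid`, solver `diagnostics`.
#' @export
db_limit <- function(process, grid = NULL, R = 6, p_x = 0.5) {
  tau <- process$tau
  if (is.null(grid)) grid <- db_grid(R, tau)
  if (any(diff(grid) <= 0) || any(grid <= 0) || any(grid >= tau + 1e-12))
    stop("`grid` must be strictly increasing inside (0, tau)")
  R <- length(grid)
  F10 <- proc_F1(process, grid, 0); F11 <- proc_F1(process, grid, 1)
  if (any(F10 <= 0) || any(F11 <= 0))
    stop("F1(s_r | x) must be positive at every grid point")
  U <- function(th) {
    a <- th[seq_len(R)]; b <- th[R + 1]
    w0 <- cloglog_inv_deriv(a) /
      (cloglog_inv(a) * (1 - cloglog_inv(a)))
    w1 <- cloglog_inv_deriv(a + b) /
      (cloglog_inv(a + b) * (1 - cloglog_inv(a + b)))
    ua <- (1 - p_x) * w0 * (F10 - cloglog_inv(a)) +
      p_x * w1 * (F11 - cloglog_inv(a + b))
    c(ua, sum(p_x * w1 * (F11 - cloglog_inv(a + b))))
  }
  th <- c(cloglog(F10), 0)
  conv <- FALSE
  for (it in 1:200) {
    u0 <- U(th)
    J <- matrix(0, R + 1, R + 1)
    for (j in seq_len(R + 1)) {
      e <- th; e[j] <- e[j] + 1e-6
      J[, j] <- (U(e) - u0) / 1e-6
    }
    step <- tryCatch(solve(J, -u0),
                     error = function(e) solve(J + diag(1e-10, R + 1), -u0))
    ## damped Newton on the residual norm
    lam <- 1
    repeat {
      thn <- th + lam * step
      if (sum(U(thn)^2) <= sum(u0^2) || lam < 1e-4) break
      lam <- lam / 2
    }
    th <- th + lam * step
    if (max(abs(lam * step)) < 1e-12) { conv <- TRUE; break }
  }
  resid <- sqrt(sum(U(th)^2))
  if (!conv && resid > 1e-8)
    warning("DB limit Newton iteration did not fully converge; ",
            "residual norm ", signif(resid, 3))
  structure(list(beta_star = th[R + 1], alpha_star = th[seq_len(R)],
                 grid = grid, p_x = p_x,
                 diagnostics = list(residual = resid, iterations = it,
                                    converged = conv)),
            class = "db_limit")
}

#' Limiting fitted CIF curves
#'
#' Evaluates the cumulative incidence function implied by a solved
#' probability limit: \eqn{1 - \exp(-\Gamma^\star(t) e^{\beta^\star x})}
#' for an FG limit (with \eqn{\Gamma^\star} interpolated on its grid) or
#' \eqn{h(\alpha_r^\star + \beta^\star x)} at the grid times for a DB
#' limit.
#'
#' @param limit an `fg_limit` or `db_limit`.
#' @param t evaluation times (FG limits only; DB limits use their grid).
#' @param x treatment indicator, 0 or 1.
#' @return numeric vector of limiting CIF values.
#' @export
limit_cif <- function(limit, t = NULL, x = 0) {
  stopifnot(x %in% c(0, 1))
  if (inherits(limit, "fg_limit")) {
    if (is.null(t)) t <- limit$curve$t
    Gam <- stats::approx(limit$curve$t, limit$curve$Gamma_star, xout = t,
                         rule = 2)$y
    1 - exp(-Gam * exp(limit$beta_star * x))
  } else if (inherits(limit, "db_limit")) {
    cloglog_inv(limit$alpha_star + limit$beta_star * x)
  } else stop("`limit` must be an fg_limit or db_limit")
}

#' @export
print.fg_limit <- function(x, ...) {
  cat("Fine-Gray probability limit (estimand)\n")
  cat(sprintf("  beta* = %.6f  (exp(beta*) = %.4f)\n", x$beta_star,
              exp(x$beta_star)))
  cat(sprintf("  P(X=1) = %g; withdrawal rate in weights: %g\n", x$p_x,
              x$rho))
  cat(sprintf("  score residual at root: %.2e\n", x$diagnostics$residual))
  invisible(x)
}

#' @export
print.db_limit <- function(x, ...) {
  cat("Direct binomial probability limit (estimand)\n")
  cat(sprintf("  beta* = %.6f  (exp(beta*) = %.4f), R = %d grid points\n",
              x$beta_star, exp(x$beta_star), length(x$grid)))
  cat(sprintf("  residual norm: %.2e\n", x$diagnostics$residual))
  invisible(x)
}
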