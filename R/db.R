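## Direct binomial regression of the cloglog CIF model on a grid of time
## points, by IPCW-weighted estimating equations under working
## independence.  With a binary treatment indicator every quantity is a
## per-arm aggregate, so the Newton iterations cost O(R) regardless of n.

#' Default direct-binomial time grid
#'
#' R equi-spaced points strictly inside (0, tau): \eqn{s_r = r\tau/(R+1)}.
#' This is the convention under which the package's deterministic estimand
#' calculator reproduces its reference values; see the methods vignette.
#'
#' @param R number of grid points.
#' @param tau administrative horizon.
#' @return numeric vector of length `R`.
#' @export
db_grid <- function(R = 6, tau = 1) seq_len(R) * tau / (R + 1)

## per-arm sufficient statistics for the DB equations
.db_prep <- function(data, grid, ghat, tau) {
  R <- length(grid)
  Ntil <- sapply(grid, function(sr) weighted_response(data, sr, ghat, tau))
  if (R == 1) Ntil <- matrix(Ntil, ncol = 1)
  arms <- lapply(0:1, function(a) {
    sel <- data$x == a
    list(n = sum(sel), Nbar = colMeans(Ntil[sel, , drop = FALSE]),
         Ntil = Ntil[sel, , drop = FALSE])
  })
  for (a in 0:1) {
    evby <- colSums(data$x == a & data$status == 1 &
                      outer(data$time, grid, `<=`))
    if (any(evby == 0))
      warning("no observed events of interest by s_r = ",
              paste(signif(grid[evby == 0], 4), collapse = ", "),
              " in arm ", a, "; alpha_r weakly identified")
  }
  list(grid = grid, R = R, Ntil = Ntil, arms = arms, x = data$x)
}

## U(theta) and Gauss-Newton curvature from per-arm aggregates
.db_score <- function(prep, theta, clip = 1e-10) {
  if (isTRUE(prep$ee)) return(.db_score_ee(prep, theta, clip))
  R <- prep$R
  alpha <- theta[seq_len(R)]; beta <- theta[R + 1]
  U <- numeric(R + 1)
  I <- matrix(0, R + 1, R + 1)
  for (a in 0:1) {
    lp <- alpha + beta * a
    mu <- pmin(pmax(cloglog_inv(lp), clip), 1 - clip)
    hp <- cloglog_inv_deriv(lp)
    v <- mu * (1 - mu)
    na <- prep$arms[[a + 1]]$n
    res <- prep$arms[[a + 1]]$Nbar - mu
    w <- hp / v
    U[seq_len(R)] <- U[seq_len(R)] + na * w * res
    if (a == 1) U[R + 1] <- sum(na * w * res)
    ## D' A^{-1} D blocks
    dia <- na * hp^2 / v
    diag(I)[seq_len(R)] <- diag(I)[seq_len(R)] + dia
    if (a == 1) {
      I[R + 1, seq_len(R)] <- I[R + 1, seq_len(R)] + dia
      I[seq_len(R), R + 1] <- I[seq_len(R), R + 1] + dia
      I[R + 1, R + 1] <- I[R + 1, R + 1] + sum(dia)
    }
  }
  list(U = U, I = I)
}

.db_solve <- function(prep, init = NULL, maxit = 100, tol = 1e-10) {
  R <- prep$R
  theta <- if (!is.null(init)) init else {
    p0 <- if (isTRUE(prep$ee))
      prep$arms[[1]]$WNsum / pmax(prep$arms[[1]]$Wtot, 1e-12)
    else prep$arms[[1]]$Nbar
    c(cloglog(pmin(pmax(p0, 1e-6), 1 - 1e-6)), 0)
  }
  conv <- FALSE
  for (it in seq_len(maxit)) {
    sc <- .db_score(prep, theta)
    step <- tryCatch(solve(sc$I, sc$U), error = function(e) NULL)
    if (is.null(step)) {    # damped fallback
      step <- solve(sc$I + diag(1e-8, R + 1), sc$U)
    }
    half <- 0
    repeat {
      thn <- theta + step
      Un <- .db_score(prep, thn)$U
      if (sum(Un^2) <= sum(sc$U^2) || half >= 20) break
      step <- step / 2; half <- half + 1
    }
    theta <- theta + step
    if (max(abs(step)) < tol) { conv <- TRUE; break }
  }
  sc <- .db_score(prep, theta)
  list(theta = theta, converged = conv, iterations = it, score = sc$U,
       I = sc$I)
}

## per-subject estimating-function contributions, (R+1) columns
.db_infl <- function(prep, theta, data, ghat, tau, clip = 1e-10) {
  R <- prep$R
  n <- nrow(data)
  alpha <- theta[seq_len(R)]; beta <- theta[R + 1]
  Umat <- matrix(0, n, R + 1)
  Bx <- list()
  for (a in 0:1) {
    lp <- alpha + beta * a
    mu <- pmin(pmax(cloglog_inv(lp), clip), 1 - clip)
    hp <- cloglog_inv_deriv(lp)
    w <- hp / (mu * (1 - mu))            # row weights of D'A^{-1}
    sel <- which(data$x == a)
    res <- if (isTRUE(prep$ee)) {
      arm <- prep$arms[[a + 1]]
      arm$Ntil - arm$Wmat * matrix(mu, length(sel), R, byrow = TRUE)
    } else {
      prep$Ntil[sel, , drop = FALSE] -
        matrix(mu, length(sel), R, byrow = TRUE)
    }
    wres <- res * matrix(w, length(sel), R, byrow = TRUE)
    Umat[sel, seq_len(R)] <- wres
    if (a == 1) Umat[sel, R + 1] <- rowSums(wres)
    Bx[[a + 1]] <- w
  }
  ## censoring-estimation influence: Ntil_i(s_r) = d1_i 1(u_i<=s_r)/G(u_i-)
  ## perturbs through 1/G(u_i-), indicator 1(s <= u_i)
  ## (the censoring-influence correction below is derived for the
  ## weighted-response variant; the EE variant's sandwich omits it and the
  ## bootstrap is the reference there)
  cidx <- which(data$status == 0 & data$time < tau - 1e-12)
  if (length(cidx) > 0 && !isTRUE(prep$ee) &&
      inherits(ghat, "censoring_km") && ghat$strata == "none") {
    u <- data$time
    ct <- sort(unique(u[cidx])); K <- length(ct)
    su <- sort(u)
    Yc <- n - findInterval(ct, su, left.open = TRUE)
    dc <- tabulate(match(u[cidx], ct), K)
    ## v_i = row of D'A^{-1} applied to the Ntil column pattern of i
    ev <- which(data$status == 1)
    if (length(ev)) {
      Vi <- matrix(0, length(ev), R + 1)
      for (a in 0:1) {
        ss <- data$x[ev] == a
        if (!any(ss)) next
        ntl <- prep$Ntil[ev[ss], , drop = FALSE]
        wn <- ntl * matrix(Bx[[a + 1]], sum(ss), R, byrow = TRUE)
        Vi[ss, seq_len(R)] <- wn
        if (a == 1) Vi[ss, R + 1] <- rowSums(wn)
      }
      o <- order(u[ev])
      uev <- u[ev][o]; Vi <- Vi[o, , drop = FALSE]
      cV <- apply(Vi, 2, function(v) rev(cumsum(rev(v))))
      idx <- findInterval(ct, uev, left.open = TRUE) + 1  # first u_ev >= s
      q <- matrix(0, K, R + 1)
      ok <- idx <= length(uev)
      q[ok, ] <- cV[idx[ok], , drop = FALSE]
      rate <- q * (dc / Yc^2)
      crate <- apply(rate, 2, cumsum)
      idx2 <- findInterval(u, ct)
      okk <- idx2 > 0
      Umat[okk, ] <- Umat[okk, ] - crate[idx2[okk], , drop = FALSE]
      kk <- match(u[cidx], ct)
      Umat[cidx, ] <- Umat[cidx, ] + q[kk, , drop = FALSE] / Yc[kk]
    }
  }
  Umat
}

#' Direct binomial regression of the cloglog CIF model
#'
#' Solves the IPCW-weighted binomial estimating equations for
#' \eqn{\theta = (\alpha_1, \ldots, \alpha_R, \beta)} in
#' \eqn{F_1(s_r \mid x) = 1 - \exp(-e^{\alpha_r + \beta x})} at R grid
#' times, under a working-independence covariance.  The default variant
#' weights the state-1 occupancy indicators
#' (\eqn{\tilde N_{1i}(s_r)}, see [weighted_response()]); the
#' `"ee"` variant instead weights the estimating equations with
#' \eqn{w_i(s_r)} and the raw indicators, so subjects censored before
#' \eqn{\min(T_i, s_r)} contribute nothing at \eqn{s_r}.  Both have the
#' same probability limit when the censoring model is correct.
#'
#' @inheritParams fg_fit
#' @param grid evaluation times; defaults to [db_grid()] with `R` points.
#' @param R number of grid points when `grid` is not given.
#' @param variant `"response"` (weighted responses) or `"ee"` (weighted
#'   estimating equations).
#' @return an object of class `c("db_fit", "cif_fit")` with `coef`
#'   (alpha vector and beta), robust `vcov`, `se_robust` for beta,
#'   `grid`, and a `convergence` record.
#' @seealso [fg_fit()], [db_limit()], [db_contrast_test()]
#' @export
db_fit <- function(data, grid = NULL, R = 6,
                   variant = c("response", "ee"),
                   variance = c("sandwich", "bootstrap", "none"),
                   ghat = NULL, strata = c("none", "x"), n_boot = 500,
                   tau = NULL, seed = NULL) {
  variant <- match.arg(variant)
  variance <- match.arg(variance)
  strata <- match.arg(strata)
  tau <- .get_tau(data, tau)
  if (is.null(grid)) grid <- db_grid(R, tau)
  if (any(diff(grid) <= 0) || any(grid <= 0) || any(grid > tau))
    stop("`grid` must be strictly increasing inside (0, tau]")
  if (is.null(ghat)) ghat <- km_censoring(data, strata, tau)
  prep <- .db_prep2(data, grid, ghat, tau, variant)
  sol <- .db_solve(prep)
  if (!sol$converged)
    warning("direct binomial Newton iteration did not converge")
  R <- length(grid)
  vcov <- matrix(NA_real_, R + 1, R + 1)
  if (variance == "sandwich") {
    if (strata == "x") {
      warning("analytic sandwich implemented for the unstratified ",
              "censoring model; falling back to bootstrap")
      variance <- "bootstrap"
    } else {
      Ui <- .db_infl(prep, sol$theta, data, ghat, tau)
      Iinv <- solve(sol$I)
      vcov <- Iinv %*% crossprod(Ui) %*% Iinv
    }
  }
  if (variance == "bootstrap") {
    if (!is.null(seed)) set.seed(seed)
    bb <- replicate(n_boot, {
      idx <- sample.int(nrow(data), replace = TRUE)
      db <- data[idx, ]
      tryCatch({
        gb <- km_censoring(db, strata, tau)
        .db_solve(.db_prep2(db, grid, gb, tau, variant))$theta
      }, error = function(e) rep(NA_real_, R + 1))
    })
    vcov <- stats::var(t(bb), na.rm = TRUE)
  }
  theta <- sol$theta
  names(theta) <- c(paste0("alpha", seq_len(R)), "beta")
  structure(list(coef = theta, vcov = vcov,
                 se_robust = sqrt(vcov[R + 1, R + 1]),
                 grid = grid, variant = variant, variance = variance,
                 n = nrow(data), tau = tau,
                 convergence = list(converged = sol$converged,
                                    iterations = sol$iterations,
                                    score = sol$score)),
            class = c("db_fit", "cif_fit"))
}

## variant dispatch: the "ee" variant replaces the weighted responses by
## w_i(s_r) * N_1i(s_r) and subtracts w_i(s_r) * mu instead of mu, which
## in aggregate form means per-(arm, r) weight totals replace counts.
.db_prep2 <- function(data, grid, ghat, tau, variant = "response") {
  if (variant == "response") return(.db_prep(data, grid, ghat, tau))
  R <- length(grid)
  W <- sapply(grid, function(sr)
    ipcw_weight(data, sr, ghat, style = "standard", tau = tau))
  if (R == 1) W <- matrix(W, ncol = 1)
  N1 <- outer(data$time, grid, `<=`) * (data$status == 1)
  WN <- W * N1
  arms <- lapply(0:1, function(a) {
    sel <- data$x == a
    ## per-arm "effective" mean response and weight totals: the score at
    ## (arm, r) is  sum_i w_i (N1_i - mu) = Wtot*(Nbar_w - mu) with
    ## Nbar_w = sum(w N1)/sum(w); keep sums to preserve the equations
    list(n = sum(sel), Wtot = colSums(W[sel, , drop = FALSE]),
         WNsum = colSums(WN[sel, , drop = FALSE]),
         Ntil = WN[sel, , drop = FALSE], Wmat = W[sel, , drop = FALSE])
  })
  structure(list(grid = grid, R = R, Ntil = WN, arms = arms, x = data$x,
                 ee = TRUE), class = "db_prep_ee")
}

## score for the EE variant: sum_i d_r/v_r w_i(s_r) (N1_i - mu_r)
.db_score_ee <- function(prep, theta, clip = 1e-10) {
  R <- prep$R
  alpha <- theta[seq_len(R)]; beta <- theta[R + 1]
  U <- numeric(R + 1)
  I <- matrix(0, R + 1, R + 1)
  for (a in 0:1) {
    lp <- alpha + beta * a
    mu <- pmin(pmax(cloglog_inv(lp), clip), 1 - clip)
    hp <- cloglog_inv_deriv(lp)
    v <- mu * (1 - mu)
    w <- hp / v
    arm <- prep$arms[[a + 1]]
    res <- arm$WNsum - arm$Wtot * mu
    U[seq_len(R)] <- U[seq_len(R)] + w * res
    if (a == 1) U[R + 1] <- sum(w * res)
    dia <- arm$Wtot * hp^2 / v
    diag(I)[seq_len(R)] <- diag(I)[seq_len(R)] + dia
    if (a == 1) {
      I[R + 1, seq_len(R)] <- I[R + 1, seq_len(R)] + dia
      I[seq_len(R), R + 1] <- I[seq_len(R), R + 1] + dia
      I[R + 1, R + 1] <- I[R + 1, R + 1] + sum(dia)
    }
  }
  list(U = U, I = I)
}

#' Per-time-effect Wald test of a constant treatment effect (DB)
#'
#' Fits the saturated per-time model
#' \eqn{g(F_1(s_r \mid x)) = \alpha_r + \beta_r x} (closed form under
#' working independence: \eqn{\hat\alpha_r = g(\bar N_{r0})},
#' \eqn{\hat\beta_r = g(\bar N_{r1}) - g(\bar N_{r0})}), estimates the
#' covariance of \eqn{\hat\beta^\dagger = (\hat\beta_1, \ldots,
#' \hat\beta_R)} by a subject-level bootstrap (re-estimating the censoring
#' distribution in each resample), and refers
#' \eqn{(C\hat\beta^\dagger)'(C\hat\Sigma C')^{-1}C\hat\beta^\dagger}
#' to a chi-squared distribution with R - 1 degrees of freedom, where C is
#' the successive-difference contrast matrix.
#'
#' @inheritParams db_fit
#' @param n_boot bootstrap replicates for the covariance of
#'   \eqn{\hat\beta^\dagger}.
#' @param seed optional seed for the bootstrap.
#' @return an object of class `db_contrast_test` with the per-time
#'   effects, contrast matrix, statistic, df and p-value.
#' @export
db_contrast_test <- function(data, grid = NULL, R = 6, ghat = NULL,
                             n_boot = 500, tau = NULL, seed = NULL) {
  tau <- .get_tau(data, tau)
  if (is.null(grid)) grid <- db_grid(R, tau)
  R <- length(grid)
  if (R < 2) stop("the contrast test needs at least two grid points")
  if (is.null(ghat)) ghat <- km_censoring(data, "none", tau)
  bdag <- function(d, g) {
    Nt <- sapply(grid, function(sr) weighted_response(d, sr, g, tau))
    if (R == 1) Nt <- matrix(Nt, ncol = 1)
    p0 <- colMeans(Nt[d$x == 0, , drop = FALSE])
    p1 <- colMeans(Nt[d$x == 1, , drop = FALSE])
    p0 <- pmin(pmax(p0, 1e-10), 1 - 1e-10)
    p1 <- pmin(pmax(p1, 1e-10), 1 - 1e-10)
    cloglog(p1) - cloglog(p0)
  }
  beta_dag <- bdag(data, ghat)
  if (!is.null(seed)) set.seed(seed)
  bb <- replicate(n_boot, {
    idx <- sample.int(nrow(data), replace = TRUE)
    d2 <- data[idx, ]
    tryCatch(bdag(d2, km_censoring(d2, "none", tau)),
             error = function(e) rep(NA_real_, R))
  })
  Sig <- stats::var(t(bb), na.rm = TRUE)
  C <- matrix(0, R - 1, R)
  for (j in seq_len(R - 1)) { C[j, j] <- 1; C[j, j + 1] <- -1 }
  M <- C %*% Sig %*% t(C)
  cb <- drop(C %*% beta_dag)
  qr.M <- qr(M)
  df <- qr.M$rank
  stat <- if (df == R - 1) drop(t(cb) %*% solve(M, cb)) else {
    warning("contrast covariance singular; using pseudo-inverse with ",
            "rank-adjusted df")
    drop(t(cb) %*% qr.coef(qr.M, cb))
  }
  structure(list(beta_dagger = beta_dag, C = C, sigma = Sig,
                 statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 grid = grid, n_boot = n_boot),
            class = "db_contrast_test")
}

#' @export
print.db_contrast_test <- function(x, ...) {
  cat("Wald test of a constant treatment effect across the DB grid\n")
  cat("  per-time effects:", paste(sprintf("%.3f", x$beta_dagger),
                                   collapse = ", "), "\n")
  cat(sprintf("  X2 = %.3f, df = %d, p = %.4g  (%d bootstrap resamples)\n",
              x$statistic, x$df, x$p.value, x$n_boot))
  invisible(x)
}
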