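#' Kaplan-Meier estimate of the censoring survivor function
#'
#' Estimates \eqn{G(u) = P(C_r > u)} for the random-withdrawal time by
#' role-reversed Kaplan-Meier: records with status 0 before the
#' administrative horizon are "events" for the censoring process, all other
#' records are censored for it.  Administrative censoring at `tau` is not
#' part of G; it is carried by the \eqn{1(t \le \tau)} factor of the
#' weights.  When an event and a withdrawal share a time, events precede
#' censorings in the risk-set bookkeeping (the usual survival convention).
#'
#' @param data observed dataset (`time`, `status`, `x` columns).
#' @param strata `"none"` for a common censoring distribution or `"x"` for
#'   per-arm Kaplan-Meier estimates.
#' @param tau administrative horizon; defaults to the dataset attribute.
#' @return an object of class `censoring_km`; evaluate it with
#'   [ipcw_ghat()].
#' @export
km_censoring <- function(data, strata = c("none", "x"), tau = NULL) {
  strata <- match.arg(strata)
  if (nrow(data) == 0) stop("empty dataset")
  tau <- .get_tau(data, tau)
  fit1 <- function(u, st) {
    dc <- st == 0 & u < tau - 1e-12
    ot <- sort(unique(u[dc]))
    if (!length(ot)) return(list(t = numeric(0), s = numeric(0)))
    su <- sort(u)
    ## events at the same u precede censorings: risk set counts u_i >= t
    nrisk <- length(su) - findInterval(ot, su, left.open = TRUE)
    nev <- tabulate(match(u[dc], ot), length(ot))
    list(t = ot, s = cumprod(1 - nev / nrisk))
  }
  est <- if (strata == "none") {
    list(all = fit1(data$time, data$status))
  } else {
    list(`0` = fit1(data$time[data$x == 0], data$status[data$x == 0]),
         `1` = fit1(data$time[data$x == 1], data$status[data$x == 1]))
  }
  structure(list(strata = strata, tau = tau, est = est),
            class = "censoring_km")
}

#' Evaluate the estimated censoring survivor function
#'
#' @param ghat a [km_censoring()] estimate.
#' @param t evaluation times.
#' @param x treatment indicator (used only for stratified estimates).
#' @param left if `TRUE` (default) return the left limit
#'   \eqn{\hat G(t^-)}, the convention used inside all weights.
#' @return numeric vector of survivor probabilities.
#' @export
ipcw_ghat <- function(ghat, t, x = 0, left = TRUE) {
  stopifnot(inherits(ghat, "censoring_km"))
  ev1 <- function(km, tt) {
    if (!length(km$t)) return(rep(1, length(tt)))
    idx <- findInterval(tt, km$t, left.open = left)
    c(1, km$s)[idx + 1]
  }
  if (ghat$strata == "none") return(ev1(ghat$est$all, t))
  n <- max(length(t), length(x))
  t <- rep_len(t, n); x <- rep_len(x, n)
  out <- numeric(n)
  out[x == 0] <- ev1(ghat$est$`0`, t[x == 0])
  out[x == 1] <- ev1(ghat$est$`1`, t[x == 1])
  out
}

#' @export
print.censoring_km <- function(x, ...) {
  cat("Kaplan-Meier censoring-survivor estimate (",
      if (x$strata == "none") "unstratified" else "stratified by treatment",
      ")\n", sep = "")
  nj <- sum(vapply(x$est, function(e) length(e$t), 0L))
  cat(sprintf("  %d withdrawal time(s); tau = %g\n", nj, x$tau))
  invisible(x)
}

#' Inverse-probability-of-censoring weights
#'
#' The weight of record i at analysis time t is
#' \deqn{w_i(t) = 1(t \le \tau)\,
#'   \frac{1(C_{ri} > \min(T_i, t))}{\hat G(\min(T_i, t)^-)},}
#' which is computable from observed data: it is \eqn{1/\hat G(t^-)} while
#' the subject is under observation and event-free, freezes at
#' \eqn{1/\hat G(T_i^-)} after an observed event, and drops to 0 after loss
#' to follow-up.  The stabilized variant multiplies by \eqn{\hat G(t^-)},
#' so a subject still under observation has weight 1.
#'
#' @param data observed dataset.
#' @param t a single analysis time.
#' @param ghat a [km_censoring()] estimate.
#' @param style `"standard"` or `"stabilized"`.
#' @param tau administrative horizon.
#' @return numeric vector of weights, one per record.
#' @export
ipcw_weight <- function(data, t, ghat, style = c("standard", "stabilized"),
                        tau = NULL) {
  style <- match.arg(style)
  tau <- .get_tau(data, tau)
  if (t > tau) return(numeric(nrow(data)))
  u <- data$time; st <- data$status; x <- data$x
  mt <- pmin(u, t)                       # = min(T_i, t) when observable
  w <- numeric(nrow(data))
  active <- (u >= t) | (st > 0)          # not lost before min(T, t)
  gm <- ipcw_ghat(ghat, mt, x, left = TRUE)
  bad <- active & gm <= 0
  if (any(bad))
    stop("estimated censoring survivor is 0 at time ",
         signif(min(mt[bad]), 6), "; weight undefined")
  w[active] <- 1 / gm[active]
  if (style == "stabilized") w <- w * ipcw_ghat(ghat, t, x, left = TRUE)
  w
}

#' IPCW-weighted state-1 occupancy response
#'
#' The weighted response used in direct binomial regression,
#' \eqn{\tilde N_{1i}(s_r) = 1(C_{ri} \ge \min(T_i, s_r)) N_{1i}(s_r) /
#' \hat G(\min(T_i, s_r)^-)}: nonzero (and equal to
#' \eqn{1/\hat G(T_i^-)}) only for subjects with an observed event of
#' interest by \eqn{s_r}.  Under independent censoring and a correct
#' censoring model it has the same expectation as the latent indicator
#' \eqn{N_{1i}(s_r)}.
#'
#' @param data observed dataset.
#' @param sr a single grid time (<= tau).
#' @param ghat a [km_censoring()] estimate.
#' @param tau administrative horizon.
#' @return numeric vector, one entry per record.
#' @export
weighted_response <- function(data, sr, ghat, tau = NULL) {
  tau <- .get_tau(data, tau)
  if (sr > tau) stop("grid time exceeds the administrative horizon")
  hit <- data$status == 1 & data$time <= sr
  out <- numeric(nrow(data))
  if (any(hit)) {
    g <- ipcw_ghat(ghat, data$time[hit], data$x[hit], left = TRUE)
    if (any(g <= 0))
      stop("estimated censoring survivor is 0 at an event time; ",
           "weighted response undefined")
    out[hit] <- 1 / g
  }
  out
}
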