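#' Draw latent competing-risks samples from a true process
#'
#' For the intensity-based family the exit time T is exponential with rate
#' \eqn{\Lambda(x) = \lambda_1 e^{\gamma_1 x} + \lambda_2 e^{\gamma_2 x}}
#' and the event type is a Bernoulli draw with probability
#' \eqn{\lambda_{01}(x)/\Lambda(x)} of being the event of interest.  For
#' the CIF-based families, T is generated by inversion: a standard uniform
#' u is equated to \eqn{F_1(t \mid x) + F_2(t \mid x)} and solved for t by
#' bracketed root-finding on \eqn{[0, 50\tau]}; the type is then Bernoulli
#' with probability \eqn{\lambda^\dagger_{01}(t\mid x) /
#' (\lambda^\dagger_{01} + \lambda^\dagger_{02})(t \mid x)}.  Draws with u
#' beyond the total incidence reachable at \eqn{50\tau} get `T = Inf`
#' (administratively censored downstream).
#'
#' @param process a `cr_process`.
#' @param n number of subjects.
#' @param p_x randomization probability P(X = 1).
#' @param seed optional integer seed (local to this call).
#' @return a `data.frame` with columns `T` (exit time), `type` (1 or 2) and
#'   `x`.
#' @export
draw_competing_risks <- function(process, n, p_x = 0.5, seed = NULL) {
  stopifnot(n >= 0, p_x > 0, p_x < 1)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0)
    return(data.frame(T = numeric(0), type = integer(0), x = integer(0)))
  x <- stats::rbinom(n, 1, p_x)
  if (inherits(process, "intensity_process")) {
    a1 <- .rate1(process, x); L <- a1 + .rate2(process, x)
    T <- stats::rexp(n, L)
    type <- 1L + stats::rbinom(n, 1, 1 - a1 / L)
  } else {
    u <- stats::runif(n)
    T <- .invert_total_cif(process, u, x)
    p1 <- rep(NA_real_, n)
    fin <- is.finite(T)
    if (any(fin)) {
      f1 <- proc_f1(process, T[fin], x[fin])
      f2 <- proc_f2(process, T[fin], x[fin])
      p1[fin] <- f1 / (f1 + f2)
    }
    type <- rep(NA_integer_, n)
    type[fin] <- 1L + stats::rbinom(sum(fin), 1, 1 - p1[fin])
  }
  data.frame(T = T, type = type, x = x)
}

## solve F1(t|x)+F2(t|x) = u for t on [0, 50 tau] by vectorized bisection
## (the total CIF is strictly increasing); tolerance 1e-10
.invert_total_cif <- function(pr, u, x) {
  hi <- 50 * pr$tau
  tot <- function(t, xi) proc_F1(pr, t, xi) + proc_F2(pr, t, xi)
  out <- rep(Inf, length(u))
  for (xi in unique(x)) {
    sel <- which(x == xi)
    solvable <- sel[u[sel] <= tot(hi, xi)]
    if (!length(solvable)) next
    uu <- u[solvable]
    lo <- rep(0, length(uu)); up <- rep(hi, length(uu))
    for (it in seq_len(ceiling(log2(hi / 1e-10)))) {
      mid <- (lo + up) / 2
      below <- tot(mid, xi) < uu
      lo[below] <- mid[below]
      up[!below] <- mid[!below]
    }
    out[solvable] <- (lo + up) / 2
  }
  out
}

#' Calibrate the random-withdrawal rate to a target loss fraction
#'
#' Finds the exponential rate rho such that the fraction of type 1 events
#' occurring by `tau` that are lost to random withdrawal,
#' \deqn{\pi_r = E_X\{P(C_r < T_1 \mid T_1 \le \min(T_2, \tau), X)\}
#'   = \sum_x P(X = x) \frac{\int_0^\tau (1 - e^{-\rho t})
#'     f_1(t \mid x)\,dt}{F_1(\tau \mid x)},}
#' equals `pi_r`.  The outer average is the expectation over the treatment
#' indicator of the per-arm conditional probabilities.
#'
#' @param process a `cr_process`.
#' @param pi_r target fraction in [0, 1).
#' @param p_x randomization probability P(X = 1).
#' @return the withdrawal rate rho (0 when `pi_r = 0`).
#' @export
calibrate_censoring_rate <- function(process, pi_r, p_x = 0.5) {
  stopifnot(pi_r >= 0, pi_r < 1)
  if (pi_r == 0) return(0)
  tau <- process$tau
  pf <- function(rho) {
    v <- vapply(0:1, function(xi)
      stats::integrate(function(t) (1 - exp(-rho * t)) *
                         proc_f1(process, t, xi),
                       0, tau, rel.tol = 1e-12, abs.tol = 1e-14)$value /
        proc_F1(process, tau, xi), 0)
    (1 - p_x) * v[1] + p_x * v[2] - pi_r
  }
  up <- 1
  while (pf(up) < 0 && up < 1e6) up <- up * 2
  if (pf(up) < 0)
    stop("target `pi_r` = ", pi_r, " unattainable: even rho = ", up,
         " censors less than requested")
  stats::uniroot(pf, c(0, up), tol = 1e-10)$root
}

#' Apply random and administrative censoring to latent samples
#'
#' Net censoring is \eqn{C = \min(C_r, \tau)} with \eqn{C_r} exponential of
#' rate `rho` (infinite when `rho = 0`).  Observed time is
#' \eqn{u = \min(T, C)} and status is the event type if \eqn{T \le C}, else
#' 0.  Censoring is generated independently of the event process, so
#' independent censoring holds by construction.
#'
#' @param latent a `data.frame` from [draw_competing_risks()].
#' @param rho exponential withdrawal rate (>= 0).
#' @param tau administrative horizon.
#' @param seed optional integer seed.
#' @return a `data.frame` with columns `id, time, status, x` (status 0 =
#'   censored, 1 = event of interest, 2 = competing event) and attribute
#'   `tau`.
#' @export
apply_censoring <- function(latent, rho, tau, seed = NULL) {
  stopifnot(rho >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(latent)
  Cr <- if (rho > 0) stats::rexp(n, rho) else rep(Inf, n)
  C <- pmin(Cr, tau)
  time <- pmin(latent$T, C)
  status <- ifelse(latent$T <= C, latent$type, 0L)
  ## continuous generators make exact ties a.s. absent; break any by a
  ## deterministic jitter keyed to record index
  if (anyDuplicated(time[status > 0])) {
    ev <- which(status > 0)
    dup <- ev[duplicated(time[ev])]
    time[dup] <- time[dup] + 1e-12 * seq_along(dup)
    message("broke ", length(dup), " exact event-time tie(s) by 1e-12 jitter")
  }
  out <- data.frame(id = seq_len(n), time = time, status = as.integer(status),
                    x = latent$x)
  attr(out, "tau") <- tau
  out
}

#' Simulate an observed competing-risks dataset
#'
#' Convenience front end combining [draw_competing_risks()] and
#' [apply_censoring()].  Random withdrawal can be given directly as a rate
#' `rho` or as a target loss fraction `pi_r` (calibrated through
#' [calibrate_censoring_rate()]).
#'
#' @param object a `cr_process`.
#' @param nsim number of datasets; 1 returns a data frame, more a list.
#' @param seed optional integer seed.
#' @param n subjects per dataset.
#' @param p_x randomization probability P(X = 1).
#' @param pi_r target fraction of type 1 events lost to withdrawal; ignored
#'   when `rho` is supplied.
#' @param rho exponential withdrawal rate.
#' @param ... unused.
#' @return observed dataset(s) with columns `id, time, status, x`.
#' @export
simulate.cr_process <- function(object, nsim = 1, seed = NULL, n = 1000,
                                p_x = 0.5, pi_r = 0, rho = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rho))
    rho <- if (pi_r > 0) calibrate_censoring_rate(object, pi_r, p_x) else 0
  one <- function() {
    lat <- draw_competing_risks(object, n, p_x)
    apply_censoring(lat, rho, object$tau)
  }
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}

#' Read / write observed competing-risks data as CSV
#'
#' The on-disk format is a plain CSV with header `id,time,status,x`;
#' status is coded 0 = censored, 1 = event of interest, 2 = competing
#' event.
#'
#' @param file path.
#' @param data a data frame with the columns above.
#' @param tau administrative horizon to attach; defaults to the maximum
#'   observed time.
#' @return `read_crdata()` returns the data frame (with a `tau`
#'   attribute); `write_crdata()` returns `file` invisibly.
#' @examples
#' # a small synthetic example trial ships with the package
#' d <- read_crdata(system.file("extdata", "synthetic_trial.csv",
#'                              package = "cifmis"), tau = 1)
#' table(d$status)
#' @export
read_crdata <- function(file, tau = NULL) {
  d <- utils::read.csv(file)
  need <- c("time", "status", "x")
  if (!all(need %in% names(d)))
    stop("CSV must contain columns time, status, x (and optionally id)")
  if (is.null(d$id)) d$id <- seq_len(nrow(d))
  if (!all(d$status %in% 0:2)) stop("status must be coded 0/1/2")
  if (!all(d$x %in% 0:1)) stop("x must be coded 0/1")
  if (any(d$time <= 0)) stop("times must be positive")
  d <- d[c("id", "time", "status", "x")]
  attr(d, "tau") <- if (is.null(tau)) max(d$time) else tau
  d
}

#' @rdname read_crdata
#' @export
write_crdata <- function(data, file) {
  utils::write.csv(data[c("id", "time", "status", "x")], file,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}

.get_tau <- function(data, tau = NULL) {
  if (!is.null(tau)) return(tau)
  tau <- attr(data, "tau")
  if (is.null(tau)) max(data$time) else tau
}
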