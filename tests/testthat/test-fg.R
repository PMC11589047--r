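test_that("FG reduces to Cox when there are no competing events or censoring", {
  set.seed(21)
  for (i in 1:50) {
    n <- 30 + sample(40, 1)
    d <- data.frame(id = seq_len(n), time = rexp(n), status = 1L,
                    x = rbinom(n, 1, 0.5))
    if (length(unique(d$x)) < 2) next
    attr(d, "tau") <- max(d$time) + 1
    f <- fg_fit(d, variance = "none")
    cx <- survival::coxph(survival::Surv(time, status) ~ x, data = d,
                          ties = "breslow")
    expect_lt(abs(unname(coef(f)) - unname(coef(cx))), 1e-8)
  }
})

test_that("mirror-symmetric arms give a null estimate", {
  d <- mirror_arms(data.frame(id = 1:6, time = c(0.2, 0.4, 0.5, 0.6, 0.8, 0.9),
                              status = c(1L, 2L, 1L, 0L, 1L, 0L),
                              x = rep(0, 6)))
  attr(d, "tau") <- 1
  f <- fg_fit(d, variance = "none")
  expect_equal(unname(coef(f)), 0, tolerance = 1e-10)
})

test_that("stabilized fit and robust variance agree with the reference
           implementation", {
  pr <- fix_intensity(0.75, 0.8)
  d <- simulate(pr, n = 2500, pi_r = 0.2, seed = 22)
  f <- fg_fit(d)
  cr <- cmprsk::crr(d$time, d$status, d$x)
  expect_equal(unname(coef(f)), unname(cr$coef), tolerance = 1e-7)
  expect_equal(f$se_robust, sqrt(cr$var[1, 1]), tolerance = 1e-3)
})

test_that("FG estimates are consistent under a correctly specified model", {
  pr <- fix_cif(exp_b = 0.8, exp_b2 = 0.8)
  d <- simulate(pr, n = 20000, pi_r = 0.2, seed = 23)
  f <- fg_fit(d)
  expect_lt(abs(coef(f) - log(0.8)), 3 * f$se_robust)
  fs <- fg_fit(d, weights = "standard")
  expect_lt(abs(coef(fs) - log(0.8)), 3 * fs$se_robust)
})

test_that("weight styles agree in law on large correctly specified data", {
  pr <- fix_cif(exp_b = 0.8, exp_b2 = 1)
  d <- simulate(pr, n = 50000, pi_r = 0.2, seed = 24)
  b1 <- coef(fg_fit(d, weights = "stabilized", variance = "none"))
  b2 <- coef(fg_fit(d, weights = "standard", variance = "none"))
  expect_lt(abs(b1 - b2), 0.01)
})

test_that("sandwich and bootstrap standard errors agree within 10 percent", {
  pr <- fix_intensity(0.8, 1.1)
  d <- simulate(pr, n = 2000, pi_r = 0.2, seed = 25)
  for (w in c("stabilized", "standard")) {
    fs <- fg_fit(d, weights = w)
    fb <- fg_fit(d, weights = w, variance = "bootstrap", n_boot = 500,
                 seed = 26)
    expect_lt(abs(fs$se_robust - fb$se_robust) / fb$se_robust, 0.10)
  }
  # without random censoring the censoring-influence term vanishes and the
  # sandwich is the plain empirical-score sandwich
  d0 <- simulate(pr, n = 2000, pi_r = 0, seed = 27)
  f0 <- fg_fit(d0)
  f0b <- fg_fit(d0, variance = "bootstrap", n_boot = 500, seed = 28)
  expect_lt(abs(f0$se_robust - f0b$se_robust) / f0b$se_robust, 0.10)
})

test_that("Breslow baseline accumulates the weighted subdistribution hazard", {
  # one-arm 5-record toy data, no censoring: at beta-hat = 0 the Breslow
  # increments are 1 / (FG risk-set size), competing-event subjects staying
  # at risk; risk sets at events 0.2, 0.5, 0.9 are {all 5}, {0.5,...,1.0
  # plus the type-2 record}, {0.9, 1.0, type-2 record}
  d <- data.frame(id = 1:5, time = c(0.2, 0.4, 0.5, 0.9, 1.0),
                  status = c(1L, 2L, 1L, 1L, 0L), x = rep(0, 5))
  attr(d, "tau") <- 1
  f <- fg_fit(d, variance = "none")
  expect_equal(f$gamma_hat$dGamma, c(1/5, 1/4, 1/3), tolerance = 1e-10)
  expect_equal(f$gamma_hat$Gamma, cumsum(c(1/5, 1/4, 1/3)),
               tolerance = 1e-10)
  # predicted CIF is the cloglog transform of the accumulated hazard
  pred <- predict(f, times = c(0.2, 0.5, 0.9), x = 0)
  expect_equal(pred$F1, 1 - exp(-f$gamma_hat$Gamma), tolerance = 1e-10)
  expect_true(all(diff(f$gamma_hat$Gamma) >= 0))
})

test_that("time-varying extension detects and respects a constant effect", {
  pr <- fix_cif(exp_b = 0.8, exp_b2 = 1)
  d <- simulate(pr, n = 4000, pi_r = 0.2, seed = 29)
  for (b in c("t", "logt")) {
    tv <- fg_timevarying_fit(d, b = b)
    expect_true(tv$convergence$converged)
    expect_gt(tv$wald_nu$p.value, 0.001)  # constant-effect truth
  }
  w <- capture_warnings(fg_timevarying_fit(d, b = function(t)
    rep(1, length(t))))
  expect_match(w, "identifiable", all = FALSE)
  # empirical size of the constant-effect test at the 5% level
  nrep <- 400
  rej <- 0
  for (i in seq_len(nrep)) {
    di <- simulate(pr, n = 1000, pi_r = 0.2, seed = 4000 + i)
    p <- tryCatch(fg_timevarying_fit(di, b = "t")$wald_nu$p.value,
                  error = function(e) NA)
    rej <- rej + isTRUE(p < 0.05)
  }
  rate <- rej / nrep
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nrep))
})

test_that("degenerate inputs are reported, not silently mis-fit", {
  # no events of interest at all
  d <- data.frame(id = 1:4, time = c(0.3, 0.4, 0.6, 0.8),
                  status = c(2L, 0L, 2L, 0L), x = c(0, 1, 0, 1))
  attr(d, "tau") <- 1
  expect_error(fg_fit(d), "no events")
  # events only in one arm: monotone pseudo-likelihood flagged
  d2 <- data.frame(id = 1:40, time = runif(40, 0.1, 0.9),
                   status = rep(c(1L, 0L), each = 20),
                   x = rep(c(0, 1), each = 20))
  attr(d2, "tau") <- 1
  expect_warning(fg_fit(d2, variance = "none"), "diverged|monotone")
})
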