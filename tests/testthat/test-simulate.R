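test_that("latent draws match the generating marginals", {
  expect_equal(nrow(draw_competing_risks(fix_intensity(), 0)), 0)
  pr <- fix_intensity()
  n <- 100000
  lat <- draw_competing_risks(pr, n, seed = 101)
  p0 <- mean(lat$T[lat$x == 0] <= 1)
  expect_lt(abs(p0 - 0.6), 3 * sqrt(0.6 * 0.4 / sum(lat$x == 0)))
  # conditional type-1 share given exit by tau
  sh <- mean(lat$type[lat$x == 0 & lat$T <= 1] == 1)
  expect_lt(abs(sh - 0.6), 3 * sqrt(0.6 * 0.4 / sum(lat$x == 0 & lat$T <= 1)))

  prc <- fix_cif(exp_b = 0.8, exp_b2 = 0.8)
  lat <- draw_competing_risks(prc, 60000, seed = 102)
  for (sr in c(0.25, 0.5, 1)) for (xx in 0:1) {
    nx <- sum(lat$x == xx)
    emp <- sum(lat$T <= sr & lat$type == 1 & lat$x == xx) / nx
    tr <- process_curves(prc, sr, xx)$F1
    expect_lt(abs(emp - tr), 3 * sqrt(tr * (1 - tr) / nx))
  }
})

test_that("identical seeds give bit-identical datasets", {
  pr <- fix_cif(0.9, 0.8)
  d1 <- simulate(pr, n = 500, pi_r = 0.2, seed = 7)
  d2 <- simulate(pr, n = 500, pi_r = 0.2, seed = 7)
  expect_identical(d1, d2)
  d3 <- simulate(pr, n = 500, pi_r = 0.2, seed = 8)
  expect_false(identical(d1$time, d3$time))
})

test_that("censoring-rate calibration reproduces the target loss fraction", {
  pr <- fix_intensity()
  expect_equal(calibrate_censoring_rate(pr, 0), 0)
  rhos <- vapply(c(0.05, 0.2, 0.5, 0.8), function(p)
    calibrate_censoring_rate(pr, p), 0)
  expect_true(all(diff(rhos) > 0))   # strictly increasing in pi_r
  # plug back in: per-arm integral identity
  rho <- rhos[2]
  v <- vapply(0:1, function(xx)
    integrate(function(t) (1 - exp(-rho * t)) * process_curves(pr, t, xx)$f1,
              0, 1, rel.tol = 1e-10)$value / process_curves(pr, 1, xx)$F1, 0)
  expect_equal(mean(v), 0.2, tolerance = 1e-6)
  # Monte Carlo: fraction of type-1-by-tau events with Cr < T1
  set.seed(103)
  lat <- draw_competing_risks(pr, 150000)
  Cr <- rexp(nrow(lat), rho)
  sel <- lat$T <= 1 & lat$type == 1
  frac <- mean(Cr[sel] < lat$T[sel])
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / sum(sel)))
})

test_that("censoring mechanics follow the net-censoring definition", {
  pr <- fix_intensity(0.8, 1.2)
  lat <- draw_competing_risks(pr, 5000, seed = 104)
  d0 <- apply_censoring(lat, rho = 0, tau = 1)
  expect_equal(d0$status == 0, lat$T > 1)
  expect_equal(d0$time, pmin(lat$T, 1))
  # with random censoring, status frequencies match the closed-form
  # exponential-race probabilities P(T < Cr, T <= tau, type = k)
  rho <- 0.5
  d1 <- apply_censoring(lat, rho = rho, tau = 1, seed = 105)
  for (xx in 0:1) for (k in 1:2) {
    pk <- integrate(function(t) exp(-rho * t) *
                      (if (k == 1) process_curves(pr, t, xx)$f1
                       else process_curves(pr, t, xx)$f2),
                    0, 1, rel.tol = 1e-10)$value
    nx <- sum(d1$x == xx)
    emp <- mean(d1$status[d1$x == xx] == k)
    expect_lt(abs(emp - pk), 3 * sqrt(pk * (1 - pk) / nx))
  }
  # recovered censoring-time survivor matches exp(-rho u) below tau
  cen <- d1$time[d1$status == 0 & d1$time < 1]
  ecdf_at <- stats::ecdf(cen)
  # among censored-before-tau records the times follow Cr | Cr < min(T,tau);
  # compare the empirical mean against its MC value from the latent draw
  Cr2 <- rexp(nrow(lat), rho)
  ref <- Cr2[Cr2 < pmin(lat$T, 1)]
  expect_lt(abs(mean(cen) - mean(ref)),
            3 * sd(ref) * sqrt(1 / length(cen) + 1 / length(ref)))
})

test_that("arms are exchangeable under the global null", {
  pr <- fix_intensity(1, 1)
  rej <- 0
  for (s in 1:30) {
    d <- simulate(pr, n = 400, pi_r = 0.2, seed = 200 + s)
    p <- suppressWarnings(
      stats::ks.test(d$time[d$x == 0], d$time[d$x == 1])$p.value)
    rej <- rej + (p < 0.05)
  }
  expect_lte(rej, 6)   # Binomial(30, 0.05): P(>6) ~ 2e-4
})

test_that("beta = 0 with beta2 != 0 separates F2 but not F1 empirically", {
  pr <- fix_cif(exp_b = 1, exp_b2 = 0.7)
  lat <- draw_competing_risks(pr, 60000, seed = 106)
  n1 <- sum(lat$x == 1); n0 <- n1 <- sum(lat$x == 1)
  f1_0 <- mean(lat$T[lat$x == 0] <= 1 & lat$type[lat$x == 0] == 1)
  f1_1 <- mean(lat$T[lat$x == 1] <= 1 & lat$type[lat$x == 1] == 1)
  expect_lt(abs(f1_0 - f1_1), 3 * sqrt(2 * 0.36 * 0.64 / n1))
  f2_0 <- mean(lat$T[lat$x == 0] <= 1 & lat$type[lat$x == 0] == 2)
  f2_1 <- mean(lat$T[lat$x == 1] <= 1 & lat$type[lat$x == 1] == 2)
  expect_gt(abs(f2_0 - f2_1), 3 * sqrt(2 * 0.27 * 0.73 / n1))
})

test_that("observed data round-trip through the CSV interface", {
  pr <- fix_intensity(0.75, 1)
  d <- simulate(pr, n = 50, pi_r = 0.2, seed = 9)
  f <- tempfile(fileext = ".csv")
  write_crdata(d, f)
  d2 <- read_crdata(f, tau = 1)
  expect_equal(d2$time, d$time)
  expect_equal(d2$status, d$status)
  expect_equal(attr(d2, "tau"), 1)
  writeLines("id,time\n1,2", f)
  expect_error(read_crdata(f), "must contain")
  unlink(f)
})
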