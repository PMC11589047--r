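test_that("intensity calibration satisfies its defining constraints", {
  pr <- fix_intensity()
  # closed form: lambda1 + lambda2 = -log(0.4), split 60/40
  expect_equal(pr$lambda1, 0.6 * -log(0.4), tolerance = 1e-12)
  expect_equal(pr$lambda1, 0.549774, tolerance = 1e-6)
  expect_equal(pr$lambda2, 0.366516, tolerance = 1e-6)
  # independent numeric check of the two constraints
  cc <- process_curves(pr, 1, 0)
  expect_equal(1 - cc$S, 0.6, tolerance = 1e-12)          # P(T <= 1 | 0)
  expect_equal(pr$lambda1 / (pr$lambda1 + pr$lambda2), 0.6)
  expect_equal(cc$F1, 0.36, tolerance = 1e-12)
  expect_equal(cc$F2, 0.24, tolerance = 1e-12)
  # degenerate single-cause case
  expect_equal(calibrate_intensity_process(0.6, 1)$lambda2, 0)
  expect_error(calibrate_intensity_process(1.2, 0.5), "p_exit")
  expect_error(calibrate_intensity_process(0.6, 0), "p_type1")
})

test_that("CIF-family calibration hits the target incidences", {
  pr <- fix_cif(exp_b = 0.8)
  expect_equal(pr$q, 0.36 / (1 - exp(-1)), tolerance = 1e-12)
  expect_lt(abs(pr$q - 0.569511), 1e-6)
  cc <- process_curves(pr, 1, 0)
  expect_equal(cc$F1, 0.36, tolerance = 1e-12)
  expect_equal(round(cc$F2, 2), 0.27)
  # indirect family hits the same control-arm targets
  pri <- fix_cif(exp_b = 0.8, family = "indirect")
  expect_equal(process_curves(pri, 1, 0)$F1, 0.36, tolerance = 1e-12)
  expect_equal(round(process_curves(pri, 1, 0)$F2, 2), 0.27)
  expect_error(calibrate_cif_process(0.8), "infeasible")
})

test_that("null CIF processes have identical arms", {
  pr <- fix_cif(exp_b = 1, exp_b2 = 1)
  tg <- seq(0.01, 1, length.out = 50)
  expect_equal(process_curves(pr, tg, 1)$F1, process_curves(pr, tg, 0)$F1)
  expect_equal(process_curves(pr, tg, 1)$F2, process_curves(pr, tg, 0)$F2)
  # beta = 0 with beta2 free: F1 equal, F2 different
  pr2 <- fix_cif(exp_b = 1, exp_b2 = 0.8)
  expect_equal(process_curves(pr2, tg, 1)$F1, process_curves(pr2, tg, 0)$F1)
  expect_gt(max(abs(process_curves(pr2, tg, 1)$F2 -
                      process_curves(pr2, tg, 0)$F2)), 0.01)
})

test_that("marginal-function identities hold for both families", {
  tg <- seq(0, 1, length.out = 21)
  for (pr in list(fix_intensity(0.75, 1.3), fix_cif(0.8, 0.9),
                  fix_cif(1.1, 0.8, family = "indirect"))) {
    for (xx in 0:1) {
      cc <- process_curves(pr, tg, xx)
      expect_equal(cc$S + cc$F1 + cc$F2, rep(1, length(tg)),
                   tolerance = 1e-12)
      expect_true(all(diff(cc$F1) >= 0) && all(diff(cc$F2) >= 0))
      expect_true(all(cc$f1 >= 0) && all(cc$f2 >= 0))
      expect_equal(cc$S[1], 1)
      expect_equal(cc$lam1[-1], (cc$f1 / cc$S)[-1])
    }
  }
})

test_that("closed-form F1 matches quadrature of the S * intensity integral", {
  pr <- fix_intensity(0.75, 1.3)
  for (xx in 0:1) for (tt in c(0.3, 0.7, 1)) {
    num <- integrate(function(u) {
      cc <- process_curves(pr, u, xx)
      cc$S * cc$lam1
    }, 0, tt, rel.tol = 1e-12)$value
    expect_equal(process_curves(pr, tt, xx)$F1, num, tolerance = 1e-8)
  }
  # total incidence reaches 1 in the long run
  L <- pr$lambda1 + pr$lambda2
  cc <- process_curves(pr, 50 / L, 0)
  expect_equal(cc$F1 + cc$F2, 1, tolerance = 1e-12)
})

test_that("CIF-family intensities match finite differences of the CIFs", {
  pr <- fix_cif(0.8, 0.9)
  h <- 1e-5
  for (xx in 0:1) for (tt in c(0.2, 0.5, 0.9)) {
    cc <- process_curves(pr, tt, xx)
    d1 <- (process_curves(pr, tt + h, xx)$F1 -
             process_curves(pr, tt - h, xx)$F1) / (2 * h)
    d2 <- (process_curves(pr, tt + h, xx)$F2 -
             process_curves(pr, tt - h, xx)$F2) / (2 * h)
    expect_equal(cc$lam1, d1 / cc$S, tolerance = 1e-6)
    expect_equal(cc$lam2, d2 / cc$S, tolerance = 1e-6)
  }
})

test_that("degenerate and invalid evaluation points are handled", {
  pr <- fix_intensity()
  expect_error(process_curves(pr, -0.1, 0), "nonnegative")
  # S = 0 far in the tail: intensities flagged NA, no crash
  prc <- fix_cif(0.8)
  far <- process_curves(prc, 500, 0)
  expect_true(is.na(far$lam1) || is.finite(far$lam1))
  # cloglog link round trip
  u <- c(0.01, 0.36, 0.99)
  expect_equal(cloglog_inv(cloglog(u)), u, tolerance = 1e-12)
})

test_that("process parameters round-trip through YAML", {
  f <- tempfile(fileext = ".yaml")
  pr <- fix_intensity(0.75, 1.1)
  write_process(pr, f)
  pr2 <- read_process(f)
  expect_equal(pr2[c("lambda1", "lambda2", "gamma1", "gamma2", "tau")],
               pr[c("lambda1", "lambda2", "gamma1", "gamma2", "tau")])
  prc <- fix_cif(0.8, 0.9)
  write_process(prc, f)
  prc2 <- read_process(f)
  expect_equal(prc2$q, prc$q)
  expect_equal(prc2$beta, prc$beta)
  unlink(f)
})
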