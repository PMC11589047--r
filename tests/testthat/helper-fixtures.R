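# Shared fixtures: the calibrated study designs used across the suite and
# small deterministic toy datasets.

# control-arm design: 60% exit by tau = 1, 60% of exits are events of interest
fix_intensity <- function(exp_g1 = 1, exp_g2 = 1)
  calibrate_intensity_process(0.6, 0.6, exp_g1, exp_g2, tau = 1)

fix_cif <- function(exp_b = 1, exp_b2 = 1, family = "extended")
  calibrate_cif_process(0.36, exp_b = exp_b, exp_b2 = exp_b2,
                        family = family, tau = 1)

# tiny hand-checkable dataset: times 1..4 with statuses event / censored /
# competing / censored, single arm unless x given
toy_data <- function(x = c(0, 0, 0, 0), tau = 5) {
  d <- data.frame(id = 1:4, time = 1:4, status = c(1L, 0L, 2L, 0L), x = x)
  attr(d, "tau") <- tau
  d
}

# duplicate a dataset into two identical arms (mirror symmetry)
mirror_arms <- function(d) {
  out <- rbind(transform(d, x = 0), transform(d, x = 1))
  out$id <- seq_len(nrow(out))
  attr(out, "tau") <- attr(d, "tau")
  out
}

# brute-force Cox partial likelihood (Breslow ties) for a binary covariate
brute_cox <- function(time, event, x) {
  logpl <- function(b) {
    s <- 0
    for (t in sort(time[event == 1])) {
      ev <- which(time == t & event == 1)
      rs <- which(time >= t)
      s <- s + sum(b * x[ev]) -
        length(ev) * log(sum(exp(b * x[rs])))
    }
    s
  }
  stats::optimize(logpl, c(-8, 8), maximum = TRUE, tol = 1e-10)$maximum
}
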