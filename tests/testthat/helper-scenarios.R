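# Small scenarios shared across tests.

ph_scenario <- function(hr = 0.5, lambda0 = 1.5, rate = 60, b = 1, tau = 2) {
  scenario_spec(
    experimental = arm_model(lambda0 * hr),
    control = arm_model(lambda0),
    accrual_rate = rate, followup = b, tau = tau
  )
}

late_diff_scenario <- function(lambda0 = 1, hr2 = 0.45, ct = 0.5,
                               rate = 120, b = 1, tau = 3) {
  scenario_spec(
    experimental = arm_model(lambda0, hr1 = 1, hr2 = hr2, change_time = ct),
    control = arm_model(lambda0),
    accrual_rate = rate, followup = b, tau = tau
  )
}

# Synthetic stage statistics with a prescribed joint distribution, for
# calibration tests that should not depend on the trial simulator.
synthetic_stats <- function(n_rep, seed, mu1 = c(0.1, 0.6), mu2 = c(0.35, 1),
                            sd = c(0.15, 0.12), rho = 0.5, null_shift = TRUE) {
  set.seed(seed)
  draw <- function(mu) {
    z1 <- rnorm(n_rep)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_rep)
    tibble::tibble(d = mu[1] + sd[1] * z1, re = mu[2] + sd[2] * z2)
  }
  one_h <- function(h, shift) {
    s1 <- draw(mu1 - shift * c(mu1[1], mu1[1]))
    s2 <- draw(mu2 - shift * c(mu2[1], mu2[1]))
    tibble::tibble(
      hypothesis = h, rep = seq_len(n_rep), tau1 = 1,
      d1 = s1$d, re1 = s1$re, d2 = s2$d, re2 = s2$re
    )
  }
  out <- dplyr::bind_rows(one_h("H0", if (null_shift) 1 else 0), one_h("H1", 0))
  attr(out, "n_total") <- 100
  attr(out, "n_interim") <- 60
  out
}
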