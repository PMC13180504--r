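test_that("logrank_stat reproduces hand-computed statistics", {
  # identical data in both arms: perfectly balanced, W = 0
  d <- tibble::tibble(
    arm = rep(c("E", "C"), each = 4),
    time = rep(c(0.5, 1, 1.5, 2), 2),
    status = rep(c(1L, 0L, 1L, 1L), 2)
  )
  out <- logrank_stat(d)
  expect_equal(out$w, 0)
  expect_gt(out$variance, 0)

  # single event in arm E with equal at-risk counts: W = -0.5, var = 0.25
  d2 <- tibble::tibble(arm = c("E", "C"), time = c(1, 2), status = c(1L, 0L))
  out2 <- logrank_stat(d2)
  expect_equal(out2$w, -0.5)
  expect_equal(out2$variance, 0.25)
  expect_equal(out2$z, -1)

  # no events: degenerate flag
  d3 <- tibble::tibble(arm = c("E", "C"), time = c(1, 2), status = c(0L, 0L))
  out3 <- logrank_stat(d3)
  expect_true(out3$degenerate)
  expect_true(is.na(out3$z))
})

test_that("logrank_stat agrees with survival::survdiff", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    d <- tibble::tibble(
      arm = sample(c("E", "C"), n, replace = TRUE),
      time = round(rexp(n), 2) + 0.01,
      status = rbinom(n, 1, 0.7)
    )
    if (length(unique(d$arm)) < 2 || sum(d$status) == 0) next
    out <- logrank_stat(d)
    sd_ <- survival::survdiff(survival::Surv(time, status) ~ arm, data = d)
    if (out$variance <= 0) next
    expect_equal(out$w^2 / out$variance, unname(sd_$chisq), tolerance = 1e-8)
    # sign convention: positive when fewer events in E than expected
    expect_equal(out$w, unname(sd_$exp[2] - sd_$obs[2]), tolerance = 1e-8)
  }
})

test_that("standardized log-rank statistic is asymptotically standard normal", {
  set.seed(22)
  n_rep <- 10000
  n <- 100
  z <- numeric(n_rep)
  is_e <- rep(c(TRUE, FALSE), each = n)
  for (i in seq_len(n_rep)) {
    tt <- rexp(2 * n, 1.2)
    ss <- as.integer(rexp(2 * n, 0.4) > tt) # ~25% censoring, exchangeable
    st <- rmstsculpt:::logrank_core(tt, ss, is_e)
    z[i] <- st[1] / sqrt(st[2])
  }
  expect_lt(abs(mean(z)), 3 / sqrt(n_rep))
  expect_lt(abs(var(z) - 1), 3 * sqrt(2 / n_rep))
})

test_that("estimate_rho0 recovers the independent-increments correlation", {
  # interim equal to final: correlation 1
  set.seed(23)
  w <- rnorm(100)
  expect_equal(estimate_rho0(w, w), 1)
  # degenerate interim with no events: zero
  expect_equal(estimate_rho0(rep(0, 50), rnorm(50)), 0)
  # nested increments with known variance ratio 0.6
  n <- 2e5
  w1 <- rnorm(n, 0, sqrt(0.6))
  w2 <- w1 + rnorm(n, 0, sqrt(0.4))
  expect_lt(abs(estimate_rho0(w1, w2) - sqrt(0.6)), 0.01)
  expect_error(estimate_rho0(rnorm(10), rep(1, 10)), "zero variance")
})

test_that("bivariate normal upper tail matches independent references", {
  # independence factorizes
  expect_equal(pbvnorm_upper(0.5, 1, 0),
               pnorm(0.5, lower.tail = FALSE) * pnorm(1, lower.tail = FALSE))
  # infinite bounds reduce to univariate tails
  expect_equal(pbvnorm_upper(-Inf, 1.2, 0.6), pnorm(1.2, lower.tail = FALSE))
  expect_equal(pbvnorm_upper(Inf, 0, 0.6), 0)
  # perfect correlation
  expect_equal(pbvnorm_upper(0.3, 1.1, 1), pnorm(1.1, lower.tail = FALSE))
  # symmetry in the two arguments
  expect_equal(pbvnorm_upper(0.4, 1.3, 0.7), pbvnorm_upper(1.3, 0.4, 0.7),
               tolerance = 1e-10)
  # Monte-Carlo oracle at a generic point
  set.seed(24)
  n <- 2e6
  x <- rnorm(n)
  y <- 0.6 * x + 0.8 * rnorm(n)
  p_mc <- mean(x > 0.3 & y > 0.8)
  p <- pbvnorm_upper(0.3, 0.8, 0.6)
  expect_lt(abs(p - p_mc), 4 * sqrt(p_mc * (1 - p_mc) / n))
})

test_that("solve_c satisfies the two-stage error constraint", {
  # single-stage reduction as the interim boundary vanishes
  expect_equal(solve_c(-8, 0.5, 0.05), qnorm(0.95), tolerance = 1e-4)
  # independence: closed form
  cl <- 0.2
  expect_equal(solve_c(cl, 0, 0.05),
               qnorm(1 - 0.05 / pnorm(cl, lower.tail = FALSE)),
               tolerance = 1e-6)
  # round trip across random configurations
  set.seed(25)
  for (i in 1:100) {
    a0 <- runif(1, 0.01, 0.2)
    rho <- runif(1, 0.05, 0.95)
    cl <- qnorm(1 - runif(1, a0 + 0.02, 0.9))
    cc <- solve_c(cl, rho, a0)
    expect_lt(abs(pbvnorm_upper(cl, cc, rho) - a0), 1e-6)
  }
  # infeasible interim boundary
  expect_error(solve_c(qnorm(0.99), 0.5, 0.05), "infeasible")
})

test_that("the final boundary relaxes as the interim boundary tightens", {
  cls <- seq(-2, 1, by = 0.25)
  cs <- vapply(cls, solve_c, numeric(1), rho0 = 0.7, alpha0 = 0.05)
  expect_true(all(diff(cs) <= 1e-9))
})

test_that("the calibrated two-stage log-rank rule controls its error", {
  sc <- ph_scenario(hr = 0.5, lambda0 = 1.5, rate = 60, b = 1, tau = 2)
  st <- simulate_stage_stats(sc, n_total = 200, n_interim = 100, n_rep = 1500,
                             logrank = TRUE, seed = 26)
  d <- calibrate_logrank(st, alpha0 = 0.05, beta0 = 0.2, rule = "max")
  expect_false(d$no_design)
  expect_lte(d$oc$alpha_e, 0.05)
  expect_gt(d$cv$rho0, 0)
  expect_lt(d$cv$rho0, 1)
  # verify the reported OC against a direct evaluation
  h0 <- st[st$hypothesis == "H0", ]
  h1 <- st[st$hypothesis == "H1", ]
  expect_equal(d$oc$alpha_e, mean(h0$z1 > d$cv$cl & h0$z2 > d$cv$c))
  expect_equal(d$oc$power_e, mean(h1$z1 > d$cv$cl & h1$z2 > d$cv$c))
  expect_equal(d$oc$pet1, mean(h1$z1 <= d$cv$cl))
  # an impossible interim bar gives zero power and certain stopping
  expect_equal(mean(h1$z1 > Inf), 0)
  expect_error(calibrate_logrank(st[, 1:7], 0.05), "logrank = TRUE")
})
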