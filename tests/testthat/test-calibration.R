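test_that("control function has the documented range and monotonicity", {
  expect_equal(control_f(100, 100, 1), exp(-1))
  expect_equal(control_f(50, 100, 2), exp(-1))
  # approaches 1 from below as gamma -> 0
  expect_lt(control_f(60, 100, 1e-9), 1)
  expect_gt(control_f(60, 100, 1e-9), 1 - 1e-8)
  expect_error(control_f(60, 100, 0), "positive")
  expect_error(control_f(0, 100, 1), "in \\(0")
  # strictly decreasing in the interim fraction and in gamma
  ni <- seq(10, 100, by = 10)
  expect_true(all(diff(control_f(ni, 100, 0.7)) < 0))
  gs <- seq(0.1, 3, by = 0.1)
  expect_true(all(diff(control_f(60, 100, gs)) < 0))
  # interim threshold is always the more lenient one
  expect_true(all(control_f(ni[ni < 100], 100, 0.7) > control_f(100, 100, 0.7)))
})

test_that("stage_moments recovers means and covariances", {
  # two replicates, hand covariance
  st <- tibble::tibble(
    hypothesis = "H1", rep = 1:2, tau1 = 1,
    d1 = c(0, 2), re1 = c(0, 2), d2 = c(1, 1), re2 = c(3, 5)
  )
  mo <- stage_moments(st)
  expect_equal(mo$mean_d, c(1, 1))
  expect_equal(mo$rho[1], 1)
  expect_equal(mo$var_d[1], 1) # divisor B, not B - 1
  expect_equal(mo$var_d[2], 0)
  expect_equal(mo$rho[2], 0) # degenerate: defined as 0

  # identical replicates: zero covariance matrix
  st2 <- st[c(1, 1), ]
  st2$rep <- 1:2
  mo2 <- stage_moments(st2)
  expect_true(all(mo2$var_d == 0 & mo2$var_re == 0 & mo2$cov == 0))

  # sampling oracle: recover a known bivariate normal
  n <- 1e5
  st3 <- synthetic_stats(n, seed = 10, null_shift = FALSE)
  mo3 <- stage_moments(st3)
  expect_lt(abs(mo3$mean_d[1] - 0.1), 3 * 0.15 / sqrt(n))
  expect_lt(abs(mo3$mean_re[2] - 1), 3 * 0.12 / sqrt(n))
  expect_lt(abs(mo3$rho[1] - 0.5), 0.01)
  expect_lt(abs(sqrt(mo3$var_d[2]) - 0.15), 0.005)
  expect_error(stage_moments(st[0, ]), "at least two")
})

test_that("conditional moments match the truncated bivariate normal", {
  # independence: conditioning changes nothing
  cm <- conditional_moments(2, 3, 0, 1, 0, m = c(-5, 0, 5))
  expect_equal(cm$mean, rep(2, 3))
  expect_equal(cm$variance, rep(9, 3))
  # no truncation
  cm <- conditional_moments(0.5, 1.5, 1, 2, 0.8, m = -Inf)
  expect_equal(cm$mean, 0.5)
  expect_equal(cm$variance, 1.5^2)
  # standard case against the closed-form inverse Mills ratio
  cm <- conditional_moments(0, 1, 0, 1, 0.5, m = 0)
  expect_equal(cm$mean, 0.5 * dnorm(0) / 0.5)
  expect_equal(cm$variance, 0.75 + 0.25 * (1 - (dnorm(0) / 0.5)^2),
               tolerance = 1e-12)
  # rejection-sampling oracle at a handful of parameter points
  set.seed(11)
  for (i in 1:10) {
    mu <- rnorm(2)
    sds <- runif(2, 0.5, 2)
    rho <- runif(1, -0.9, 0.9)
    m <- mu[2] + runif(1, -1, 0.8) * sds[2]
    n <- 4e5
    zd <- rnorm(n)
    ze <- rho * zd + sqrt(1 - rho^2) * rnorm(n)
    d <- mu[2] + sds[2] * zd
    re <- mu[1] + sds[1] * ze
    keep <- re[d > m]
    cm <- conditional_moments(mu[1], sds[1], mu[2], sds[2], rho, m)
    k <- length(keep)
    se_mean <- sd(keep) / sqrt(k)
    expect_lt(abs(cm$mean - mean(keep)), 4 * se_mean)
    m4 <- mean((keep - mean(keep))^4)
    se_var <- sqrt(max(m4 - var(keep)^2, 0) / k) # kurtosis-robust
    expect_lt(abs(cm$variance - var(keep)), 4 * se_var)
  }
  expect_error(conditional_moments(0, 1, 0, 1, 0.5, m = 50), "underflow")
})

test_that("q_from_m returns conditional quantiles of the stage statistics", {
  st <- synthetic_stats(5e4, seed = 12, null_shift = FALSE)
  mo <- stage_moments(st)
  # median target: q equals the conditional mean
  q50 <- q_from_m(mo, 1L, m = 0.1, target_prob = 0.5)
  cm <- conditional_moments(mo$mean_re[1], sqrt(mo$var_re[1]),
                            mo$mean_d[1], sqrt(mo$var_d[1]), mo$rho[1], 0.1)
  expect_equal(q50, cm$mean)
  # composition with the control function
  f <- control_f(60, 100, 1)
  q <- q_from_m(mo, 2L, m = 0.3, target_prob = f)
  cm2 <- conditional_moments(mo$mean_re[2], sqrt(mo$var_re[2]),
                             mo$mean_d[2], sqrt(mo$var_d[2]), mo$rho[2], 0.3)
  expect_equal(q, cm2$mean + qnorm(1 - f) * sqrt(cm2$variance))
  # extreme targets push q to the corresponding tails
  expect_gt(q_from_m(mo, 1L, 0.1, 0.001), q50)
  expect_lt(q_from_m(mo, 1L, 0.1, 0.999), q50)
})

test_that("empirical_oc evaluates the four-way strict rule", {
  st <- synthetic_stats(500, seed = 13)
  # no thresholds: always reject, never stop
  oc <- empirical_oc(st, -Inf, -Inf, -Inf, -Inf)
  expect_equal(oc$alpha_e, 1)
  expect_equal(oc$power_e, 1)
  expect_equal(oc$pet0, 0)
  expect_equal(oc$en0, 100)
  # impossible interim bar: always stop
  oc <- empirical_oc(st, Inf, -Inf, -Inf, -Inf)
  expect_equal(oc$pet0, 1)
  expect_equal(oc$pet1, 1)
  expect_equal(oc$alpha_e, 0)
  expect_equal(oc$en1, 60)
  # boundary equality does not reject
  st2 <- st[st$hypothesis == "H1", ][1, ]
  st2 <- dplyr::bind_rows(
    dplyr::mutate(st2, hypothesis = "H0"),
    st2
  )
  oc <- empirical_oc(st2, st2$d1[1], -Inf, -Inf, -Inf)
  expect_equal(oc$power_e, 0)
  expect_equal(oc$pet1, 1)
})

test_that("rejection rates are monotone in every critical value", {
  st <- synthetic_stats(2000, seed = 14)
  base <- c(m1 = 0.0, q1 = 0.5, m2 = 0.3, q2 = 0.9)
  oc0 <- empirical_oc(st, base["m1"], base["q1"], base["m2"], base["q2"])
  for (k in names(base)) {
    up <- base
    up[k] <- up[k] + 0.1
    oc1 <- empirical_oc(st, up["m1"], up["q1"], up["m2"], up["q2"])
    expect_lte(oc1$alpha_e, oc0$alpha_e)
    expect_lte(oc1$power_e, oc0$power_e)
  }
})

test_that("sculpted rejection sets are nested inside simple ones", {
  st <- synthetic_stats(2000, seed = 15)
  h1 <- st[st$hypothesis == "H1", ]
  for (m in list(c(0, 0.3), c(-0.1, 0.2), c(0.1, 0.4))) {
    simple_rej <- h1$d1 > m[1] & h1$d2 > m[2]
    sculpt_rej <- simple_rej & h1$re1 > 0.55 & h1$re2 > 0.95
    expect_true(all(sculpt_rej <= simple_rej)) # replicate-wise subset
    oc_s <- empirical_oc(st, m[1], 0, m[2], 0)
    oc_c <- empirical_oc(st, m[1], 0.55, m[2], 0.95)
    expect_lte(oc_c$alpha_e, oc_s$alpha_e)
    expect_lte(oc_c$power_e, oc_s$power_e)
  }
})

test_that("calibration selects feasible maximum-power combinations", {
  st <- synthetic_stats(3000, seed = 16)
  d <- calibrate_simple(st, alpha0 = 1, beta0 = 0.2, rule = "max",
                        n_m = 21, keep_feasible = TRUE)
  # alpha0 = 1: every grid point feasible, global power maximizer selected
  expect_equal(d$n_feasible, nrow(d$feasible_set))
  expect_equal(d$oc$power_e, max(d$feasible_set$power_e))
  expect_equal(d$cv$q1, 0)
  expect_equal(d$cv$q2, 0)

  # realistic bound: constraint honored and selected design reported
  d2 <- calibrate_sculpted(st, alpha0 = 0.05, beta0 = 0.2, rule = "max",
                           gamma_grid = c(0.05, 0.2, 0.5, 1), n_m = 21)
  expect_false(d2$no_design)
  expect_lte(d2$oc$alpha_e, 0.05)
  oc <- empirical_oc(st, d2$cv$m1, d2$cv$q1, d2$cv$m2, d2$cv$q2)
  expect_equal(oc$alpha_e, d2$oc$alpha_e)
  expect_equal(oc$power_e, d2$oc$power_e)

  # closest rule picks the smallest feasible power at or above the target
  d3 <- calibrate_simple(st, alpha0 = 0.2, beta0 = 0.2, rule = "closest",
                         n_m = 21, keep_feasible = TRUE)
  fs <- d3$feasible_set
  if (any(fs$power_e >= 0.8)) {
    expect_equal(d3$oc$power_e, min(fs$power_e[fs$power_e >= 0.8]))
  }
})

test_that("an unattainable alpha bound yields a no-design result", {
  # H0 replicates identical to H1 with perfect stage dependence: every grid
  # cell rejects at least one null replicate, so alpha can never reach 0
  set.seed(17)
  n <- 100
  dd <- rnorm(n, 0.2, 0.1)
  st <- tibble::tibble(
    hypothesis = rep(c("H0", "H1"), each = n), rep = rep(1:n, 2),
    tau1 = 1, d1 = rep(dd, 2), re1 = rep(dd + 1, 2),
    d2 = rep(dd, 2), re2 = rep(dd + 1, 2)
  )
  attr(st, "n_total") <- 100
  attr(st, "n_interim") <- 60
  d <- calibrate_simple(st, alpha0 = 1e-6, beta0 = 0.2, rule = "max", n_m = 11)
  expect_true(d$no_design)
  expect_s3_class(d, "rmst_design")
  expect_equal(nrow(tidy(d)), 0)
})

test_that("expected sample size identity matches the published design row", {
  expect_equal(expected_sample_size(74, 128, 0), 128)
  expect_equal(expected_sample_size(74, 128, 1), 74)
  en0 <- expected_sample_size(74, 128, 0.451)
  expect_equal(en0, 103.646)
  en1 <- expected_sample_size(74, 128, 0.122)
  expect_equal(en1, 121.412)
})
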