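# A strong treatment effect keeps these search tests small and fast.
strong_scenario <- function() {
  ph_scenario(hr = 0.25, lambda0 = 1.5, rate = 60, b = 1, tau = 2)
}

test_that("single_stage_n0 finds the smallest adequately powered size", {
  sc <- strong_scenario()
  n0 <- single_stage_n0(sc, alpha0 = 0.05, beta0 = 0.2, n_rep = 1500,
                        step = 4, n_min = 12, seed = 31)
  curve <- attr(n0, "power_curve")
  expect_gte(curve$power[nrow(curve)], 0.8)
  expect_true(all(curve$power[-nrow(curve)] < 0.8))
  # minimality against an independent larger simulation at the same sizes
  for (n in c(n0 - 4L, as.integer(n0))) {
    rej <- vapply(1:1200, function(j) {
      tr <- simulate_trial(sc, n, seed = 31000 + j)
      fin <- snapshot(tr, calendar_time = n / 60 + 1, stage = "final")
      single_stage_test(fin, tau = 2, extend = TRUE)$reject
    }, logical(1))
    pw <- mean(rej)
    se <- sqrt(pw * (1 - pw) / length(rej))
    if (n < n0) expect_lt(pw, 0.8 + 3 * se) else expect_gt(pw, 0.8 - 3 * se)
  }
  # a null effect never reaches the target and reports diagnostics
  expect_error(
    single_stage_n0(ph_scenario(hr = 1), n_rep = 300, step = 20,
                    n_min = 20, n_max = 60, seed = 32),
    "reaches power"
  )
})

test_that("search_designs returns consistent minimax and optimal designs", {
  sc <- strong_scenario()
  args <- list(
    spec = sc, alpha0 = 0.1, beta0 = 0.2, methods = c("sculpted", "simple"),
    n_rep = 400, n_stride = 2, interim_stride = 4, interim_min = 10,
    n_extra_steps = 2, gamma_grid = c(0.05, 0.2, 0.5, 1, 2),
    n_m = 15, seed = 33
  )
  sr <- do.call(search_designs, args)
  expect_gt(nrow(sr$designs), 0)
  # stored designs all satisfy the constraints on their replicates
  expect_true(all(sr$designs$alpha_e <= 0.1 + 1e-12))
  expect_true(all(sr$designs$power_e >= 0.8))
  expect_true(all(sr$designs$n_interim < sr$designs$n_total))
  # EN identity recomputed exactly from PET
  expect_equal(sr$designs$en0,
               expected_sample_size(sr$designs$n_interim,
                                    sr$designs$n_total, sr$designs$pet0))
  expect_equal(sr$designs$enbar, (sr$designs$en0 + sr$designs$en1) / 2)
  # definitional orderings per method
  for (m in unique(sr$designs$method)) {
    mm <- sr$minimax[sr$minimax$method == m, ]
    oo <- sr$optimal[sr$optimal$method == m, ]
    expect_lte(mm$n_total, oo$n_total)
    expect_lte(oo$en0, mm$en0)
  }
  # reproducibility: identical result at the same seed
  sr2 <- do.call(search_designs, args)
  expect_identical(sr$designs, sr2$designs)
  expect_identical(sr$minimax, sr2$minimax)
})

test_that("the search is invariant to small perturbations of n0", {
  sc <- strong_scenario()
  base <- list(
    spec = sc, alpha0 = 0.1, beta0 = 0.2, methods = "sculpted",
    n_rep = 400, n_stride = 2, interim_stride = 4, interim_min = 10,
    n_extra_steps = 2, gamma_grid = c(0.05, 0.2, 0.5, 1, 2),
    n_m = 15, seed = 33
  )
  n0 <- single_stage_n0(sc, 0.1, 0.2, n_rep = 1500, step = 2,
                        n_min = 12, seed = 33)
  runs <- lapply(c(-4L, 0L, 4L), function(delta) {
    do.call(search_designs, c(base, list(n0 = as.integer(n0) + delta)))
  })
  mm <- lapply(runs, function(r) r$minimax[, c("n_interim", "n_total")])
  expect_identical(mm[[1]], mm[[2]])
  expect_identical(mm[[2]], mm[[3]])
})

test_that("power_vs_interim traces feasible designs across interim sizes", {
  sc <- strong_scenario()
  pc <- power_vs_interim(sc, n_total = 40, n_interim_grid = c(16, 28),
                         alpha0 = 0.1, beta0 = 0.2,
                         methods = c("sculpted", "simple"), n_rep = 400,
                         gamma_grid = c(0.05, 0.2, 0.5, 1, 2), n_m = 15,
                         seed = 34)
  expect_equal(nrow(pc), 4)
  expect_true(all(pc$alpha_e <= 0.1 + 1e-12))
  expect_s3_class(autoplot(pc), "ggplot")
  # the two methods are evaluated on shared replicates at each interim size
  expect_equal(unique(pc$n_interim), c(16, 28))
})

test_that("robustness profiles respond to hazard drift as expected", {
  sc <- strong_scenario()
  st <- simulate_stage_stats(sc, n_total = 40, n_interim = 20, n_rep = 800,
                             seed = 35)
  d <- calibrate_sculpted(st, alpha0 = 0.1, beta0 = 0.2, rule = "max",
                          gamma_grid = c(0.05, 0.2, 0.5, 1), n_m = 21)
  expect_false(d$no_design)
  lam1 <- 1.5 * 0.25
  rp <- robustness_profile(d, sc, lambda1_grid = c(lam1, lam1 * 2.5),
                           n_rep = 800, seed = 36)
  expect_equal(nrow(rp), 2)
  # zero drift reproduces the base operating characteristics within MC error
  se <- 3 * sqrt(0.25 / 800) # conservative binomial half-width
  expect_lt(abs(rp$power_e[1] - d$oc$power_e), 2 * se)
  expect_lt(abs(rp$alpha_e[1] - d$oc$alpha_e), 0.05)
  # a much weaker drug loses power; the null is untouched so alpha is stable
  expect_lt(rp$power_e[2], rp$power_e[1] - 0.1)
  expect_lt(abs(rp$alpha_e[2] - rp$alpha_e[1]), 0.05)
  expect_s3_class(autoplot(rp), "ggplot")
  # drifting the control hazard moves the null as well
  rp0 <- robustness_profile(d, sc, lambda0_grid = c(1.5, 1.8),
                            n_rep = 800, seed = 37)
  expect_equal(rp0$parameter, c("lambda0", "lambda0"))
  expect_true(all(is.finite(rp0$alpha_e)))
})

test_that("tidiers expose designs and search results as tibbles", {
  st <- synthetic_stats(1500, seed = 38)
  d <- calibrate_sculpted(st, alpha0 = 0.1, beta0 = 0.2, rule = "max",
                          gamma_grid = c(0.1, 0.5, 1), n_m = 15)
  td <- tidy(d)
  expect_named(td, c("term", "estimate"))
  expect_setequal(td$term, c("m1", "q1", "m2", "q2", "gamma"))
  gl <- glance(d)
  expect_equal(gl$method, "sculpted")
  expect_true(all(c("alpha_e", "power_e", "en0") %in% names(gl)))
})
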