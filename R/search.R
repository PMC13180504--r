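# Minimax / optimal design search over (n_interim, n_total), the single-stage
# reference sample size, power-vs-interim curves and robustness profiles.

#' Empirical single-stage reference sample size
#'
#' Smallest total sample size whose single-stage one-sided RMST z-test at
#' level `alpha0` reaches power `1 - beta0` in simulation, stepping `n` by
#' `step`. Used as the anchor `n0` of the two-stage search, which starts at
#' `0.9 * n0`.
#'
#' @inheritParams simulate_stage_stats
#' @param alpha0 One-sided type I error level.
#' @param beta0 Type II error (power target `1 - beta0`).
#' @param step Even increment of the candidate sample sizes.
#' @param n_min,n_max Search range (even).
#' @return The sample size `n0` (integer) with attribute `power_curve`, a
#'   tibble of the simulated power at each `n` visited.
#' @export
single_stage_n0 <- function(spec, alpha0 = 0.05, beta0 = 0.2, n_rep = 2000,
                            step = 2, n_min = 20, n_max = 1000, seed = NULL) {
  stopifnot(step %% 2 == 0, step > 0, n_min %% 2 == 0, n_min >= 4)
  seed <- seed %||% sample.int(2^30, 1)
  z <- qnorm(1 - alpha0)
  visited <- list()
  for (n in seq(n_min, n_max, by = step)) {
    bank <- sim_bank(spec, n, "H1", n_rep, seed = derive_seed(seed, c(9L, n)))
    tcal <- bank$a + bank$b
    rej <- vapply(seq_len(n_rep), function(j) {
      e <- observe_row(bank$E, j, tcal)
      c_ <- observe_row(bank$C, j, tcal)
      ke <- rmst_core(e$time, e$status, spec$tau, extend = TRUE)
      kc <- rmst_core(c_$time, c_$status, spec$tau, extend = TRUE)
      (ke[1] - kc[1]) > z * sqrt(ke[2] + kc[2])
    }, logical(1))
    pw <- mean(rej)
    visited[[length(visited) + 1]] <- tibble(n = n, power = pw)
    if (pw >= 1 - beta0) {
      out <- n
      attr(out, "power_curve") <- dplyr::bind_rows(visited)
      return(out)
    }
  }
  stop(sprintf(
    "no single-stage sample size up to %d reaches power %.3f (last simulated power %.3f)",
    n_max, 1 - beta0, visited[[length(visited)]]$power
  ), call. = FALSE)
}

calibrate_method <- function(method, stats, alpha0, beta0, rule,
                             gamma_grid, n_m, n_cl, n_interim, n_total) {
  switch(method,
    sculpted = calibrate_sculpted(stats, alpha0, beta0, rule,
                                  gamma_grid = gamma_grid, n_m = n_m,
                                  n_interim = n_interim, n_total = n_total),
    simple = calibrate_simple(stats, alpha0, beta0, rule, n_m = n_m,
                              n_interim = n_interim, n_total = n_total),
    logrank = calibrate_logrank(stats, alpha0, beta0, rule, n_cl = n_cl,
                                n_interim = n_interim, n_total = n_total),
    stop("unknown method: ", method, call. = FALSE)
  )
}

design_row <- function(d) {
  tibble(
    method = d$method,
    n_interim = d$n_interim, n_total = d$n_total,
    m1 = d$cv$m1 %||% NA_real_, q1 = d$cv$q1 %||% NA_real_,
    m2 = d$cv$m2 %||% NA_real_, q2 = d$cv$q2 %||% NA_real_,
    gamma = d$cv$gamma %||% NA_real_,
    cl = d$cv$cl %||% NA_real_, c_final = d$cv$c %||% NA_real_,
    pet0 = d$oc$pet0, pet1 = d$oc$pet1,
    alpha_e = d$oc$alpha_e, power_e = d$oc$power_e,
    en0 = d$oc$en0, en1 = d$oc$en1, enbar = d$oc$enbar
  )
}

#' Search minimax and optimal two-stage designs
#'
#' Double grid search over total sample size `N` (ascending from
#' `0.9 * n0` rounded up to even) and interim size `n_interim < N`. At each
#' pair the requested methods are calibrated with the `"closest"` selection
#' rule on shared simulated replicates; designs meeting both the type I error
#' bound and the power target are stored. When the starting `N` is already
#' feasible the search also descends below it until no design is found, and it
#' keeps ascending a few grid steps past the first feasible `N` so the optimal
#' (minimum `EN0`) design can be identified. The minimax design minimizes `N`
#' (ties: smaller `EN0`); the optimal design minimizes `EN0` (ties: smaller
#' `N`).
#'
#' @inheritParams calibrate_sculpted
#' @param spec A [scenario_spec()]. With an accrual *rate* the accrual period
#'   scales with `N`; with a fixed accrual *period* the rate does.
#' @param methods Any of `"sculpted"`, `"simple"`, `"logrank"`.
#' @param n_rep Simulated trials per hypothesis at each `N`.
#' @param n0 Single-stage reference size; computed by [single_stage_n0()]
#'   when `NULL`.
#' @param n_stride,interim_stride Even grid strides for `N` and `n_interim`.
#' @param interim_min Smallest interim sample size considered.
#' @param n_extra_steps Grid steps to continue past the first feasible `N`.
#' @param n_max Ascending cap (default `2 * n0`).
#' @param n_cl Interim-boundary grid size for the log-rank comparator.
#' @param seed Root seed; per-(hypothesis, N) substreams are derived from it.
#' @return An object of class `design_search`: stored designs (tibble
#'   `designs`), one `minimax` and one `optimal` row per method, `n0`, and
#'   the search settings.
#' @export
search_designs <- function(spec, alpha0 = 0.05, beta0 = 0.2,
                           methods = c("sculpted", "simple", "logrank"),
                           n_rep = 2000, n0 = NULL,
                           n_stride = 2, interim_stride = 2, interim_min = 20,
                           n_extra_steps = 5, n_max = NULL,
                           gamma_grid = default_gamma_grid(),
                           n_m = 81, n_cl = 61, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"),
            n_stride %% 2 == 0, interim_stride %% 2 == 0, interim_min %% 2 == 0)
  methods <- match.arg(methods, several.ok = TRUE)
  seed <- seed %||% sample.int(2^30, 1)
  if (is.null(n0)) {
    n0 <- single_stage_n0(spec, alpha0, beta0, n_rep = n_rep,
                          step = n_stride, seed = seed)
  }
  n_start <- ceiling(0.9 * n0 / 2) * 2
  n_max <- n_max %||% (2 * n0)
  needs_lr <- "logrank" %in% methods

  rows <- list()
  log_rows <- list()
  scan_n <- function(n_total) {
    if (interim_min > n_total - interim_stride) return(FALSE)
    banks <- lapply(c("H0", "H1"), function(h) {
      sim_bank(spec, n_total, h, n_rep,
               seed = derive_seed(seed, c(match(h, c("H0", "H1")), n_total)))
    })
    finals <- lapply(banks, bank_final_stats, tau2 = spec$tau, logrank = needs_lr)
    interim_grid <- seq(interim_min, n_total - interim_stride, by = interim_stride)
    found_any <- FALSE
    for (ni in interim_grid) {
      stats <- dplyr::bind_rows(purrr::map2(banks, finals, function(b, f) {
        bank_stage_stats(b, n_interim = ni, tau2 = spec$tau,
                         logrank = needs_lr, final_stats = f)
      }))
      for (method in methods) {
        d <- calibrate_method(method, stats, alpha0, beta0, rule = "closest",
                              gamma_grid, n_m, n_cl, ni, n_total)
        feasible <- !d$no_design && d$oc$power_e >= 1 - beta0
        log_rows[[length(log_rows) + 1]] <<- tibble(
          method = method, n_interim = ni, n_total = n_total,
          n_feasible = d$n_feasible, stored = feasible
        )
        if (feasible) {
          rows[[length(rows) + 1]] <<- design_row(d)
          found_any <- TRUE
        }
      }
    }
    found_any
  }

  # ascending phase
  first_feasible <- NA_integer_
  n <- n_start
  while (n <= n_max) {
    found <- scan_n(n)
    if (found && is.na(first_feasible)) first_feasible <- n
    if (!is.na(first_feasible) && n >= first_feasible + n_extra_steps * n_stride) break
    n <- n + n_stride
  }
  # descending continuation below the anchor
  if (!is.na(first_feasible) && first_feasible == n_start) {
    n <- n_start - n_stride
    while (n > interim_min && scan_n(n)) n <- n - n_stride
  }

  designs <- if (length(rows)) {
    dplyr::bind_rows(rows)
  } else {
    tibble(
      method = character(), n_interim = numeric(), n_total = numeric(),
      m1 = numeric(), q1 = numeric(), m2 = numeric(), q2 = numeric(),
      gamma = numeric(), cl = numeric(), c_final = numeric(),
      pet0 = numeric(), pet1 = numeric(), alpha_e = numeric(),
      power_e = numeric(), en0 = numeric(), en1 = numeric(), enbar = numeric()
    )
  }
  pick_per_method <- function(ord_cols) {
    designs |>
      dplyr::group_by(.data$method) |>
      dplyr::arrange(!!!rlang::syms(ord_cols), .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  }
  structure(
    list(
      designs = designs,
      minimax = pick_per_method(c("n_total", "en0")),
      optimal = pick_per_method(c("en0", "n_total")),
      n0 = as.integer(n0),
      feasibility_log = dplyr::bind_rows(log_rows),
      settings = list(
        alpha0 = alpha0, beta0 = beta0, methods = methods, n_rep = n_rep,
        n_stride = n_stride, interim_stride = interim_stride,
        interim_min = interim_min, n_extra_steps = n_extra_steps,
        n_max = n_max, seed = seed,
        scenario = scenario_fingerprint(spec)
      )
    ),
    class = "design_search"
  )
}

#' @export
print.design_search <- function(x, ...) {
  cat(sprintf("<design_search> scenario %s\n", x$settings$scenario))
  cat(sprintf("  n0 = %d, %d stored designs (B = %d per hypothesis)\n",
              x$n0, nrow(x$designs), x$settings$n_rep))
  if (nrow(x$designs)) {
    cat("  minimax:\n")
    print(as.data.frame(x$minimax[, c("method", "n_interim", "n_total",
                                      "alpha_e", "power_e", "en0")]),
          row.names = FALSE)
    cat("  optimal:\n")
    print(as.data.frame(x$optimal[, c("method", "n_interim", "n_total",
                                      "alpha_e", "power_e", "en0")]),
          row.names = FALSE)
  } else {
    cat("  no feasible design found\n")
  }
  invisible(x)
}

#' Power and early-termination curves versus interim sample size
#'
#' Fixes the total sample size and calibrates each method (maximum-power
#' rule) at a grid of interim sample sizes on shared replicates, tracing how
#' operating characteristics respond to the interim timing.
#'
#' @inheritParams search_designs
#' @param n_total Fixed total sample size.
#' @param n_interim_grid Even interim sizes, all `< n_total`.
#' @return A tibble of class `power_curve`: one row per (method, interim
#'   size) with the selected rule and its operating characteristics.
#' @export
power_vs_interim <- function(spec, n_total, n_interim_grid,
                             alpha0 = 0.05, beta0 = 0.2,
                             methods = c("sculpted", "simple", "logrank"),
                             n_rep = 2000,
                             gamma_grid = default_gamma_grid(),
                             n_m = 81, n_cl = 61, seed = NULL) {
  stopifnot(all(n_interim_grid %% 2 == 0), all(n_interim_grid < n_total))
  methods <- match.arg(methods, several.ok = TRUE)
  seed <- seed %||% sample.int(2^30, 1)
  needs_lr <- "logrank" %in% methods
  banks <- lapply(c("H0", "H1"), function(h) {
    sim_bank(spec, n_total, h, n_rep,
             seed = derive_seed(seed, c(match(h, c("H0", "H1")), n_total)))
  })
  finals <- lapply(banks, bank_final_stats, tau2 = spec$tau, logrank = needs_lr)
  rows <- purrr::map(n_interim_grid, function(ni) {
    stats <- dplyr::bind_rows(purrr::map2(banks, finals, function(b, f) {
      bank_stage_stats(b, n_interim = ni, tau2 = spec$tau,
                       logrank = needs_lr, final_stats = f)
    }))
    purrr::map(methods, function(method) {
      d <- calibrate_method(method, stats, alpha0, beta0, rule = "max",
                            gamma_grid, n_m, n_cl, ni, n_total)
      if (d$no_design) return(NULL)
      design_row(d)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  class(rows) <- c("power_curve", class(rows))
  rows
}

#' Type I error and power drift under misspecified hazards
#'
#' Applies a frozen calibrated decision rule to data simulated under drifted
#' exponential hazards. Drifting the experimental hazard (`lambda1`) changes
#' only the alternative, so the empirical type I error stays flat; drifting
#' the common control/null hazard (`lambda0`) changes both hypotheses, which
#' is where the sculpted rule pays for its extra power with more type I error
#' sensitivity.
#'
#' @param design A calibrated `rmst_design` (sculpted, simple, or logrank).
#' @param spec The base scenario the design was calibrated at; both arm
#'   models must be exponential.
#' @param lambda1_grid,lambda0_grid Drifted hazards (per year); exactly one
#'   must be supplied.
#' @inheritParams search_designs
#' @return A tibble of class `robustness_profile`: one row per drift value
#'   with the empirical operating characteristics of the frozen rule.
#' @export
robustness_profile <- function(design, spec, lambda1_grid = NULL,
                               lambda0_grid = NULL, n_rep = 2000, seed = NULL) {
  stopifnot(inherits(design, "rmst_design"), !design$no_design,
            inherits(spec, "scenario_spec"),
            spec$experimental$kind == "exponential",
            spec$control$kind == "exponential")
  if (is.null(lambda1_grid) == is.null(lambda0_grid)) {
    stop("supply exactly one of `lambda1_grid` and `lambda0_grid`", call. = FALSE)
  }
  seed <- seed %||% sample.int(2^30, 1)
  grid <- lambda1_grid %||% lambda0_grid
  what <- if (is.null(lambda0_grid)) "lambda1" else "lambda0"
  lam1 <- spec$experimental$lambda0 * spec$experimental$hr1
  lam0 <- spec$control$lambda0 * spec$control$hr1
  rows <- purrr::imap(grid, function(lam, i) {
    sc <- if (what == "lambda1") {
      scenario_spec(arm_model(lam), arm_model(lam0),
                    tau = spec$tau, followup = spec$followup,
                    accrual_rate = spec$accrual_rate,
                    accrual_period = spec$accrual_period)
    } else {
      scenario_spec(arm_model(lam1), arm_model(lam),
                    tau = spec$tau, followup = spec$followup,
                    accrual_rate = spec$accrual_rate,
                    accrual_period = spec$accrual_period)
    }
    stats <- simulate_stage_stats(
      sc, design$n_total, design$n_interim, n_rep = n_rep,
      logrank = design$method == "logrank",
      seed = derive_seed(seed, c(17L, i))
    )
    oc <- if (design$method == "logrank") {
      h0 <- stats[stats$hypothesis == "H0", ]
      h1 <- stats[stats$hypothesis == "H1", ]
      go0 <- h0$z1 > design$cv$cl
      go1 <- h1$z1 > design$cv$cl
      oc_row(mean(go0 & h0$z2 > design$cv$c),
             mean(go1 & h1$z2 > design$cv$c),
             1 - mean(go0), 1 - mean(go1),
             design$n_interim, design$n_total)
    } else {
      empirical_oc(stats, design$cv$m1, design$cv$q1,
                   design$cv$m2, design$cv$q2,
                   n_interim = design$n_interim, n_total = design$n_total)
    }
    dplyr::bind_cols(tibble(parameter = what, value = lam), oc)
  }) |> dplyr::bind_rows()
  class(rows) <- c("robustness_profile", class(rows))
  rows
}
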