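# Monte-Carlo engine: banks of simulated trials and per-replicate stage
# statistics. A bank holds the latent data of B replicates of one hypothesis
# at one total sample size; interim statistics for any interim size are
# derived from the same bank, so every interim analysis is nested in its
# final analysis and all methods are compared on identical replicates.

sim_bank <- function(spec, n_total, hypothesis, n_rep, seed = NULL) {
  stopifnot(n_total %% 2 == 0)
  if (!is.null(seed)) set.seed(seed)
  a <- accrual_period_for(spec, n_total)
  b <- spec$followup
  half <- n_total / 2L
  arms <- arm_for(spec, hypothesis)
  draw_arm <- function(model) {
    list(
      entry = matrix(runif(n_rep * half, 0, a), n_rep, half),
      time = matrix(draw_survival_time(model, runif(n_rep * half)), n_rep, half),
      cens = matrix(runif(n_rep * half, b, a + b), n_rep, half)
    )
  }
  list(
    a = a, b = b, half = half, n_rep = n_rep, n_total = n_total,
    hypothesis = hypothesis, tau = spec$tau,
    E = draw_arm(arms$E), C = draw_arm(arms$C)
  )
}

# Observed (time, status) for one replicate of one arm at calendar time tcal.
observe_row <- function(arm, j, tcal) {
  keep <- arm$entry[j, ] <= tcal
  if (!any(keep)) {
    stop("no patients enrolled in one arm at the interim calendar time", call. = FALSE)
  }
  cut <- pmin(arm$cens[j, keep], tcal - arm$entry[j, keep])
  tt <- arm$time[j, keep]
  list(time = pmin(tt, cut), status = as.integer(tt <= cut))
}

# Interim statistics at the expected accrual time of n_interim patients,
# tcal1 = a * n_interim / n_total. Interim RMSTs use the replicate's
# data-driven horizon tau1 (minimum over arms of the largest observed time).
bank_interim_stats <- function(bank, n_interim, logrank = FALSE) {
  n_rep <- bank$n_rep
  tcal1 <- bank$a * n_interim / bank$n_total
  d1 <- re1 <- tau1 <- numeric(n_rep)
  if (logrank) z1 <- w1 <- numeric(n_rep)
  for (j in seq_len(n_rep)) {
    # an interim analysis needs data from both arms; in the rare replicate
    # where one arm has not enrolled anyone by the scheduled time, the look
    # is deferred to the first time both arms have a patient
    tj <- max(tcal1, min(bank$E$entry[j, ]), min(bank$C$entry[j, ]))
    ei <- observe_row(bank$E, j, tj)
    ci <- observe_row(bank$C, j, tj)
    t1 <- min(max(ei$time), max(ci$time))
    ke <- rmst_core(ei$time, ei$status, t1, extend = TRUE)
    kc <- rmst_core(ci$time, ci$status, t1, extend = TRUE)
    tau1[j] <- t1
    re1[j] <- ke[1]
    d1[j] <- ke[1] - kc[1]
    if (logrank) {
      li <- logrank_core(c(ei$time, ci$time), c(ei$status, ci$status),
                         c(rep(TRUE, length(ei$time)), rep(FALSE, length(ci$time))))
      w1[j] <- li[1]
      z1[j] <- if (li[2] > 0) li[1] / sqrt(li[2]) else -Inf
    }
  }
  out <- tibble(tau1 = tau1, d1 = d1, re1 = re1)
  if (logrank) {
    out$w1 <- w1
    out$z1 <- z1
  }
  out
}

# Final-stage statistics at calendar time a + b, at the design horizon tau2,
# with the KM curve carried to tau2 when observations end earlier. These do
# not depend on the interim size, so searches compute them once per bank.
bank_final_stats <- function(bank, tau2 = bank$tau, logrank = FALSE) {
  n_rep <- bank$n_rep
  tcal2 <- bank$a + bank$b
  d2 <- re2 <- numeric(n_rep)
  if (logrank) z2 <- w2 <- numeric(n_rep)
  for (j in seq_len(n_rep)) {
    ef <- observe_row(bank$E, j, tcal2)
    cf <- observe_row(bank$C, j, tcal2)
    ke <- rmst_core(ef$time, ef$status, tau2, extend = TRUE)
    kc <- rmst_core(cf$time, cf$status, tau2, extend = TRUE)
    re2[j] <- ke[1]
    d2[j] <- ke[1] - kc[1]
    if (logrank) {
      lf <- logrank_core(c(ef$time, cf$time), c(ef$status, cf$status),
                         c(rep(TRUE, length(ef$time)), rep(FALSE, length(cf$time))))
      w2[j] <- lf[1]
      z2[j] <- if (lf[2] > 0) lf[1] / sqrt(lf[2]) else -Inf
    }
  }
  out <- tibble(d2 = d2, re2 = re2)
  if (logrank) {
    out$w2 <- w2
    out$z2 <- z2
  }
  out
}

# Per-replicate statistics of both stages of one bank.
bank_stage_stats <- function(bank, n_interim, tau2 = bank$tau, logrank = FALSE,
                             final_stats = NULL) {
  int <- bank_interim_stats(bank, n_interim, logrank = logrank)
  fin <- final_stats %||% bank_final_stats(bank, tau2, logrank = logrank)
  out <- dplyr::bind_cols(
    tibble(hypothesis = bank$hypothesis, rep = seq_len(bank$n_rep)),
    int, fin
  )
  out[, c("hypothesis", "rep", "tau1", "d1", "re1", "d2", "re2",
          if (logrank) c("w1", "z1", "w2", "z2"))]
}

#' Simulate paired interim/final stage statistics
#'
#' Runs the Monte-Carlo engine behind calibration: simulates `n_rep` trials
#' per hypothesis and returns, for each replicate, the interim RMST difference
#' and experimental-arm RMST (at the replicate's data-driven horizon `tau1`)
#' and the final-stage pair (at the design horizon `tau`), with the interim
#' snapshot nested inside the final data of the same trial. Optionally also
#' the standardized two-stage log-rank statistics.
#'
#' @param spec A [scenario_spec()].
#' @param n_total Total sample size `N` (even).
#' @param n_interim Interim sample size (even, `< n_total`); the interim
#'   analysis happens at the expected calendar time of its accrual.
#' @param n_rep Number of simulated trials per hypothesis.
#' @param hypotheses Which hypotheses to simulate (default both).
#' @param logrank Also compute per-stage log-rank statistics.
#' @param seed Root seed; per-hypothesis substreams are derived from it.
#' @return A tibble of class `stage_stats` with columns `hypothesis`, `rep`,
#'   `tau1`, `d1`, `re1`, `d2`, `re2` (plus `w1`, `w2`, `z1`, `z2` when
#'   `logrank = TRUE`), and attributes `n_total`, `n_interim`, `tau2`.
#' @examples
#' sc <- scenario_spec(arm_model(0.75), arm_model(1.5),
#'                     accrual_rate = 60, followup = 1, tau = 2)
#' st <- simulate_stage_stats(sc, n_total = 40, n_interim = 20,
#'                            n_rep = 50, seed = 1)
#' @export
simulate_stage_stats <- function(spec, n_total, n_interim, n_rep = 10000,
                                 hypotheses = c("H0", "H1"), logrank = FALSE,
                                 seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"),
            n_total %% 2 == 0, n_interim %% 2 == 0,
            n_interim > 0, n_interim <= n_total, n_rep >= 2)
  seed <- seed %||% sample.int(2^30, 1)
  out <- purrr::map(hypotheses, function(h) {
    bank <- sim_bank(spec, n_total, h, n_rep,
                     seed = derive_seed(seed, c(match(h, c("H0", "H1")), n_total)))
    bank_stage_stats(bank, n_interim, tau2 = spec$tau, logrank = logrank)
  })
  out <- dplyr::bind_rows(out)
  attr(out, "n_total") <- n_total
  attr(out, "n_interim") <- n_interim
  attr(out, "tau2") <- spec$tau
  attr(out, "seed") <- seed
  class(out) <- c("stage_stats", class(out))
  out
}
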