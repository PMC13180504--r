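#' Simulate patient-level data for one trial
#'
#' Draws a complete latent dataset for a 1:1 randomized two-arm trial:
#' `n / 2` patients per arm, entry times uniform on `[0, a]`, dropout-censoring
#' times (from entry) uniform on `[b, a + b]`, and event times from each arm's
#' survival model by inverse-CDF sampling. The returned table holds the latent
#' times; observable data at a given calendar time come from [snapshot()].
#'
#' @param spec A [scenario_spec()].
#' @param n Total number of patients (even; split equally between arms).
#' @param hypothesis `"H1"` (default) simulates the scenario as specified;
#'   `"H0"` gives both arms the control model.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `id`, `arm` (`"E"`/`"C"`), `entry`
#'   (calendar years), `event_time` and `censor_time` (years from entry).
#' @examples
#' sc <- scenario_spec(arm_model(0.75), arm_model(1.5),
#'                     accrual_rate = 60, followup = 1, tau = 2)
#' simulate_trial(sc, n = 8, seed = 1)
#' @export
simulate_trial <- function(spec, n, hypothesis = c("H1", "H0"), seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), is.numeric(n), length(n) == 1, n >= 2)
  hypothesis <- match.arg(hypothesis)
  if (n %% 2 != 0) {
    stop("`n` must be even: patients are randomized 1:1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  a <- accrual_period_for(spec, n)
  b <- spec$followup
  arms <- arm_for(spec, hypothesis)
  half <- n / 2
  one_arm <- function(model, label) {
    tibble(
      arm = label,
      entry = runif(half, 0, a),
      event_time = draw_survival_time(model, runif(half)),
      censor_time = runif(half, b, a + b)
    )
  }
  out <- dplyr::bind_rows(one_arm(arms$E, "E"), one_arm(arms$C, "C"))
  dplyr::mutate(out, id = dplyr::row_number(), .before = 1)
}

#' Administratively censored view of a trial at a calendar time
#'
#' Restricts a latent dataset to patients enrolled by `calendar_time` and
#' applies administrative censoring: the observed time is
#' `min(event_time, censor_time, calendar_time - entry)` and the event
#' indicator is 1 only when the event precedes both censoring mechanisms.
#' The final-analysis snapshot of a trial uses calendar time `a + b`.
#'
#' @param records Patient table from [simulate_trial()] (columns `id`, `arm`,
#'   `entry`, `event_time`, `censor_time`).
#' @param calendar_time Calendar time of the analysis (years, positive).
#' @param stage Label stored in the output, e.g. `"interim"` or `"final"`.
#' @return A tibble with columns `id`, `arm`, `entry`, `time` (observed,
#'   years from entry), `status` (1 event / 0 censored) and `snapshot`.
#' @export
snapshot <- function(records, calendar_time, stage = "interim") {
  stopifnot(is.data.frame(records),
            all(c("id", "arm", "entry", "event_time", "censor_time") %in% names(records)),
            is.numeric(calendar_time), length(calendar_time) == 1, calendar_time > 0)
  enrolled <- records[records$entry <= calendar_time, , drop = FALSE]
  if (nrow(enrolled) == 0) {
    stop("no patients enrolled by the requested calendar time", call. = FALSE)
  }
  admin <- calendar_time - enrolled$entry
  cut <- pmin(enrolled$censor_time, admin)
  tibble(
    id = enrolled$id,
    arm = enrolled$arm,
    entry = enrolled$entry,
    time = pmin(enrolled$event_time, cut),
    status = as.integer(enrolled$event_time <= cut),
    snapshot = stage
  )
}
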