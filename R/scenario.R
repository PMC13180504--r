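#' Trial scenario: arm models, accrual, censoring and the RMST horizon
#'
#' Bundles the generative description of one two-arm trial world. Patients are
#' randomized 1:1; entry times are uniform on `[0, a]` where `a` is the accrual
#' period; dropout-censoring times (measured from entry) are uniform on
#' `[b, a + b]` where `b` is the minimum follow-up, so the final analysis at
#' calendar time `a + b` guarantees every patient at least `b` years of
#' potential observation. Exactly one of `accrual_rate` and `accrual_period`
#' must be supplied: design searches vary the total sample size `N` and need a
#' constant rate `r`, with `a = N / r`.
#'
#' @param experimental,control [arm_model()] objects for the two arms.
#' @param tau RMST restriction time at the final analysis (years).
#' @param followup Minimum follow-up `b` (years), non-negative.
#' @param accrual_rate Patients accrued per year (`r`), or `NULL`.
#' @param accrual_period Accrual duration `a` in years, or `NULL`.
#' @return An object of class `scenario_spec`.
#' @examples
#' sc <- scenario_spec(
#'   experimental = arm_model(0.9),
#'   control = arm_model(0.9 * 1.7),
#'   accrual_rate = 60, followup = 1, tau = 2.5
#' )
#' @export
scenario_spec <- function(experimental, control, tau, followup = 1,
                          accrual_rate = NULL, accrual_period = NULL) {
  stopifnot(
    inherits(experimental, "arm_model"), inherits(control, "arm_model"),
    is.numeric(tau), length(tau) == 1, tau > 0,
    is.numeric(followup), length(followup) == 1, followup >= 0
  )
  if (is.null(accrual_rate) == is.null(accrual_period)) {
    stop("supply exactly one of `accrual_rate` and `accrual_period`", call. = FALSE)
  }
  if (!is.null(accrual_rate)) stopifnot(accrual_rate > 0) else stopifnot(accrual_period > 0)
  structure(
    list(
      experimental = experimental, control = control, tau = tau,
      followup = followup, accrual_rate = accrual_rate,
      accrual_period = accrual_period
    ),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>\n")
  cat("  experimental: "); print(x$experimental)
  cat("  control:      "); print(x$control)
  if (!is.null(x$accrual_rate)) {
    cat(sprintf("  accrual rate %g /year", x$accrual_rate))
  } else {
    cat(sprintf("  accrual period %g years", x$accrual_period))
  }
  cat(sprintf(", min follow-up %g years, tau %g years\n", x$followup, x$tau))
  invisible(x)
}

# Accrual period for a given total sample size.
accrual_period_for <- function(spec, n_total) {
  if (!is.null(spec$accrual_period)) spec$accrual_period else n_total / spec$accrual_rate
}

#' Null-hypothesis version of a scenario
#'
#' Under the null both arms share the control arm's survival model (the control
#' hazard under the alternative equals the common hazard under the null).
#'
#' @param spec A [scenario_spec()].
#' @return A `scenario_spec` whose experimental arm model equals the control's.
#' @export
under_null <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  spec$experimental <- spec$control
  spec
}

arm_for <- function(spec, hypothesis) {
  # per-hypothesis pair of arm models
  if (hypothesis == "H0") {
    list(E = spec$control, C = spec$control)
  } else {
    list(E = spec$experimental, C = spec$control)
  }
}

#' Read or write a scenario configuration file
#'
#' Scenario configurations are stored as YAML with blocks `experimental`,
#' `control` (fields `lambda0`, `hr1`, `hr2`, `change_time`) and top-level
#' `tau`, `followup`, and `accrual_rate` or `accrual_period`.
#'
#' @param path File path.
#' @return `read_scenario()` returns a [scenario_spec()];
#'   `write_scenario()` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  mk_arm <- function(a) {
    arm_model(
      lambda0 = a$lambda0,
      hr1 = a$hr1 %||% 1,
      hr2 = a$hr2 %||% a$hr1 %||% 1,
      change_time = a$change_time %||% 0
    )
  }
  scenario_spec(
    experimental = mk_arm(cfg$experimental),
    control = mk_arm(cfg$control),
    tau = cfg$tau,
    followup = cfg$followup %||% 1,
    accrual_rate = cfg$accrual_rate,
    accrual_period = cfg$accrual_period
  )
}

#' @param spec A [scenario_spec()] to serialize.
#' @rdname read_scenario
#' @export
write_scenario <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  dump_arm <- function(a) {
    list(lambda0 = a$lambda0, hr1 = a$hr1, hr2 = a$hr2, change_time = a$change_time)
  }
  cfg <- list(
    experimental = dump_arm(spec$experimental),
    control = dump_arm(spec$control),
    tau = spec$tau, followup = spec$followup
  )
  if (!is.null(spec$accrual_rate)) cfg$accrual_rate <- spec$accrual_rate
  if (!is.null(spec$accrual_period)) cfg$accrual_period <- spec$accrual_period
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# Short deterministic fingerprint used in output audit trails.
scenario_fingerprint <- function(spec) {
  fmt_arm <- function(a) {
    sprintf("l%g-h%g-h%g-ct%g", a$lambda0, a$hr1, a$hr2, a$change_time)
  }
  acc <- if (!is.null(spec$accrual_rate)) {
    sprintf("r%g", spec$accrual_rate)
  } else {
    sprintf("a%g", spec$accrual_period)
  }
  paste0("E[", fmt_arm(spec$experimental), "]C[", fmt_arm(spec$control), "]",
         acc, "-b", spec$followup, "-tau", spec$tau)
}
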