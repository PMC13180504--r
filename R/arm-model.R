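#' Survival model for one trial arm
#'
#' Describes the event-time distribution of a single arm as an exponential or
#' piecewise-exponential model. The hazard is `hr1 * lambda0` before
#' `change_time` and `hr2 * lambda0` afterwards, giving the survival function
#' \deqn{S(t) = \exp\{-hr_1 \lambda_0 (t \wedge CT) - hr_2 \lambda_0 (t - CT)_+\}.}
#' With `hr1 == hr2` (or `change_time = 0`) this collapses to an exponential
#' distribution with hazard `hr1 * lambda0`, which is how proportional-hazards
#' scenarios are expressed: the control arm uses `hr1 = 1` and the experimental
#' arm the hazard ratio of interest.
#'
#' @param lambda0 Baseline hazard (events per year), positive.
#' @param hr1 Hazard ratio applied before `change_time` (dimensionless, > 0).
#' @param hr2 Hazard ratio applied after `change_time`. Defaults to `hr1`,
#'   i.e. an exponential model.
#' @param change_time Time (years) at which the hazard ratio switches from
#'   `hr1` to `hr2`. Ignored when `hr1 == hr2`.
#'
#' @return An object of class `arm_model`.
#' @examples
#' control <- arm_model(lambda0 = 1.5)
#' late_benefit <- arm_model(lambda0 = 1.5, hr1 = 1, hr2 = 0.5, change_time = 0.5)
#' surv_prob(late_benefit, c(0.25, 1, 2))
#' @export
arm_model <- function(lambda0, hr1 = 1, hr2 = hr1, change_time = 0) {
  stopifnot(
    is.numeric(lambda0), length(lambda0) == 1, is.finite(lambda0), lambda0 > 0,
    is.numeric(hr1), length(hr1) == 1, is.finite(hr1), hr1 > 0,
    is.numeric(hr2), length(hr2) == 1, is.finite(hr2), hr2 > 0,
    is.numeric(change_time), length(change_time) == 1,
    is.finite(change_time), change_time >= 0
  )
  kind <- if (hr1 == hr2 || change_time == 0) "exponential" else "piecewise_exponential"
  if (kind == "exponential" && change_time == 0 && hr1 != hr2) {
    # hazard switches at 0: only hr2 ever applies
    hr1 <- hr2
  }
  structure(
    list(lambda0 = lambda0, hr1 = hr1, hr2 = hr2,
         change_time = change_time, kind = kind),
    class = "arm_model"
  )
}

#' @export
print.arm_model <- function(x, ...) {
  if (x$kind == "exponential") {
    cat(sprintf("<arm_model> exponential, hazard %.4g /year\n", x$lambda0 * x$hr1))
  } else {
    cat(sprintf(
      "<arm_model> piecewise exponential, lambda0 %.4g /year, HR %.3g -> %.3g at t = %.3g years\n",
      x$lambda0, x$hr1, x$hr2, x$change_time
    ))
  }
  invisible(x)
}

#' Survival probability of an arm model
#'
#' @param model An [arm_model()].
#' @param t Vector of times (years), non-negative.
#' @return `S(t)` for each element of `t`.
#' @export
surv_prob <- function(model, t) {
  stopifnot(inherits(model, "arm_model"), is.numeric(t), all(t >= 0))
  ct <- model$change_time
  h1 <- model$lambda0 * model$hr1
  h2 <- model$lambda0 * model$hr2
  if (model$kind == "exponential") {
    return(exp(-h1 * t))
  }
  exp(-h1 * pmin(t, ct) - h2 * pmax(t - ct, 0))
}

#' Inverse-CDF draw of event times
#'
#' Maps uniform(0, 1) variates to event times by inverting the model survival
#' function, so `draw_survival_time(model, u)` has survival function
#' `surv_prob(model, .)` when `u` is uniform.
#'
#' @param model An [arm_model()].
#' @param u Numeric vector of uniform(0, 1) variates (strictly inside (0, 1)).
#' @return Event times in years, one per element of `u`.
#' @examples
#' draw_survival_time(arm_model(1), exp(-2)) # exactly 2
#' @export
draw_survival_time <- function(model, u) {
  stopifnot(inherits(model, "arm_model"), is.numeric(u))
  if (any(!is.finite(u)) || any(u <= 0) || any(u >= 1)) {
    stop("`u` must be finite and strictly inside (0, 1)", call. = FALSE)
  }
  h1 <- model$lambda0 * model$hr1
  h2 <- model$lambda0 * model$hr2
  if (model$kind == "exponential") {
    return(-log(u) / h1)
  }
  ct <- model$change_time
  nl <- -log(u) # cumulative hazard to invert
  brk <- h1 * ct # cumulative hazard at the change time
  ifelse(nl <= brk, nl / h1, ct + (nl - brk) / h2)
}

#' True restricted mean survival time of an arm model
#'
#' Analytic integral of the model survival function on `[0, tau]`,
#' \eqn{R(\tau) = \int_0^\tau S(t)\,dt = E\min(T, \tau)}. Used as the
#' ground-truth effect size when configuring scenarios and as an oracle in
#' tests.
#'
#' @param model An [arm_model()].
#' @param tau Restriction time (years), positive.
#' @return RMST in years (a scalar; at most `tau`).
#' @examples
#' true_rmst(arm_model(1), 2) # (1 - exp(-2)) / 1
#' @export
true_rmst <- function(model, tau) {
  stopifnot(inherits(model, "arm_model"), is.numeric(tau), length(tau) == 1, tau > 0)
  h1 <- model$lambda0 * model$hr1
  h2 <- model$lambda0 * model$hr2
  ct <- model$change_time
  if (model$kind == "exponential" || tau <= ct) {
    return((1 - exp(-h1 * tau)) / h1)
  }
  (1 - exp(-h1 * ct)) / h1 + exp(-h1 * ct) * (1 - exp(-h2 * (tau - ct))) / h2
}
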