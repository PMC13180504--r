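#' Kaplan-Meier product-limit estimate
#'
#' Minimal product-limit estimator used throughout the package. Ties between
#' events and censorings at the same time follow the usual convention that
#' events happen first, i.e. censored subjects at time `t` are still at risk
#' for events at `t`.
#'
#' @param time Observed times (non-negative).
#' @param status Event indicators (1 event, 0 censored).
#' @return A tibble of class `km_curve` with one row per distinct observed
#'   time: `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @examples
#' km_fit(c(1, 2, 3), c(1, 0, 1))
#' @export
km_fit <- function(time, status) {
  stopifnot(is.numeric(time), length(time) >= 1, all(is.finite(time)), all(time >= 0))
  status <- as.integer(status)
  stopifnot(length(status) == length(time), all(status %in% c(0L, 1L)))
  n <- length(time)
  o <- order(time)
  tt <- time[o]
  ss <- status[o]
  new <- c(TRUE, tt[-1] != tt[-n])
  ends <- c(which(new[-1]) , n) # last index of each tie group
  cs <- cumsum(ss)
  d <- diff(c(0L, cs[ends]))
  cnt <- diff(c(0L, ends))
  n_risk <- n - cumsum(cnt) + cnt
  surv <- cumprod(1 - d / n_risk)
  out <- tibble(
    time = tt[new], n_risk = n_risk, n_event = d,
    n_censor = cnt - d, surv = surv
  )
  class(out) <- c("km_curve", class(out))
  out
}

# Fast scalar RMST kernel shared by the public interface and the Monte-Carlo
# engine. Returns c(estimate, variance, max observed time). `extend = TRUE`
# integrates the KM step function carried out to tau (the summation
# sum_j (t_{j+1} - t_j) S(t_j) with t_{D+1} = tau), which is always defined;
# `extend = FALSE` errors when tau exceeds the largest observed time.
rmst_core <- function(time, status, tau, extend = FALSE) {
  n <- length(time)
  o <- order(time)
  tt <- time[o]
  ss <- status[o]
  maxobs <- tt[n]
  if (!extend && tau > maxobs) {
    stop(sprintf(
      "tau = %g exceeds the largest observed time %g: RMST not estimable (use `extend = TRUE` to carry the survival curve to tau)",
      tau, maxobs
    ), call. = FALSE)
  }
  new <- c(TRUE, tt[-1] != tt[-n])
  ends <- c(which(new[-1]), n)
  cs <- cumsum(ss)
  d <- diff(c(0, cs[ends]))
  cnt <- diff(c(0, ends))
  Y <- n - cumsum(cnt) + cnt
  ut <- tt[new]
  keep <- d > 0 & ut < tau
  tj <- ut[keep]
  dj <- d[keep]
  Yj <- Y[keep]
  s <- cumprod(1 - dj / Yj)
  est <- sum(diff(c(0, tj, tau)) * c(1, s))
  if (length(tj) == 0) {
    return(c(est, 0, maxobs))
  }
  seg <- diff(c(tj, tau)) * s
  wk <- rev(cumsum(rev(seg))) # integral of S-hat from tj to tau
  gw <- ifelse(Yj - dj == 0, 0, dj / (Yj * (Yj - dj)))
  c(est, sum(wk^2 * gw), maxobs)
}

#' Restricted mean survival time with Greenwood-type variance
#'
#' Area under the Kaplan-Meier curve up to `tau`,
#' \eqn{\hat R(\tau) = \sum_{j=0}^{D} (t_{j+1} - t_j)\hat S(t_j)} with
#' \eqn{t_{D+1} = \tau}, and the standard product-limit variance
#' \eqn{\sum_j [\int_{t_j}^{\tau} \hat S(u) du]^2\, d_j / \{Y_j (Y_j - d_j)\}}
#' over event times before `tau`.
#'
#' By default `tau` may not exceed the largest observed time (an estimability
#' error mirroring common RMST software). With `extend = TRUE` the last value
#' of the step function is carried to `tau` — the convention the Monte-Carlo
#' design engine uses, since heavy-event configurations routinely exhaust all
#' observations before a fixed design horizon.
#'
#' @inheritParams km_fit
#' @param tau Restriction time (years).
#' @param extend Carry the KM curve beyond the last observed time (default
#'   `FALSE`).
#' @return A one-row tibble: `rmst`, `variance`, `tau`, `n`.
#' @examples
#' rmst(c(1, 3), c(1, 1), tau = 2) # area 1*1 + 1*0.5 = 1.5
#' @export
rmst <- function(time, status, tau, extend = FALSE) {
  stopifnot(is.numeric(time), length(time) >= 1, all(is.finite(time)), all(time >= 0),
            is.numeric(tau), length(tau) == 1, tau > 0)
  status <- as.integer(status)
  stopifnot(length(status) == length(time), all(status %in% c(0L, 1L)))
  z <- rmst_core(time, status, tau, extend = extend)
  tibble(rmst = z[1], variance = z[2], tau = tau, n = length(time))
}

#' Between-arm RMST difference
#'
#' `D(tau) = RMST(E) - RMST(C)`; the two arms are independent, so the variance
#' is the sum of the per-arm variances.
#'
#' @param data Patient-level data with columns `arm` (`"E"`/`"C"`), `time`,
#'   `status`, e.g. a [snapshot()].
#' @inheritParams rmst
#' @return One-row tibble: `diff`, `variance`, `rmst_e`, `rmst_c`,
#'   `var_e`, `var_c`, `tau`.
#' @export
rmst_difference <- function(data, tau, extend = FALSE) {
  stopifnot(is.data.frame(data), all(c("arm", "time", "status") %in% names(data)))
  e <- data[data$arm == "E", ]
  c_ <- data[data$arm == "C", ]
  if (nrow(e) == 0 || nrow(c_) == 0) stop("both arms must be non-empty", call. = FALSE)
  re <- rmst(e$time, e$status, tau, extend = extend)
  rc <- rmst(c_$time, c_$status, tau, extend = extend)
  tibble(
    diff = re$rmst - rc$rmst, variance = re$variance + rc$variance,
    rmst_e = re$rmst, rmst_c = rc$rmst,
    var_e = re$variance, var_c = rc$variance, tau = tau
  )
}

#' Single-stage RMST superiority test
#'
#' One-sided z-test on the RMST difference: reject the null of equal RMSTs
#' when \eqn{\hat D(\tau) > z_{1-\alpha}\sqrt{\widehat{Var}[\hat D(\tau)]}}.
#' The inequality is strict, so a boundary tie (including the degenerate
#' all-censored case with zero difference and zero variance) does not reject.
#'
#' @inheritParams rmst_difference
#' @param alpha One-sided type I error level in (0, 1).
#' @return One-row tibble: `reject`, `diff`, `threshold`, `z` (the
#'   standardized difference, `NA` when the variance is zero), `tau`, `alpha`.
#' @export
single_stage_test <- function(data, tau, alpha = 0.05, extend = FALSE) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  d <- rmst_difference(data, tau, extend = extend)
  threshold <- qnorm(1 - alpha) * sqrt(d$variance)
  tibble(
    reject = d$diff > threshold,
    diff = d$diff, threshold = threshold,
    z = ifelse(d$variance > 0, d$diff / sqrt(d$variance), NA_real_),
    tau = tau, alpha = alpha
  )
}

#' Data-dependent interim RMST horizon
#'
#' The interim restriction time is the minimum over arms of the largest
#' observed follow-up time (censored times included), so both interim RMSTs
#' are computed on a common horizon supported by the data of each arm.
#'
#' @param data Interim patient-level data with columns `arm`, `time`.
#' @return `tau1` in years.
#' @export
interim_tau <- function(data) {
  stopifnot(is.data.frame(data), all(c("arm", "time") %in% names(data)))
  e <- data$time[data$arm == "E"]
  c_ <- data$time[data$arm == "C"]
  if (length(e) == 0 || length(c_) == 0) {
    stop("both arms must have enrolled patients at interim", call. = FALSE)
  }
  min(max(e), max(c_))
}
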