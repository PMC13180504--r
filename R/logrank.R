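# Two-stage log-rank comparator: per-stage statistics, the Monte-Carlo
# estimate of the H0 correlation between stages, and the bivariate-normal
# type-I-error constraint that links the interim and final boundaries.

# Scalar kernel: observed-minus-expected sum over distinct event times, with
# the sign flipped so that positive values favor the experimental arm
# (fewer events in E than expected), and the hypergeometric variance.
logrank_core <- function(time, status, is_e) {
  o <- order(time)
  tt <- time[o]
  ss <- status[o]
  ee <- is_e[o]
  n <- length(tt)
  new <- c(TRUE, tt[-1] != tt[-n])
  ends <- c(which(new[-1]), n)
  cs_d <- cumsum(ss)
  cs_de <- cumsum(ss * ee)
  cs_e <- cumsum(ee)
  d <- diff(c(0, cs_d[ends]))
  de <- diff(c(0, cs_de[ends]))
  cnt <- diff(c(0, ends))
  ecnt <- diff(c(0, cs_e[ends]))
  Y <- n - cumsum(cnt) + cnt
  YE <- sum(ee) - cumsum(ecnt) + ecnt
  keep <- d > 0
  d <- d[keep]; de <- de[keep]; Y <- Y[keep]; YE <- YE[keep]
  p <- YE / Y
  w <- sum(d * p - de)
  vfac <- ifelse(Y > 1, (Y - d) / (Y - 1), 0)
  c(w, sum(d * p * (1 - p) * vfac))
}

#' Log-rank statistic of a pooled two-arm sample
#'
#' Observed-minus-expected event sum with hypergeometric variance over the
#' distinct event times, signed so that a positive statistic favors the
#' experimental arm. The standardized statistic `w / sqrt(variance)` is `NA`
#' (flagged `degenerate`) when the variance is zero, e.g. with no events.
#'
#' @param data Patient-level data with columns `arm` (`"E"`/`"C"`), `time`,
#'   `status`.
#' @return One-row tibble: `w`, `variance`, `z`, `n_event`, `degenerate`.
#' @export
logrank_stat <- function(data) {
  stopifnot(is.data.frame(data), all(c("arm", "time", "status") %in% names(data)))
  st <- logrank_core(data$time, as.integer(data$status), data$arm == "E")
  degenerate <- st[2] <= 0
  tibble(
    w = st[1], variance = st[2],
    z = ifelse(degenerate, NA_real_, st[1] / sqrt(st[2])),
    n_event = sum(data$status == 1), degenerate = degenerate
  )
}

#' Correlation between interim and final log-rank statistics under the null
#'
#' By the independent-increments property of the log-rank statistic the
#' correlation between the unstandardized interim statistic `W1` and the final
#' `W` is `sqrt(Var(W1) / Var(W))`; both variances are estimated by
#' Monte-Carlo over null replicates, so the estimate does not rely on
#' proportional hazards. The result is clipped to `[0, 1]`.
#'
#' @param w1,w Vectors of unstandardized interim and final statistics from
#'   the same null replicates.
#' @return Estimated correlation `rho0` in `[0, 1]`.
#' @export
estimate_rho0 <- function(w1, w) {
  stopifnot(length(w1) == length(w), length(w) >= 2)
  v1 <- var(w1)
  v <- var(w)
  if (v <= 0) stop("final-stage log-rank statistic has zero variance", call. = FALSE)
  min(1, max(0, sqrt(v1 / v)))
}

#' Upper tail of the standard bivariate normal
#'
#' `P(X > a, Y > b)` for standard normal `(X, Y)` with correlation `rho`,
#' computed by reducing to a single integral over the conditional
#' distribution, accurate to about 1e-10.
#'
#' @param a,b Lower bounds (may be infinite).
#' @param rho Correlation in `[-1, 1]`.
#' @return The tail probability.
#' @export
pbvnorm_upper <- function(a, b, rho) {
  stopifnot(is.numeric(rho), length(rho) == 1, abs(rho) <= 1)
  if (is.infinite(a) && a > 0) return(0)
  if (is.infinite(b) && b > 0) return(0)
  if (is.infinite(a)) return(pnorm(b, lower.tail = FALSE))
  if (is.infinite(b)) return(pnorm(a, lower.tail = FALSE))
  if (rho == 0) return(pnorm(a, lower.tail = FALSE) * pnorm(b, lower.tail = FALSE))
  if (rho == 1) return(pnorm(max(a, b), lower.tail = FALSE))
  if (rho == -1) return(max(0, pnorm(-b) - pnorm(a)))
  s <- sqrt(1 - rho^2)
  integrate(function(x) dnorm(x) * pnorm((rho * x - b) / s),
            lower = a, upper = Inf,
            rel.tol = 1e-12, abs.tol = 1e-14)$value
}

#' Final log-rank boundary for a given interim boundary
#'
#' Solves the two-stage type-I-error constraint
#' `P(Z1 > cl, Z > c | H0) = alpha0` for the final boundary `c`, where
#' `(Z1, Z)` is standard bivariate normal with correlation `rho0`. As
#' `cl -> -Inf` this reduces to the single-stage `c = qnorm(1 - alpha0)`.
#'
#' @param cl Interim boundary on the standardized statistic.
#' @param rho0 Interim/final correlation under the null (see
#'   [estimate_rho0()]).
#' @param alpha0 Type I error level in (0, 1).
#' @return The final boundary `c`, with `|P(Z1 > cl, Z > c) - alpha0| <= 1e-6`.
#' @export
solve_c <- function(cl, rho0, alpha0) {
  stopifnot(is.numeric(alpha0), length(alpha0) == 1, alpha0 > 0, alpha0 < 1)
  if (pnorm(cl, lower.tail = FALSE) <= alpha0) {
    stop("infeasible interim boundary: P(Z > cl) must exceed alpha0", call. = FALSE)
  }
  uniroot(
    function(cc) pbvnorm_upper(cl, cc, rho0) - alpha0,
    lower = -40, upper = 40, tol = 1e-10
  )$root
}

#' Calibrate the two-stage log-rank comparator
#'
#' Grid-searches the interim boundary `cl` over empirical quantiles of the
#' simulated null interim statistic; each final boundary `c` solves the
#' bivariate-normal type-I-error constraint [solve_c()] with the Monte-Carlo
#' correlation [estimate_rho0()]. Feasibility additionally requires the
#' empirical type I error on the null replicates to stay within `alpha0`;
#' selection mirrors the RMST rules for a fair comparison. Requires stage
#' statistics simulated with `logrank = TRUE`.
#'
#' @inheritParams calibrate_sculpted
#' @param n_cl Number of interim-boundary grid points (1st-99th percentile
#'   range).
#' @return An object of class `rmst_design` with `cv = list(cl, c, rho0)`.
#' @export
calibrate_logrank <- function(stats, alpha0 = 0.05, beta0 = 0.2,
                              rule = c("max", "closest"),
                              n_cl = 61, n_interim = NULL, n_total = NULL) {
  rule <- match.arg(rule)
  if (!all(c("z1", "z2", "w1", "w2") %in% names(stats))) {
    stop("stage statistics must be simulated with `logrank = TRUE`", call. = FALSE)
  }
  n_interim <- n_interim %||% attr(stats, "n_interim")
  n_total <- n_total %||% attr(stats, "n_total")
  h0 <- stats[stats$hypothesis == "H0", ]
  h1 <- stats[stats$hypothesis == "H1", ]
  if (nrow(h0) == 0 || nrow(h1) == 0 || nrow(h0) != nrow(h1)) {
    stop("need the same number of replicates under each hypothesis", call. = FALSE)
  }
  n_rep <- nrow(h0)
  rho0 <- estimate_rho0(h0$w1, h0$w2)
  cl_grid <- unique(quantile(h0$z1, probs = seq(0.01, 0.99, length.out = n_cl),
                             names = FALSE, type = 7))
  cl_grid <- cl_grid[pnorm(cl_grid, lower.tail = FALSE) > alpha0]
  if (length(cl_grid) == 0) {
    return(no_design_result("logrank", n_interim, n_total, alpha0, beta0, rule))
  }
  c_grid <- vapply(cl_grid, solve_c, numeric(1), rho0 = rho0, alpha0 = alpha0)
  s1_0 <- outer(h0$z1, cl_grid, `>`)
  s1_1 <- outer(h1$z1, cl_grid, `>`)
  alpha_e <- colMeans(s1_0 * outer(h0$z2, c_grid, `>`))
  power_e <- colMeans(s1_1 * outer(h1$z2, c_grid, `>`))
  pet0 <- 1 - colMeans(s1_0)
  pet1 <- 1 - colMeans(s1_1)
  feas <- which(alpha_e <= alpha0 + 1e-12)
  if (length(feas) == 0) {
    return(no_design_result("logrank", n_interim, n_total, alpha0, beta0, rule))
  }
  pick <- select_candidates(
    power = power_e[feas], pet0 = pet0[feas], qlast = cl_grid[feas],
    rule = rule, target = 1 - beta0
  )
  k <- feas[pick]
  new_design(
    method = "logrank",
    cv = list(cl = cl_grid[k], c = c_grid[k], rho0 = rho0),
    oc = oc_row(alpha_e[k], power_e[k], pet0[k], pet1[k], n_interim, n_total),
    n_interim = n_interim, n_total = n_total,
    alpha0 = alpha0, beta0 = beta0, rule = rule,
    n_rep = n_rep, n_feasible = length(feas)
  )
}
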