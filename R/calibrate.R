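# Calibration of the sculpted two-stage decision rule: the control function,
# truncated bivariate-normal conditional moments, the m -> q mapping, and the
# grid search over (gamma, m1, m2) under the empirical type-I-error constraint.

#' Interim-sample-size control function
#'
#' `f(n_interim) = exp(-gamma * n_interim / n_total)`, the conditional
#' probability threshold that links the sculpting constraints of the two
#' stages: stage 1 uses `f(n_interim)` and stage 2 the stricter `f(n_total)`,
#' so early analyses on few patients are sculpted leniently. Strictly
#' decreasing in both the interim fraction and `gamma`.
#'
#' @param n_interim Accumulated sample size at the analysis (0 < value <=
#'   `n_total`).
#' @param n_total Total planned sample size.
#' @param gamma Positive decay parameter.
#' @return A probability in (0, 1), vectorized over any argument.
#' @examples
#' control_f(60, 100, gamma = 1)
#' @export
control_f <- function(n_interim, n_total, gamma) {
  if (any(gamma <= 0)) stop("`gamma` must be positive", call. = FALSE)
  if (any(n_interim <= 0) || any(n_interim > n_total)) {
    stop("`n_interim` must be in (0, n_total]", call. = FALSE)
  }
  exp(-gamma * n_interim / n_total)
}

#' Stage-wise Monte-Carlo moments of the RMST statistics
#'
#' Means and covariance of the pair (RMST difference, experimental-arm RMST)
#' per stage, estimated from stage statistics simulated under the alternative
#' hypothesis only (the null replicates are reserved for empirical error
#' control). The covariance uses the outer-product estimator with divisor `B`.
#'
#' @param stats A `stage_stats` tibble (see [simulate_stage_stats()]); rows
#'   with `hypothesis == "H1"` are used.
#' @return A tibble of class `moment_summary` with one row per stage:
#'   `stage`, `mean_d`, `mean_re`, `var_d`, `var_re`, `cov`, `rho`.
#' @export
stage_moments <- function(stats) {
  h1 <- stats[stats$hypothesis == "H1", , drop = FALSE]
  if (nrow(h1) < 2) stop("need at least two replicates under H1", call. = FALSE)
  one <- function(d, re, stage) {
    b <- length(d)
    md <- mean(d)
    me <- mean(re)
    x <- cbind(d - md, re - me)
    sig <- crossprod(x) / b
    rho <- if (sig[1, 1] > 0 && sig[2, 2] > 0) {
      sig[1, 2] / sqrt(sig[1, 1] * sig[2, 2])
    } else {
      0
    }
    tibble(stage = stage, mean_d = md, mean_re = me,
           var_d = sig[1, 1], var_re = sig[2, 2], cov = sig[1, 2],
           rho = min(1, max(-1, rho)))
  }
  out <- dplyr::bind_rows(
    one(h1$d1, h1$re1, 1L),
    one(h1$d2, h1$re2, 2L)
  )
  class(out) <- c("moment_summary", class(out))
  out
}

#' Moments of a truncated bivariate-normal component
#'
#' For bivariate normal `(D, RE)` with marginal means `mu_d`, `mu_e`,
#' standard deviations `sigma_d`, `sigma_e` and correlation `rho`, returns the
#' mean and variance of `RE | D > m`:
#' \deqn{E = \mu_E + \rho\sigma_E \lambda(\theta), \quad
#'       Var = (1-\rho^2)\sigma_E^2 + \rho^2 \sigma_E^2
#'             \{1 + \theta\lambda(\theta) - \lambda(\theta)^2\},}
#' with \eqn{\theta = (m - \mu_D)/\sigma_D} and the inverse Mills ratio
#' \eqn{\lambda(\theta) = \phi(\theta)/\{1-\Phi(\theta)\}}. At `rho = 0` or
#' `m -> -Inf` this reduces to the unconditional marginal moments.
#'
#' @param mu_e,sigma_e Marginal mean / sd of the conditioned component.
#' @param mu_d,sigma_d Marginal mean / sd of the truncation component.
#' @param rho Correlation, in `[-1, 1]`.
#' @param m Truncation point(s); vectorized.
#' @return A tibble with columns `mean` and `variance`, one row per `m`.
#' @export
conditional_moments <- function(mu_e, sigma_e, mu_d, sigma_d, rho, m) {
  stopifnot(sigma_e > 0, sigma_d > 0, abs(rho) <= 1)
  theta <- (m - mu_d) / sigma_d
  surv <- pnorm(theta, lower.tail = FALSE)
  if (any(surv == 0 & is.finite(theta))) {
    stop("truncation point too extreme: P(D > m) underflows", call. = FALSE)
  }
  lam <- ifelse(
    is.infinite(theta) & theta < 0, 0,
    exp(dnorm(theta, log = TRUE) - pnorm(theta, lower.tail = FALSE, log.p = TRUE))
  )
  # truncated-normal variance deflation: Var(Z | Z > theta) = 1 + theta*lam - lam^2
  delta <- ifelse(is.infinite(theta) & theta < 0, 1,
                  pmin(1, pmax(0, 1 + theta * lam - lam^2)))
  tibble(
    mean = mu_e + rho * sigma_e * lam,
    variance = (1 - rho^2) * sigma_e^2 + rho^2 * sigma_e^2 * delta
  )
}

#' Sculpting threshold q for a given difference threshold m
#'
#' Given the stage moments, the critical value `q` is the upper
#' `target_prob` quantile of the normal approximation to `RE | D > m`:
#' `q = mean + qnorm(1 - target_prob) * sd`, so that
#' `P(RE > q | D > m) = target_prob`. With a degenerate conditional variance
#' the conditional mean is returned.
#'
#' @param moments A [stage_moments()] summary.
#' @param stage Stage index, 1 (interim) or 2 (final).
#' @param m Difference threshold(s); vectorized.
#' @param target_prob Conditional probability target in (0, 1), usually the
#'   [control_f()] value of the stage.
#' @return Numeric vector of `q` values.
#' @export
q_from_m <- function(moments, stage, m, target_prob) {
  stopifnot(inherits(moments, "moment_summary"),
            stage %in% c(1L, 2L),
            is.numeric(target_prob), length(target_prob) == 1,
            target_prob > 0, target_prob < 1)
  mo <- moments[moments$stage == stage, ]
  cm <- conditional_moments(
    mu_e = mo$mean_re, sigma_e = sqrt(mo$var_re),
    mu_d = mo$mean_d, sigma_d = sqrt(mo$var_d),
    rho = mo$rho, m = m
  )
  cm$mean + qnorm(1 - target_prob) * sqrt(cm$variance)
}

#' Expected sample size of a two-stage design
#'
#' `EN = n_interim * PET + n_total * (1 - PET)`: a trial stopped at interim
#' uses `n_interim` patients, one that continues uses all `n_total`.
#'
#' @param n_interim,n_total Interim and total sample sizes.
#' @param pet Probability of early termination in `[0, 1]`; vectorized.
#' @return Expected number of patients.
#' @examples
#' expected_sample_size(74, 128, 0.451) # 103.646
#' @export
expected_sample_size <- function(n_interim, n_total, pet) {
  stopifnot(all(pet >= 0 & pet <= 1))
  n_interim * pet + n_total * (1 - pet)
}

oc_row <- function(alpha_e, power_e, pet0, pet1, n_interim, n_total) {
  en0 <- expected_sample_size(n_interim, n_total, pet0)
  en1 <- expected_sample_size(n_interim, n_total, pet1)
  tibble(
    alpha_e = alpha_e, power_e = power_e, pet0 = pet0, pet1 = pet1,
    en0 = en0, en1 = en1, enbar = (en0 + en1) / 2
  )
}

#' Operating characteristics of a fixed decision rule
#'
#' Applies a four-threshold rule to paired stage statistics: a replicate stops
#' at interim when `d1 <= m1` or `re1 <= q1` and rejects the null when all of
#' `d1 > m1`, `re1 > q1`, `d2 > m2`, `re2 > q2` hold (strict inequalities;
#' boundary ties never reject). Empirical alpha comes from the null
#' replicates, power from the alternative ones, and expected sample sizes from
#' the early-termination probabilities.
#'
#' @param stats A `stage_stats` tibble with both hypotheses and equal
#'   replicate counts.
#' @param m1,q1,m2,q2 Critical values (years); `q1 = q2 = 0` gives the simple
#'   RMST difference rule.
#' @param n_interim,n_total Sample sizes; default to the attributes of
#'   `stats`.
#' @return One-row tibble: `alpha_e`, `power_e`, `pet0`, `pet1`, `en0`,
#'   `en1`, `enbar`.
#' @export
empirical_oc <- function(stats, m1, q1, m2, q2,
                         n_interim = NULL, n_total = NULL) {
  n_interim <- n_interim %||% attr(stats, "n_interim")
  n_total <- n_total %||% attr(stats, "n_total")
  h0 <- stats[stats$hypothesis == "H0", ]
  h1 <- stats[stats$hypothesis == "H1", ]
  if (nrow(h0) != nrow(h1) || nrow(h0) == 0) {
    stop("need the same positive number of replicates under each hypothesis",
         call. = FALSE)
  }
  go1_0 <- h0$d1 > m1 & h0$re1 > q1
  go1_1 <- h1$d1 > m1 & h1$re1 > q1
  oc_row(
    alpha_e = mean(go1_0 & h0$d2 > m2 & h0$re2 > q2),
    power_e = mean(go1_1 & h1$d2 > m2 & h1$re2 > q2),
    pet0 = 1 - mean(go1_0), pet1 = 1 - mean(go1_1),
    n_interim = n_interim, n_total = n_total
  )
}

# Vectorized tie-broken selection among feasible candidates.
# rule "max": highest power; rule "closest": smallest power at or above the
# target when any candidate reaches it, otherwise highest power below.
# Ties: larger pet0, then larger qlast (final-stage sculpting threshold).
select_candidates <- function(power, pet0, qlast, rule, target) {
  if (rule == "closest" && any(power >= target)) {
    ok <- power >= target
    power_ord <- ifelse(ok, -power, -Inf) # minimize power among those >= target
  } else {
    power_ord <- power
  }
  order(power_ord, pet0, qlast, decreasing = TRUE)[1]
}

new_design <- function(method, cv, oc, n_interim, n_total, alpha0, beta0,
                       rule, n_rep, n_feasible, feasible_set = NULL) {
  structure(
    list(
      method = method, cv = cv, oc = oc,
      n_interim = n_interim, n_total = n_total,
      alpha0 = alpha0, beta0 = beta0, rule = rule,
      n_rep = n_rep, n_feasible = n_feasible,
      feasible_set = feasible_set, no_design = FALSE
    ),
    class = "rmst_design"
  )
}

no_design_result <- function(method, n_interim, n_total, alpha0, beta0, rule) {
  structure(
    list(
      method = method, cv = NULL, oc = NULL,
      n_interim = n_interim, n_total = n_total,
      alpha0 = alpha0, beta0 = beta0, rule = rule,
      n_rep = NA_integer_, n_feasible = 0L,
      feasible_set = NULL, no_design = TRUE
    ),
    class = "rmst_design"
  )
}

#' @export
print.rmst_design <- function(x, ...) {
  cat(sprintf("<rmst_design> %s rule, n_interim = %s, n_total = %s\n",
              x$method, x$n_interim, x$n_total))
  if (x$no_design) {
    cat("  no feasible design (empirical alpha constraint unmet on the grid)\n")
    return(invisible(x))
  }
  if (x$method == "logrank") {
    cat(sprintf("  cl = %.4f, c = %.4f (rho0 = %.3f)\n",
                x$cv$cl, x$cv$c, x$cv$rho0))
  } else {
    cat(sprintf("  m1 = %.4f, q1 = %.4f, m2 = %.4f, q2 = %.4f%s\n",
                x$cv$m1, x$cv$q1, x$cv$m2, x$cv$q2,
                if (is.na(x$cv$gamma)) "" else sprintf(", gamma = %.2f", x$cv$gamma)))
  }
  cat(sprintf("  alphaE = %.4f, powerE = %.4f, PET0 = %.3f, PET1 = %.3f\n",
              x$oc$alpha_e, x$oc$power_e, x$oc$pet0, x$oc$pet1))
  cat(sprintf("  EN0 = %.3f, EN1 = %.3f, ENbar = %.3f  (B = %d, %d feasible)\n",
              x$oc$en0, x$oc$en1, x$oc$enbar, x$n_rep, x$n_feasible))
  invisible(x)
}

# Shared grid engine for the sculpted and simple rules. q1_fun / q2_fun map an
# m-grid to sculpting thresholds for one gamma value (identically 0 for the
# simple rule). Rejection-rate surfaces over (m1, m2) are crossproducts of
# per-stage pass indicator matrices, so the whole grid is evaluated in a few
# BLAS calls per gamma.
calibrate_grid <- function(stats, gamma_grid, q_for_gamma,
                           alpha0, beta0, rule, n_m,
                           n_interim, n_total, keep_feasible = FALSE,
                           method = "sculpted") {
  h0 <- stats[stats$hypothesis == "H0", ]
  h1 <- stats[stats$hypothesis == "H1", ]
  if (nrow(h0) != nrow(h1) || nrow(h0) < 2) {
    stop("need the same number (>= 2) of replicates under each hypothesis",
         call. = FALSE)
  }
  n_rep <- nrow(h0)
  # Threshold grids span the differences plausible under the design
  # alternative (the same replicates the calibration moments come from);
  # null replicates are reserved for error control. Grids anchored in the H0
  # left tail would admit strongly negative difference thresholds, i.e. a
  # degenerate near-single-arm rule.
  probs <- seq(0.01, 0.99, length.out = n_m)
  m1_grid <- unique(quantile(h1$d1, probs, names = FALSE))
  m2_grid <- unique(quantile(h1$d2, probs, names = FALSE))
  target <- 1 - beta0
  best <- NULL
  best_gamma <- NA_real_
  n_feasible_total <- 0L
  feasible_rows <- list()
  pass_matrix <- function(d, re, grid, q) {
    s <- outer(d, grid, `>`) & outer(re, q, `>`)
    storage.mode(s) <- "double"
    s
  }
  for (g in gamma_grid) {
    qq <- q_for_gamma(g, m1_grid, m2_grid)
    s1_0 <- pass_matrix(h0$d1, h0$re1, m1_grid, qq$q1)
    s1_1 <- pass_matrix(h1$d1, h1$re1, m1_grid, qq$q1)
    s2_0 <- pass_matrix(h0$d2, h0$re2, m2_grid, qq$q2)
    s2_1 <- pass_matrix(h1$d2, h1$re2, m2_grid, qq$q2)
    alpha_m <- crossprod(s1_0, s2_0) / n_rep
    power_m <- crossprod(s1_1, s2_1) / n_rep
    pet0_v <- 1 - colMeans(s1_0)
    pet1_v <- 1 - colMeans(s1_1)
    feas <- which(alpha_m <= alpha0 + 1e-12)
    n_feasible_total <- n_feasible_total + length(feas)
    if (length(feas) == 0) next
    idx <- arrayInd(feas, dim(alpha_m))
    k1 <- idx[, 1]
    k2 <- idx[, 2]
    if (keep_feasible) {
      feasible_rows[[length(feasible_rows) + 1]] <- tibble(
        gamma = if (method == "simple") NA_real_ else g,
        m1 = m1_grid[k1], q1 = qq$q1[k1],
        m2 = m2_grid[k2], q2 = qq$q2[k2],
        alpha_e = alpha_m[feas], power_e = power_m[feas],
        pet0 = pet0_v[k1], pet1 = pet1_v[k1]
      )
    }
    pick <- select_candidates(
      power = power_m[feas], pet0 = pet0_v[k1], qlast = qq$q2[k2],
      rule = rule, target = target
    )
    cand <- list(
      gamma = g,
      m1 = m1_grid[k1[pick]], q1 = qq$q1[k1[pick]],
      m2 = m2_grid[k2[pick]], q2 = qq$q2[k2[pick]],
      alpha_e = alpha_m[feas[pick]], power_e = power_m[feas[pick]],
      pet0 = pet0_v[k1[pick]], pet1 = pet1_v[k1[pick]]
    )
    if (is.null(best) || candidate_beats(cand, best, rule, target)) {
      best <- cand
      best_gamma <- g
    }
  }
  if (is.null(best)) {
    out <- no_design_result(method, n_interim, n_total, alpha0, beta0, rule)
    out$n_rep <- n_rep
    return(out)
  }
  new_design(
    method = method,
    cv = list(
      m1 = best$m1, q1 = best$q1, m2 = best$m2, q2 = best$q2,
      gamma = if (method == "simple") NA_real_ else best_gamma
    ),
    oc = oc_row(best$alpha_e, best$power_e, best$pet0, best$pet1,
                n_interim, n_total),
    n_interim = n_interim, n_total = n_total,
    alpha0 = alpha0, beta0 = beta0, rule = rule,
    n_rep = n_rep, n_feasible = n_feasible_total,
    feasible_set = if (keep_feasible) dplyr::bind_rows(feasible_rows) else NULL
  )
}

candidate_beats <- function(a, b, rule, target) {
  if (rule == "closest") {
    a_ge <- a$power_e >= target
    b_ge <- b$power_e >= target
    if (a_ge != b_ge) return(a_ge)
    if (a$power_e != b$power_e) {
      return(if (a_ge) a$power_e < b$power_e else a$power_e > b$power_e)
    }
  } else if (a$power_e != b$power_e) {
    return(a$power_e > b$power_e)
  }
  if (a$pet0 != b$pet0) return(a$pet0 > b$pet0)
  if (a$q2 != b$q2) return(a$q2 > b$q2)
  FALSE
}

#' Calibrate the sculpted two-stage RMST rule
#'
#' Grid-searches `(gamma, m1, m2)`; for each `gamma` and difference threshold
#' `m_i` the sculpting threshold `q_i` is the conditional quantile from
#' [q_from_m()] with target [control_f()] of the stage (`f(n_interim)` at
#' interim, `f(n_total)` at the final stage), using moments estimated from the
#' alternative-hypothesis replicates only. Combinations whose empirical type I
#' error exceeds `alpha0` are discarded; among the rest the selection rule
#' picks either the maximum empirical power (`"max"`, used when comparing
#' designs at a fixed sample size) or the power closest to `1 - beta0` from
#' above (`"closest"`, used inside the design search). An empty feasible set
#' yields a `no_design` result rather than an error.
#'
#' @inheritParams empirical_oc
#' @param alpha0 Type I error bound.
#' @param beta0 Type II error target (power target `1 - beta0`).
#' @param rule Selection rule, `"max"` or `"closest"`.
#' @param gamma_grid Values of the control-function decay parameter.
#' @param n_m Number of grid points per difference threshold; grids span the
#'   1st-99th percentile of the pooled simulated differences of the stage.
#' @param keep_feasible Also return the full feasible-set table for audit.
#' @return An object of class `rmst_design`; see [tidy()] and [glance()]
#'   methods.
#' @export
calibrate_sculpted <- function(stats, alpha0 = 0.05, beta0 = 0.2,
                               rule = c("max", "closest"),
                               gamma_grid = default_gamma_grid(),
                               n_m = 81, n_interim = NULL, n_total = NULL,
                               keep_feasible = FALSE) {
  rule <- match.arg(rule)
  n_interim <- n_interim %||% attr(stats, "n_interim")
  n_total <- n_total %||% attr(stats, "n_total")
  stopifnot(!is.null(n_interim), !is.null(n_total), length(gamma_grid) >= 1)
  moments <- stage_moments(stats)
  q_for_gamma <- function(g, m1_grid, m2_grid) {
    list(
      q1 = q_from_m(moments, 1L, m1_grid, control_f(n_interim, n_total, g)),
      q2 = q_from_m(moments, 2L, m2_grid, control_f(n_total, n_total, g))
    )
  }
  calibrate_grid(stats, gamma_grid, q_for_gamma, alpha0, beta0, rule, n_m,
                 n_interim, n_total, keep_feasible, method = "sculpted")
}

#' Calibrate the simple RMST difference rule
#'
#' The degenerate sculpted rule with `q1 = q2 = 0`: only the between-arm RMST
#' differences are thresholded (an RMST is non-negative, so the sculpting
#' constraints are inert). Same grids, feasibility filter and selection rules
#' as [calibrate_sculpted()].
#'
#' @inheritParams calibrate_sculpted
#' @return An object of class `rmst_design`.
#' @export
calibrate_simple <- function(stats, alpha0 = 0.05, beta0 = 0.2,
                             rule = c("max", "closest"),
                             n_m = 81, n_interim = NULL, n_total = NULL,
                             keep_feasible = FALSE) {
  rule <- match.arg(rule)
  n_interim <- n_interim %||% attr(stats, "n_interim")
  n_total <- n_total %||% attr(stats, "n_total")
  stopifnot(!is.null(n_interim), !is.null(n_total))
  q_zero <- function(g, m1_grid, m2_grid) {
    list(q1 = rep(0, length(m1_grid)), q2 = rep(0, length(m2_grid)))
  }
  calibrate_grid(stats, gamma_grid = 1, q_zero, alpha0, beta0, rule, n_m,
                 n_interim, n_total, keep_feasible, method = "simple")
}
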