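# Reporting and orchestration: side-by-side design tables in the canonical
# column layout, and application of a calibrated rule to patient-level data.

#' Side-by-side design table for a scenario
#'
#' Runs the full minimax/optimal search for each requested method and reports
#' one row per method in the standard column layout
#' `method, PET0, PET1, alphaE, powerE, EN0, EN1, ENbar, N_interim, N_total`.
#' Deterministic given the seed; rows for methods without a feasible design
#' carry `"no design"` in every numeric column (as `NA`) and the method name.
#'
#' @param config A named list (or path to a YAML file with the same fields):
#'   `scenario` (a [scenario_spec()] or path to a scenario YAML), `alpha0`,
#'   `beta0`, `methods`, `seed`, `n_rep`, `criterion` (`"minimax"` or
#'   `"optimal"`), plus any optional [search_designs()] grid settings
#'   (`n_stride`, `interim_stride`, `interim_min`, `n_m`, `n_cl`, `n0`).
#' @param out Optional CSV path; written with [utils::write.csv()].
#' @return The table as a tibble (invisibly also written to `out`), with the
#'   run settings attached as attribute `audit`.
#' @export
run_table <- function(config, out = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  spec <- config$scenario
  if (is.character(spec)) spec <- read_scenario(spec)
  stopifnot(inherits(spec, "scenario_spec"))
  methods <- config$methods %||% c("sculpted", "simple", "logrank")
  criterion <- config$criterion %||% "minimax"
  stopifnot(criterion %in% c("minimax", "optimal"))
  cols <- c("method", "PET0", "PET1", "alphaE", "powerE",
            "EN0", "EN1", "ENbar", "N_interim", "N_total")
  if (length(methods) == 0) {
    tab <- as_tibble(stats::setNames(
      c(list(character()), replicate(9, numeric(), simplify = FALSE)), cols))
  } else {
    sr <- search_designs(
      spec,
      alpha0 = config$alpha0 %||% 0.05, beta0 = config$beta0 %||% 0.2,
      methods = methods, n_rep = config$n_rep %||% 2000,
      n0 = config$n0, n_stride = config$n_stride %||% 2,
      interim_stride = config$interim_stride %||% 2,
      interim_min = config$interim_min %||% 20,
      n_m = config$n_m %||% 81, n_cl = config$n_cl %||% 61,
      seed = config$seed %||% 1
    )
    chosen <- if (criterion == "minimax") sr$minimax else sr$optimal
    tab <- purrr::map(methods, function(m) {
      row <- chosen[chosen$method == m, ]
      if (nrow(row) == 0) {
        tibble(method = paste(m, "(no design)"), PET0 = NA_real_,
               PET1 = NA_real_, alphaE = NA_real_, powerE = NA_real_,
               EN0 = NA_real_, EN1 = NA_real_, ENbar = NA_real_,
               N_interim = NA_real_, N_total = NA_real_)
      } else {
        tibble(method = m, PET0 = row$pet0, PET1 = row$pet1,
               alphaE = row$alpha_e, powerE = row$power_e,
               EN0 = row$en0, EN1 = row$en1, ENbar = row$enbar,
               N_interim = row$n_interim, N_total = row$n_total)
      }
    }) |> dplyr::bind_rows()
    attr(tab, "audit") <- list(
      scenario = scenario_fingerprint(spec),
      seed = config$seed %||% 1, n_rep = config$n_rep %||% 2000,
      criterion = criterion,
      package_version = as.character(utils::packageVersion("rmstsculpt"))
    )
  }
  if (!is.null(out)) {
    utils::write.csv(tab, out, row.names = FALSE)
  }
  tab
}

#' Apply a calibrated two-stage rule to trial data
#'
#' Evaluates the four sculpted comparisons on real (or simulated)
#' patient-level data: at interim the horizon is the data-driven
#' [interim_tau()], and the trial stops for futility when the RMST difference
#' or the experimental-arm RMST fails its threshold (strict inequalities:
#' boundary equality stops). If the trial continues, the final stage applies
#' the second pair of thresholds at the design horizon `tau2` and the null is
#' rejected only when all four comparisons pass.
#'
#' @param design A calibrated `rmst_design` (sculpted or simple), or a list
#'   with elements `m1`, `q1`, `m2`, `q2`.
#' @param interim_data,final_data Patient-level tables with columns `arm`,
#'   `time`, `status` (e.g. from [snapshot()] or the simulator's CSV).
#'   `final_data` may be `NULL` when only the interim decision is wanted.
#' @param tau2 Final-stage RMST horizon (years).
#' @return A list of class `decision_report`: `decision` (`"stop for
#'   futility"`, `"reject H0"`, `"do not reject H0"`, or `"continue to final
#'   stage"`), and a tibble `comparisons` with one row per evaluated
#'   comparison (`stage`, `statistic`, `value`, `threshold`, `pass`).
#' @export
apply_rule <- function(design, interim_data, final_data = NULL, tau2) {
  cv <- if (inherits(design, "rmst_design")) design$cv else design
  stopifnot(all(c("m1", "q1", "m2", "q2") %in% names(cv)))
  tau1 <- interim_tau(interim_data)
  d1 <- rmst_difference(interim_data, tau1)
  comp <- tibble(
    stage = c(1L, 1L),
    statistic = c("rmst difference", "experimental rmst"),
    value = c(d1$diff, d1$rmst_e),
    threshold = c(cv$m1, cv$q1),
    pass = c(d1$diff > cv$m1, d1$rmst_e > cv$q1)
  )
  if (!all(comp$pass)) {
    out <- list(decision = "stop for futility", comparisons = comp,
                tau1 = tau1, tau2 = tau2)
    class(out) <- "decision_report"
    return(out)
  }
  if (is.null(final_data)) {
    out <- list(decision = "continue to final stage", comparisons = comp,
                tau1 = tau1, tau2 = tau2)
    class(out) <- "decision_report"
    return(out)
  }
  d2 <- rmst_difference(final_data, tau2)
  comp <- dplyr::bind_rows(comp, tibble(
    stage = c(2L, 2L),
    statistic = c("rmst difference", "experimental rmst"),
    value = c(d2$diff, d2$rmst_e),
    threshold = c(cv$m2, cv$q2),
    pass = c(d2$diff > cv$m2, d2$rmst_e > cv$q2)
  ))
  out <- list(
    decision = if (all(comp$pass)) "reject H0" else "do not reject H0",
    comparisons = comp, tau1 = tau1, tau2 = tau2
  )
  class(out) <- "decision_report"
  out
}

#' @export
print.decision_report <- function(x, ...) {
  cat("<decision_report>\n")
  cat(sprintf("  interim horizon tau1 = %.4g years, final horizon tau2 = %.4g years\n",
              x$tau1, x$tau2))
  print(as.data.frame(x$comparisons), row.names = FALSE, digits = 4)
  cat(sprintf("  decision: %s\n", x$decision))
  invisible(x)
}
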