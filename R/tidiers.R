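# broom-style accessors for calibrated designs and search results.

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a calibrated design
#'
#' One row per critical value of the decision rule.
#'
#' @param x An `rmst_design`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.rmst_design <- function(x, ...) {
  if (x$no_design) {
    return(tibble(term = character(), estimate = numeric()))
  }
  cv <- x$cv[!vapply(x$cv, is.na, logical(1))]
  tibble(term = names(cv), estimate = unlist(cv, use.names = FALSE))
}

#' Glance at a calibrated design
#'
#' One-row summary of the operating characteristics.
#'
#' @inheritParams tidy.rmst_design
#' @return A one-row tibble: `method`, `n_interim`, `n_total`, `alpha_e`,
#'   `power_e`, `pet0`, `pet1`, `en0`, `en1`, `enbar`, `n_rep`,
#'   `n_feasible`, `no_design`.
#' @export
glance.rmst_design <- function(x, ...) {
  base <- tibble(method = x$method, n_interim = x$n_interim,
                 n_total = x$n_total)
  if (x$no_design) {
    return(dplyr::bind_cols(base, tibble(no_design = TRUE)))
  }
  dplyr::bind_cols(base, x$oc,
                   tibble(n_rep = x$n_rep, n_feasible = x$n_feasible,
                          no_design = FALSE))
}

#' Tidy a design search
#'
#' @param x A `design_search` result.
#' @param which `"designs"` (all stored), `"minimax"`, or `"optimal"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @export
tidy.design_search <- function(x, which = c("designs", "minimax", "optimal"),
                               ...) {
  which <- match.arg(which)
  x[[which]]
}
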