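# ggplot2 displays for curves produced by the design tools.

#' Plot operating characteristics versus interim sample size
#'
#' @param object A `power_curve` tibble from [power_vs_interim()].
#' @param ... Unused.
#' @return A ggplot faceting empirical power, type I error and the two
#'   early-termination probabilities over the interim sample size, one line
#'   per method.
#' @export
autoplot.power_curve <- function(object, ...) {
  long <- object |>
    dplyr::select("method", "n_interim", "alpha_e", "power_e", "pet0", "pet1") |>
    tidyr::pivot_longer(c("alpha_e", "power_e", "pet0", "pet1"),
                        names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_interim, y = .data$value,
                                     colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "interim sample size", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a robustness profile
#'
#' @param object A `robustness_profile` tibble from [robustness_profile()].
#' @param ... Unused.
#' @return A ggplot of empirical type I error and power against the drifted
#'   hazard.
#' @export
autoplot.robustness_profile <- function(object, ...) {
  long <- object |>
    dplyr::select("parameter", "value", "alpha_e", "power_e") |>
    tidyr::pivot_longer(c("alpha_e", "power_e"),
                        names_to = "quantity", values_to = "rate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$rate,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = unique(object$parameter)[1], y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Kaplan-Meier curve
#'
#' @param object A `km_curve` from [km_fit()].
#' @param ... Unused.
#' @return A ggplot step function of the survival estimate.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(time = 0, surv = 1),
    object[, c("time", "surv")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (years)", y = "survival probability") +
    ggplot2::theme_minimal()
}
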