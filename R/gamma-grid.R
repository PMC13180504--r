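#' Default grid for the control-function decay parameter
#'
#' Graded spacing: fine below 0.2 where the implied conditional quantile
#' `qnorm(1 - exp(-gamma))` changes fastest (this is where the sculpting
#' thresholds approach the lenient end and the feasibility boundary of the
#' empirical type I error usually lies), coarser toward 3 where one grid step
#' moves `q` by only a few hundredths of a conditional standard deviation.
#'
#' @return Numeric vector of 56 gamma values in (0, 3].
#' @export
default_gamma_grid <- function() {
  c(seq(0.01, 0.2, by = 0.01), seq(0.25, 1, by = 0.05), seq(1.1, 3, by = 0.1))
}
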