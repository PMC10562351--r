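# Report graphics (ggplot2, suggested dependency).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("ggplot2 is required for plotting")
  }
}

#' Plot the reliability curve of an evaluation report
#' @param report an [eval_report()].
#' @return a ggplot object.
#' @export
plot_calibration <- function(report) {
  need_ggplot()
  d <- report$calibration
  ggplot2::ggplot(d, ggplot2::aes(x = mean_predicted, y = observed_fraction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = count)) +
    ggplot2::geom_line() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted risk", y = "Observed AKI fraction",
                  title = "Calibration") +
    ggplot2::theme_minimal()
}

#' Plot the decision curve of an evaluation report
#' @param report an [eval_report()].
#' @return a ggplot object.
#' @export
plot_decision_curve <- function(report) {
  need_ggplot()
  d <- report$decision_curve
  ggplot2::ggplot(d, ggplot2::aes(x = threshold)) +
    ggplot2::geom_line(ggplot2::aes(y = net_benefit, colour = "model")) +
    ggplot2::geom_line(ggplot2::aes(y = treat_all, colour = "treat all")) +
    ggplot2::geom_line(ggplot2::aes(y = treat_none, colour = "treat none")) +
    ggplot2::coord_cartesian(ylim = c(-0.05, max(d$net_benefit) + 0.05)) +
    ggplot2::labs(x = "Decision threshold", y = "Net benefit", colour = NULL,
                  title = "Decision curve analysis") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("mean_predicted", "observed_fraction", "count",
                         "threshold", "net_benefit", "treat_all",
                         "treat_none"))
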