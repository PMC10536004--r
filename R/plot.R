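#' Plot simulated fraction-of-dose trajectories
#'
#' @param traj Tidy trajectory from [simulate_kinetics()].
#' @param compartments Optional subset of compartments/sinks to show.
#' @return A ggplot.
#' @export
plot_trajectories <- function(traj, compartments = NULL) {
  if (!is.null(compartments)) {
    traj <- traj[traj$compartment %in% compartments, ]
  }
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$time_h,
                                     y = .data$fraction_of_dose,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "fraction of dose",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.catekin_fit <- function(object, ...) {
  obs <- object$observed
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$fraction_of_dose)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted),
                       colour = "steelblue") +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "fraction of dose",
                  title = paste0("observed vs fitted",
                                 if (!is.na(object$catechin))
                                   paste0(" - ", object$catechin))) +
    ggplot2::theme_minimal()
}

#' Grouped bar chart of a factorial ANOVA with letter annotations
#'
#' Cell means with SEM error bars; catechins sharing a letter do not
#' differ under Tukey's HSD at the stored alpha.
#'
#' @param x A `catekin_anova`.
#' @return A ggplot.
#' @export
plot_factorial <- function(x) {
  stopifnot(inherits(x, "catekin_anova"))
  m <- x$means
  ggplot2::ggplot(m, ggplot2::aes(x = .data$catechin, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.15) +
    ggplot2::geom_text(ggplot2::aes(y = .data$mean + 1.6 * .data$sem,
                                    label = .data$letters),
                       vjust = 0) +
    ggplot2::labs(x = NULL, y = x$response) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.catekin_anova <- function(object, ...) plot_factorial(object)
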