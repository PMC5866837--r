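#' Plot a simulated blood concentration-time course
#'
#' @param object a `pbk_simulation`.
#' @param log_y log-scale the concentration axis.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pbk_simulation <- function(object, log_y = FALSE, ...) {
  p <- ggplot2::ggplot(object$timecourse,
                       ggplot2::aes(x = .data$time_h, y = .data$conc_blood_uM)) +
    ggplot2::geom_line() +
    ggplot2::annotate("point", x = object$tmax, y = object$cmax, shape = 1) +
    ggplot2::labs(x = "Time (h)", y = "Blood concentration (uM)",
                  title = paste0(object$chem$name, ", ", object$scenario$route,
                                 " ", object$scenario$dose, " mg/kg bw"),
                  subtitle = paste0("Cmax ", signif(object$cmax, 3),
                                    " uM at ", signif(object$tmax, 3), " h")) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a fitted Hill concentration-response curve
#'
#' @param object a `hill_fit`.
#' @param ... unused.
#' @return a ggplot with the data and the fitted sigmoid on a
#'   log10-concentration axis.
#' @export
autoplot.hill_fit <- function(object, ...) {
  rng <- range(object$data$conc_M)
  grid <- tibble::tibble(
    conc_M = 10^seq(log10(rng[1]), log10(rng[2]), length.out = 200))
  grid$fitted <- predict_hill(object, grid$conc_M)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$conc_M,
                               y = .data[[object$response_col]])) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration (M)", y = "Response (% of maximum)",
                  subtitle = paste0("EC50 ", signif(object$ec50, 3),
                                    " M, slope ", signif(object$slope, 3))) +
    ggplot2::theme_minimal()
}

#' Plot a benchmark-dose fit
#'
#' @param object a `bmd_fit`.
#' @param ... unused.
#' @return a ggplot of the dose-response data, the fitted exponential model,
#'   and the BMD with its confidence bounds.
#' @export
autoplot.bmd_fit <- function(object, ...) {
  fit <- object$fit
  dat <- fit$data
  grid <- tibble::tibble(dose = seq(0, max(dat$dose), length.out = 200))
  grid$fitted <- fit$a * exp(fit$b * grid$dose^fit$d)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$dose, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted)) +
    ggplot2::labs(x = "Dose (mg/kg bw)", y = "Response") +
    ggplot2::theme_minimal()
  if (object$accepted) {
    p <- p +
      ggplot2::geom_vline(xintercept = object$bmd10) +
      ggplot2::geom_vline(xintercept = c(object$bmdl10, object$bmdu10),
                          linetype = "dashed") +
      ggplot2::labs(subtitle = paste0("BMD", object$bmr * 100, " ",
                                      signif(object$bmd10, 3),
                                      " [", signif(object$bmdl10, 3), ", ",
                                      signif(object$bmdu10, 3), "] mg/kg bw"))
  }
  p
}

#' Bar chart of a sensitivity screen
#'
#' @param screen output of [sensitivity_screen()].
#' @param threshold reference lines at +/- threshold.
#' @return a ggplot.
#' @export
plot_sensitivity <- function(screen, threshold = 0.1) {
  ggplot2::ggplot(screen,
                  ggplot2::aes(x = stats::reorder(.data$parameter, .data$abs_sc),
                               y = .data$sc)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Normalized sensitivity coefficient") +
    ggplot2::theme_minimal()
}

#' Overlay predicted dose-response curves
#'
#' @param dose_response a table from [translate_curve()] (rows from several
#'   assays can be bound together; the `source` column maps to colour).
#' @return a ggplot with dose on a log axis.
#' @export
plot_dose_response <- function(dose_response) {
  ggplot2::ggplot(dose_response,
                  ggplot2::aes(x = .data$dose_mg_per_kg, y = .data$response_pct,
                               colour = .data$source)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Dose (mg/kg bw)", y = "Response (% of maximum)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
#' @importFrom stats setNames
NULL
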