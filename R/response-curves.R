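#' Normalize in vitro responses to percent of the compound maximum
#'
#' The maximum response the chemical induced in the assay is set to 100% and
#' every response is expressed relative to it. The maximal observed point maps
#' to exactly 100 regardless of the raw scale, and the operation is
#' idempotent.
#'
#' @param data a data frame with columns `conc_M` and `response` (raw assay
#'   units; at least one positive value).
#' @return a tibble with `conc_M`, `response`, and `response_pct`.
#' @examples
#' normalize_to_percent_max(
#'   data.frame(conc_M = c(1e-10, 1e-9, 1e-8), response = c(1, 2, 4)))
#' @export
normalize_to_percent_max <- function(data) {
  abort_if(!all(c("conc_M", "response") %in% names(data)),
           "`data` needs columns conc_M and response.")
  mx <- max(data$response, na.rm = TRUE)
  abort_if(!is.finite(mx) || mx <= 0,
           "Need at least one positive response to normalize.")
  tibble::as_tibble(data) |>
    dplyr::mutate(response_pct = 100 * .data$response / mx)
}

#' Fit a symmetrical sigmoidal (Hill) model to a concentration-response curve
#'
#' Least-squares fit of
#' `y = bottom + (top - bottom) / (1 + (ec50 / c)^slope)` on the
#' log10-concentration axis, with the EC50 log-parameterized for stability.
#' Starting values: bottom = min(y), top = max(y), EC50 = geometric
#' mid-concentration, slope = 1. At `c = ec50` the fitted response is
#' `(bottom + top) / 2` (Hill symmetry), and the EC50 is invariant to
#' rescaling the responses.
#'
#' @param data a data frame with columns `conc_M` (> 0) and a response column
#'   (`response_pct` if present, else `response`); at least 4 concentrations
#'   spanning the transition.
#' @return an object of class `hill_fit` with elements `bottom`, `top`,
#'   `ec50` (M), `slope`, `rss`, `data`, and the underlying `nls` fit.
#' @examples
#' curve <- make_hill_curve(ec50 = 1e-9, noise_sd_pct = 0, seed = 1)
#' fit_hill(curve)
#' @export
fit_hill <- function(data) {
  abort_if(!("conc_M" %in% names(data)), "`data` needs a conc_M column.")
  ycol <- if ("response_pct" %in% names(data)) "response_pct" else "response"
  abort_if(!(ycol %in% names(data)),
           "`data` needs a response_pct or response column.")
  abort_if(any(data$conc_M <= 0), "Concentrations must be > 0 (M).")
  abort_if(length(unique(data$conc_M)) < 4,
           "Need at least 4 distinct concentrations.")
  df <- data.frame(lc = log10(data$conc_M), y = data[[ycol]])
  start <- list(bottom = min(df$y), top = max(df$y),
                log_ec50 = mean(range(df$lc)), slope = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(slope * (log_ec50 - lc))),
      data = df, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      rlang::abort(paste0(
        "Hill fit did not converge (", conditionMessage(e),
        "); starting values were bottom=", signif(start$bottom, 3),
        ", top=", signif(start$top, 3),
        ", log10(ec50)=", signif(start$log_ec50, 3), ", slope=1."))
    })
  cf <- stats::coef(fit)
  structure(
    list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
         ec50 = unname(10^cf["log_ec50"]), slope = unname(cf["slope"]),
         rss = sum(stats::residuals(fit)^2),
         data = tibble::as_tibble(data), response_col = ycol, fit = fit),
    class = "hill_fit"
  )
}

#' Evaluate a Hill curve
#' @param object a `hill_fit`.
#' @param conc_M concentrations (M).
#' @return predicted responses.
#' @export
predict_hill <- function(object, conc_M) {
  object$bottom + (object$top - object$bottom) /
    (1 + (object$ec50 / conc_M)^object$slope)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit> bottom ", signif(x$bottom, 4), " | top ", signif(x$top, 4),
      " | EC50 ", signif(x$ec50, 4), " M | slope ", signif(x$slope, 4),
      " | RSS ", signif(x$rss, 4), "\n", sep = "")
  invisible(x)
}
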