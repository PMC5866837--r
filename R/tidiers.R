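#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a depletion fit
#' @param x a `depletion_fit`.
#' @param ... unused.
#' @return a tibble with one row per quantity (`term`, `estimate`).
#' @export
tidy.depletion_fit <- function(x, ...) {
  tibble::tibble(term = c("k", "clint_invitro"),
                 estimate = c(x$k, x$clint_invitro),
                 unit = c("1/min", "uL/min/mg protein"))
}

#' @rdname tidy.depletion_fit
#' @export
glance.depletion_fit <- function(x, ...) {
  tibble::tibble(k = x$k, clint_invitro = x$clint_invitro,
                 fit_r2 = x$fit_r2, window_points = length(x$window),
                 no_depletion = x$no_depletion, below_km = x$below_km)
}

#' Tidy a Hill fit
#' @param x a `hill_fit`.
#' @param ... unused.
#' @return a tibble of parameter estimates.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(term = c("bottom", "top", "ec50", "slope"),
                 estimate = c(x$bottom, x$top, x$ec50, x$slope))
}

#' @rdname tidy.hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(ec50 = x$ec50, slope = x$slope, rss = x$rss,
                 n = nrow(x$data))
}

#' Tidy an exponential dose-response fit
#' @param x an `exp_fit`.
#' @param ... unused.
#' @return a tibble of parameter estimates.
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "d", "sigma"),
                 estimate = c(x$a, x$b, x$d, x$sigma))
}

#' @rdname tidy.exp_fit
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, loglik_null = x$loglik_null,
                 converged = x$converged, accepted = x$accepted,
                 error_model = x$error_model)
}

#' Tidy a benchmark-dose result
#' @param x a `bmd_fit`.
#' @param ... unused.
#' @return a tibble with the BMD point estimate and bounds.
#' @export
tidy.bmd_fit <- function(x, ...) {
  tibble::tibble(term = c("bmd10", "bmdl10", "bmdu10"),
                 estimate = c(x$bmd10, x$bmdl10, x$bmdu10),
                 unit = "mg/kg bw")
}

#' @rdname tidy.bmd_fit
#' @export
glance.bmd_fit <- function(x, ...) {
  tibble::tibble(bmd10 = x$bmd10, bmdl10 = x$bmdl10, bmdu10 = x$bmdu10,
                 bmr = x$bmr, level = x$level, accepted = x$accepted,
                 loglik = x$fit$loglik)
}

#' Long-format time course of a simulation
#' @param x a `pbk_simulation`.
#' @param ... unused.
#' @return a tibble (`time_h`, `compartment`, `amount_umol`, `conc_uM`);
#'   `conc_uM` is the blood concentration, repeated per compartment row for
#'   the blood compartment and `NA` elsewhere.
#' @export
tidy.pbk_simulation <- function(x, ...) {
  x$timecourse |>
    tidyr::pivot_longer(-c("time_h", "conc_blood_uM"),
                        names_to = "compartment",
                        values_to = "amount_umol") |>
    dplyr::mutate(conc_uM = ifelse(.data$compartment == "blood",
                                   .data$conc_blood_uM, NA_real_)) |>
    dplyr::select("time_h", "compartment", "amount_umol", "conc_uM")
}

#' @rdname tidy.pbk_simulation
#' @export
glance.pbk_simulation <- function(x, ...) cmax_auc(x)
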