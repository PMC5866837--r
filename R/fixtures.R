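#' Synthetic substrate-depletion series
#'
#' Generates a depletion time course with the statistical structure the
#' clearance fitter assumes: first-order loss of the compound/control ratio,
#' `ratio = exp(-k_true * t)`, with multiplicative lognormal noise per
#' replicate and the t = 0 ratio forced to 1 (each time point has its own
#' control incubation, so the zero-time ratio is 1 by construction). The
#' default time grid is the 14-point incubation design 0-45 min.
#'
#' @param k_true true elimination rate constant (1/min), >= 0.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param n_replicates number of replicate incubations.
#' @param times time grid (min).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return a tibble (`time_min`, `replicate`, `ratio`) with the generating
#'   parameters attached as attribute `ground_truth`.
#' @examples
#' make_depletion(k_true = 0.0875, noise_cv = 0.05, seed = 42)
#' @export
make_depletion <- function(k_true = 0.0875, noise_cv = 0.05, n_replicates = 3,
                           times = c(0, 1, 2, 3, 4, 5, 7, 8.5, 10, 15, 20,
                                     25, 30, 45),
                           seed = NULL) {
  abort_if(k_true < 0 || noise_cv < 0, "`k_true` and `noise_cv` must be >= 0.")
  sdlog <- sqrt(log(1 + noise_cv^2))
  with_seed(seed, {
    out <- tidyr::expand_grid(replicate = seq_len(n_replicates),
                              time_min = times) |>
      dplyr::mutate(
        ratio = exp(-k_true * .data$time_min) *
          stats::rlnorm(dplyr::n(), meanlog = -sdlog^2 / 2, sdlog = sdlog),
        ratio = ifelse(.data$time_min == 0, 1, .data$ratio)
      )
    attr(out, "ground_truth") <- list(k_true = k_true, noise_cv = noise_cv)
    out
  })
}

#' Synthetic Hill concentration-response curve
#'
#' Emulates an in vitro estrogenicity curve: a symmetrical sigmoid on the
#' log-concentration axis with additive Gaussian noise on the percent scale.
#'
#' @param bottom,top,ec50,slope Hill parameters (ec50 in M).
#' @param noise_sd_pct additive noise SD in percent-of-maximum units.
#' @param conc concentration grid (M).
#' @param n_replicates replicates per concentration.
#' @param seed integer seed.
#' @return a tibble (`conc_M`, `response`) with attribute `ground_truth`.
#' @examples
#' make_hill_curve(ec50 = 1e-9, noise_sd_pct = 2, seed = 1)
#' @export
make_hill_curve <- function(bottom = 0, top = 100, ec50 = 1e-9, slope = 1,
                            noise_sd_pct = 2,
                            conc = 10^seq(-12, -6, by = 0.5),
                            n_replicates = 1, seed = NULL) {
  abort_if(ec50 <= 0 || any(conc <= 0), "Concentrations and EC50 must be > 0.")
  abort_if(noise_sd_pct < 0, "`noise_sd_pct` must be >= 0.")
  with_seed(seed, {
    out <- tidyr::expand_grid(replicate = seq_len(n_replicates),
                              conc_M = conc) |>
      dplyr::mutate(
        response = bottom + (top - bottom) / (1 + (ec50 / .data$conc_M)^slope) +
          stats::rnorm(dplyr::n(), sd = noise_sd_pct)
      ) |>
      dplyr::select("conc_M", "response")
    attr(out, "ground_truth") <- list(bottom = bottom, top = top, ec50 = ec50,
                                      slope = slope,
                                      noise_sd_pct = noise_sd_pct)
    out
  })
}

#' Synthetic uterotrophic dose-response data
#'
#' Emulates a rat uterotrophic assay: control uterus weight `a` (mg) growing
#' with dose as `a * exp(b * dose^d)`, with multiplicative lognormal
#' between-animal noise, on the dose design of an oral-gavage study.
#'
#' @param a control uterus weight (mg).
#' @param b,d exponential model parameters (per-dose potency and shape).
#' @param noise_cv between-animal coefficient of variation.
#' @param doses dose groups (mg/kg bw).
#' @param n_per_group animals per dose group.
#' @param seed integer seed.
#' @return a tibble (`dose_mg_per_kg`, `response`) with attribute
#'   `ground_truth` including the true benchmark dose at 10% BMR.
#' @examples
#' make_uterotrophic(a = 100, b = 2, d = 1, seed = 1)
#' @export
make_uterotrophic <- function(a = 100, b = 2, d = 1, noise_cv = 0.05,
                              doses = c(0, 0.01, 0.02, 0.04, 0.1, 0.2, 0.4),
                              n_per_group = 5, seed = NULL) {
  abort_if(a <= 0 || b < 0 || d < 1 || d > 4,
           "Need a > 0, b >= 0, d in [1, 4].")
  abort_if(noise_cv < 0 || any(doses < 0), "Noise and doses must be >= 0.")
  sdlog <- sqrt(log(1 + noise_cv^2))
  with_seed(seed, {
    out <- tidyr::expand_grid(dose_mg_per_kg = doses,
                              animal = seq_len(n_per_group)) |>
      dplyr::mutate(
        response = a * exp(b * .data$dose_mg_per_kg^d) *
          stats::rlnorm(dplyr::n(), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      ) |>
      dplyr::select("dose_mg_per_kg", "response")
    attr(out, "ground_truth") <- list(
      a = a, b = b, d = d, noise_cv = noise_cv,
      bmd10_true = if (b > 0) (log(1.1) / b)^(1 / d) else NA_real_)
    out
  })
}
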