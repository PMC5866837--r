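#' Intrinsic clearance from substrate-depletion time courses
#'
#' In a liver S9 incubation run under first-order conditions (substrate well
#' below Km, linear in protein), the parent compound disappears exponentially.
#' The depletion curve `ln(C_compound / C_control)` against incubation time is
#' linear; the negative slope over its linear part is the elimination rate
#' constant `k` (1/min), and the in vitro intrinsic clearance follows as
#' `CLint = V/P * k` (uL/min/mg protein) with `V` the incubation volume (uL)
#' and `P` the protein amount (mg).
#'
#' Replicates are pooled by averaging `ln(ratio)` per time point. The "linear
#' part" is selected automatically: among contiguous windows starting at t = 0
#' with at least `min_points` points, the longest window with r^2 >=
#' `r2_threshold` is used; if none qualifies, all points are used.
#'
#' @param data depletion measurements: a data frame with columns `time_min`,
#'   `ratio` (C_compound/C_control, > 0) and optionally `replicate`.
#' @param incubation_volume incubation volume V (uL).
#' @param protein_amount protein amount P in the incubation (mg).
#' @param substrate_conc substrate concentration (uM), optional, used by
#'   [check_substrate_below_km()].
#' @param km_lower_bound lowest reported Km (uM), optional.
#' @param min_points minimum window length for the linear-part search.
#' @param r2_threshold r^2 required for a window to count as linear.
#' @return an object of class `depletion_fit` with elements `k` (1/min),
#'   `clint_invitro` (uL/min/mg), `window` (indices of time points used),
#'   `fit_r2`, `no_depletion` flag, `below_km` flag (TRUE/FALSE/NA), and the
#'   pooled points used for the fit.
#' @examples
#' dep <- make_depletion(k_true = 0.05, noise_cv = 0, seed = 1)
#' fit_depletion(dep, incubation_volume = 200, protein_amount = 0.1)
#' @export
fit_depletion <- function(data, incubation_volume = 200, protein_amount = 0.1,
                          substrate_conc = NULL, km_lower_bound = NULL,
                          min_points = 5, r2_threshold = 0.9) {
  abort_if(!all(c("time_min", "ratio") %in% names(data)),
           "`data` needs columns time_min and ratio.")
  abort_if(any(!is.finite(data$ratio)) || any(data$ratio <= 0),
           "Depletion ratios must be positive (log scale fit).")
  abort_if(incubation_volume <= 0 || protein_amount <= 0,
           "Incubation volume and protein amount must be > 0.")
  pooled <- data |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(log_ratio = mean(log(.data$ratio)), .groups = "drop") |>
    dplyr::arrange(.data$time_min)
  n <- nrow(pooled)
  abort_if(n < 4, "Need at least 4 time points with positive ratios.")

  slope_r2 <- function(idx) {
    t <- pooled$time_min[idx]; y <- pooled$log_ratio[idx]
    fit <- stats::lm.fit(cbind(1, t), y)
    ssr <- sum(fit$residuals^2)
    sst <- sum((y - mean(y))^2)
    list(slope = fit$coefficients[2],
         r2 = if (sst > 0) 1 - ssr / sst else NA_real_)
  }

  window <- seq_len(n)
  if (n >= min_points) {
    for (end in rev(seq(min_points, n))) {
      cand <- slope_r2(seq_len(end))
      if (!is.na(cand$r2) && cand$r2 >= r2_threshold) {
        window <- seq_len(end)
        break
      }
    }
  }
  fit <- slope_r2(window)
  k <- max(0, -fit$slope)
  no_depletion <- !is.finite(fit$slope) || fit$slope >= 0 ||
    (!is.na(fit$r2) && k < .Machine$double.eps^0.5)
  if (is.na(fit$r2)) { # flat series: zero variance on the log scale
    k <- 0
    no_depletion <- TRUE
  }
  if (no_depletion && k == 0) {
    rlang::warn("No depletion detected; k = 0, CLint = 0.")
  }
  below_km <- check_substrate_below_km(substrate_conc, km_lower_bound,
                                       quiet = TRUE)
  structure(
    list(k = k,
         clint_invitro = clint_invitro(k, incubation_volume, protein_amount),
         window = window, fit_r2 = fit$r2, no_depletion = no_depletion,
         below_km = below_km,
         incubation_volume = incubation_volume,
         protein_amount = protein_amount,
         pooled = pooled),
    class = "depletion_fit"
  )
}

#' @export
print.depletion_fit <- function(x, ...) {
  cat("<depletion_fit> k = ", signif(x$k, 4), " /min, CLint = ",
      signif(x$clint_invitro, 4), " uL/min/mg (window ",
      min(x$window), "-", max(x$window), ", r2 = ", signif(x$fit_r2, 3),
      ")\n", sep = "")
  if (x$no_depletion) cat("  flag: no depletion\n")
  invisible(x)
}

#' In vitro intrinsic clearance from an elimination rate constant
#'
#' `CLint,in vitro (uL/min/mg protein) = V (uL) / P (mg) * k (1/min)`.
#'
#' @param k elimination rate constant (1/min), >= 0.
#' @param volume incubation volume (uL), > 0.
#' @param protein protein amount (mg), > 0.
#' @return intrinsic clearance in uL/min/mg protein.
#' @examples
#' clint_invitro(0.0875, 200, 0.1)
#' @export
clint_invitro <- function(k, volume, protein) {
  abort_if(any(volume <= 0) || any(protein <= 0),
           "`volume` and `protein` must be > 0.")
  abort_if(any(k < 0), "`k` must be >= 0.")
  volume / protein * k
}

#' Sum intrinsic clearances over metabolic pathways
#'
#' Single-co-factor incubations (NADPH, UDPGA, PAPS, acetyl CoA) each probe one
#' pathway; the total clearance is their arithmetic sum. Pathways from which no
#' clearance could be derived enter as `NA` and contribute 0.
#'
#' @param pathway_values numeric vector of per-pathway CLint values
#'   (uL/min/mg protein); `NA` marks a pathway with no derivable clearance.
#' @return the summed CLint (uL/min/mg protein).
#' @examples
#' sum_pathway_clints(c(NADPH = 154.7, UDPGA = 23.3, PAPS = 4.4,
#'                      acetyl_coa = NA))
#' @export
sum_pathway_clints <- function(pathway_values) {
  abort_if(any(pathway_values < 0, na.rm = TRUE),
           "Pathway CLint values must be >= 0.")
  if (length(pathway_values) == 0) return(0)
  sum(pathway_values, na.rm = TRUE)
}

#' Scale in vitro intrinsic clearance to whole-liver clearance
#'
#' Unit chain: `CLint (uL/min/mg) * 1e-6 L/uL * 60 min/h` gives L/h per mg S9
#' protein; multiplying by the liver S9 protein content (`s9_protein` g/kg
#' liver x 1000 mg/g) and the liver mass (kg) yields whole-liver clearance in
#' L/h.
#'
#' @param clint_invitro in vitro intrinsic clearance (uL/min/mg S9 protein).
#' @param s9_protein S9 protein content of liver (g/kg liver), default 87.
#' @param liver_mass liver mass (kg), > 0.
#' @return whole-liver clearance (L/h); linear in every argument.
#' @examples
#' scale_clint_to_liver(175, 87, 0.0085) # male-rat E2, 8.5 g liver
#' @export
scale_clint_to_liver <- function(clint_invitro, s9_protein = 87, liver_mass) {
  abort_if(any(liver_mass <= 0), "`liver_mass` must be > 0 (kg).")
  abort_if(any(s9_protein <= 0), "`s9_protein` must be > 0 (g/kg liver).")
  abort_if(any(clint_invitro < 0), "`clint_invitro` must be >= 0.")
  clint_invitro * 1e-6 * 60 * (s9_protein * 1000) * liver_mass
}

#' Check the first-order prerequisite of the substrate-depletion approach
#'
#' The depletion approach assumes the substrate concentration is below the
#' lowest Michaelis constant of the metabolizing enzymes, so depletion is
#' first-order. This surfaces a warning (never an error) when the condition
#' fails, and returns `NA` when no Km bound is available.
#'
#' @param substrate_conc substrate concentration in the incubation (uM).
#' @param km_lower_bound lowest reported Km (uM).
#' @param quiet suppress the warning.
#' @return `TRUE` if `substrate_conc < km_lower_bound`, `FALSE` if not,
#'   `NA` if either value is missing.
#' @examples
#' check_substrate_below_km(3, 18)
#' @export
check_substrate_below_km <- function(substrate_conc, km_lower_bound,
                                     quiet = FALSE) {
  if (is.null(substrate_conc) || is.null(km_lower_bound) ||
      is.na(substrate_conc) || is.na(km_lower_bound)) {
    return(NA)
  }
  ok <- substrate_conc < km_lower_bound
  if (!ok && !quiet) {
    rlang::warn(paste0("Substrate concentration (", substrate_conc,
                       " uM) is not below the Km lower bound (",
                       km_lower_bound, " uM); depletion may not be first-order."))
  }
  ok
}
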