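#' Oral dose producing a target blood Cmax
#'
#' Reverse dosimetry step: find the oral dose whose predicted blood Cmax
#' equals a target nominal blood concentration. Because every process in the
#' model is first-order, Cmax is proportional to dose; the implementation
#' computes Cmax per unit dose once, verifies proportionality at two doses
#' (ratio within 0.1%), and scales. If the linearity check ever fails (e.g. a
#' future nonlinear model variant), it falls back to bracketed root finding.
#'
#' @param target_conc target nominal blood concentration (uM), >= 0.
#' @param chem a [chemical_params()] object.
#' @param pc optional [partition_coefficients()].
#' @param phys a [physiology_params()] object.
#' @param ... passed to [pbk_simulate()] (solver tolerances).
#' @return the oral dose in mg/kg bw.
#' @examples
#' bpa <- chemical_params("BPA", mw = 228.29, log_pow = 3.32, papp_caco2 = 20,
#'                        clint_invitro = 392, fub_serum = 0.040)
#' find_oral_dose(0.5, bpa)
#' @export
find_oral_dose <- function(target_conc, chem, pc = NULL,
                           phys = physiology_params(), ...) {
  abort_if(any(target_conc < 0), "`target_conc` must be >= 0 (uM).")
  per_unit <- cmax_per_unit_dose(chem, pc, phys, check = TRUE, ...)
  if (is.na(per_unit)) { # linearity check failed: bracketed root finding
    return(vapply(target_conc, function(tc) {
      if (tc == 0) return(0)
      f <- function(ld) {
        pbk_simulate(chem, pc, phys,
                     exposure_scenario("oral", exp(ld)), ...)$cmax - tc
      }
      lo <- log(1e-8); hi <- log(1e5)
      abort_if(f(lo) > 0 || f(hi) < 0,
               "Target concentration not reachable within the dose bracket [1e-8, 1e5] mg/kg.")
      exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
    }, numeric(1)))
  }
  target_conc / per_unit
}

# Cmax per unit oral dose (uM per mg/kg), with an optional two-dose
# proportionality verification.
cmax_per_unit_dose <- function(chem, pc, phys, check = FALSE,
                               ref_dose = 1, ...) {
  c1 <- pbk_simulate(chem, pc, phys, exposure_scenario("oral", ref_dose), ...)$cmax
  if (check) {
    c2 <- pbk_simulate(chem, pc, phys,
                       exposure_scenario("oral", 2 * ref_dose), ...)$cmax
    if (abs(c2 / c1 - 2) > 2e-3) return(NA_real_)
  }
  c1 / ref_dose
}

#' Translate an in vitro concentration-response curve to a predicted in vivo
#' dose-response curve
#'
#' For each in vitro concentration the nominal blood concentration with equal
#' unbound level is computed with [correct_concentration()], and the oral dose
#' reaching that blood Cmax is found with [find_oral_dose()]. Responses (% of
#' the compound's maximum) carry over unchanged. The mapping is monotone:
#' ordered concentrations give ordered doses.
#'
#' @param curve a data frame with columns `conc_M` (molar, > 0) and
#'   `response_pct` (e.g. from [normalize_to_percent_max()]).
#' @param assay_fub fraction unbound in the assay medium, (0, 1].
#' @param fub_serum fraction unbound in rat serum, (0, 1]; defaults to
#'   `chem$fub_serum`.
#' @param chem,pc,phys model inputs as in [pbk_simulate()].
#' @param source label for the output rows (assay name).
#' @param ... passed to [pbk_simulate()].
#' @return a tibble with columns `dose_mg_per_kg`, `response_pct`, `source`,
#'   consumable by [fit_exponential()] / [bmd()].
#' @export
translate_curve <- function(curve, assay_fub, fub_serum = chem$fub_serum,
                            chem, pc = NULL, phys = physiology_params(),
                            source = NA_character_, ...) {
  abort_if(!all(c("conc_M", "response_pct") %in% names(curve)),
           "`curve` needs columns conc_M and response_pct.")
  abort_if(any(curve$conc_M <= 0), "Curve concentrations must be > 0 (M).")
  target <- correct_concentration(M_to_uM(curve$conc_M), assay_fub, fub_serum)
  per_unit <- cmax_per_unit_dose(chem, pc, phys, check = TRUE, ...)
  doses <- if (is.na(per_unit)) {
    find_oral_dose(target, chem, pc, phys, ...)
  } else {
    target / per_unit
  }
  tibble::tibble(dose_mg_per_kg = doses,
                 response_pct = curve$response_pct,
                 source = source)
}
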