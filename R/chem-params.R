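#' Chemical-specific PBK input parameters
#'
#' Bundles the per-compound inputs the minimal PBK model needs: molar mass,
#' lipophilicity (log Pow, used for tissue:blood partitioning), Caco-2 apparent
#' permeability (used for intestinal absorption), in vitro intrinsic clearance
#' per mg liver S9 protein, and fractions unbound in rat serum and in the assay
#' media of interest.
#'
#' @param name compound label.
#' @param mw molar mass (g/mol), > 0.
#' @param log_pow log10 octanol-water partition coefficient.
#' @param papp_caco2 apparent permeability from a Caco-2 transport assay, in
#'   1e-6 cm/s, > 0.
#' @param clint_invitro in vitro intrinsic clearance (uL/min/mg S9 protein),
#'   >= 0.
#' @param fub_serum fraction unbound in rat serum, in (0, 1].
#' @param fub_medium named list of fractions unbound in assay media
#'   (e.g. `list(YES = 1, ER_CALUX = 0.628)`), each in (0, 1].
#' @param partition_coefficients optional explicit [partition_coefficients()];
#'   when supplied it bypasses the QPPR estimate downstream.
#'
#' @return an object of class `chemical_params`.
#' @examples
#' estradiol <- chemical_params(
#'   name = "E2", mw = 272.38, log_pow = 4.01, papp_caco2 = 17,
#'   clint_invitro = 175, fub_serum = 0.050,
#'   fub_medium = list(YES = 1, ER_CALUX = 0.628, MCF7 = 0.628)
#' )
#' @export
chemical_params <- function(name, mw, log_pow, papp_caco2, clint_invitro,
                            fub_serum, fub_medium = list(),
                            partition_coefficients = NULL) {
  abort_if(!is.numeric(mw) || mw <= 0, "`mw` must be a positive molar mass (g/mol).")
  abort_if(!is.numeric(papp_caco2) || papp_caco2 <= 0,
           "`papp_caco2` must be positive (1e-6 cm/s).")
  abort_if(!is.numeric(clint_invitro) || clint_invitro < 0,
           "`clint_invitro` must be >= 0 (uL/min/mg protein).")
  check_fraction(fub_serum, "fub_serum")
  for (nm in names(fub_medium)) check_fraction(fub_medium[[nm]], paste0("fub_medium$", nm))
  if (!is.null(partition_coefficients)) {
    abort_if(!inherits(partition_coefficients, "partition_coefficients"),
             "`partition_coefficients` must be built with partition_coefficients().")
  }
  structure(
    list(name = name, mw = mw, log_pow = log_pow, papp_caco2 = papp_caco2,
         clint_invitro = clint_invitro, fub_serum = fub_serum,
         fub_medium = fub_medium, partition_coefficients = partition_coefficients),
    class = "chemical_params"
  )
}

check_fraction <- function(x, what) {
  abort_if(!is.numeric(x) || length(x) != 1 || x <= 0 || x > 1,
           paste0("`", what, "` must be a fraction in (0, 1]."))
}

#' @export
print.chemical_params <- function(x, ...) {
  cat("<chemical_params> ", x$name, "\n", sep = "")
  cat("  MW ", x$mw, " g/mol | log Pow ", x$log_pow,
      " | Papp,Caco-2 ", x$papp_caco2, "e-6 cm/s\n", sep = "")
  cat("  CLint ", x$clint_invitro, " uL/min/mg S9 | fub,serum ",
      x$fub_serum, "\n", sep = "")
  invisible(x)
}

#' In vivo intestinal permeability from Caco-2 permeability
#'
#' Converts an apparent permeability measured in the Caco-2 monolayer assay to
#' an estimated in vivo intestinal permeability with the log-log regression
#' `log10(Papp,in vivo) = 0.6836 * log10(Papp,Caco-2) - 0.5579`.
#'
#' The regression itself is unit-bound but its source does not travel with the
#' coefficient values, so the convention is explicit here: under the default
#' `"caco2_1e-6_invivo_1e-4"` the Caco-2 value is taken in 1e-6 cm/s and the
#' regression output is interpreted in 1e-4 cm/s (the jejunal effective
#' permeability scale), then converted to cm/h. `"raw_cm_s"` applies the
#' regression to plain cm/s on both sides.
#'
#' @param papp_caco2 Caco-2 apparent permeability, in 1e-6 cm/s (default
#'   convention), > 0.
#' @param unit_convention one of `"caco2_1e-6_invivo_1e-4"` (default) or
#'   `"raw_cm_s"`.
#' @return estimated in vivo permeability in cm/h; strictly increasing in the
#'   input.
#' @examples
#' papp_invivo_from_caco2(17) # E2
#' papp_invivo_from_caco2(20) # BPA
#' @export
papp_invivo_from_caco2 <- function(papp_caco2,
                                   unit_convention = c("caco2_1e-6_invivo_1e-4",
                                                       "raw_cm_s")) {
  unit_convention <- match.arg(unit_convention)
  abort_if(any(!is.finite(papp_caco2)) || any(papp_caco2 <= 0),
           "`papp_caco2` must be positive.")
  reg <- function(p) 10^(0.6836 * log10(p) - 0.5579)
  switch(unit_convention,
    "caco2_1e-6_invivo_1e-4" = cms_1e4_to_cmh(reg(papp_caco2)),
    "raw_cm_s" = reg(papp_caco2 * 1e-6) * 3600
  )
}

#' Explicit tissue:blood partition coefficients
#'
#' @param liver,fat,richly_perfused,slowly_perfused tissue:blood concentration
#'   ratios (dimensionless), all > 0.
#' @return an object of class `partition_coefficients`.
#' @seealso [partition_coefficients_qppr()] for the log Pow based estimate.
#' @export
partition_coefficients <- function(liver, fat, richly_perfused, slowly_perfused) {
  vals <- c(liver = liver, fat = fat, richly_perfused = richly_perfused,
            slowly_perfused = slowly_perfused)
  abort_if(any(!is.finite(vals)) || any(vals <= 0),
           "All partition coefficients must be finite and > 0.")
  structure(as.list(vals), class = "partition_coefficients")
}

#' @export
print.partition_coefficients <- function(x, ...) {
  cat("<partition_coefficients> liver ", signif(x$liver, 4),
      " | fat ", signif(x$fat, 4),
      " | richly ", signif(x$richly_perfused, 4),
      " | slowly ", signif(x$slowly_perfused, 4), "\n", sep = "")
  invisible(x)
}

#' Reference tissue composition for the QPPR partition estimate
#'
#' Approximate rat tissue neutral-lipid and water volume fractions in the style
#' of the tissue-composition-based QPPR literature, shipped as a reference
#' default for [partition_coefficients_qppr()]. Values are an approximate
#' transcription from published rodent tissue-composition tables; supply your
#' own table (or explicit partition coefficients) for decision-critical work.
#'
#' @return a tibble with columns `tissue`, `lipid`, `water`.
#' @export
qppr_tissue_composition <- function() {
  tibble::tibble(
    tissue = c("blood", "liver", "fat", "richly_perfused", "slowly_perfused"),
    lipid  = c(0.0023, 0.042, 0.853, 0.042, 0.010),
    water  = c(0.83,   0.72,  0.141, 0.72,  0.79)
  )
}

#' Tissue:blood partition coefficients from log Pow (QPPR)
#'
#' Estimates tissue:blood partition coefficients from the octanol-water
#' partition coefficient and tissue lipid/water composition:
#' `P = (lipid_t * Pow^n + water_t) / (lipid_blood * Pow^n + water_blood)`,
#' with `n = 1` for non-adipose tissues and an attenuated lipid affinity
#' `n = fat_exponent` (default 0.81) for adipose, reflecting the poorer
#' correspondence of octanol with storage fat.
#'
#' @param log_pow log10 octanol-water partition coefficient.
#' @param composition tissue composition table with columns `tissue`, `lipid`,
#'   `water`; must contain rows `blood`, `liver`, `fat`, `richly_perfused`,
#'   `slowly_perfused`. Defaults to [qppr_tissue_composition()].
#' @param fat_exponent exponent applied to Pow for adipose tissue.
#' @return a [partition_coefficients()] object. Deterministic: identical inputs
#'   give bit-identical outputs.
#' @examples
#' partition_coefficients_qppr(4.01) # E2
#' @export
partition_coefficients_qppr <- function(log_pow,
                                        composition = qppr_tissue_composition(),
                                        fat_exponent = 0.81) {
  needed <- c("blood", "liver", "fat", "richly_perfused", "slowly_perfused")
  abort_if(!all(c("tissue", "lipid", "water") %in% names(composition)),
           "`composition` needs columns tissue, lipid, water.")
  missing <- setdiff(needed, composition$tissue)
  abort_if(length(missing) > 0,
           paste0("`composition` is missing tissue(s): ",
                  paste(missing, collapse = ", ")))
  abort_if(any(composition$lipid < 0 | composition$lipid > 1 |
               composition$water < 0 | composition$water > 1),
           "Composition fractions must lie in [0, 1].")
  row <- function(t) composition[match(t, composition$tissue), ]
  pc_one <- function(t, n) {
    pow_n <- 10^(log_pow * n)
    b <- row("blood"); ti <- row(t)
    (ti$lipid * pow_n + ti$water) / (b$lipid * pow_n + b$water)
  }
  partition_coefficients(
    liver = pc_one("liver", 1),
    fat = pc_one("fat", fat_exponent),
    richly_perfused = pc_one("richly_perfused", 1),
    slowly_perfused = pc_one("slowly_perfused", 1)
  )
}

#' Intestinal absorption rate
#'
#' Absorption rate from one intestinal sub-compartment:
#' `rate (umol/h) = Papp,in vivo (cm/h) x surface area (cm^2) x luminal
#' concentration (mM)`, using 1 mM = 1 umol/cm^3 so the units close exactly.
#' Bilinear in permeability and concentration; zero whenever any factor is 0.
#'
#' @param papp_invivo in vivo permeability (cm/h), >= 0.
#' @param surface_area absorptive surface area (cm^2), >= 0.
#' @param lumen_conc luminal concentration of parent compound (mM), >= 0.
#' @return absorption rate in umol/h.
#' @examples
#' absorption_rate(0.1, 10, 1) # 1 umol/h
#' @export
absorption_rate <- function(papp_invivo, surface_area, lumen_conc) {
  abort_if(any(papp_invivo < 0) || any(surface_area < 0) || any(lumen_conc < 0),
           "All inputs to absorption_rate() must be >= 0.")
  papp_invivo * surface_area * lumen_conc
}
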