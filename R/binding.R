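#' Fraction unbound from rapid equilibrium dialysis
#'
#' In the RED assay the protein-containing matrix (serum or assay medium) sits
#' in the plasma chamber and protein-free buffer in the buffer chamber; at
#' equilibrium only free compound has crossed the membrane, so
#' `fub = concentration in buffer chamber / concentration in plasma chamber`.
#' Measurement noise can push the raw ratio slightly above 1 for protein-poor
#' matrices; such values are clipped to 1 with a warning.
#'
#' @param conc_buffer compound concentration in the buffer chamber (uM), > 0.
#' @param conc_plasma compound concentration in the plasma chamber (uM), > 0.
#' @return fraction unbound in (0, 1], vectorized over the inputs.
#' @examples
#' fub_from_red(0.25, 5.0) # 0.05, a highly bound compound in serum
#' @export
fub_from_red <- function(conc_buffer, conc_plasma) {
  abort_if(any(!is.finite(conc_plasma)) || any(conc_plasma <= 0),
           "Plasma-chamber concentration must be > 0.")
  abort_if(any(!is.finite(conc_buffer)) || any(conc_buffer <= 0),
           "Buffer-chamber concentration must be > 0; a zero reading is a data problem, not fub = 0.")
  fub <- conc_buffer / conc_plasma
  if (any(fub > 1)) {
    rlang::warn("RED ratio(s) > 1 clipped to 1 (measurement noise in a protein-poor matrix).")
    fub <- pmin(fub, 1)
  }
  fub
}

#' Summarize replicate RED measurements per matrix
#'
#' @param data a data frame with columns `matrix`, `conc_buffer`,
#'   `conc_plasma` and optionally `replicate`.
#' @return a tibble with one row per matrix: `fub_mean`, `fub_sd`, `n`.
#' @export
summarize_fub <- function(data) {
  abort_if(!all(c("matrix", "conc_buffer", "conc_plasma") %in% names(data)),
           "`data` needs columns matrix, conc_buffer, conc_plasma.")
  data |>
    dplyr::mutate(fub = fub_from_red(.data$conc_buffer, .data$conc_plasma)) |>
    dplyr::group_by(.data$matrix) |>
    dplyr::summarise(fub_mean = mean(.data$fub),
                     fub_sd = stats::sd(.data$fub),
                     n = dplyr::n(), .groups = "drop")
}

#' Free-fraction correction from in vitro medium to blood
#'
#' The biologically active concentration is taken to be the unbound one, so a
#' nominal in vitro concentration is translated to the nominal blood
#' concentration with the same unbound level:
#' `C_in vivo = C_in vitro * fub,in vitro / fub,in vivo`.
#' Blood:plasma partitioning is assumed to be 1 (serum fub stands for the
#' blood free fraction); pass an adjusted `fub_invivo` to override.
#'
#' @param c_invitro nominal in vitro concentration (uM), >= 0.
#' @param fub_invitro fraction unbound in the assay medium, (0, 1].
#' @param fub_invivo fraction unbound in serum/blood, (0, 1].
#' @return nominal blood concentration (uM); linear in `c_invitro`,
#'   increasing in `fub_invitro`, decreasing in `fub_invivo`. Satisfies the
#'   round trip `correct_concentration(correct_concentration(c, a, b), b, a)
#'   == c`.
#' @examples
#' correct_concentration(1, 1, 0.050)      # YES medium -> rat blood, E2
#' correct_concentration(1, 0.628, 0.050)  # ER-CALUX medium -> rat blood, E2
#' @export
correct_concentration <- function(c_invitro, fub_invitro, fub_invivo) {
  abort_if(any(c_invitro < 0), "`c_invitro` must be >= 0.")
  abort_if(any(fub_invitro <= 0 | fub_invitro > 1),
           "`fub_invitro` must be in (0, 1].")
  abort_if(any(fub_invivo <= 0 | fub_invivo > 1),
           "`fub_invivo` must be in (0, 1].")
  c_invitro * fub_invitro / fub_invivo
}
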