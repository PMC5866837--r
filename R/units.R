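#' Unit conversions used across the package
#'
#' All public interfaces use micromolar (uM) blood/medium concentrations and
#' mg/kg body weight doses. These helpers centralize every conversion so the
#' unit chain is auditable in one place.
#'
#' @name units
#' @keywords internal
NULL

#' Convert an administered dose from mg/kg bw to micromoles
#'
#' @param dose_mg_per_kg dose in mg per kg body weight
#' @param body_weight body weight in kg
#' @param mw molar mass in g/mol
#' @return dose in umol
#' @examples
#' dose_mgkg_to_umol(10, 0.25, 228.29) # 10 mg/kg BPA in a 250 g rat
#' @export
dose_mgkg_to_umol <- function(dose_mg_per_kg, body_weight, mw) {
  stopifnot(dose_mg_per_kg >= 0, body_weight > 0, mw > 0)
  # mg / (g/mol) = mmol; x1000 -> umol
  dose_mg_per_kg * body_weight / mw * 1000
}

#' Convert micromolar to molar and back
#' @param x concentration
#' @return converted concentration
#' @rdname units
#' @export
uM_to_M <- function(x) x * 1e-6

#' @rdname units
#' @export
M_to_uM <- function(x) x * 1e6

# cm/s expressed in 1e-6 cm/s units -> cm/h
cms_1e6_to_cmh <- function(x) x * 1e-6 * 3600

# cm/s expressed in 1e-4 cm/s units -> cm/h
cms_1e4_to_cmh <- function(x) x * 1e-4 * 3600

#' Run code with a temporary RNG seed, restoring RNG state afterwards
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

abort_if <- function(cond, msg) {
  if (cond) rlang::abort(msg)
  invisible(TRUE)
}
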