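#' Rat physiological and anatomical parameters
#'
#' Reference physiology for the minimal rat PBK model: compartment volumes as
#' fractions of body weight, blood flows as fractions of cardiac output, and
#' the geometry of the 7 sub-compartment small intestine. Defaults follow
#' standard reported rat values; the slowly perfused volume and flow fractions
#' are always computed by difference, so the sum constraints hold for any
#' perturbation of the explicit fractions (the slowly perfused compartment is
#' the slack variable).
#'
#' @param body_weight body weight (kg).
#' @param VLc,VFc,VBc,VRc liver, fat, blood and richly perfused tissue volumes
#'   as fractions of body weight. The slowly perfused fraction is
#'   `perfused_total - VLc - VFc - VBc - VRc`.
#' @param perfused_total total perfused fraction of body weight (the remainder
#'   is non-perfused mass: gut contents, fur, etc.).
#' @param cardiac_output cardiac output (L/h); default the allometric
#'   `15 * body_weight^0.74`.
#' @param QLc,QFc,QRc fractions of cardiac output to liver, fat and richly
#'   perfused tissue; the slowly perfused flow fraction is the remainder.
#' @param n_intestine number of small-intestinal sub-compartments.
#' @param intestine_length,intestine_radius small intestine length and luminal
#'   radius (cm); set per-sub-compartment volume `Vin` (mL) and surface area
#'   `SAin` (cm^2) unless those are given directly.
#' @param Vin,SAin per-sub-compartment luminal volume (mL) and surface area
#'   (cm^2); override the cylindrical geometry when supplied.
#' @param kin lumen-to-lumen transfer rate (1/h); the default gives a
#'   small-intestinal transit time of ~1.5 h across 7 sub-compartments.
#' @param stomach_emptying first-order gastric emptying rate (1/h); the
#'   default (6/h, a ~7 min emptying half-life) sits in the reported range
#'   for liquid dosing in fasted rats.
#' @param s9_protein liver S9 protein content (g per kg liver).
#' @return an object of class `physiology_params`.
#' @examples
#' physiology_params()
#' @export
physiology_params <- function(body_weight = 0.25,
                              VLc = 0.034, VFc = 0.07, VBc = 0.074, VRc = 0.05,
                              perfused_total = 0.91,
                              cardiac_output = NULL,
                              QLc = 0.25, QFc = 0.07, QRc = 0.51,
                              n_intestine = 7L,
                              intestine_length = 105, intestine_radius = 0.18,
                              Vin = NULL, SAin = NULL,
                              kin = n_intestine / 1.5,
                              stomach_emptying = 6,
                              s9_protein = 87) {
  abort_if(body_weight <= 0, "`body_weight` must be > 0.")
  fracs <- c(VLc = VLc, VFc = VFc, VBc = VBc, VRc = VRc)
  abort_if(any(fracs <= 0) || sum(fracs) >= perfused_total,
           "Volume fractions must be positive and sum to < `perfused_total`.")
  qf <- c(QLc = QLc, QFc = QFc, QRc = QRc)
  abort_if(any(qf <= 0) || sum(qf) >= 1,
           "Flow fractions must be positive and sum to < 1.")
  abort_if(kin < 0 || stomach_emptying < 0, "Rates must be >= 0.")
  abort_if(s9_protein <= 0, "`s9_protein` must be > 0 (g/kg liver).")
  if (is.null(cardiac_output)) cardiac_output <- 15 * body_weight^0.74
  if (is.null(Vin)) Vin <- pi * intestine_radius^2 * intestine_length / n_intestine
  if (is.null(SAin)) SAin <- 2 * pi * intestine_radius * intestine_length / n_intestine
  abort_if(Vin <= 0 || SAin < 0,
           "Intestinal volume must be positive and surface area non-negative.")
  structure(
    list(body_weight = body_weight,
         VLc = VLc, VFc = VFc, VBc = VBc, VRc = VRc,
         perfused_total = perfused_total,
         cardiac_output = cardiac_output,
         QLc = QLc, QFc = QFc, QRc = QRc,
         n_intestine = as.integer(n_intestine),
         Vin = Vin, SAin = SAin, kin = kin,
         stomach_emptying = stomach_emptying,
         s9_protein = s9_protein),
    class = "physiology_params"
  )
}

#' @export
print.physiology_params <- function(x, ...) {
  d <- phys_derived(x)
  cat("<physiology_params> rat, BW ", x$body_weight, " kg\n", sep = "")
  cat("  volumes (L): blood ", signif(d$VB, 3), ", liver ", signif(d$VL, 3),
      ", fat ", signif(d$VF, 3), ", rich ", signif(d$VR, 3),
      ", slow ", signif(d$VS, 3), "\n", sep = "")
  cat("  flows (L/h): QC ", signif(d$QC, 4), ", liver ", signif(d$QL, 3),
      ", fat ", signif(d$QF, 3), ", rich ", signif(d$QR, 3),
      ", slow ", signif(d$QS, 3), "\n", sep = "")
  cat("  intestine: ", x$n_intestine, " x (Vin ", signif(x$Vin, 3), " mL, SAin ",
      signif(x$SAin, 3), " cm^2), kin ", signif(x$kin, 3),
      " /h, stomach emptying ", signif(x$stomach_emptying, 3), " /h\n", sep = "")
  invisible(x)
}

# Absolute volumes (L, density 1 kg/L) and flows (L/h), with the slowly
# perfused compartment absorbing the remainders so sum constraints always hold.
phys_derived <- function(phys) {
  bw <- phys$body_weight
  VSc <- phys$perfused_total - phys$VLc - phys$VFc - phys$VBc - phys$VRc
  QSc <- 1 - phys$QLc - phys$QFc - phys$QRc
  abort_if(VSc <= 0 || QSc <= 0,
           "Slowly perfused remainder is non-positive; check fractions.")
  list(
    VL = phys$VLc * bw, VF = phys$VFc * bw, VB = phys$VBc * bw,
    VR = phys$VRc * bw, VS = VSc * bw,
    QC = phys$cardiac_output,
    QL = phys$QLc * phys$cardiac_output,
    QF = phys$QFc * phys$cardiac_output,
    QR = phys$QRc * phys$cardiac_output,
    QS = QSc * phys$cardiac_output,
    liver_mass = phys$VLc * bw # kg, density 1
  )
}
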