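---
title: "A minimal PBK model for reverse dosimetry of in vitro estrogenicity data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A minimal PBK model for reverse dosimetry of in vitro estrogenicity data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbkrd)
```

## The problem

Concentration–response data from in vitro estrogenicity assays cannot be used
directly for risk assessment, which needs in vivo dose–response data and
points of departure such as benchmark doses. `pbkrd` implements quantitative
in-vitro-to-in-vivo extrapolation (QIVIVE) by reverse dosimetry: a minimal
physiologically based kinetic (PBK) model of the rat predicts which oral dose
produces a blood peak concentration (C~max~) equal to each in vitro effect
concentration, after correcting for protein binding differences between assay
medium and serum. The approach is deliberately generic — every
chemical-specific parameter is derived from in vitro measurements (S9
substrate depletion, rapid equilibrium dialysis, Caco-2 permeability) or in
silico estimates (log P~ow~-based partitioning), never from in vivo fits — so
it can scale to chemicals for which no animal data exist.

## The kinetic model

The model has flow-limited compartments for blood, liver, fat, richly
perfused and slowly perfused tissue, plus a stomach and a small intestine
divided into 7 sub-compartments in series. For each perfused tissue T with
blood flow $Q_T$, volume $V_T$ and tissue:blood partition coefficient $P_T$:

$$\frac{dA_T}{dt} = Q_T\left(C_B - \frac{C_T}{P_T}\right)$$

with $C_B$ the blood concentration and $C_T = A_T/V_T$. An oral dose enters
the stomach and empties first-order (rate $k_s$) into the first intestinal
sub-compartment; luminal material moves down the chain at rate $k_{in}$ and
is absorbed from each sub-compartment $i$ into the liver (portal delivery)
at rate

$$R_i = P_{app,\,in\,vivo} \cdot SA_{in} \cdot \frac{A_{lumen,i}}{V_{in}},$$

in µmol/h with $P_{app}$ in cm/h, $SA_{in}$ in cm² and the luminal
concentration in mM (1 mM = 1 µmol/cm³, so the units close exactly).
Material leaving sub-compartment 7 unabsorbed is tallied separately. An IV
dose is a bolus into blood. The only clearance is hepatic metabolism, at rate
$CL_{liver} \cdot C_{liver}/P_{liver}$ (venous equilibration). Two modelling
conventions deserve emphasis:

* **Clearance acts on the total (not unbound) liver concentration**, because
  the in vitro CL~int~ is used as measured, without a binding correction.
  The convention is isolated in one term of the right-hand side
  (`pbk_rhs()`), so it can be switched if a restrictive-clearance variant is
  ever needed.
* **Everything is first-order**, which makes the system linear in the state:
  C~max~ is exactly proportional to dose. The reverse-dosimetry inversion
  exploits this (one simulation per chemical, verified by a two-dose
  proportionality check with a 0.1% tolerance, with bracketed root finding
  as a fallback for future nonlinear variants).

Whole-liver clearance is scaled from the in vitro value as
$CL_{liver}\,[\mathrm{L/h}] = CL_{int}\,[\mu\mathrm{L/min/mg}] \times 10^{-6}
\times 60 \times S9P\,[\mathrm{g/kg}] \times 10^{3} \times
M_{liver}\,[\mathrm{kg}]$ with the default S9 protein content of 87 g per kg
liver.

## Default physiology and its provenance

Defaults (all overridable in `physiology_params()`): body weight 0.25 kg;
volume fractions of body weight — liver 0.034, fat 0.07, blood 0.074, richly
perfused 0.05, slowly perfused by difference against a perfused total of
0.91; cardiac output $15 \cdot BW^{0.74}$ L/h with flow fractions 0.25
(liver, including portal), 0.07 (fat), 0.51 (richly perfused) and the
remainder to slowly perfused. These are standard reported rat values. The
slowly perfused compartment is always the slack variable: any perturbation
of an explicit fraction is absorbed there, so the sum constraints hold by
construction (this matters for the sensitivity analysis below).

The intestinal geometry is a cylinder of length 105 cm and luminal radius
0.18 cm split into 7 equal sub-compartments (per-compartment volume
$V_{in} \approx 1.53$ mL, surface area $SA_{in} \approx 17$ cm²); only the
surface-to-volume ratio matters for absorption kinetics. The lumen transfer
rate $k_{in} = 7/1.5$ h⁻¹ gives a small-intestinal transit time of ~1.5 h
across the chain. The gastric emptying rate default is 6 h⁻¹ (half-life
~7 min), in the reported 5–15 min range for liquid dosing in fasted rats and
chosen, within that range, as the value under which the model's predicted
oral C~max~ values for the two reference estrogens best match the reference
predictions this model family was built to reproduce. Both rates are plain
arguments; study-specific values take precedence whenever they are known.

Study-specific body weights are generally unknown for literature data; the
0.25 kg default is flagged as such and should be overridden when the source
reports weights.

## Chemical-specific inputs

* **Permeability.** The Caco-2 to in vivo regression
  $\log P_{app,\,in\,vivo} = 0.6836 \log P_{app,\,Caco2} - 0.5579$ is
  published without units attached to its coefficients. `pbkrd` makes the
  convention explicit: the default reads the Caco-2 value in $10^{-6}$ cm/s
  and the output in $10^{-4}$ cm/s (the jejunal effective-permeability
  scale) before converting to cm/h. This is the convention under which the
  downstream C~max~ predictions are of the right magnitude; a plain-cm/s
  alternative is available via `unit_convention = "raw_cm_s"`.
* **Partitioning.** Tissue:blood partition coefficients come from the
  tissue-composition QPPR
  $P_T = (L_T \cdot P_{ow}^{n} + W_T)/(L_B \cdot P_{ow}^{n} + W_B)$ with
  $n = 1$ for non-adipose tissue and $n = 0.81$ for fat (octanol is a poorer
  surrogate for storage fat). The shipped composition table
  (`qppr_tissue_composition()`) is an approximate transcription of published
  rodent values; explicitly supplied partition coefficients bypass the QPPR
  entirely and are the recommended route when measured or published values
  exist.
* **Clearance.** The substrate-depletion approach requires the substrate to
  sit below the lowest relevant K~m~ (checked, with a warning, by
  `check_substrate_below_km()`). The "linear part" of a depletion curve is
  selected automatically: among contiguous windows starting at t = 0 with at
  least 5 points, the longest window with $r^2 \ge 0.9$ wins, falling back
  to all points. This is reproducible and needs no manual curation; the
  threshold is an argument, and a stricter threshold (e.g. 0.99) trims
  late-time curvature harder at the cost of window length. Replicates are
  pooled by averaging ln(ratio) per time point — variance-stabilizing on the
  log scale, where the model is linear.
* **Binding.** f~ub~ is the buffer/plasma chamber concentration ratio of a
  RED measurement. Ratios slightly above 1 (noise in protein-poor matrices)
  clip to 1 with a warning rather than erroring; a zero buffer reading is
  treated as a data problem, never as f~ub~ = 0. Blood:plasma partitioning
  is assumed to be 1 (serum f~ub~ stands for the blood free fraction); pass
  an adjusted value to override.
* **Molar mass** is a user input; it is needed for the mg/kg → µmol dose
  conversion and is rarely printed alongside kinetic data.

## Reverse dosimetry

The biologically active concentration is taken to be the unbound one:
$C_{in\,vivo} = C_{in\,vitro} \cdot f_{ub,\,in\,vitro}/f_{ub,\,in\,vivo}$.
`translate_curve()` applies this per concentration, inverts the PBK model
for the dose, and carries responses (percent of the compound's maximum) over
unchanged. Because the pipeline is linear end-to-end, curve ordering and
fold differences in concentration are preserved exactly in dose space — an
assay that needs 100× higher concentrations maps to 100× higher predicted
doses.

## Benchmark-dose analysis

Predicted (and observed) dose–response tables are summarized with the
increasing exponential model for continuous data,
$y = a\,e^{b x^d}$ with $a > 0$, $b \ge 0$, $d \in [1, 4]$, fitted by
maximum likelihood with lognormal errors by default (responses are
positive-valued; uterus weights in particular are classically
log-normally distributed). The exponential family has several members; the
3-parameter increasing member was chosen as the simplest one that can
represent the low-dose rise the BMD concerns, and the likelihood code is
pluggable (a normal-error variant ships). On the log scale the model is
linear in $\log a$ and $b$ for fixed $d$, so the fit profiles $d$ by
one-dimensional optimization over $[1, 4]$ with the inner problem solved
exactly — no multidimensional starting-value fragility.

With a 10% benchmark response, the benchmark dose has the closed form
$BMD_{10} = (\ln 1.1 / b)^{1/d}$. Confidence bounds reparameterize the model
so the BMD is itself a parameter ($b = \ln(1.1)/BMD^d$) and profile the
likelihood, with the bounds at the $\chi^2_1$ cutoff for a two-sided 90%
interval — the convention that yields a one-sided 95% BMDL. A profile that
never reaches the cutoff within ±8 decades of the point estimate is reported
as an open-ended bound with a warning. A fit is only *accepted* (and a BMD
only reported) when it converges and beats the flat model in a
likelihood-ratio test at the 5% level; flat data therefore yield a flagged
result rather than a spurious BMD.

Two practical notes. First, the exponential model has upward curvature in
dose, while a saturating sigmoid is concave near its top: the model is meant
for the low-dose rise, and feeding it a fully saturated predicted curve will
(correctly) fit poorly. Second, predicted dose–response curves have no true
dose-0 control; the pipeline's BMD stage anchors the background at the
lowest predicted response so the benchmark response has a reference. Both
behaviours are deliberate and documented here rather than hidden.

## Sensitivity analysis

`sensitivity_screen()` computes normalized sensitivity coefficients
$SC = \frac{C' - C}{P' - P}\cdot\frac{P}{C}$ by one-at-a-time forward
perturbation at +5%, matching the published procedure for this model class
(a central difference would be numerically nicer but would not reproduce the
procedure). For the all-linear model the SC of dose on C~max~ is exactly 1,
which doubles as an implementation check. When a perturbed fraction feeds a
sum-to-one constraint, the slowly perfused remainder absorbs the difference,
so every perturbed model is still a valid physiology; this renormalization
choice is the package's own and is what makes fraction SCs well defined.

## Synthetic data

The generators produce data with exactly the statistical structure the
fitters assume: first-order depletion with multiplicative lognormal noise
and the t = 0 ratio pinned at 1 (each time point has its own co-factor-free
control); Hill curves with additive Gaussian noise on the percent scale;
uterotrophic responses $a\,e^{b x^d}$ with lognormal between-animal
variation (positive-valued weights). Defaults mirror the laboratory designs
the package targets: a 14-point 0–45 min incubation grid in triplicate, 5%
depletion CV, 2% assay noise, 5% between-animal CV, and a 7-group oral
gavage design (0–0.4 mg/kg bw). Every fixture carries its generating
parameters as a `ground_truth` attribute, so recovery tests always compare
against the truth, not against the fitter.

What passing tests on these fixtures show is that the estimators are
*correct under their own assumptions* — they do not show robustness to real
data's features that the generators omit: non-first-order depletion
(substrate above K~m~, enzyme loss over 45 min), cytotoxicity at high assay
concentrations, heteroscedastic or non-lognormal animal variation, and
between-study heterogeneity.

## Numerical choices

* ODE integration: `deSolve::lsoda` (switches to a stiff method as needed)
  at rtol 10⁻⁸ / atol 10⁻¹²; mass balance (all compartments + metabolized +
  unabsorbed vs dose) is checked at every output time and must close to
  10⁻⁶ relative; the tests additionally verify that halving the tolerances
  moves C~max~ by < 0.1%.
* C~max~: the coarse output grid (5 min resolution by default) is refined by
  dense re-integration from t = 0 over the bracketing interval of the grid
  maximum; refinement can only raise the estimate.
* Hill fitting: Levenberg–Marquardt on the log₁₀-concentration axis with a
  log-parameterized EC50; starting values bottom = min, top = max, EC50 at
  the geometric mid-concentration, slope 1. Non-convergence reports the
  starting values in the error. Bottom and top are left unconstrained; the
  normalization anchor is the *observed* maximum (mapped to exactly 100),
  with the fitted top retained for diagnostics.
* Degenerate inputs fail loudly and early: non-positive depletion ratios,
  zero plasma-chamber concentrations, all-zero responses, missing tissues in
  a composition table, unknown configuration keys.

## Test problem sizes

The test suite runs the property checks on 12–24 h simulations at 0.02–0.05 h
output resolution, the BMD coverage study on 250 seeded replicates of a
7 × 5-animal design, and estimator-recovery checks on triplicate fixtures at
the default noise levels; these sizes were chosen so the full suite settles
in well under a minute of compute per module while keeping Monte-Carlo error
small relative to the asserted tolerances.

## Known limitations

* Parent compound only; active metabolites would need their own sub-models.
* No renal clearance, no enterohepatic recirculation, no dermal or
  inhalation routes.
* C~max~ is the assumed internal dose metric; an AUC-based variant is out of
  scope by design.
* The QPPR composition table is an approximate transcription; for
  decision-critical work supply measured partition coefficients.
* Rat only; no interspecies extrapolation is attempted.
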