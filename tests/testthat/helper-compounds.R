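# Shared model inputs: the two reference estrogens with their measured
# physicochemical and kinetic parameters (male-rat CLint, serum/medium fub).
e2_params <- function(clint = 175) {
  chemical_params(
    name = "E2", mw = 272.38, log_pow = 4.01, papp_caco2 = 17,
    clint_invitro = clint, fub_serum = 0.050,
    fub_medium = list(YES = 1, ER_CALUX = 0.628, MCF7 = 0.628)
  )
}

bpa_params <- function(clint = 392) {
  chemical_params(
    name = "BPA", mw = 228.29, log_pow = 3.32, papp_caco2 = 20,
    clint_invitro = clint, fub_serum = 0.040,
    fub_medium = list(YES = 1, ER_CALUX = 0.461, MCF7 = 0.461)
  )
}

# a coarse but adequate grid keeps the many property-suite simulations fast
fast_scenario <- function(route, dose, duration = 12) {
  exposure_scenario(route, dose, duration,
                    times = seq(0, duration, by = 0.02))
}
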