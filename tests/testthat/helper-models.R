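# shared fixtures for the simulation tests: a slightly shortened axon
# (40 internodes, the minimum that still spans the white matter) keeps
# each integration cheap; results are cached per test run
test_morph <- function(ais_length = 20.3, ...) {
  morphology_spec(ais_length, n_internodes = 40, ...)
}

.model_cache <- new.env(parent = emptyenv())

cached_settled <- function(key, model) {
  if (is.null(.model_cache[[key]]))
    .model_cache[[key]] <- settle_model(model)
  .model_cache[[key]]
}

# hand-built uniform cable parameters for integrator oracles (bypasses the
# morphology layer on purpose: these tests probe the numerics directly)
uniform_cable_pars <- function(n, len_um, diam_um, gna = 0, gkdr = 0,
                               gleak = 1 / 30000, cm = 1, e_rest = -70,
                               ra = 150) {
  area <- pi * diam_um * len_um * 1e-8
  xarea <- pi * (diam_um * 1e-4)^2 / 4
  half_r <- ra * (len_um * 1e-4) / (2 * xarea)
  kin <- list(vs_act12 = 0, vs_inact12 = 0, vs_act16 = 0, vs_inact16 = 0)
  list(C = rep(cm * area * 1e3, n),
       gL = rep(gleak * area * 1e6, n),
       eL = rep(e_rest, n),
       gna12 = rep(0, n),
       gna16 = rep(gna * area * 1e6, n),
       gkdr = rep(gkdr * area * 1e6, n),
       gkv7 = rep(0, n),
       ga = rep(1e6 / (2 * half_r), n - 1),
       ena = 60, ek = -90, tadj = 1, kinetics = kin)
}

run_uniform <- function(pars, dt, n_steps, stim_nA, stim_idx, on, off,
                        record, v0 = -70) {
  st <- demyelin:::cable_init_gating(rep(v0, length(pars$C)),
                                     pars$kinetics, pars$tadj)
  demyelin:::cable_run(st, pars, dt, n_steps, stim_nA,
                       as.integer(stim_idx - 1), as.integer(on),
                       as.integer(off), as.integer(record - 1))
}

# calibrated channel set shared by the acceptance tests (computed once)
calibrated_chans <- function() {
  if (is.null(.model_cache$calib))
    .model_cache$calib <- calibrate_model()
  .model_cache$calib
}
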