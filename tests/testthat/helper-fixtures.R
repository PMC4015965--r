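# Shared fixture builders for the suite.  Everything is generated in code
# from small integer seeds.

quick_cfg <- function(seed = 1, n = 5) fixture_config(seed = seed, n_components = n)

quick_circuit <- function(seed = 1, fluctuations = no_fluctuations()) {
  make_circuit(quick_cfg(seed), fluctuations = fluctuations)
}

# A hand-specified repressor component with round numbers, used where tests
# recompute the regulation function independently.
hand_repressor <- function(id = "T3", P_M = 40, P_m = 0.5, K_tf = 20,
                           n_tf = 2, K_I = 5, n_I = 2) {
  prbs_component(id, "repressor_regulated", P_M = P_M, P_m = P_m,
                 K_tf = K_tf, n_tf = n_tf, K_I = K_I, n_I = n_I,
                 inducer_name = "aTc")
}

# Write a design spec as the JSON dialect the CLI reads.
write_spec_json <- function(spec, path) {
  payload <- c(list(type = if (inherits(spec, "amplifier_spec"))
    "amplifier" else "switch"), unclass(spec))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  path
}
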