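# shared fixtures: profiles and parameter sets used across test files

# a profile with hand-picked indifference points at the assessment intervals
fixed_profile <- function(p = c(`1` = 0.9, `4` = 0.7, `8` = 0.55,
                                `12` = 0.45)) {
  participant_profile(p)
}

# noise-free attractor parameters for deterministic integration checks
det_params <- function(...) {
  attractor_params(noise_sd = 0, ...)
}
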