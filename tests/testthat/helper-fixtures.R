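# Shared fixtures. Gonads are generated at reduced volume_scale where only
# estimator properties (not organ size) are under test: occupancy estimates
# depend on field-local densities, so scaling the organ down leaves their
# distribution essentially unchanged while keeping the suite fast.

cfg_noiseless <- function(...) {
  generator_config(gv_noise_cv = 0, ...)
}

# 1/10-size organs, default occupancy and diameter parameters
cfg_fast <- function(...) {
  generator_config(gv_noise_cv = 0, volume_scale = 0.1, ...)
}

# very small organs for exhaustive-geometry tests; fields shrunk to fit
cfg_tiny <- function(...) {
  generator_config(gv_noise_cv = 0, volume_scale = 0.001, ...)
}

plan_tiny <- function(...) {
  section_plan(field_dim = c(200, 150), ...)
}

# run one gonad through field sampling + estimation (the pipeline hot path)
estimate_one <- function(gonad, plan, config, seed, ...) {
  tab <- stereofec:::section_and_sample(gonad, plan, seed = seed)
  estimate_fecundity(tab, config = config, ...)
}
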