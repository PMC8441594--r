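# Shared fixtures: tiny life tables and parameter variants, built in code.

# life table with no background mortality until certain death at max_age
lt_zero <- function(min_age = 50, max_age = 100) {
  qx <- rep(0, max_age - min_age + 1)
  qx[length(qx)] <- 1
  life_table(min_age:max_age, qx)
}

# constant annual mortality q until certain death at max_age
lt_const <- function(q, min_age = 50, max_age = 100) {
  qx <- rep(q, max_age - min_age + 1)
  qx[length(qx)] <- 1
  life_table(min_age:max_age, qx)
}

# default parameters with fields overridden (bypasses re-derivation of rr)
params_with <- function(...) {
  p <- default_parameters()
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  p
}

# parameters that make both arms structurally identical
neutral_intervention <- function() {
  params_with(rr_intervention = 1,
              qaly_diff_trial = 0,
              c_hs_intervention = default_parameters()$c_hs_control,
              c_program = 0)
}

default_lt <- function() generate_life_table()
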