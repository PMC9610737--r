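# Shared fixtures: every test builds its inputs in code.

# Baseline parameter set used throughout (the extinction study conditions
# unless transmission is overridden).
params_base <- function(...) {
  args <- list(...)
  do.call(svir_params, args)
}

hist_default <- function() svir_history(c(S = 0.3, V = 0.3, I = 0.2))

# Noise-free parameter variant (all sigmas zero) for deterministic oracles.
params_nonoise <- function(...) {
  params_base(sigma1 = 0, sigma2 = 0, sigma3 = 0, ...)
}
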