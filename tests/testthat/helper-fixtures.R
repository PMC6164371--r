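# shared fixture builders; everything is generated in code at test time

log_grid <- function(n = 60, lo = -1, hi = 2) 10^seq(lo, hi, length.out = n)

model_curve <- function(model_key, params, R, times = log_grid(),
                        noise_sd = 0, seed = NULL) {
  generate_curve(model_key, params, R, times = times, noise_sd = noise_sd,
                 seed = seed, units = frap_units("au", "au"))
}

small_sim <- function(..., n_particles = 5000, seed = 1) {
  simulate_recovery(ctrw_config(n_particles = n_particles, seed = seed, ...))
}

# cache for the acceptance-scale simulation grid, shared across test blocks
.acc_cache <- new.env(parent = emptyenv())
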