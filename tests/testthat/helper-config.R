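# Shared builders for scaled-down configurations and memoized simulation
# products reused across test files. Lattices here are sized so that the
# coupling disc (radius D) never exceeds half the lattice unless a test is
# explicitly about wraparound multiplicity.

small_config <- function(N = 40L, W_S = 0, D = 8, sigma_E = 4, sigma_S = 4,
                         roi_radius = 6, duration = 400, burn_in = 100,
                         t_on = 200, I_0 = 0.4, ...) {
  circuit_config(
    geometry = lattice_geometry(N),
    params = model_params(D = D, sigma_E = sigma_E, ...),
    protocol = stimulus_protocol(I_0 = I_0, W_S = W_S, t_on = t_on,
                                 sigma_S = sigma_S, roi_radius = roi_radius),
    duration = duration, burn_in = burn_in)
}

# uncoupled network: every neuron is an isolated LIF under I_0
uncoupled_config <- function(N = 6L, I_0 = 0.4, duration = 3500,
                             burn_in = 500) {
  circuit_config(
    geometry = lattice_geometry(N),
    params = model_params(W_E = 0, W_I = 0, D = 2),
    protocol = stimulus_protocol(I_0 = I_0, W_S = 0, t_on = duration),
    duration = duration, burn_in = burn_in)
}

# memoized expensive simulation products (computed once per test run)
.acc_cache <- new.env(parent = emptyenv())
acc_cached <- function(key, expr) {
  if (!exists(key, envir = .acc_cache))
    assign(key, force(expr), envir = .acc_cache)
  get(key, envir = .acc_cache)
}

# reference-parameter trials at reduced lattice size
scaled_trials <- function(W_S, n, N = 150L, seed0 = 500L, duration = 3500,
                          probes = "roi") {
  cfg <- circuit_config(lattice_geometry(N), model_params(),
                        stimulus_protocol(W_S = W_S),
                        duration = duration, burn_in = 1000)
  lapply(seq_len(n), function(i)
    run_trial(cfg, seed0 + i - 1L, probes = probes))
}

expect_within <- function(value, target, rel) {
  expect_gte(value, target * (1 - rel))
  expect_lte(value, target * (1 + rel))
}
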