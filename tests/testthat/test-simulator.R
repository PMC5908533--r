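test_that("initial state is uniform on [V_R, V_th) with quiescent synapses", {
  cfg <- small_config(N = 30)
  st <- initialize_state(cfg, 7)
  expect_true(all(st$V >= -70 & st$V < -55))
  expect_true(all(st$g_E == 0) && all(st$g_I == 0))
  expect_true(all(st$refractory == 0L))
  st2 <- initialize_state(cfg, 7)
  expect_identical(st$V, st2$V)
  expect_gt(max(abs(st$V - initialize_state(cfg, 8)$V)), 0)
})

test_that("single Euler steps match hand-computed membrane and synapse updates", {
  cfg <- circuit_config(lattice_geometry(4), model_params(W_E = 0, W_I = 0, D = 2),
                        stimulus_protocol(I_0 = 0, W_S = 0, t_on = 50,
                                          roi_radius = 1),
                        duration = 100, burn_in = 0)
  st <- initialize_state(cfg, 1)
  st$V[] <- -60
  st1 <- step_state(st, cfg)
  expect_equal(st1$V, rep(-60.025, 16))        # dV = -(V-V_L) dt/tau_m

  st$g_E[] <- 1
  st2 <- step_state(st, cfg)
  expect_equal(st2$g_E, rep(0.975, 16))        # g <- g (1 - dt/tau_E)
})

test_that("threshold crossing resets to V_R and silences for tau_ref", {
  cfg <- circuit_config(lattice_geometry(4), model_params(W_E = 0, W_I = 0, D = 2),
                        stimulus_protocol(I_0 = 2, W_S = 0, t_on = 1e3,
                                          roi_radius = 1),
                        duration = 100, burn_in = 0)
  st <- initialize_state(cfg, 1)
  st$V[] <- -55.01   # one sub-threshold step away under strong drive
  st1 <- step_state(st, cfg)
  sp <- attr(st1, "spikes")
  expect_equal(nrow(sp), 16L)
  expect_true(all(st1$V == -70))
  # silent for the full refractory period despite the strong drive
  st2 <- step_state(st1, cfg, n_steps = round(5 / 0.05) - 1L)
  expect_equal(nrow(attr(st2, "spikes")), 0L)
  expect_true(all(st2$V == -70))
  # and integrating again afterwards
  st3 <- step_state(st2, cfg, n_steps = 40L)
  expect_true(all(st3$V > -70))
})

test_that("no drive above threshold means no spikes; V relaxes to V_L monotonically", {
  cfg <- small_config(N = 16, I_0 = 0, D = 4, duration = 300, burn_in = 0)
  rec <- run_trial(cfg, 3, probes = data.frame(x = 2, y = 3))
  expect_identical(nrow(rec$spikes), 0L)
  v <- rec$probes$V[1, ]
  expect_true(all(diff(v) <= 0))               # V0 in [V_R, V_th) >= V_L: decays
  expect_lt(abs(v[length(v)] - (-70)), 0.1)
})

test_that("isolated LIF firing matches the closed-form interspike interval", {
  cfg <- uncoupled_config(N = 6, duration = 2500, burn_in = 500)
  rec <- run_trial(cfg, 42)
  sp <- rec$spikes[rec$spikes$time_ms > 500, ]
  rate <- nrow(sp) / 36 / 2.0
  expect_within(rate, lif_rate(cfg$params, 0.4), 0.02)
  # every neuron fires periodically: ISI constant and >= tau_ref
  isi <- unlist(tapply(sp$time_ms, interaction(sp$x, sp$y), diff))
  expect_true(all(abs(isi - 1000 / lif_rate(cfg$params, 0.4)) < 0.2))
})

test_that("refractory invariant holds in the coupled network", {
  cfg <- small_config(N = 40, duration = 600, burn_in = 0)
  rec <- run_trial(cfg, 11)
  isi <- unlist(tapply(rec$spikes$time_ms,
                       interaction(rec$spikes$x, rec$spikes$y), diff))
  expect_true(all(isi >= cfg$params$tau_ref))
})

test_that("identical config and seed give bit-identical recordings", {
  cfg <- small_config(N = 30, W_S = 0.5, duration = 300)
  r1 <- run_trial(cfg, 99, probes = data.frame(x = c(1, 5), y = c(2, 8)))
  r2 <- run_trial(cfg, 99, probes = data.frame(x = c(1, 5), y = c(2, 8)))
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$probes$V, r2$probes$V)
  expect_identical(r1$probes$g_E, r2$probes$g_E)
  expect_identical(r1$digest, r2$digest)
})

test_that("kernel scatter equals the brute-force pairwise afferent sum", {
  N <- 12L
  p <- model_params(D = 4, sigma_E = 2)
  k <- build_kernels(p)
  jumps <- kernel_jumps(k, p)
  set.seed(5)
  spikes <- sample(0:(N * N - 1L), 30, replace = TRUE)
  fast <- cpp_spike_increments(spikes, N, k$dx, k$dy, jumps$E)
  slow <- numeric(N * N)
  for (s in spikes) {                 # pairwise sum, offset by offset
    sx <- s %% N; sy <- s %/% N
    for (o in seq_along(k$dx)) {
      tx <- (sx + k$dx[o]) %% N; ty <- (sy + k$dy[o]) %% N
      slow[tx + N * ty + 1L] <- slow[tx + N * ty + 1L] + jumps$E[o]
    }
  }
  expect_identical(fast, slow)
})

test_that("sweeps are seeded, manifest-mapped and reproducible", {
  cfg <- small_config(N = 20, duration = 200, D = 5)
  sw <- run_sweep(cfg, strengths = c(0, 0.8), n_trials = 2, seed_base = 10)
  expect_equal(nrow(sw$manifest), 4L)
  expect_equal(anyDuplicated(sw$manifest$seed), 0L)
  expect_equal(sw$recordings[[3]]$config$protocol$W_S, 0.8)
  sw2 <- run_sweep(cfg, strengths = c(0, 0.8), n_trials = 2, seed_base = 10)
  for (i in 1:4)
    expect_identical(sw$recordings[[i]]$spikes, sw2$recordings[[i]]$spikes)
  expect_error(run_sweep(cfg, numeric(0)), "non-empty")
})
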