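test_that("detection finds synthetic blobs at their true centroids", {
  fx <- generate_fixture("stationary_blob", lattice_geometry(60),
                         duration = 50, seed = 3, amplitude = 3)
  det <- detect_patterns(fx, t_start = 0, t_end = 50)
  expect_true(all(table(det$frame) == 1))       # one component per frame
  expect_true(all(abs(det$x - 30) <= 1 & abs(det$y - 30) <= 1))

  # empty recording: zero components, not an error
  empty <- fx; empty$spikes <- fx$spikes[0, ]
  expect_identical(nrow(detect_patterns(empty, 0, 50)), 0L)

  # two blobs far apart give two components per frame
  fx2 <- generate_fixture("stationary_blob", lattice_geometry(120),
                          duration = 30, seed = 4, amplitude = 3,
                          start = c(20, 20))
  fx3 <- generate_fixture("stationary_blob", lattice_geometry(120),
                          duration = 30, seed = 5, amplitude = 3,
                          start = c(80, 80))
  both <- fx2
  both$spikes <- rbind(fx2$spikes, fx3$spikes)
  det2 <- detect_patterns(both, 0, 30)
  expect_true(all(table(det2$frame) == 2))
})

test_that("detection is periodic-aware across the lattice boundary", {
  fx <- generate_fixture("stationary_blob", lattice_geometry(60),
                         duration = 30, seed = 8, amplitude = 3,
                         start = c(0, 0))   # blob straddles all 4 corners
  det <- detect_patterns(fx, 0, 30)
  expect_true(all(table(det$frame) == 1))   # not split into corner pieces
  d <- lattice_distance(cbind(det$x, det$y), cbind(0, 0), lattice_geometry(60))
  expect_true(all(d <= 1.5))
})

test_that("tracking recovers generator speeds within 5% across 10-80 mm/s", {
  g <- lattice_geometry(80)
  for (v in c(10, 40, 80)) {
    fx <- generate_fixture("moving_blob", g, duration = 400, seed = v,
                           speed = v, direction = pi / 7, amplitude = 2)
    tr <- track_patterns(detect_patterns(fx, 0, 400), g)
    main <- tr$summary[which.max(tr$summary$n_frames), ]
    expect_gt(main$n_frames, 350)
    expect_within(main$mean_speed_mm_s, v, 0.05)
  }
})

test_that("wave and patch labels match generator intent", {
  g <- lattice_geometry(80)
  # fast blob: displacement >> threshold
  fx <- generate_fixture("moving_blob", g, duration = 300, seed = 1,
                         speed = 40, amplitude = 2)
  tr <- track_patterns(detect_patterns(fx, 0, 300), g)
  main <- tr$summary[which.max(tr$summary$n_frames), ]
  expect_identical(main$label, "wave")
  expect_identical(fx$ground_truth$label, "wave")

  fx2 <- generate_fixture("stationary_blob", g, duration = 300, seed = 2,
                          amplitude = 2)
  tr2 <- track_patterns(detect_patterns(fx2, 0, 300), g)
  main2 <- tr2$summary[which.max(tr2$summary$n_frames), ]
  expect_identical(main2$label, "patch")
  expect_lt(main2$mean_speed_mm_s, 5)
})

test_that("centroid unwrapping crosses the periodic boundary smoothly", {
  g <- lattice_geometry(60)
  fx <- generate_fixture("moving_blob", g, duration = 500, seed = 6,
                         speed = 40, direction = 0, amplitude = 2,
                         start = c(40, 30))   # crosses x = 60 twice
  tr <- track_patterns(detect_patterns(fx, 0, 500), g)
  main <- tr$summary[which.max(tr$summary$n_frames), ]
  pt <- tr$points[tr$points$track_id == main$track_id, ]
  expect_true(all(abs(diff(pt$x_unwrapped) - 1) < 2))  # ~1 gp/ms, no jumps
  expect_gt(max(pt$x_unwrapped), 60)                   # left the base domain
})

test_that("MSD exponent separates ballistic from Brownian trajectories", {
  xy <- cbind(0.7 * (0:200), 0.2 * (0:200))
  expect_equal(msd_exponent(xy), 2, tolerance = 1e-6)

  set.seed(12)
  steps <- matrix(sample(c(-1, 1), 2e4, replace = TRUE), ncol = 2)
  walk <- apply(steps, 2, cumsum)
  expect_equal(msd_exponent(walk, max_lag = 25), 1, tolerance = 0.25)

  expect_error(msd_exponent(xy[1:20, ]), "too short")
})

test_that("afferent spike distances use the minimal image and the cutoff", {
  g <- lattice_geometry(100)
  cfg <- circuit_config(g, model_params(), stimulus_protocol(W_S = 0),
                        duration = 200, burn_in = 0)
  rec <- list(spikes = data.frame(time_ms = c(10.5, 20.5, 30.5, 40.5),
                                  x = c(60, 81, 50, 99),
                                  y = c(50, 50, 72, 50)),
              config = cfg)
  ds <- afferent_spike_distances(rec, c(50, 50), cfg$params,
                                 epoch = c(0, 200))
  # offsets (10,0) -> 400 um; (31,0) and (49,0) -> beyond the cutoff;
  # (0,22) -> 880 um
  expect_equal(ds$events$distance_um, c(400, 880))
  expect_equal(ds$series$count[c(11, 31)], c(1L, 1L))
  expect_equal(ds$series$mean_distance_um[11], 400)
  expect_true(all(ds$events$distance_um <= cfg$params$D * g$spacing))

  # a source across the periodic boundary is afferent via the minimal image
  rec2 <- list(spikes = data.frame(time_ms = 5.5, x = 97, y = 50),
               config = cfg)
  ds2 <- afferent_spike_distances(rec2, c(2, 50), cfg$params,
                                  epoch = c(0, 200))
  expect_equal(ds2$events$distance_um, 200)   # dx = -95 wraps to +5
})

test_that("conductance reconstruction reproduces single-event dynamics", {
  g <- lattice_geometry(40)
  cfg <- circuit_config(g, model_params(D = 10),
                        stimulus_protocol(W_S = 0, t_on = 100,
                                          roi_radius = 5),
                        duration = 50, burn_in = 0)
  # no spikes: pure exponential decay from g0
  rec0 <- list(spikes = data.frame(time_ms = numeric(0), x = integer(0),
                                   y = integer(0)), config = cfg)
  tr0 <- reconstruct_conductance(rec0, c(20, 20), cfg, g0 = 2)
  expect_equal(tr0$g, 2 * (1 - 0.05 / 2)^(0:1000))

  # one excitatory spike at offset (4,0): jump of exactly K_E(4)/tau
  rec1 <- list(spikes = data.frame(time_ms = 10, x = 24, y = 20),
               config = cfg)
  tr1 <- reconstruct_conductance(rec1, c(20, 20), cfg)
  k <- build_kernels(cfg$params)
  jump <- kernel_jumps(k, cfg$params)$E[k$dx == 4 & k$dy == 0]
  step <- round(10 / 0.05)        # spike lands at the start of this step
  expect_identical(tr1$g[step + 1], 0)             # g[i] is after step i-1
  expect_equal(tr1$g[step + 2], jump * (1 - 0.05 / 2))
  expect_equal(tr1$time_ms[step + 2], 10.05)
  # inhibitory source spikes do not feed g_E
  rec2 <- list(spikes = data.frame(time_ms = 10, x = 23, y = 21),
               config = cfg)
  expect_true(all(reconstruct_conductance(rec2, c(20, 20), cfg)$g == 0))
})

test_that("reconstruction matches the simulator's recorded g_E exactly", {
  cfg <- small_config(N = 40, D = 8, duration = 300, burn_in = 0)
  probe <- data.frame(x = 21, y = 19)
  rec <- run_trial(cfg, 17, probes = probe)
  gr <- reconstruct_conductance(rec, c(21, 19), cfg)
  samp <- match(rec$probes$times, gr$time_ms)
  expect_identical(gr$g[samp], as.vector(rec$probes$g_E[1, ]))
})
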