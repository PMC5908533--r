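# build a recording-like object with hand-set movie frames
fake_movie_rec <- function(N, frames_V, frames_gE, frames_gI,
                           W_S = 0, roi_radius = 5) {
  cfg <- circuit_config(lattice_geometry(N), model_params(D = 5),
                        stimulus_protocol(W_S = W_S, t_on = 1e3,
                                          roi_radius = roi_radius),
                        duration = ncol(frames_V) + 200, burn_in = 0)
  structure(list(
    spikes = data.frame(time_ms = numeric(0), x = integer(0), y = integer(0)),
    movie = list(times = seq_len(ncol(frames_V)), V = frames_V,
                 g_E = frames_gE, g_I = frames_gI),
    config = cfg),
    class = "wp_recording")
}

test_that("a quiescent network has identically zero LFP", {
  N <- 20L
  V <- matrix(-70, N * N, 5)
  z <- matrix(0, N * N, 5)
  lfp <- compute_lfp(fake_movie_rec(N, V, z, z))
  expect_true(all(lfp$frames == 0))
})

test_that("a point current source maps to the Gaussian electrode envelope", {
  N <- 40L
  V <- matrix(-70, N * N, 1)
  gE <- matrix(0, N * N, 1); gI <- matrix(0, N * N, 1)
  src <- 20 + N * 20 + 1
  gE[src, 1] <- 1                      # |g_E (V - V_E)| = 70 at one site
  lfp <- compute_lfp(fake_movie_rec(N, V, gE, gI), sigma_lfp = 2.5)
  f <- matrix(lfp$frames[, 1], N, N)
  delta <- matrix(0, N, N); delta[21, 21] <- 70
  expect_equal(f, cpp_blur_periodic(delta, 2.5))
  expect_equal(sum(f), 70)             # normalized envelope conserves mass
  # non-increasing amplitude with distance from the source along an axis
  prof <- f[21:35, 21]
  expect_true(all(diff(prof) <= 1e-12))
})

test_that("the LFP proxy is linear: superposition of sources", {
  N <- 30L
  V <- matrix(-65, N * N, 3)
  set.seed(4)
  gA <- matrix(runif(N * N * 3), N * N); gB <- matrix(runif(N * N * 3), N * N)
  zi <- matrix(0, N * N, 3)
  la <- compute_lfp(fake_movie_rec(N, V, gA, zi))
  lb <- compute_lfp(fake_movie_rec(N, V, gB, zi))
  lab <- compute_lfp(fake_movie_rec(N, V, gA + gB, zi))
  expect_equal(lab$frames, la$frames + lb$frames, tolerance = 1e-12)
})

test_that("stLFP of a blinking central source peaks at the centre electrode", {
  N <- 60L
  n_fr <- 400L
  V <- matrix(-70, N * N, n_fr)
  gE <- matrix(0, N * N, n_fr); gI <- matrix(0, N * N, n_fr)
  ctr <- c(30, 30)
  src <- ctr[1] + N * ctr[2] + 1
  on_times <- seq(60, 340, by = 40)    # blinks, spike at each blink
  gE[src, on_times] <- 5
  rec <- fake_movie_rec(N, V, gE, gI)
  rec$spikes <- data.frame(time_ms = on_times, x = ctr[1], y = ctr[2])
  rec$config$protocol$center <- ctr
  lfp <- compute_lfp(rec)
  cu <- spike_triggered_lfp(lfp, rec, epoch = c(51, 390), max_triggers = 100)
  expect_equal(cu$distance_um, seq(0, 1000, by = 200))
  expect_gt(cu$amplitude[1], cu$amplitude[2])
  expect_true(all(diff(cu$amplitude) <= 1e-9))  # isotropic: non-increasing
  expect_error(spike_triggered_lfp(lfp, rec, epoch = c(1, 2)), "no trigger")
})

test_that("triggers uncorrelated with a stationary noise field average out", {
  N <- 40L
  n_fr <- 600L
  set.seed(9)
  V <- matrix(-65, N * N, n_fr)
  gE <- matrix(runif(N * N * n_fr), N * N)   # stationary spatio-temporal noise
  gI <- matrix(0, N * N, n_fr)
  rec <- fake_movie_rec(N, V, gE, gI)
  trig <- sort(sample(60:540, 120))
  rec$spikes <- data.frame(time_ms = trig + 0.5, x = 20, y = 20)
  rec$config$protocol$center <- c(20, 20)
  lfp <- compute_lfp(rec)
  cu <- spike_triggered_lfp(lfp, rec, epoch = c(55, 545), max_triggers = 120)
  # amplitudes are small relative to the raw field scale (~16 at the
  # electrode after averaging 65 * U(0,1) over the envelope)
  expect_true(all(cu$amplitude < 1.5))
})

test_that("space-constant fitting exactly recovers noiseless exponentials", {
  d_um <- seq(0, 1600, by = 200)
  for (lam in c(0.05, 0.175, 0.5, 0.8, 2)) {
    a <- 3.2 * exp(-(d_um / 1000) / lam) + 0.4
    fit <- fit_space_constant(data.frame(distance_um = d_um, amplitude = a))
    expect_equal(fit$lambda, lam, tolerance = 1e-6)
    expect_equal(fit$M, 3.2, tolerance = 1e-5)
    expect_equal(fit$B, 0.4, tolerance = 1e-5)
  }
  flat <- data.frame(distance_um = d_um, amplitude = rep(1, length(d_um)))
  expect_error(fit_space_constant(flat), "unidentifiable")
  expect_error(fit_space_constant(flat[1:3, ]), "at least 4")
})
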