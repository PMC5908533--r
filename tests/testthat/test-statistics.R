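test_that("skewness estimator behaves on known distributions", {
  expect_identical(skewness(c(-1, 0, 1)), 0)
  expect_true(is.nan(skewness(rep(3, 10))))
  expect_error(skewness(c(1, 2)), "at least 3")

  set.seed(1)
  expect_equal(skewness(rexp(2e5)), 2, tolerance = 0.05)
  # small-sample correction increases magnitude
  x <- rexp(30)
  expect_gt(abs(skewness(x, adjust = TRUE)), abs(skewness(x)))
})

test_that("skewness sign agrees with mean-minus-median on unimodal samples", {
  set.seed(2)
  for (i in 1:21) {
    x <- switch(1 + i %% 3,
                rexp(500),               # right-skewed
                -rexp(500),              # left-skewed
                exp(rnorm(500)))         # lognormal, right-skewed
    expect_identical(sign(skewness(x)), sign(mean(x) - median(x)))
  }
})

test_that("subthreshold distance is V_th minus the time-averaged potential", {
  p <- model_params()
  expect_identical(subthreshold_distance(rep(-66, 100), p), 11)
  expect_equal(subthreshold_distance(c(-60, -70), p), 10)
  expect_error(subthreshold_distance(numeric(0), p), "empty")
})

test_that("sliding-window counts match a naive implementation", {
  fx <- generate_fixture("poisson_grid", lattice_geometry(10),
                         duration = 600, seed = 31, rate = 20)
  neurons <- data.frame(x = c(0, 3, 7), y = c(0, 5, 9))
  cs <- count_spikes(list(fx), neurons, window = 100, step = 50,
                     epoch = c(0, 600))
  sp <- fx$spikes
  for (ni in seq_len(3)) {
    own <- sp[sp$x == neurons$x[ni] & sp$y == neurons$y[ni], ]
    for (w in seq_along(cs$times)) {
      lo <- cs$times[w] - 50; hi <- cs$times[w] + 50
      expect_identical(cs$counts[ni, w, 1],
                       sum(own$time_ms > lo & own$time_ms <= hi))
    }
  }
})

test_that("firing-rate estimator is consistent for Poisson input", {
  fx <- generate_fixture("poisson_grid", lattice_geometry(20),
                         duration = 2000, seed = 7, rate = 9)
  neurons <- expand.grid(x = 0:19, y = 0:19)
  fr <- firing_rate(list(fx), neurons, epoch = c(0, 2000))
  expect_equal(mean(fr$rate), 9, tolerance = 0.1)

  empty <- fx; empty$spikes <- fx$spikes[0, ]
  fr0 <- firing_rate(list(empty), neurons, epoch = c(0, 2000))
  expect_true(all(fr0$rate == 0))
})

test_that("Fano factor of Poisson counts is 1 within the sampling band", {
  set.seed(11)
  counts <- array(rpois(50 * 8 * 500, lambda = 3), c(50, 8, 500))
  ff <- fano_factor(counts)
  expect_true(all(ff > 0.7 & ff < 1.3))      # per-neuron sampling spread
  expect_true(abs(mean(ff) - 1) < 0.02)      # unbiased on average

  same <- array(rep(4L, 50 * 8 * 10), c(50, 8, 10))
  expect_true(all(fano_factor(same) == 0))
  expect_error(fano_factor(counts[, , 1, drop = FALSE]), "2 trials")
})

test_that("rate-switching input is doubly stochastic: FF > 1, growing with window", {
  g <- lattice_geometry(10)
  recs <- lapply(1:40, function(i)
    generate_fixture("rate_switching", g, duration = 1200, seed = 100 + i,
                     rate_lo = 2, rate_hi = 25, switch_ms = 150))
  neurons <- expand.grid(x = 0:9, y = 0:9)
  fv <- fano_vs_window(recs, neurons, windows = c(100, 300, 600),
                       epoch = c(0, 1200), seed = 5)
  expect_true(all(fv$ff > 1.2))
  expect_true(all(diff(fv$ff) > 0))
})

test_that("mean matching reduces to the raw average when rates are equal", {
  set.seed(21)
  counts <- array(rpois(40 * 6 * 60, lambda = 5), c(40, 6, 60))
  mm <- mean_matched_fano(counts, seed = 2)
  expect_true(mm$matched)
  # every neuron's mean is ~5 at every window: nothing is discarded beyond
  # histogram granularity, so matched and raw series agree closely
  expect_equal(mm$mm_ff, mm$raw_ff, tolerance = 0.1)

  # the common histogram never exceeds any single window's histogram
  m <- apply(counts, c(1, 2), mean)
  expect_lte(mm$n_kept, min(colSums(!is.na(m))))
})

test_that("disjoint mean-count histograms fall back to raw FF with a warning", {
  counts <- array(0L, c(10, 2, 20))
  counts[, 1, ] <- rpois(200, 1)
  counts[, 2, ] <- rpois(200, 40)     # no overlap in mean counts
  expect_warning(mm <- mean_matched_fano(counts, seed = 3), "empty common")
  expect_false(mm$matched)
  expect_equal(mm$mm_ff, mm$raw_ff)
})

test_that("windows straddling the stimulus onset belong to neither epoch", {
  times <- seq(125, 3375, by = 50)
  keep_s <- windows_in_epoch(times, 250, c(1000, 2000), t_on = 2000)
  keep_e <- windows_in_epoch(times, 250, c(2000, 3500), t_on = 2000)
  expect_true(all(times[keep_s] <= 1875))
  expect_true(all(times[keep_e] >= 2125))
  straddle <- times > 1875 & times < 2125
  expect_true(all(!keep_s[straddle] & !keep_e[straddle]))
})
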