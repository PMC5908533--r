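test_that("neuron classes follow the odd-odd inhibitory sublattice", {
  g <- lattice_geometry(300)
  expect_equal(neuron_class(1, 1, g), "inhibitory")
  expect_equal(neuron_class(0, 0, g), "excitatory")
  expect_equal(neuron_class(c(2, 3, 5), c(4, 3, 2), g),
               c("excitatory", "inhibitory", "excitatory"))
  expect_error(neuron_class(300, 0, g), "out of lattice range")
  expect_error(neuron_class(-1, 0, g), "out of lattice range")

  xy <- expand.grid(x = 0:299, y = 0:299)
  frac <- mean(neuron_class(xy$x, xy$y, g) == "inhibitory")
  expect_identical(frac, 0.25)
})

test_that("kernel offsets match brute-force punctured-disc enumeration", {
  # independent oracle: count integer columns per dx row
  disc_count <- function(D) {
    n <- 0L
    for (dx in -floor(D):floor(D)) {
      rem <- D^2 - dx^2
      if (rem < 0) next
      n <- n + 2L * as.integer(floor(sqrt(rem))) + 1L
    }
    n - 1L   # remove the origin
  }
  for (D in c(1:8, 15, 30)) {
    k <- build_kernels(model_params(D = D))
    expect_identical(length(k$dx), disc_count(D))
    expect_true(all(k$dist > 0 & k$dist <= D))
  }
})

test_that("kernel strengths follow the Gaussian-E / uniform-I profile", {
  p <- model_params()
  k <- build_kernels(p)
  expect_equal(k$K_E, p$W_E * exp(-k$dist^2 / (2 * p$sigma_E^2)))
  expect_true(all(k$K_I == p$W_I))
  # amplitude at |dr| -> 0+: nearest offsets approach W_E from below
  expect_lt(max(k$K_E), p$W_E)
  expect_equal(p$W_E * exp(0), 7.5e-3)

  # invariance under the 8 lattice symmetries
  key <- function(dx, dy) paste(dx, dy)
  lut <- setNames(k$K_E, key(k$dx, k$dy))
  for (tf in list(c(-1, 1), c(1, -1), c(-1, -1))) {
    expect_equal(unname(lut[key(tf[1] * k$dx, tf[2] * k$dy)]), k$K_E)
  }
  expect_equal(unname(lut[key(k$dy, k$dx)]), k$K_E)  # coordinate swap
})

test_that("parameter invariants are enforced", {
  expect_error(model_params(sigma_E = 0), "sigma_E")
  expect_error(model_params(D = 0), "'D'")
  expect_error(model_params(V_th = -80), "ordering")
  expect_error(model_params(tau_E = -1), "strictly positive")
  expect_error(lattice_geometry(301), "even")
  expect_error(stimulus_protocol(W_S = -1), "W_S")
})

test_that("external input is background plus a gated minimal-image Gaussian", {
  g <- lattice_geometry(100)
  cfg <- circuit_config(g, model_params(),
                        stimulus_protocol(W_S = 1.2), duration = 3500)
  pr <- cfg$protocol
  ctr <- pr$center
  # before onset: background only, everywhere
  expect_equal(external_input(c(3, 97), 1000, pr, g), 0.4)
  expect_equal(external_input(ctr, pr$t_on - 1e-9, pr, g), 0.4)
  # at the centre after onset: I_0 + W_S exactly
  expect_equal(external_input(ctr, 3000, pr, g), 0.4 + 1.2)
  # far from the centre: ~ background
  far <- (ctr + 50) %% g$N
  expect_equal(external_input(far, 3000, pr, g), 0.4, tolerance = 1e-6)
  # minimal image: symmetric across the periodic boundary
  expect_equal(external_input((ctr + c(47, 0)) %% g$N, 3000, pr, g),
               external_input((ctr - c(47, 0)) %% g$N, 3000, pr, g))

  # monotone non-decreasing in W_S at every point and time
  pts <- cbind(c(0, 10, 50, 77), c(0, 93, 50, 12))
  for (t in c(0, 1999, 2000, 3000)) {
    prev <- rep(-Inf, nrow(pts))
    for (ws in c(0, 0.3, 0.6, 1.2)) {
      pr2 <- pr; pr2$W_S <- ws
      cur <- external_input(pts, t, pr2, g)
      expect_true(all(cur >= prev))
      prev <- cur
    }
  }
})
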