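#' Local field potential proxy from synaptic currents
#'
#' The temporal component at each lattice site is the summed magnitude of
#' the excitatory and inhibitory synaptic currents,
#' `|g_E (V - V_E)| + |g_I (V - V_I)|` (configurable to the signed sum); the
#' spatial component convolves each frame with a normalized periodic
#' Gaussian of width `sigma_lfp` gridpoints, emulating the spatial reach of
#' an extracellular electrode. The proxy is linear in the current fields,
#' so superposition holds exactly.
#'
#' @param rec a `wp_recording` whose movie captured `V`, `g_E` and `g_I`
#'   frames ([run_trial()] with `movie_conductances = TRUE`).
#' @param sigma_lfp Gaussian envelope width, gridpoints (default 2.5,
#'   i.e. 100 um at 40 um spacing).
#' @param signed use the signed sum of currents instead of magnitudes.
#' @return object of class `wp_lfp`: `$frames` (`N^2 x n_frames` matrix),
#'   `$times` (ms), `$N`, `$sigma_lfp`.
#' @export
compute_lfp <- function(rec, sigma_lfp = 2.5, signed = FALSE) {
  mv <- rec$movie
  if (is.null(mv) || is.null(mv$g_E))
    stop("recording has no conductance movie; rerun run_trial() with ",
         "movie_stride_ms set and movie_conductances = TRUE")
  p <- rec$config$params
  N <- rec$config$geometry$N
  n_frames <- length(mv$times)
  frames <- matrix(0, N * N, n_frames)
  for (f in seq_len(n_frames)) {
    iE <- mv$g_E[, f] * (mv$V[, f] - p$V_E)
    iI <- mv$g_I[, f] * (mv$V[, f] - p$V_I)
    tempo <- if (signed) iE + iI else abs(iE) + abs(iI)
    frames[, f] <- as.vector(cpp_blur_periodic(matrix(tempo, N, N), sigma_lfp))
  }
  structure(list(frames = frames, times = mv$times, N = N,
                 sigma_lfp = sigma_lfp),
            class = "wp_lfp")
}

#' Spike-triggered LFP amplitude versus distance
#'
#' Virtual electrodes are placed at multiples of `electrode_spacing`
#' gridpoints (200 um at the default spacing of 5) from the RoI centre
#' along the four lattice axes. For each trigger spike of an RoI neuron the
#' LFP at every electrode is extracted in a `+/- window_ms` window around
#' the spike, averaged across triggers, and baseline-corrected with the
#' mean over the `baseline` pre-trigger interval; the amplitude at each
#' distance is the maximum absolute deflection of the trigger-averaged,
#' baseline-corrected LFP, averaged over the four electrodes of that
#' distance. When more triggers are available than `max_triggers`, an
#' evenly spaced (deterministic) subset is used.
#'
#' @param lfp a `wp_lfp` from [compute_lfp()].
#' @param rec the recording that produced it (for spikes and protocol).
#' @param electrode_spacing spacing between electrode distances, gridpoints.
#' @param max_distance_gp furthest electrode, gridpoints (default: largest
#'   multiple of the spacing below `N/2`).
#' @param window_ms half-width of the trigger window, ms.
#' @param baseline pre-trigger interval for the baseline, ms (relative to
#'   the trigger).
#' @param max_triggers upper bound on triggers used.
#' @param epoch interval from which triggers are taken, ms; default burn-in
#'   to end, shrunk so every window fits in the movie.
#' @return data.frame of class `wp_stlfp`: `distance_um`, `amplitude`,
#'   with attributes `n_triggers` and `spacing_um`.
#' @export
spike_triggered_lfp <- function(lfp, rec, electrode_spacing = 5,
                                max_distance_gp = NULL, window_ms = 50,
                                baseline = c(-50, -25), max_triggers = 2000,
                                epoch = NULL) {
  N <- lfp$N
  cfg <- rec$config
  ctr <- cfg$protocol$center
  spacing <- cfg$geometry$spacing
  if (is.null(max_distance_gp))
    max_distance_gp <- electrode_spacing * ((ceiling(N / 2) - 1) %/% electrode_spacing)
  dists <- seq(0, max_distance_gp, by = electrode_spacing)

  frame_ms <- diff(lfp$times[1:2])
  wlen <- round(window_ms / frame_ms)
  if (is.null(epoch)) epoch <- c(cfg$burn_in, cfg$duration)
  t_lo <- max(epoch[1], lfp$times[1] + window_ms)
  t_hi <- min(epoch[2], lfp$times[length(lfp$times)] - window_ms)

  roi <- roi_neurons(cfg$geometry, cfg$protocol)
  sp <- rec$spikes
  in_roi <- (sp$x + N * sp$y) %in% roi$index
  trig <- sp$time_ms[in_roi & sp$time_ms > t_lo & sp$time_ms <= t_hi]
  if (!length(trig)) stop("no trigger spikes in the requested epoch")
  if (length(trig) > max_triggers)
    trig <- trig[round(seq(1, length(trig), length.out = max_triggers))]
  # frame index of each trigger
  tf <- round((trig - lfp$times[1]) / frame_ms) + 1L

  rel <- (-wlen):wlen
  bl_keep <- rel * frame_ms >= baseline[1] & rel * frame_ms <= baseline[2]
  axes <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  amp <- vapply(dists, function(d) {
    a <- vapply(seq_len(nrow(axes)), function(ax) {
      ex <- (ctr[1] + axes[ax, 1] * d) %% N
      ey <- (ctr[2] + axes[ax, 2] * d) %% N
      series <- lfp$frames[ex + N * ey + 1L, ]
      snip <- matrix(series[outer(tf, rel, `+`)], length(tf))
      avg <- colMeans(snip)
      max(abs(avg - mean(avg[bl_keep])))
    }, numeric(1))
    mean(if (d == 0) a[1] else a)
  }, numeric(1))

  out <- data.frame(distance_um = dists * spacing, amplitude = amp)
  attr(out, "n_triggers") <- length(trig)
  attr(out, "spacing_um") <- spacing
  class(out) <- c("wp_stlfp", "data.frame")
  out
}

#' Exponential space-constant fit of an stLFP curve
#'
#' Nonlinear least-squares fit of `M * exp(-d / lambda) + B` to stLFP
#' amplitude versus distance, with distances in mm. Initialized at
#' `M = range`, `B = min`, `lambda = ` distance at half range, with
#' `lambda` bounded positive. The space constant `lambda` quantifies the
#' propagation range of the underlying activity patterns.
#'
#' @param curve a `wp_stlfp` data.frame (`distance_um`, `amplitude`), or any
#'   data.frame with those columns.
#' @param tol minimal amplitude range below which the curve is flagged
#'   unidentifiable.
#' @return list of class `wp_stlfp_fit`: `M`, `lambda` (mm), `B`,
#'   `resid_norm`, `fitted`.
#' @export
fit_space_constant <- function(curve, tol = 1e-12) {
  if (nrow(curve) < 4L) stop("need at least 4 distance points")
  if (any(curve$amplitude < 0)) stop("amplitudes must be non-negative")
  d <- curve$distance_um / 1000
  a <- curve$amplitude
  rng <- max(a) - min(a)
  if (rng < tol)
    stop("flat stLFP curve: space constant unidentifiable")
  half <- min(a) + rng / 2
  lam0 <- d[which.min(abs(a - half))]
  if (lam0 <= 0) lam0 <- max(d[2], 0.05)
  # several starts guard against singular gradients on noisy or slowly
  # decaying curves; the best converged fit (residual norm) is kept
  fit <- NULL
  for (l0 in unique(c(lam0, 0.1, 0.3, 1, max(d) / 2, 2 * max(d)))) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        a ~ M * exp(-d / lambda) + B,
        start = list(M = rng, lambda = l0, B = min(a)),
        lower = c(M = 0, lambda = 1e-4, B = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(fit) || sum(residuals(cand)^2) < sum(residuals(fit)^2)))
      fit <- cand
  }
  if (is.null(fit)) stop("space-constant fit failed to converge")
  cf <- coef(fit)
  structure(list(M = unname(cf["M"]), lambda = unname(cf["lambda"]),
                 B = unname(cf["B"]),
                 resid_norm = sqrt(sum(residuals(fit)^2)),
                 fitted = fitted(fit)),
            class = "wp_stlfp_fit")
}

#' @export
print.wp_stlfp_fit <- function(x, ...) {
  cat(sprintf("<wp_stlfp_fit> M = %.4g, lambda = %.4g mm, B = %.4g (resid %.3g)\n",
              x$M, x$lambda, x$B, x$resid_norm))
  invisible(x)
}

#' @export
plot.wp_stlfp <- function(x, fit = NULL, ...) {
  graphics::plot(x$distance_um / 1000, x$amplitude, pch = 16,
                 xlab = "distance (mm)", ylab = "stLFP amplitude", ...)
  if (!is.null(fit)) {
    dd <- seq(0, max(x$distance_um) / 1000, length.out = 200)
    graphics::lines(dd, fit$M * exp(-dd / fit$lambda) + fit$B, col = 2)
  }
  invisible(x)
}
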