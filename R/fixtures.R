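#' Generate synthetic spike fields with known ground truth
#'
#' Seeded generators of spike recordings whose true structure is known, so
#' every analysis (detection, tracking, stLFP, rate and Fano statistics)
#' can be tested without running the full circuit:
#'
#' * `moving_blob` — a Gaussian rate envelope (width `sigma` gridpoints,
#'   peak `amplitude` expected spikes per cell per ms) whose centre moves
#'   at `speed` mm/s in direction `direction` (radians), thinned to Poisson
#'   spikes each millisecond. Ground truth: the centre trajectory
#'   (unwrapped), the speed, and the wave/patch label implied by the net
#'   displacement.
#' * `stationary_blob` — the same envelope with zero velocity (label patch).
#' * `poisson_grid` — every neuron fires as an independent homogeneous
#'   Poisson process at `rate` Hz.
#' * `rate_switching` — every neuron is an independent two-state Markov
#'   (telegraph) process switching between `rate_lo` and `rate_hi` Hz with
#'   mean dwell time `switch_ms`; a doubly stochastic process whose Fano
#'   factor exceeds 1 and grows with the counting window.
#'
#' @param kind fixture type, see Details.
#' @param geometry a [lattice_geometry()].
#' @param duration recording length, ms.
#' @param seed integer RNG seed; output is reproducible from (parameters, seed).
#' @param speed blob speed, mm/s.
#' @param direction blob heading, radians.
#' @param amplitude blob peak rate, expected spikes per cell per ms.
#' @param sigma blob envelope width, gridpoints.
#' @param start blob start centre (0-based coordinates); default lattice
#'   centre.
#' @param rate Poisson rate, Hz.
#' @param rate_lo,rate_hi telegraph rates, Hz.
#' @param switch_ms mean dwell time in each telegraph state, ms.
#' @return object of class `wp_fixture`: `$spikes` (`time_ms`, `x`, `y`),
#'   `$config` (geometry, `duration`, `burn_in = 0`), `$ground_truth`
#'   (kind-specific), `$kind`, `$seed`. The spike table and config mimic a
#'   `wp_recording`, so analysis functions accept fixtures directly.
#' @export
generate_fixture <- function(kind = c("moving_blob", "stationary_blob",
                                      "poisson_grid", "rate_switching"),
                             geometry = lattice_geometry(60),
                             duration = 1000, seed = 1L,
                             speed = 40, direction = 0, amplitude = 2,
                             sigma = 3, start = NULL,
                             rate = 9, rate_lo = 2, rate_hi = 20,
                             switch_ms = 200) {
  kind <- match.arg(kind)
  if (duration <= 0) stop("'duration' must be positive")
  N <- geometry$N
  set.seed(seed)
  if (is.null(start)) start <- c(N / 2, N / 2)

  spikes <- NULL
  truth <- list()
  if (kind %in% c("moving_blob", "stationary_blob")) {
    if (kind == "stationary_blob") speed <- 0
    v_gp <- speed / geometry$spacing             # mm/s = um/ms; / (um/gp) = gp/ms
    vel <- v_gp * c(cos(direction), sin(direction))
    r <- ceiling(4 * sigma)
    off <- expand.grid(dx = -r:r, dy = -r:r)
    off <- off[off$dx^2 + off$dy^2 <= r^2, ]
    centres <- matrix(NA_real_, duration, 2)
    frames <- vector("list", duration)
    for (f in seq_len(duration)) {
      ctr <- start + vel * (f - 1)               # unwrapped
      centres[f, ] <- ctr
      cx <- round(ctr[1]); cy <- round(ctr[2])
      lam <- amplitude *
        exp(-((off$dx + cx - ctr[1])^2 + (off$dy + cy - ctr[2])^2) /
              (2 * sigma^2))
      n <- rpois(nrow(off), lam)
      if (sum(n) == 0) next
      i <- rep.int(seq_len(nrow(off)), n)
      frames[[f]] <- data.frame(
        time_ms = f - 0.5,
        x = (off$dx[i] + cx) %% N,
        y = (off$dy[i] + cy) %% N)
    }
    spikes <- do.call(rbind, frames)
    net <- sqrt(sum((centres[duration, ] - centres[1, ])^2))
    truth <- list(centres = centres, speed_mm_s = speed,
                  net_displacement_gp = net,
                  label = if (net > 15) "wave" else "patch",
                  sigma = sigma, amplitude = amplitude)
  } else if (kind == "poisson_grid") {
    M <- N * N
    n <- rpois(1L, M * rate * duration / 1000)
    idx <- sample.int(M, n, replace = TRUE) - 1L
    spikes <- data.frame(time_ms = sort(runif(n, 0, duration)),
                         x = idx %% N, y = idx %/% N)
    truth <- list(rate_hz = rate)
  } else if (kind == "rate_switching") {
    M <- N * N
    per_neuron <- lapply(seq_len(M) - 1L, function(i) {
      t <- 0; hi <- runif(1) < 0.5
      ts <- numeric(0)
      while (t < duration) {
        dwell <- rexp(1, 1 / switch_ms)
        seg_end <- min(t + dwell, duration)
        r <- if (hi) rate_hi else rate_lo
        k <- rpois(1L, r * (seg_end - t) / 1000)
        if (k) ts <- c(ts, runif(k, t, seg_end))
        t <- seg_end; hi <- !hi
      }
      if (length(ts)) data.frame(time_ms = ts, x = i %% N, y = i %/% N)
    })
    spikes <- do.call(rbind, per_neuron)
    spikes <- spikes[order(spikes$time_ms), ]
    truth <- list(rate_lo = rate_lo, rate_hi = rate_hi,
                  switch_ms = switch_ms,
                  mean_rate_hz = (rate_lo + rate_hi) / 2)
  }
  if (is.null(spikes))
    spikes <- data.frame(time_ms = numeric(0), x = integer(0), y = integer(0))
  rownames(spikes) <- NULL

  structure(list(spikes = spikes,
                 config = list(geometry = geometry, duration = duration,
                               burn_in = 0),
                 ground_truth = truth, kind = kind, seed = as.integer(seed)),
            class = "wp_fixture")
}

#' @export
print.wp_fixture <- function(x, ...) {
  cat(sprintf("<wp_fixture> %s, N = %d, %g ms, seed %d: %d spikes\n",
              x$kind, x$config$geometry$N, x$config$duration, x$seed,
              nrow(x$spikes)))
  invisible(x)
}
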