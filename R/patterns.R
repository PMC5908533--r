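#' Detect population activity patterns in binned spike frames
#'
#' Spikes are binned into `bin_ms` frames; each frame's spike-count field is
#' smoothed with a periodic Gaussian (`sigma` gridpoints), thresholded at
#' `mean + k * sd` of the smoothed frame, and segmented into periodic-aware
#' 8-connected components. Components smaller than `min_size` cells are
#' discarded. Component centroids are weighted by the above-threshold
#' density and unwrapped relative to a seed cell, so patterns straddling the
#' periodic boundary get consistent coordinates.
#'
#' The defaults (`sigma = 2`, `k = 2`, `min_size = 10`) are fixed package
#' choices validated on synthetic fixtures; all are configurable.
#'
#' @param rec a `wp_recording` or `wp_fixture` (anything with `$spikes` and
#'   `$config$geometry`).
#' @param t_start,t_end analysed time range, ms; default is burn-in to end.
#' @param bin_ms frame length, ms.
#' @param sigma smoothing width, gridpoints.
#' @param k threshold in standard deviations above the frame mean.
#' @param min_size minimum component size, cells.
#' @return data.frame of class `wp_components`: `frame`, `time_ms` (frame
#'   start), `id` (within frame), `size`, `x`, `y` (centroid, wrapped into
#'   `[0, N)`), `mass` (summed above-threshold density). Empty recording
#'   gives zero rows.
#' @export
detect_patterns <- function(rec, t_start = NULL, t_end = NULL, bin_ms = 1,
                            sigma = 2, k = 2, min_size = 10) {
  N <- rec$config$geometry$N
  if (is.null(t_start)) t_start <- rec$config$burn_in
  if (is.null(t_end)) t_end <- rec$config$duration
  sp <- rec$spikes
  sp <- sp[sp$time_ms > t_start & sp$time_ms <= t_end, , drop = FALSE]
  n_frames <- floor((t_end - t_start) / bin_ms)
  out <- vector("list", n_frames)
  if (nrow(sp)) {
    fr <- pmin(floor((sp$time_ms - t_start - 1e-9) / bin_ms) + 1L, n_frames)
    idx <- sp$x + N * sp$y + 1L
    by_frame <- split(idx, factor(fr, levels = seq_len(n_frames)))
  } else {
    by_frame <- rep(list(integer(0)), n_frames)
  }
  m <- matrix(0, N, N)
  for (f in seq_len(n_frames)) {
    cells <- by_frame[[f]]
    if (!length(cells)) next
    m[] <- tabulate(cells, nbins = N * N)
    dens <- cpp_blur_periodic(m, sigma)
    thr <- mean(dens) + k * sd(as.vector(dens))
    mask <- dens > thr
    if (!any(mask)) next
    lab <- cpp_label_components(mask)
    comps <- component_stats(lab, dens - thr, N, min_size)
    if (nrow(comps)) {
      comps <- cbind(frame = f, time_ms = t_start + (f - 1L) * bin_ms, comps)
      out[[f]] <- comps
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- matrix(0, 0, 7)
  res <- as.data.frame(res)
  names(res) <- c("frame", "time_ms", "id", "size", "x", "y", "mass")
  attr(res, "N") <- N
  attr(res, "bin_ms") <- bin_ms
  class(res) <- c("wp_components", "data.frame")
  res
}

# density-weighted, periodic-aware centroids of labelled components;
# returns a numeric matrix with columns id, size, x, y, mass
component_stats <- function(lab, w, N, min_size) {
  nz <- which(lab > 0)
  if (!length(nz)) return(matrix(0, 0, 5))
  labs <- lab[nz]
  xi <- (nz - 1L) %% N      # row index = x
  yi <- (nz - 1L) %/% N
  rows <- lapply(split(seq_along(nz), labs), function(ii) {
    if (length(ii) < min_size) return(NULL)
    x <- xi[ii]; y <- yi[ii]
    # unwrap relative to the first cell (components are compact)
    rx <- x[1] + wrap_delta(x - x[1], N)
    ry <- y[1] + wrap_delta(y - y[1], N)
    ww <- w[nz[ii]]
    sw <- sum(ww)
    c(length(ii), (sum(rx * ww) / sw) %% N, (sum(ry * ww) / sw) %% N, sw)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(matrix(0, 0, 5))
  m <- do.call(rbind, rows)
  cbind(id = seq_len(nrow(m)), size = m[, 1], x = m[, 2], y = m[, 3],
        mass = m[, 4])
}

#' Track detected patterns across frames
#'
#' Links components frame-to-frame by nearest centroid (minimal-image
#' distance, greedy, maximum jump `max_jump` gridpoints per elapsed frame).
#' A track not matched for more than `max_gap` frames is terminated; later
#' components start new tracks (no merging or splitting). Centroids are
#' unwrapped across the periodic boundary by accumulating minimal-image
#' frame displacements. A track is labelled a `wave` when its net unwrapped
#' displacement over its lifetime exceeds `wave_threshold` gridpoints,
#' otherwise a `patch`; its `mean_speed` is the mean per-frame centroid
#' displacement converted to mm/s via the lattice spacing.
#'
#' @param comps a `wp_components` table from [detect_patterns()].
#' @param geometry the [lattice_geometry()] of the recording.
#' @param max_jump maximum link distance per elapsed frame, gridpoints.
#' @param max_gap frames a track may go unmatched before termination.
#' @param wave_threshold wave/patch displacement threshold, gridpoints
#'   (the RoI radius in the reference protocol).
#' @param speed_lag lag (frames) over which centroid displacements are
#'   taken for the speed estimate; single-frame displacements are dominated
#'   by centroid estimation noise, which a 10-frame lag suppresses to below
#'   a few percent (see the methods vignette). Tracks shorter than the lag
#'   fall back to their net displacement over their lifetime.
#' @return list of class `wp_tracks`: `$points` (track_id, frame, time_ms,
#'   x, y, x_unwrapped, y_unwrapped) and `$summary` (track_id, n_frames,
#'   net_displacement_gp, mean_speed_mm_s, label).
#' @export
track_patterns <- function(comps, geometry, max_jump = 10, max_gap = 3,
                           wave_threshold = 15, speed_lag = 10L) {
  N <- geometry$N
  bin_ms <- attr(comps, "bin_ms")
  if (is.null(bin_ms)) bin_ms <- 1
  pts <- list()
  active <- list()   # each: id, x, y (wrapped), ux, uy, frame, rows (matrix)
  next_id <- 0L
  frames <- sort(unique(comps$frame))
  cx_all <- comps$x; cy_all <- comps$y
  tms_all <- comps$time_ms; fr_all <- comps$frame
  for (f in frames) {
    sel <- which(fr_all == f)
    cx <- cx_all[sel]; cy <- cy_all[sel]; tms <- tms_all[sel][1]
    used <- rep(FALSE, length(sel))
    if (length(active)) {
      # candidate links: (track, component, distance), greedily matched
      ca <- ci <- integer(0); cd <- numeric(0)
      for (a in seq_along(active)) {
        tr <- active[[a]]
        gap <- f - tr$frame
        if (gap > max_gap) next
        dx <- wrap_delta(cx - tr$x, N); dy <- wrap_delta(cy - tr$y, N)
        d <- sqrt(dx^2 + dy^2)
        ok <- which(d <= max_jump * gap)
        ca <- c(ca, rep.int(a, length(ok))); ci <- c(ci, ok)
        cd <- c(cd, d[ok])
      }
      if (length(ca)) {
        taken_a <- logical(length(active))
        for (r in order(cd)) {
          a <- ca[r]; cc_i <- ci[r]
          if (taken_a[a] || used[cc_i]) next
          taken_a[a] <- TRUE; used[cc_i] <- TRUE
          tr <- active[[a]]
          tr$ux <- tr$ux + wrap_delta(cx[cc_i] - tr$x, N)
          tr$uy <- tr$uy + wrap_delta(cy[cc_i] - tr$y, N)
          tr$x <- cx[cc_i]; tr$y <- cy[cc_i]
          tr$frame <- f
          tr$rows[[length(tr$rows) + 1L]] <-
            c(f, tms, cx[cc_i], cy[cc_i], tr$ux, tr$uy)
          active[[a]] <- tr
        }
      }
    }
    # retire stale tracks
    if (length(active)) {
      stale <- vapply(active, function(tr) f - tr$frame >= max_gap, logical(1))
      for (tr in active[stale]) pts[[length(pts) + 1L]] <- tr
      active <- active[!stale]
    }
    # unmatched components found new tracks
    for (cc_i in which(!used)) {
      next_id <- next_id + 1L
      active[[length(active) + 1L]] <-
        list(id = next_id, x = cx[cc_i], y = cy[cc_i],
             ux = cx[cc_i], uy = cy[cc_i], frame = f,
             rows = list(c(f, tms, cx[cc_i], cy[cc_i], cx[cc_i], cy[cc_i])))
    }
  }
  for (tr in active) pts[[length(pts) + 1L]] <- tr

  as_rows <- function(tr) {
    m <- do.call(rbind, tr$rows)
    data.frame(track_id = tr$id, frame = as.integer(m[, 1]),
               time_ms = m[, 2], x = m[, 3], y = m[, 4],
               x_unwrapped = m[, 5], y_unwrapped = m[, 6])
  }
  points <- do.call(rbind, lapply(pts, as_rows))
  summary <- do.call(rbind, lapply(pts, function(tr) {
    rows <- as_rows(tr)
    net <- sqrt((tr$ux - rows$x_unwrapped[1])^2 +
                (tr$uy - rows$y_unwrapped[1])^2)
    data.frame(track_id = tr$id, n_frames = nrow(rows),
               net_displacement_gp = net,
               mean_speed_mm_s = track_speed(rows, speed_lag, geometry$spacing,
                                             bin_ms),
               label = if (net > wave_threshold) "wave" else "patch")
  }))
  if (is.null(points))
    points <- data.frame(track_id = integer(0), frame = integer(0),
                         time_ms = numeric(0), x = numeric(0), y = numeric(0),
                         x_unwrapped = numeric(0), y_unwrapped = numeric(0))
  if (is.null(summary))
    summary <- data.frame(track_id = integer(0), n_frames = integer(0),
                          net_displacement_gp = numeric(0),
                          mean_speed_mm_s = numeric(0), label = character(0))
  structure(list(points = points, summary = summary,
                 bin_ms = bin_ms, spacing = geometry$spacing),
            class = "wp_tracks")
}

#' @export
print.wp_tracks <- function(x, ...) {
  cat(sprintf("<wp_tracks> %d tracks (%d wave, %d patch), mean speed %.1f mm/s\n",
              nrow(x$summary), sum(x$summary$label == "wave"),
              sum(x$summary$label == "patch"),
              mean(x$summary$mean_speed_mm_s)))
  invisible(x)
}

# Lagged-displacement speed of one track: mean over t of
# |x(t+L) - x(t)| / L_elapsed, converted to mm/s. Falls back to the net
# displacement over the lifetime for tracks shorter than the lag.
track_speed <- function(rows, speed_lag, spacing, bin_ms) {
  n <- nrow(rows)
  if (n < 2L) return(0)
  tgt <- match(rows$frame + speed_lag, rows$frame)
  i <- which(!is.na(tgt))
  if (!length(i)) {   # short track: net displacement over lifetime
    dd <- sqrt((rows$x_unwrapped[n] - rows$x_unwrapped[1])^2 +
               (rows$y_unwrapped[n] - rows$y_unwrapped[1])^2)
    return(dd / (rows$frame[n] - rows$frame[1]) * spacing / bin_ms)
  }
  j <- tgt[i]
  dd <- sqrt((rows$x_unwrapped[j] - rows$x_unwrapped[i])^2 +
             (rows$y_unwrapped[j] - rows$y_unwrapped[i])^2)
  mean(dd / speed_lag) * spacing / bin_ms
}

#' Pooled mean propagation speed of tracked patterns
#'
#' Pools the lagged centroid displacements (`speed_lag` frames, see
#' [track_patterns()]) of all sufficiently long tracks and converts the
#' mean to mm/s. This is the population propagation-speed summary used for
#' the spontaneous/evoked comparison.
#'
#' @param tracks a `wp_tracks` object.
#' @param min_frames only tracks observed in at least this many frames enter.
#' @param speed_lag displacement lag, frames.
#' @return speed in mm/s (NaN if no usable displacements).
#' @export
mean_track_speed <- function(tracks, min_frames = 5L, speed_lag = 10L) {
  keep <- tracks$summary$track_id[tracks$summary$n_frames >= min_frames]
  pt <- tracks$points[tracks$points$track_id %in% keep, , drop = FALSE]
  if (!nrow(pt)) return(NaN)
  disp <- numeric(0)
  for (id in unique(pt$track_id)) {
    p <- pt[pt$track_id == id, , drop = FALSE]
    tgt <- match(p$frame + speed_lag, p$frame)
    i <- which(!is.na(tgt))
    if (!length(i)) next
    j <- tgt[i]
    disp <- c(disp, sqrt((p$x_unwrapped[j] - p$x_unwrapped[i])^2 +
                         (p$y_unwrapped[j] - p$y_unwrapped[i])^2) / speed_lag)
  }
  if (!length(disp)) return(NaN)
  mean(disp) * tracks$spacing / tracks$bin_ms
}

#' Mean-squared-displacement exponent of a track
#'
#' Slope of `log MSD` versus `log lag` over lags 1..`max_lag` frames, using
#' the unwrapped centroid trajectory. An exponent near 2 indicates
#' ballistic (wave-like) motion, near 1 Brownian (patch-like) wandering.
#'
#' @param track either a `wp_tracks` object with a single track, or a
#'   two-column matrix of unwrapped centroid coordinates per frame.
#' @param max_lag largest lag, frames.
#' @param min_frames minimum trajectory length.
#' @return the fitted exponent.
#' @export
msd_exponent <- function(track, max_lag = 25L, min_frames = 50L) {
  if (inherits(track, "wp_tracks")) {
    if (length(unique(track$points$track_id)) != 1L)
      stop("supply a single track (subset $points first)")
    xy <- as.matrix(track$points[, c("x_unwrapped", "y_unwrapped")])
  } else xy <- as.matrix(track)
  n <- nrow(xy)
  if (n < min_frames) stop(sprintf("track too short (%d < %d frames)", n, min_frames))
  lags <- seq_len(min(max_lag, n - 1L))
  msd <- vapply(lags, function(L) {
    d <- xy[(1 + L):n, , drop = FALSE] - xy[1:(n - L), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  ok <- msd > 0
  unname(coef(lm(log(msd[ok]) ~ log(lags[ok])))[2])
}

#' Distances of afferent spikes to a test neuron
#'
#' For every spike of a neuron afferent to `test_neuron` (minimal-image
#' distance `0 < d <= D` gridpoints), records the spike time and physical
#' distance, and summarizes them with a 1 ms sliding window: per-window
#' mean afferent distance (um) and afferent spike count. A heavy-tailed
#' count histogram is the signature of transient, synchronized input from
#' passing wavefronts; a bell-shaped one of sustained local input from a
#' patch.
#'
#' @param rec a `wp_recording` (or fixture with `$spikes`).
#' @param test_neuron 0-based coordinates `c(x, y)`.
#' @param params a [model_params()] (for the cutoff `D`).
#' @param classes restrict afferent class: `"both"`, `"excitatory"` or
#'   `"inhibitory"`.
#' @param window_ms sliding-window length and step, ms.
#' @param epoch `c(start, end)` ms; defaults to burn-in .. duration.
#' @return list of class `wp_distance_series`: `$events` (time_ms,
#'   distance_um), `$series` (t_ms, mean_distance_um, count).
#' @export
afferent_spike_distances <- function(rec, test_neuron, params,
                                     classes = c("both", "excitatory",
                                                 "inhibitory"),
                                     window_ms = 1, epoch = NULL) {
  classes <- match.arg(classes)
  geom <- rec$config$geometry
  if (is.null(epoch)) epoch <- c(rec$config$burn_in, rec$config$duration)
  sp <- rec$spikes
  sp <- sp[sp$time_ms > epoch[1] & sp$time_ms <= epoch[2], , drop = FALSE]
  d <- lattice_distance(cbind(sp$x, sp$y),
                        matrix(test_neuron, max(nrow(sp), 1L), 2, byrow = TRUE),
                        geom)
  keep <- d > 0 & d <= params$D
  if (classes != "both")
    keep <- keep & neuron_class(sp$x, sp$y, geom) == classes
  ev <- data.frame(time_ms = sp$time_ms[keep],
                   distance_um = d[keep] * geom$spacing)
  tgrid <- seq(epoch[1], epoch[2] - window_ms, by = window_ms)
  bin <- findInterval(ev$time_ms, tgrid, left.open = TRUE)
  mean_d <- vapply(seq_along(tgrid), function(b) {
    v <- ev$distance_um[bin == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  cnt <- tabulate(bin[bin >= 1 & bin <= length(tgrid)], nbins = length(tgrid))
  structure(list(events = ev,
                 series = data.frame(t_ms = tgrid + window_ms / 2,
                                     mean_distance_um = mean_d,
                                     count = cnt),
                 test_neuron = test_neuron),
            class = "wp_distance_series")
}

#' Reconstruct a neuron's synaptic conductance from afferent spikes
#'
#' Replays the conductance dynamics of a single target neuron offline: the
#' complete afferent spike record is converted to kernel-weighted
#' conductance jumps and evolved with exactly the Euler scheme, jump
#' convention, and summation order used by the simulator, so the
#' reconstruction reproduces the recorded trace to floating-point
#' round-off. This is the bookkeeping identity linking population spiking
#' patterns to single-neuron synaptic input.
#'
#' @param rec a `wp_recording` (its full spike table is the afferent record).
#' @param test_neuron 0-based coordinates `c(x, y)`.
#' @param config the recording's [circuit_config()] (defaults to
#'   `rec$config`).
#' @param field which conductance to reconstruct: `"E"` or `"I"`.
#' @param g0 initial conductance, nS.
#' @return data.frame `time_ms`, `g` (nS) at Euler-step resolution, from
#'   t = 0 to the trial end.
#' @export
reconstruct_conductance <- function(rec, test_neuron, config = rec$config,
                                    field = c("E", "I"), g0 = 0) {
  field <- match.arg(field)
  p <- config$params
  N <- config$geometry$N
  kernels <- build_kernels(p)
  jumps <- kernel_jumps(kernels, p)
  jump <- if (field == "E") jumps$E else jumps$I
  want_class <- if (field == "E") "excitatory" else "inhibitory"
  dt <- p$dt
  n_steps <- round(config$duration / dt)

  # sources feeding the target through each kernel offset (with wraparound);
  # a source can appear under several offsets when N <= 2D
  src <- ((test_neuron[1] - kernels$dx) %% N) +
    N * ((test_neuron[2] - kernels$dy) %% N)
  by_src <- split(seq_along(src), src)   # offset indices in kernel order

  sp <- rec$spikes
  cls <- neuron_class(sp$x, sp$y, config$geometry)
  sp_idx <- sp$x + N * sp$y
  sel <- which(cls == want_class & sp_idx %in% as.integer(names(by_src)))

  step_of <- as.integer(round(sp$time_ms[sel] / dt))
  ord <- order(step_of)                   # stable: preserves recording order
  jump_step <- integer(0); jump_val <- numeric(0)
  if (length(sel)) {
    js <- vector("list", length(sel))
    for (k in seq_along(ord)) {
      i <- ord[k]
      off <- by_src[[as.character(sp_idx[sel[i]])]]
      js[[k]] <- list(step = rep(step_of[i], length(off)), val = jump[off])
    }
    jump_step <- unlist(lapply(js, `[[`, "step"))
    jump_val <- unlist(lapply(js, `[[`, "val"))
  }
  tau <- if (field == "E") p$tau_E else p$tau_I
  g <- cpp_reconstruct(jump_step, jump_val, n_steps, 1 - dt / tau, g0)
  data.frame(time_ms = (0:n_steps) * dt, g = g)
}
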