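#' Sample skewness (third standardized central moment)
#'
#' Default is the bias-uncorrected moment estimator
#' `m3 / m2^(3/2)` with `m_k` the k-th central sample moment; `adjust = TRUE`
#' applies the usual small-sample (Fisher-Pearson) correction. Positive
#' values indicate a heavy tail towards large values (depolarized membrane
#' potentials, large conductances).
#'
#' @param x numeric sample, length >= 3.
#' @param adjust apply the small-sample correction.
#' @return skewness, or `NaN` (flagged undefined) when the sample variance
#'   is zero.
#' @export
skewness <- function(x, adjust = FALSE) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) stop("skewness needs at least 3 finite observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NaN)
  s <- mean((x - m)^3) / m2^1.5
  if (adjust) s <- s * sqrt(n * (n - 1)) / (n - 2)
  s
}

#' Time-averaged distance of the membrane potential to threshold
#'
#' For a subthreshold trace `V(t)`, returns `V_th - mean(V)` in mV, a
#' positive distance when the neuron sits below threshold. The caller is
#' responsible for restricting the trace to the epoch of interest (burn-in
#' excluded).
#'
#' @param V numeric membrane-potential trace, mV.
#' @param params a [model_params()].
#' @export
subthreshold_distance <- function(V, params) {
  V <- V[is.finite(V)]
  if (!length(V)) stop("empty membrane-potential trace")
  params$V_th - mean(V)
}

#' Per-neuron trial statistics of probe traces
#'
#' Applies `stat` to each probe neuron's trace restricted to `epoch`, in
#' every trial, then takes the median across trials per neuron. This is the
#' summary used for both the distance-to-threshold and the skewness
#' analyses: per-trial statistic, median over trials, then (by the caller)
#' an average over RoI neurons.
#'
#' @param recordings list of `wp_recording`s with identical probe sets.
#' @param field which probe trace to analyse: `"V"`, `"g_E"` or `"g_I"`.
#' @param epoch `c(start, end)` ms; samples with `start < t <= end` enter.
#' @param stat function of a numeric vector returning a scalar.
#' @return list with `per_trial` (neurons x trials matrix), `median`
#'   (per-neuron median across trials) and `mean` (across-neuron average of
#'   the medians).
#' @export
probe_trial_stat <- function(recordings, field = c("V", "g_E", "g_I"),
                             epoch, stat) {
  field <- match.arg(field)
  stopifnot(length(epoch) == 2L, epoch[1] < epoch[2])
  vals <- lapply(recordings, function(rec) {
    if (is.null(rec$probes)) stop("recording has no probe traces")
    keep <- rec$probes$times > epoch[1] & rec$probes$times <= epoch[2]
    if (!any(keep)) stop("epoch contains no probe samples")
    apply(rec$probes[[field]][, keep, drop = FALSE], 1L, stat)
  })
  per_trial <- do.call(cbind, vals)
  med <- apply(per_trial, 1L, median)
  list(per_trial = per_trial, median = med, mean = mean(med))
}

#' Membrane-potential summary over RoI probes
#'
#' Convenience wrapper around [probe_trial_stat()] computing, for an epoch,
#' the across-neuron average of per-neuron trial medians of (a) the
#' distance to threshold `V_th - <V>` and (b) the membrane-potential
#' skewness.
#'
#' @inheritParams probe_trial_stat
#' @param params the [model_params()] of the recordings.
#' @return list with elements `distance` and `skewness`, each as returned
#'   by [probe_trial_stat()].
#' @export
vm_summary <- function(recordings, params, epoch) {
  list(distance = probe_trial_stat(recordings, "V", epoch,
                                   function(v) subthreshold_distance(v, params)),
       skewness = probe_trial_stat(recordings, "V", epoch, skewness))
}

#' Excitatory-conductance skewness summary over RoI probes
#'
#' @inheritParams probe_trial_stat
#' @return as [probe_trial_stat()].
#' @export
conductance_skewness <- function(recordings, epoch) {
  probe_trial_stat(recordings, "g_E", epoch, skewness)
}

#' Sliding-window spike counts
#'
#' Counts spikes of each selected neuron in sliding windows of length
#' `window` ms advanced by `step` ms over `epoch`, for each recording.
#' `window` must be a multiple of `step` (counts are rolling sums of
#' `step`-sized bins).
#'
#' @param recordings list of `wp_recording`s (or anything with a `$spikes`
#'   table and `$config`).
#' @param neurons data.frame with columns `x`, `y` selecting the neurons
#'   (e.g. [roi_neurons()]).
#' @param window window length, ms.
#' @param step window increment, ms.
#' @param epoch `c(start, end)` ms; windows lie fully inside the epoch.
#' @return list with `counts`, an array `neurons x windows x trials`, and
#'   `times`, the window centres (ms).
#' @export
count_spikes <- function(recordings, neurons, window = 250, step = 50,
                         epoch = NULL) {
  if (window %% step != 0) stop("'window' must be a multiple of 'step'")
  if (is.null(epoch)) {
    cfg <- recordings[[1]]$config
    epoch <- c(cfg$burn_in, cfg$duration)
  }
  n_bins <- floor((epoch[2] - epoch[1]) / step)
  k <- window %/% step
  if (n_bins < k) stop("epoch shorter than one window")
  n_win <- n_bins - k + 1L
  N <- recordings[[1]]$config$geometry$N
  idx_sel <- neurons$x + N * neurons$y
  counts <- array(0L, c(length(idx_sel), n_win, length(recordings)))
  for (tr in seq_along(recordings)) {
    sp <- recordings[[tr]]$spikes
    keep <- sp$time_ms > epoch[1] & sp$time_ms <= epoch[2]
    sp <- sp[keep, , drop = FALSE]
    ni <- match(sp$x + N * sp$y, idx_sel)
    ok <- !is.na(ni)
    bin <- pmin(floor((sp$time_ms[ok] - epoch[1] - 1e-9) / step) + 1L, n_bins)
    base <- matrix(0L, length(idx_sel), n_bins)
    if (any(ok)) {
      tab <- table(factor(ni[ok], levels = seq_along(idx_sel)),
                   factor(bin, levels = seq_len(n_bins)))
      base <- matrix(as.integer(tab), length(idx_sel), n_bins)
    }
    cs <- cbind(0L, t(apply(base, 1L, cumsum)))
    counts[, , tr] <- cs[, (k + 1L):(n_bins + 1L), drop = FALSE] -
      cs[, 1L:n_win, drop = FALSE]
  }
  times <- epoch[1] + (seq_len(n_win) - 1L) * step + window / 2
  list(counts = counts, times = times, window = window, step = step)
}

#' Sliding-window firing rate
#'
#' Per-neuron spike counts in sliding windows divided by the window length,
#' in Hz. With `average = TRUE` the rate is additionally averaged over
#' neurons and trials, giving the population rate time series.
#'
#' @inheritParams count_spikes
#' @param average return the neuron- and trial-averaged time series.
#' @return list with `times` (window centres, ms) and either `rate`
#'   (numeric vector, Hz) if `average`, else `rates`
#'   (`neurons x windows x trials` array, Hz).
#' @export
firing_rate <- function(recordings, neurons, window = 250, step = 50,
                        epoch = NULL, average = TRUE) {
  cs <- count_spikes(recordings, neurons, window, step, epoch)
  scale <- 1000 / window
  if (average)
    list(times = cs$times, rate = apply(cs$counts, 2L, mean) * scale)
  else
    list(times = cs$times, rates = cs$counts * scale)
}

#' Raw Fano factor of spike counts across trials
#'
#' Variance over mean of each neuron's spike count across trials, per
#' window. Windows where a neuron's mean count is zero are returned as
#' `NaN` (flagged undefined rather than zero).
#'
#' @param counts array `neurons x windows x trials` (from [count_spikes()]).
#' @return matrix `neurons x windows` of Fano factors.
#' @export
fano_factor <- function(counts) {
  if (length(dim(counts)) != 3L) stop("'counts' must be neurons x windows x trials")
  if (dim(counts)[3] < 2L) stop("Fano factor needs at least 2 trials")
  m <- apply(counts, c(1L, 2L), mean)
  v <- apply(counts, c(1L, 2L), var)
  ff <- v / m
  ff[m == 0] <- NaN
  ff
}

#' Mean-matched Fano factor time series
#'
#' Controls for rate changes when comparing variability across time: the
#' distribution of per-neuron mean counts is equalized across windows by
#' computing the greatest common (floor) histogram of mean counts over all
#' windows and, at each window, randomly discarding neurons until its mean
#' count histogram matches that common histogram. The Fano factor is then
#' averaged over the kept neurons; the discard is repeated `n_resamples`
#' times and averaged. If the common histogram is empty the raw
#' (unmatched) average is returned with `matched = FALSE` and a warning.
#'
#' @param counts array `neurons x windows x trials`.
#' @param bin_width histogram bin width for mean counts (spikes).
#' @param n_resamples number of random discard rounds.
#' @param seed integer seed for the discard RNG.
#' @return list of class `wp_fano`: `mm_ff` (time series), `se` (standard
#'   error over kept neurons, averaged over resamples), `raw_ff`
#'   (unmatched across-neuron average), `n_kept`, `matched`.
#' @export
mean_matched_fano <- function(counts, bin_width = 0.5, n_resamples = 50,
                              seed = 1L) {
  ffm <- fano_factor(counts)           # neurons x windows, NaN where mean 0
  m <- apply(counts, c(1L, 2L), mean)
  n_win <- ncol(m)
  if (n_win < 2L) stop("mean matching needs at least 2 windows")
  raw_ff <- colMeans(ffm, na.rm = TRUE)

  breaks <- seq(0, max(m) + bin_width, by = bin_width)
  bin_of <- matrix(findInterval(m, breaks, left.open = TRUE) + 1L, nrow(m))
  # histogram per window, then elementwise minimum = common floor histogram
  hists <- vapply(seq_len(n_win), function(w)
    tabulate(bin_of[, w], nbins = length(breaks)), integer(length(breaks)))
  common <- apply(hists, 1L, min)
  if (sum(common) == 0L) {
    warning("empty common mean-count histogram; returning raw Fano factor")
    return(structure(list(mm_ff = raw_ff, se = rep(NA_real_, n_win),
                          raw_ff = raw_ff, n_kept = 0L, matched = FALSE),
                     class = "wp_fano"))
  }
  set.seed(seed)
  acc <- matrix(0, n_resamples, n_win)
  acc_se <- matrix(0, n_resamples, n_win)
  for (r in seq_len(n_resamples)) {
    for (w in seq_len(n_win)) {
      keep <- integer(0)
      for (b in which(common > 0L)) {
        in_bin <- which(bin_of[, w] == b)
        keep <- c(keep, if (length(in_bin) == common[b]) in_bin
                  else sample(in_bin, common[b]))
      }
      f <- ffm[keep, w]
      f <- f[is.finite(f)]
      acc[r, w] <- mean(f)
      acc_se[r, w] <- sd(f) / sqrt(length(f))
    }
  }
  structure(list(mm_ff = colMeans(acc), se = colMeans(acc_se),
                 raw_ff = raw_ff, n_kept = sum(common), matched = TRUE),
            class = "wp_fano")
}

#' @export
print.wp_fano <- function(x, ...) {
  cat(sprintf("<wp_fano> %d windows, %s, mean FF %.3f\n",
              length(x$mm_ff),
              if (x$matched) sprintf("mean-matched (%d neurons kept)", x$n_kept)
              else "raw (matching impossible)",
              mean(x$mm_ff, na.rm = TRUE)))
  invisible(x)
}

#' Fano factor versus counting-window size
#'
#' Computes the mean-matched Fano factor, averaged over windows inside an
#' epoch, for each counting-window length. During irregular activity with
#' slow rate fluctuations the Fano factor grows with the window; for a
#' rate-stable (Poisson-like) regime it is window-size independent.
#'
#' @param recordings list of `wp_recording`s.
#' @param neurons neuron selection (see [count_spikes()]).
#' @param windows vector of window lengths, ms.
#' @param epoch `c(start, end)` ms.
#' @param step window increment, ms.
#' @param ... passed to [mean_matched_fano()].
#' @return data.frame `window`, `ff`.
#' @export
fano_vs_window <- function(recordings, neurons, windows = seq(150, 600, 50),
                           epoch, step = 50, ...) {
  ff <- vapply(windows, function(w) {
    cs <- count_spikes(recordings, neurons, window = w, step = step,
                       epoch = epoch)
    mean(mean_matched_fano(cs$counts, ...)$mm_ff, na.rm = TRUE)
  }, numeric(1))
  data.frame(window = windows, ff = ff)
}

#' Windows assigned to an epoch, onset-straddling windows excluded
#'
#' Helper for epoch summaries of sliding-window series: keeps window
#' centres whose full window lies inside `epoch` and does not straddle
#' `t_on`.
#'
#' @param times window centres, ms.
#' @param window window length, ms.
#' @param epoch `c(start, end)` ms.
#' @param t_on stimulus onset, ms (or `NULL`).
#' @return logical vector.
#' @export
windows_in_epoch <- function(times, window, epoch, t_on = NULL) {
  lo <- times - window / 2
  hi <- times + window / 2
  ok <- lo >= epoch[1] & hi <= epoch[2]
  if (!is.null(t_on)) ok <- ok & !(lo < t_on & hi > t_on)
  ok
}
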