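#' Initialize the network state
#'
#' Membrane potentials are drawn i.i.d. uniformly on `[V_R, V_th)`;
#' conductances start at zero (quiescent synapses) and no neuron is
#' refractory. The draw uses R's RNG, so the state is reproducible from the
#' seed.
#'
#' @param config a [circuit_config()].
#' @param seed integer RNG seed for the initial condition.
#' @return an object of class `wp_state`: list with vectors `V`, `g_E`,
#'   `g_I` (length `N^2`, indexed `x + N*y`), integer `refractory` (steps
#'   remaining), `pending` (0-based indices of neurons that spiked in the
#'   last completed step) and scalar time `t` (ms).
#' @export
initialize_state <- function(config, seed) {
  stopifnot(inherits(config, "wp_config"))
  M <- config$geometry$N^2
  set.seed(seed)
  structure(list(
    V = runif(M, config$params$V_R, config$params$V_th),
    g_E = numeric(M), g_I = numeric(M),
    refractory = integer(M), pending = integer(0), t = 0
  ), class = "wp_state")
}

run_core <- function(state, config, kernels, n_steps,
                     probe_idx = integer(0), sample_every = 0L,
                     movie_stride = 0L, movie_conductances = FALSE) {
  p <- config$params
  jumps <- kernel_jumps(kernels, p)
  pars <- list(g_L = p$g_L, C = p$C, V_L = p$V_L, V_E = p$V_E, V_I = p$V_I,
               V_th = p$V_th, V_R = p$V_R, tau_ref = p$tau_ref,
               tau_E = p$tau_E, tau_I = p$tau_I, I_0 = config$protocol$I_0)
  cpp_run_steps(state$V, state$g_E, state$g_I, state$refractory,
                as.integer(state$pending),
                config$geometry$N, as.integer(n_steps), state$t, p$dt,
                pars, stimulus_field(config$protocol, config$geometry),
                config$protocol$t_on,
                as.integer(kernels$dx), as.integer(kernels$dy),
                jumps$E, jumps$I,
                as.integer(probe_idx), as.integer(sample_every),
                as.integer(movie_stride), movie_conductances)
}

#' Advance the network state by one or more Euler steps
#'
#' Each step applies, in this fixed order: (1) conductance increments from
#' spikes of the previous step, scattered through the coupling kernels with
#' periodic wraparound; (2) Euler conductance decay `g <- g * (1 - dt/tau)`;
#' (3) Euler membrane update for non-refractory neurons (refractory neurons
#' are clamped at `V_R` and ignore synaptic input while their conductances
#' keep evolving); (4) threshold crossing: `V >= V_th` emits a spike, resets
#' to `V_R` and starts the refractory countdown. The ordering is fixed
#' because it affects bit-level results.
#'
#' @param state a `wp_state` (modified copy returned; input not changed).
#' @param config a [circuit_config()].
#' @param kernels kernels from [build_kernels()] (rebuilt if missing).
#' @param n_steps number of Euler steps of size `params$dt`.
#' @return the advanced `wp_state`; spikes emitted during the call are in
#'   `attr(, "spikes")` as a data.frame `time_ms`, `x`, `y`.
#' @export
step_state <- function(state, config, kernels = NULL, n_steps = 1L) {
  stopifnot(inherits(state, "wp_state"))
  if (is.null(kernels)) kernels <- build_kernels(config$params)
  res <- run_core(lapply(state, identity), config, kernels, n_steps)
  out <- structure(list(V = res$V, g_E = res$gE, g_I = res$gI,
                        refractory = res$refrac, pending = res$pending,
                        t = res$t), class = "wp_state")
  attr(out, "spikes") <- data.frame(time_ms = res$spike_t,
                                    x = res$spike_x, y = res$spike_y)
  out
}

#' Run one trial of the circuit
#'
#' Integrates the network for `config$duration` ms from a seeded random
#' initial condition. Spike events are always recorded; membrane and
#' conductance traces of selected probe neurons are sampled every
#' `sample_ms` (default 1 ms), and full state frames can be captured at a
#' chosen stride for LFP computation. Identical `(config, seed)` give a
#' bit-identical recording.
#'
#' @param config a [circuit_config()].
#' @param seed integer seed for the initial condition.
#' @param probes `NULL`, or a 2-column matrix / data.frame of 0-based
#'   gridpoint coordinates whose `V`, `g_E`, `g_I` traces are recorded, or
#'   the string `"roi"` for all RoI neurons.
#' @param sample_ms probe sampling interval, ms (must be a multiple of `dt`).
#' @param movie_stride_ms `NA` for no state movie, otherwise the frame
#'   interval in ms; frames record `V` and, if `movie_conductances`, also
#'   `g_E`/`g_I` (needed for the LFP proxy).
#' @param movie_conductances record conductance frames along with `V`.
#' @return an object of class `wp_recording`: spike table `$spikes`
#'   (`time_ms`, `x`, `y`), optional `$probes` (coordinate table, `times`,
#'   matrices `V`, `g_E`, `g_I` of size neurons x samples), optional
#'   `$movie` (`times` and `N^2 x frames` matrices), `$config`, `$seed`,
#'   `$digest`.
#' @export
run_trial <- function(config, seed, probes = NULL, sample_ms = 1,
                      movie_stride_ms = NA, movie_conductances = FALSE) {
  stopifnot(inherits(config, "wp_config"))
  kernels <- build_kernels(config$params)
  state <- initialize_state(config, seed)
  dt <- config$params$dt
  n_steps <- round(config$duration / dt)

  if (identical(probes, "roi"))
    probes <- roi_neurons(config$geometry, config$protocol)
  probe_idx <- integer(0); probe_coords <- NULL; sample_every <- 0L
  if (!is.null(probes)) {
    probe_coords <- as.data.frame(probes)[, c("x", "y")]
    probe_idx <- probe_coords$x + config$geometry$N * probe_coords$y
    sample_every <- round(sample_ms / dt)
    if (abs(sample_every * dt - sample_ms) > 1e-9)
      stop("'sample_ms' must be a multiple of dt")
  }
  movie_stride <- 0L
  if (!is.na(movie_stride_ms)) {
    movie_stride <- round(movie_stride_ms / dt)
    if (abs(movie_stride * dt - movie_stride_ms) > 1e-9)
      stop("'movie_stride_ms' must be a multiple of dt")
  }

  res <- run_core(state, config, kernels, n_steps, probe_idx, sample_every,
                  movie_stride, movie_conductances)

  rec <- list(
    spikes = data.frame(time_ms = res$spike_t, x = res$spike_x,
                        y = res$spike_y),
    probes = if (length(probe_idx)) list(
      coords = probe_coords, times = res$probe_times,
      V = res$probe_V, g_E = res$probe_gE, g_I = res$probe_gI) else NULL,
    movie = if (movie_stride > 0) list(
      times = res$movie_times, V = res$movie_V,
      g_E = if (movie_conductances) res$movie_gE else NULL,
      g_I = if (movie_conductances) res$movie_gI else NULL) else NULL,
    config = config, seed = as.integer(seed),
    digest = config_digest(config)
  )
  structure(rec, class = "wp_recording")
}

#' @export
print.wp_recording <- function(x, ...) {
  cat(sprintf("<wp_recording> N = %d, %g ms, seed %d: %d spikes",
              x$config$geometry$N, x$config$duration, x$seed,
              nrow(x$spikes)))
  if (!is.null(x$probes)) cat(sprintf(", %d probes", nrow(x$probes$coords)))
  if (!is.null(x$movie)) cat(sprintf(", %d movie frames", length(x$movie$times)))
  cat("\n")
  invisible(x)
}

#' Run a sweep over stimulus strengths
#'
#' Runs `n_trials` independent seeded trials for every stimulus amplitude in
#' `strengths`. Trial `j` of strength `i` uses seed
#' `seed_base + (i-1)*n_trials + (j-1)`; the manifest maps each
#' `(strength, trial)` to its seed, so re-running with the same `seed_base`
#' reproduces every recording exactly.
#'
#' @param config a [circuit_config()]; its `W_S` is overridden per strength.
#' @param strengths numeric vector of stimulus amplitudes `W_S`, nA.
#' @param n_trials trials per strength.
#' @param seed_base integer base seed.
#' @param ... passed to [run_trial()] (probes, movie options).
#' @return an object of class `wp_sweep`: list with `$manifest`
#'   (data.frame `strength`, `trial`, `seed`) and `$recordings` (list in
#'   manifest row order).
#' @export
run_sweep <- function(config, strengths, n_trials = 1L, seed_base = 1L, ...) {
  if (!length(strengths)) stop("'strengths' must be non-empty")
  manifest <- expand.grid(trial = seq_len(n_trials),
                          strength = strengths)[, c("strength", "trial")]
  manifest$seed <- seed_base + seq_len(nrow(manifest)) - 1L
  recordings <- vector("list", nrow(manifest))
  for (k in seq_len(nrow(manifest))) {
    cfg <- config
    cfg$protocol$W_S <- manifest$strength[k]
    recordings[[k]] <- run_trial(cfg, manifest$seed[k], ...)
  }
  structure(list(manifest = manifest, recordings = recordings),
            class = "wp_sweep")
}

#' Closed-form firing rate of an isolated LIF neuron under constant drive
#'
#' With coupling switched off and constant current `I`, the membrane relaxes
#' towards `V_inf = V_L + I/g_L`; if that exceeds threshold the neuron fires
#' periodically with interspike interval
#' `tau_ref + tau_m * log((V_inf - V_R) / (V_inf - V_th))`. Used as an
#' analytic oracle for the integrator.
#'
#' @param params a [model_params()].
#' @param I constant input current, nA.
#' @return firing rate in Hz (0 if `V_inf <= V_th`).
#' @export
lif_rate <- function(params, I) {
  V_inf <- params$V_L + (I / params$g_L) * 1000  # nA/nS = V, hence x1000 mV
  if (V_inf <= params$V_th) return(0)
  tau_m <- params$C / params$g_L * 1000          # nF / nS = s -> ms
  isi <- params$tau_ref +
    tau_m * log((V_inf - params$V_R) / (V_inf - params$V_th))
  1000 / isi
}
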