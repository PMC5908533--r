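#' Physical parameters of the conductance-based LIF lattice
#'
#' Defaults are the reference parameter set of the balanced circuit: a leak
#' conductance of 25 nS and capacitance of 0.5 nF give a 20 ms membrane time
#' constant; reversal potentials place rest at -70 mV between the inhibitory
#' (-80 mV) and excitatory (0 mV) reversals, with threshold -55 mV and reset
#' -70 mV followed by a 5 ms refractory period. Synaptic conductances decay
#' with 2 ms time constants. Coupling is excitatory-Gaussian (amplitude
#' `W_E`, width `sigma_E`) and inhibitory-uniform (`W_I`) out to a shared
#' cutoff of `D` gridpoints (1200 um at 40 um spacing, 2820 afferents).
#'
#' `sigma_E` is a calibrated value, not a published one: the published
#' figure is unavailable, so the default of 4 gridpoints (160 um) was fixed
#' once so that the excitatory kernel decays well inside the cutoff and the
#' network exhibits coexisting waves and patches at a spontaneous rate near
#' 9 Hz (see the methods vignette).
#'
#' `jump_convention` selects the discretization of the synaptic delta pulses:
#' `"K_over_tau"` (default) increments a conductance by `K/tau` per afferent
#' spike so that each spike contributes a conductance time-integral of `K`
#' (with `K` in nS s); `"K"` increments by `K` directly. See the methods
#' vignette for why `"K_over_tau"` is the default.
#'
#' @param g_L leak conductance, nS.
#' @param C membrane capacitance, nF.
#' @param V_L,V_E,V_I leak / excitatory / inhibitory reversal potentials, mV.
#' @param V_th spike threshold, mV.
#' @param V_R reset potential, mV.
#' @param tau_ref refractory period, ms.
#' @param tau_E,tau_I conductance decay time constants, ms.
#' @param W_E excitatory kernel amplitude, nS.
#' @param W_I inhibitory kernel strength, nS.
#' @param sigma_E excitatory Gaussian decay, gridpoints (calibrated default).
#' @param D connection cutoff radius, gridpoints.
#' @param dt Euler time step, ms.
#' @param jump_convention `"K_over_tau"` or `"K"`; see Details.
#' @return an object of class `wp_params`.
#' @export
model_params <- function(g_L = 25, C = 0.5,
                         V_L = -70, V_E = 0, V_I = -80,
                         V_th = -55, V_R = -70,
                         tau_ref = 5, tau_E = 2, tau_I = 2,
                         W_E = 7.5e-3, W_I = 5.0e-3,
                         sigma_E = 4, D = 30, dt = 0.05,
                         jump_convention = c("K_over_tau", "K")) {
  jump_convention <- match.arg(jump_convention)
  p <- list(g_L = g_L, C = C, V_L = V_L, V_E = V_E, V_I = V_I,
            V_th = V_th, V_R = V_R, tau_ref = tau_ref,
            tau_E = tau_E, tau_I = tau_I, W_E = W_E, W_I = W_I,
            sigma_E = sigma_E, D = D, dt = dt,
            jump_convention = jump_convention)
  validate_params(p)
  structure(p, class = "wp_params")
}

validate_params <- function(p) {
  num <- p[setdiff(names(p), "jump_convention")]
  if (!all(vapply(num, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                  logical(1L))))
    stop("all model parameters must be finite scalars")
  with(p, {
    if (!(V_I < V_R && V_R <= V_L && V_L < V_th && V_th < V_E))
      stop("reversal/threshold ordering violated: need V_I < V_R <= V_L < V_th < V_E")
    for (nm in c("g_L", "C", "tau_ref", "tau_E", "tau_I", "dt"))
      if (p[[nm]] <= 0) stop(sprintf("'%s' must be strictly positive", nm))
    if (W_E < 0 || W_I < 0) stop("kernel amplitudes must be non-negative")
    if (sigma_E <= 0) stop("'sigma_E' must be strictly positive")
    if (D < 1) stop("connection cutoff 'D' must be >= 1 gridpoint")
  })
  invisible(p)
}

#' @export
print.wp_params <- function(x, ...) {
  cat("<wp_params> conductance-based LIF parameters\n")
  cat(sprintf("  g_L %g nS, C %g nF (tau_m %g ms); V_L/V_E/V_I %g/%g/%g mV\n",
              x$g_L, x$C, x$C / x$g_L * 1000, x$V_L, x$V_E, x$V_I))
  cat(sprintf("  V_th %g mV, V_R %g mV, tau_ref %g ms; tau_E/I %g/%g ms\n",
              x$V_th, x$V_R, x$tau_ref, x$tau_E, x$tau_I))
  cat(sprintf("  W_E %g nS (sigma_E %g gp), W_I %g nS, cutoff D %g gp; dt %g ms; jumps %s\n",
              x$W_E, x$sigma_E, x$W_I, x$D, x$dt, x$jump_convention))
  invisible(x)
}

#' Stimulus protocol: background drive plus a gated localized Gaussian
#'
#' Every neuron receives a constant background current `I_0`. From `t_on`
#' onwards an additional localized current is applied: a spatial Gaussian of
#' amplitude `W_S` and decay `sigma_S` centred on `center`, gated by a
#' Heaviside step in time (exactly zero before `t_on`). The Gaussian is not
#' truncated at the RoI edge; `roi_radius` only defines the analysis region.
#'
#' `sigma_S` is calibrated, not published: the default of 7.5 gridpoints
#' (300 um, half the RoI radius) keeps the stimulus effectively contained in
#' the RoI.
#'
#' @param I_0 background current, nA.
#' @param W_S localized stimulus amplitude, nA (0 = spontaneous activity;
#'   the strong-stimulus condition uses 1.2).
#' @param t_on stimulus onset time, ms.
#' @param center stimulus centre, 0-based gridpoint coordinates `c(x, y)`;
#'   `NULL` means the lattice centre (filled in when a config is assembled).
#' @param sigma_S stimulus Gaussian decay, gridpoints (calibrated default).
#' @param roi_radius radius of the region of input / analysis disc, gridpoints.
#' @return an object of class `wp_protocol`.
#' @export
stimulus_protocol <- function(I_0 = 0.4, W_S = 0, t_on = 2000,
                              center = NULL, sigma_S = 7.5,
                              roi_radius = 15) {
  p <- list(I_0 = I_0, W_S = W_S, t_on = t_on, center = center,
            sigma_S = sigma_S, roi_radius = roi_radius)
  validate_protocol(p)
  structure(p, class = "wp_protocol")
}

validate_protocol <- function(p) {
  if (p$I_0 < 0) stop("background current 'I_0' must be >= 0")
  if (p$W_S < 0) stop("stimulus amplitude 'W_S' must be >= 0")
  if (p$t_on < 0) stop("stimulus onset 't_on' must be >= 0 ms")
  if (p$sigma_S <= 0) stop("'sigma_S' must be strictly positive")
  if (p$roi_radius <= 0) stop("'roi_radius' must be strictly positive")
  if (!is.null(p$center) &&
      (length(p$center) != 2L || any(p$center < 0)))
    stop("'center' must be NULL or c(x, y) with non-negative coordinates")
  invisible(p)
}

#' Assemble a full simulation configuration
#'
#' Bundles geometry, model parameters, stimulus protocol and trial timing.
#' The reference protocol integrates 3500 ms per trial and excludes the
#' first 1000 ms (burn-in) from every analysis.
#'
#' @param geometry a [lattice_geometry()].
#' @param params a [model_params()].
#' @param protocol a [stimulus_protocol()]; a `NULL` stimulus centre is
#'   replaced by the lattice centre `c(N/2, N/2)`.
#' @param duration trial duration, ms.
#' @param burn_in initial window excluded from analyses, ms.
#' @return an object of class `wp_config`.
#' @export
circuit_config <- function(geometry = lattice_geometry(),
                           params = model_params(),
                           protocol = stimulus_protocol(),
                           duration = 3500, burn_in = 1000) {
  stopifnot(inherits(geometry, "wp_geometry"), inherits(params, "wp_params"),
            inherits(protocol, "wp_protocol"))
  if (duration <= 0 || burn_in < 0 || burn_in >= duration)
    stop("need 0 <= burn_in < duration")
  if (protocol$W_S > 0 && protocol$t_on > duration)
    stop("stimulus onset 't_on' is outside the trial duration")
  if (is.null(protocol$center))
    protocol$center <- c(geometry$N %/% 2L, geometry$N %/% 2L)
  if (any(protocol$center >= geometry$N))
    stop("stimulus centre is outside the lattice")
  structure(list(geometry = geometry, params = params, protocol = protocol,
                 duration = duration, burn_in = burn_in),
            class = "wp_config")
}

#' @export
print.wp_config <- function(x, ...) {
  cat(sprintf("<wp_config> N = %d, duration %g ms (burn-in %g ms)\n",
              x$geometry$N, x$duration, x$burn_in))
  cat(sprintf("  I_0 = %g nA, W_S = %g nA at t >= %g ms, centre (%d, %d), RoI radius %g gp\n",
              x$protocol$I_0, x$protocol$W_S, x$protocol$t_on,
              x$protocol$center[1], x$protocol$center[2],
              x$protocol$roi_radius))
  invisible(x)
}

#' Stable digest of a configuration
#'
#' MD5 of the canonical YAML serialization; recorded with every trial so
#' that recordings can be matched to the configuration that produced them.
#'
#' @param config a [circuit_config()].
#' @return a hex digest string.
#' @export
config_digest <- function(config) {
  stopifnot(inherits(config, "wp_config"))
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(config_to_list(config)), f)
  unname(tools::md5sum(f))
}
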