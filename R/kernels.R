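#' Build the distance-dependent coupling kernels
#'
#' Enumerates every lattice offset `(dx, dy)` in the punctured disc
#' `0 < |dr| <= D` (self-connections excluded) and attaches the excitatory
#' and inhibitory coupling strengths:
#' `K_E(dr) = W_E * exp(-|dr|^2 / (2 sigma_E^2))` and `K_I(dr) = W_I`
#' (uniform out to the cutoff). A spiking excitatory neuron feeds the
#' excitatory conductance of every neuron within `D` through `K_E`; a
#' spiking inhibitory neuron feeds the inhibitory conductance through `K_I`.
#' With the reference cutoff `D = 30` the punctured disc holds 2820
#' offsets, i.e. every neuron receives 2820 afferent connections.
#'
#' @param params a [model_params()].
#' @return an object of class `wp_kernels`: data.frame-like list with
#'   integer offsets `dx`, `dy`, distances `dist` (gridpoints) and strengths
#'   `K_E`, `K_I` (nS).
#' @export
build_kernels <- function(params) {
  stopifnot(inherits(params, "wp_params"))
  D <- params$D
  rng <- -floor(D):floor(D)
  g <- expand.grid(dx = rng, dy = rng)
  d2 <- g$dx^2 + g$dy^2
  keep <- d2 > 0 & d2 <= D^2
  g <- g[keep, , drop = FALSE]
  d2 <- d2[keep]
  structure(list(dx = as.integer(g$dx), dy = as.integer(g$dy),
                 dist = sqrt(d2),
                 K_E = params$W_E * exp(-d2 / (2 * params$sigma_E^2)),
                 K_I = rep(params$W_I, nrow(g)),
                 D = D),
            class = "wp_kernels")
}

#' @export
print.wp_kernels <- function(x, ...) {
  cat(sprintf("<wp_kernels> %d offsets within cutoff D = %g gp\n",
              length(x$dx), x$D))
  cat(sprintf("  K_E in [%.3g, %.3g] nS (Gaussian), K_I = %.3g nS (uniform)\n",
              min(x$K_E), max(x$K_E), x$K_I[1]))
  invisible(x)
}

#' Per-spike conductance increments implied by the kernels
#'
#' Converts kernel strengths into the increment added to a target neuron's
#' conductance per afferent spike under the configured delta-pulse
#' convention: `K / tau` (tau in seconds; default) or plain `K`.
#'
#' @param kernels a [build_kernels()] result.
#' @param params the matching [model_params()].
#' @return list with numeric vectors `E` and `I`, nS per spike, aligned
#'   with `kernels$dx`/`kernels$dy`.
#' @export
kernel_jumps <- function(kernels, params) {
  if (params$jump_convention == "K_over_tau")
    list(E = kernels$K_E / (params$tau_E / 1000),
         I = kernels$K_I / (params$tau_I / 1000))
  else
    list(E = kernels$K_E, I = kernels$K_I)
}

#' External input current at a gridpoint
#'
#' `I(r, t) = I_0 + H(t - t_on) * W_S * exp(-|r - r_S|^2 / (2 sigma_S^2))`,
#' with the distance to the stimulus centre `r_S` taken with the
#' minimal-image convention. Smooth in space, a Heaviside gate in time; a
#' total function of its arguments.
#'
#' @param coord 0-based gridpoint coordinates, a length-2 vector or a
#'   2-column matrix.
#' @param t time, ms (vectorized if `coord` is a single point).
#' @param protocol a [stimulus_protocol()] with a non-`NULL` centre.
#' @param geometry a [lattice_geometry()].
#' @return current in nA.
#' @export
external_input <- function(coord, t, protocol, geometry) {
  if (any(t < 0)) stop("time must be >= 0")
  if (is.null(protocol$center))
    stop("protocol has no stimulus centre; assemble it via circuit_config()")
  d <- lattice_distance(coord, matrix(protocol$center,
                                      nrow(matrix(coord, ncol = 2)), 2,
                                      byrow = TRUE), geometry)
  gate <- as.numeric(t >= protocol$t_on)
  protocol$I_0 + gate * protocol$W_S * exp(-d^2 / (2 * protocol$sigma_S^2))
}

#' Localized stimulus field over the whole lattice (without the gate)
#'
#' @return numeric vector of length `N^2`, nA, indexed `x + N*y`.
#' @keywords internal
stimulus_field <- function(protocol, geometry) {
  N <- geometry$N
  g <- expand.grid(x = 0:(N - 1L), y = 0:(N - 1L))
  d <- lattice_distance(cbind(g$x, g$y),
                        matrix(protocol$center, nrow(g), 2, byrow = TRUE),
                        geometry)
  protocol$W_S * exp(-d^2 / (2 * protocol$sigma_S^2))
}
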