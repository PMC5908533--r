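#' Lattice geometry of the circuit
#'
#' The network lives on an `N x N` square lattice with periodic boundary
#' conditions; neighbouring gridpoints are `spacing` micrometres apart.
#' Coordinates are 0-based, `x, y` in `0..N-1`, and a neuron is addressed by
#' the linear index `x + N*y`. `N` must be even so that the inhibitory
#' sublattice (both coordinates odd) is exactly a quarter of the neurons.
#'
#' @param N side length in neurons (even; the reference network uses 300).
#' @param spacing physical distance between neighbouring gridpoints, um.
#' @param periodic must be `TRUE`; kept as an explicit field because every
#'   distance in the package uses the minimal-image convention.
#' @return an object of class `wp_geometry`.
#' @export
lattice_geometry <- function(N = 300L, spacing = 40, periodic = TRUE) {
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 4L) stop("N must be an integer >= 4")
  if (N %% 2L != 0L) stop("N must be even (inhibitory sublattice = 25% of neurons)")
  if (!isTRUE(periodic)) stop("only periodic boundaries are supported")
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be positive")
  structure(list(N = N, spacing = spacing, periodic = TRUE),
            class = "wp_geometry")
}

#' @export
print.wp_geometry <- function(x, ...) {
  cat(sprintf("<wp_geometry> %d x %d lattice, %g um spacing, periodic\n",
              x$N, x$N, x$spacing))
  invisible(x)
}

#' Minimal-image displacement and distance on the periodic lattice
#'
#' @param d integer displacement(s) along one axis.
#' @param N lattice side length.
#' @return signed displacement folded into `(-N/2, N/2]`.
#' @keywords internal
wrap_delta <- function(d, N) {
  d <- d %% N
  ifelse(d > N / 2, d - N, d)
}

#' Minimal-image Euclidean distance between lattice points, in gridpoints
#'
#' @param a,b 2-column matrices (or length-2 vectors) of 0-based coordinates.
#' @param geometry a [lattice_geometry()].
#' @export
lattice_distance <- function(a, b, geometry) {
  a <- matrix(as.numeric(a), ncol = 2)
  b <- matrix(as.numeric(b), ncol = 2)
  dx <- wrap_delta(a[, 1] - b[, 1], geometry$N)
  dy <- wrap_delta(a[, 2] - b[, 2], geometry$N)
  sqrt(dx^2 + dy^2)
}

#' Neuron class at a gridpoint
#'
#' Inhibitory neurons sit at gridpoints where both coordinates are odd
#' (one quarter of the lattice); all other gridpoints hold excitatory
#' neurons. Vectorized over coordinates.
#'
#' @param x,y 0-based integer coordinates.
#' @param geometry a [lattice_geometry()]; used for range checking.
#' @return character vector, `"excitatory"` or `"inhibitory"`.
#' @export
neuron_class <- function(x, y, geometry) {
  x <- as.integer(x); y <- as.integer(y)
  if (any(is.na(x) | is.na(y) | x < 0L | y < 0L |
          x >= geometry$N | y >= geometry$N))
    stop("coordinate out of lattice range")
  ifelse(x %% 2L == 1L & y %% 2L == 1L, "inhibitory", "excitatory")
}

#' Neurons within the region of input (RoI)
#'
#' The RoI is the disc of radius `protocol$roi_radius` gridpoints around the
#' stimulus centre, measured with the minimal-image convention. It receives
#' the localized stimulus and is also the default analysis region for
#' single-neuron statistics.
#'
#' @param geometry a [lattice_geometry()].
#' @param protocol a [stimulus_protocol()].
#' @param classes which neuron classes to keep.
#' @return data.frame with columns `x`, `y`, `index` (0-based linear index)
#'   and `class`.
#' @export
roi_neurons <- function(geometry, protocol,
                        classes = c("both", "excitatory", "inhibitory")) {
  classes <- match.arg(classes)
  N <- geometry$N
  ctr <- protocol$center
  g <- expand.grid(x = 0:(N - 1L), y = 0:(N - 1L))
  d <- lattice_distance(cbind(g$x, g$y),
                        matrix(ctr, nrow(g), 2, byrow = TRUE), geometry)
  keep <- d <= protocol$roi_radius
  out <- g[keep, , drop = FALSE]
  out$index <- out$x + N * out$y
  out$class <- neuron_class(out$x, out$y, geometry)
  if (classes != "both") out <- out[out$class == classes, , drop = FALSE]
  rownames(out) <- NULL
  out
}
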