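---
title: "Methods: a balanced spiking circuit with waves and patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a balanced spiking circuit with waves and patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`wavepatch` simulates a two-dimensional cortical circuit of `N x N`
conductance-based leaky integrate-and-fire neurons on an evenly spaced
lattice (40 um per gridpoint) with periodic boundaries. The membrane
potential of the neuron at gridpoint `r` obeys

    C dV_r/dt = -g_L (V_r - V_L) - g^E_r (V_r - V_E) - g^I_r (V_r - V_I) + I_ext(r, t)

with leak conductance `g_L = 25` nS, capacitance `C = 0.5` nF (membrane
time constant 20 ms), and reversal potentials `V_L = -70`, `V_E = 0`,
`V_I = -80` mV. Crossing the threshold `V_th = -55` mV emits a spike,
resets the neuron to `V_R = -70` mV, and clamps it there for a 5 ms
refractory period. Three quarters of the neurons are excitatory; the
inhibitory quarter sits at gridpoints where both coordinates are odd.

Synaptic conductances decay exponentially (`tau_E = tau_I = 2` ms) and
jump when an afferent neuron spikes. Coupling is distance dependent with a
shared cutoff of `D = 30` gridpoints (1200 um), giving every neuron
exactly 2820 afferents: excitatory sources contribute through a Gaussian
kernel `K_E(d) = W_E exp(-d^2 / 2 sigma_E^2)` with `W_E = 7.5e-3` nS,
inhibitory sources through a uniform kernel `K_I = W_I = 5.0e-3` nS. All
distances use the minimal-image convention.

External input is a constant background current `I_0 = 0.4` nA plus, from
`t_on = 2` s, a localized Gaussian stimulus of amplitude `W_S` (up to
1.2 nA) and width `sigma_S` centred on the region of input (RoI, radius 15
gridpoints). The stimulus Gaussian is not truncated at the RoI edge; the
RoI is an analysis region only.

In this regime a weak or absent stimulus yields propagating wave patterns;
a strong stimulus pins a localized activity patch to the RoI. These
population patterns in turn shape single-neuron statistics: transient
synchronized inputs (heavy-tailed conductance distributions, positively
skewed membrane potentials) during spontaneous activity versus sustained,
near-Gaussian input when a patch covers the neuron.

## Delta-pulse normalization of the synaptic jumps

The conductance equation's spike term is a Dirac-delta sum whose
normalization must be fixed by the implementation. With jumps of literally
`K` nanosiemens (`K ~ 5e-3` nS) the steady-state synaptic conductances at
realistic rates are of order `1e-2` nS against a 25 nS leak: the network
is effectively uncoupled, cannot form any spatial pattern, and every
neuron fires at the isolated-LIF rate of ~16.5 Hz. `wavepatch` therefore
defaults to the conductance-time-integral convention, `jump = K / tau`
with `tau` in seconds (each spike contributes a time-integrated
conductance of `K` nS s). Mean conductances are then of order 10 nS
(inhibitory) and several nS (excitatory); the excitatory and inhibitory
synaptic currents balance near ratio one and the circuit fires irregularly
at ~9 Hz, the regime the model is built around. The literal convention
remains selectable (`model_params(jump_convention = "K")`), a one-line
change.

## Calibrated parameters

Two spatial scales have no usable published value and are exposed as
calibrated package defaults:

* `sigma_E = 4` gridpoints (160 um). Calibrated once so that the excitatory
  kernel decays well inside the 1200 um cutoff and the unstimulated network
  exhibits coexisting waves and patches at a spontaneous RoI rate near
  9 Hz. At `sigma_E = 5` the network runs over-excited (~25 Hz, fast waves
  only); at 3.5 the rate falls to ~7 Hz with mostly patches.
* `sigma_S = 7.5` gridpoints (300 um), half the RoI radius, so the
  stimulus is effectively contained in the RoI.

Both are ordinary `model_params()`/`stimulus_protocol()` arguments;
configuration files must state `sigma_E` explicitly so the calibration is
a visible choice, never a silent one.

## Integration and bookkeeping

The Euler step (`dt = 0.05` ms) applies, in a fixed order: (1) conductance
increments from spikes of the previous step, scattered through the kernels
(numerically identical to the pairwise afferent sum, which a test asserts
exactly); (2) conductance decay `g <- g (1 - dt/tau)`; (3) membrane update
for non-refractory neurons — refractory neurons are clamped at `V_R` and
ignore synaptic input while their conductances keep evolving; (4)
threshold, reset, refractory countdown. The order is documented because it
affects bit-level results. There is no synaptic or conduction delay: a
spike takes effect on the next step. Initial potentials are i.i.d. uniform
on `[V_R, V_th)`; conductances start at zero.

`reconstruct_conductance()` replays these rules offline for one target
neuron from the recorded spike table, with the same summation order, so
the reconstruction equals the recorded trace to machine precision — also
when the lattice is small enough (`N <= 2D`) that one source reaches a
target through several wrapped offsets. This identity is asserted
bitwise in the test suite.

Trials are deterministic given `(config, seed)`: the only randomness is
the R-side initial condition. Sweeps derive per-trial seeds as
`seed_base + trial index` and record them in a manifest.

## Analysis choices

**Epochs.** Burn-in is 1 s and is excluded everywhere. Spontaneous
single-neuron statistics use the pre-onset window [1, 2] s (of stimulated
trials — before the Heaviside gate the dynamics are exactly stimulus-free);
evoked statistics start 250 ms after onset to skip the transient. Sliding
windows advance in 50 ms steps, and windows straddling the onset belong to
neither epoch. Statistics follow the pipeline: per-trial statistic, median
across trials per neuron, mean across RoI neurons. Skewness is the
bias-uncorrected third standardized moment (`adjust = TRUE` selects the
small-sample correction).

**Pattern detection and tracking.** Spikes are binned into 1 ms frames,
smoothed with a periodic Gaussian (sigma 2 gridpoints), thresholded at the
frame mean plus two standard deviations, and segmented into periodic-aware
8-connected components; components under 10 cells are discarded. These
thresholds are fixed package defaults validated on synthetic fixtures, all
configurable. Tracks link nearest centroids (max jump 10 gridpoints per
elapsed frame, termination after 3 unmatched frames) and unwrap
coordinates by accumulating minimal-image displacements. A track whose net
unwrapped displacement exceeds the RoI radius is a wave, otherwise a patch.

**Speed estimation.** Centroids of sparse 1 ms spike frames carry
estimation noise of a few tenths of a gridpoint. Adding that noise in
quadrature to a true displacement of 0.25–2 gridpoints per frame biases a
single-frame speed estimate upward by tens of percent, so `wavepatch`
estimates speed from centroid displacements over a 10-frame lag, for which
the residual bias is ~`sigma^2 / (v L^2)` — under 2% across 10–80 mm/s on
fixture blobs. The lag is a parameter (`speed_lag`).

**LFP proxy.** The temporal component at each site is the summed magnitude
of the synaptic currents, `|g_E (V - V_E)| + |g_I (V - V_I)|`
(configurable to the signed sum); the spatial component is a normalized
periodic Gaussian of width 2.5 gridpoints (100 um). Because the inhibitory
kernel is uniform out to 1200 um, every active pattern carries a flat
inhibitory-current pedestal of that radius; the spontaneous spike-triggered
LFP therefore only begins to decay beyond ~1.4 mm, and electrode arrays
must extend well past the pedestal for the exponential fit
`M exp(-d/lambda) + B` to be identifiable. The fit uses multi-start
Levenberg–Marquardt with `lambda` bounded positive and is exact on
noiseless synthetic curves; a flat curve is rejected as unidentifiable
rather than fitted.

**Fano factors.** Raw FF is variance over mean of per-neuron spike counts
across trials; windows with zero mean are flagged `NaN`, not zero.
Mean-matching computes the greatest common (floor) histogram of per-neuron
mean counts across windows (bin width 0.5 spikes) and randomly discards
neurons per window to match it, averaging over 50 seeded resamples.

## What the scaled-down runs do and do not show

The reference protocol (N = 300, 500 trials of 3.5 s) is far beyond a test
suite or a desk run. The package's tests and the acceptance script run
N = 150 (analyses on the radius-15 RoI), 3–5 trials for membrane and
conductance statistics, and N = 90–150 with up to 14 trials for the
variability analyses; the methods are identical, only problem sizes
shrink. At this scale the circuit reproduces the spontaneous rate
(8–11 Hz across seed sets), pattern speed (~47 mm/s), distance to
threshold (~11 mV spontaneous), and the skewness contrasts between
spontaneous and evoked epochs. Two quantities are known not to transfer to desk scale under the
calibrated `sigma_E`:

* the evoked distance to threshold measures ~9.9 mV against the reference
  7.6 mV, because the scaled network's evoked RoI rate (~75 Hz) keeps
  neurons at the reset potential ~37% of the time;
* the spontaneous Fano factor is sub-Poisson (~0.6) rather than well above
  one: the scaled network's patterns are dense and fast-moving, so
  neurons lack the slow switching between high- and low-rate states that
  drives doubly stochastic counts, and mean-matching across the onset
  keeps almost no neurons (the spontaneous and evoked mean-count
  distributions barely overlap). The onset *drop* in variability is
  nevertheless reproduced by the unmatched FF.

The synthetic fixtures (`generate_fixture()`) emulate single features with
exact ground truth — a moving or stationary Gaussian rate blob, a
homogeneous Poisson field, a two-state telegraph rate — and validate the
analysis estimators in isolation. They do not emulate full network
statistics (crescent-shaped fronts, refractory wakes, E/I balance), so
passing fixture tests certifies the estimators, not the circuit.

## Known limitations

* Inhibitory coupling is uniform within the cutoff; a distance-decaying
  inhibitory kernel is only available through the configurable kernel
  amplitudes, not as a separate shape family.
* The LFP proxy is a current-magnitude heuristic, not a biophysical
  forward model; absolute amplitudes are arbitrary units.
* Tracking has no merge/split handling; two patterns passing within the
  linking radius can exchange identities.
* Probe traces are sampled at 1 ms; sub-millisecond membrane transients
  are only visible in the Euler-step-resolution reconstructions.
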