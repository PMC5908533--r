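// Compiled core of the lattice circuit: Euler integration with spike
// scatter over precomputed coupling offsets, periodic Gaussian smoothing,
// periodic-aware connected components, and the offline conductance
// reconstruction stepper.
//
// Conventions shared with the R layer (do not change one side only):
//  - neurons indexed i = x + N*y, 0-based coordinates x,y in 0..N-1;
//  - a neuron that crosses threshold during step k is recorded at time
//    (k+1)*dt and its kernel-weighted conductance increments land at the
//    start of step k+1 (before decay);
//  - per step: (1) scatter pending spikes into g, (2) g *= (1 - dt/tau),
//    (3) Euler V update (refractory neurons clamped at V_R), (4) threshold,
//    reset, start refractory countdown;
//  - refractory neurons ignore synaptic input (V clamped) but their
//    conductances keep evolving.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int wrap(int a, int N) {
  a %= N;
  if (a < 0) a += N;
  return a;
}

// Scatter kernel-weighted increments from a set of source spikes into a
// field of size N*N. Offsets are applied with periodic wraparound. Exported
// so tests can compare against a brute-force pairwise sum.
// [[Rcpp::export]]
NumericVector cpp_spike_increments(IntegerVector spike_idx, int N,
                                   IntegerVector dx, IntegerVector dy,
                                   NumericVector jump) {
  const int M = N * N, K = dx.size();
  NumericVector out(M);
  for (int s = 0; s < spike_idx.size(); ++s) {
    int i = spike_idx[s];
    int x = i % N, y = i / N;
    for (int o = 0; o < K; ++o) {
      int tx = wrap(x + dx[o], N), ty = wrap(y + dy[o], N);
      out[tx + N * ty] += jump[o];
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_run_steps(NumericVector V, NumericVector gE, NumericVector gI,
                   IntegerVector refrac, IntegerVector pending,
                   int N, int n_steps, double t0, double dt,
                   List pars, NumericVector stim_field, double t_on,
                   IntegerVector kdx, IntegerVector kdy,
                   NumericVector jumpE, NumericVector jumpI,
                   IntegerVector probe_idx, int sample_every,
                   int movie_stride, bool movie_conductances) {
  const int M = N * N;
  if (V.size() != M || gE.size() != M || gI.size() != M)
    stop("state size does not match lattice");
  const double gL  = pars["g_L"],  C   = pars["C"];
  const double VL  = pars["V_L"],  VE  = pars["V_E"], VI = pars["V_I"];
  const double Vth = pars["V_th"], VR  = pars["V_R"];
  const double tauE = pars["tau_E"], tauI = pars["tau_I"];
  const double I0  = pars["I_0"];
  const int ref_steps = (int) std::lround((double) pars["tau_ref"] / dt);
  const double decE = 1.0 - dt / tauE, decI = 1.0 - dt / tauI;
  const double dt_over_C = dt / C;
  const int K = kdx.size();

  // class of each neuron: inhibitory iff both coordinates odd
  std::vector<unsigned char> inh(M);
  for (int y = 0; y < N; ++y)
    for (int x = 0; x < N; ++x)
      inh[x + N * y] = (x % 2 == 1 && y % 2 == 1);

  std::vector<int> pend(pending.begin(), pending.end()), next;
  next.reserve(256);

  std::vector<double> sp_t; std::vector<int> sp_x, sp_y;
  sp_t.reserve(4096);

  const int nP = probe_idx.size();
  int n_samples = (sample_every > 0) ? n_steps / sample_every : 0;
  NumericMatrix prV(nP, nP ? n_samples : 0), prE(nP, nP ? n_samples : 0),
                prI(nP, nP ? n_samples : 0);
  NumericVector pr_times(nP ? n_samples : 0);

  int n_frames = (movie_stride > 0) ? n_steps / movie_stride : 0;
  NumericMatrix mvV(n_frames ? M : 0, n_frames),
                mvE(movie_conductances && n_frames ? M : 0,
                    movie_conductances ? n_frames : 0),
                mvI(movie_conductances && n_frames ? M : 0,
                    movie_conductances ? n_frames : 0);
  NumericVector mv_times(n_frames);

  int si = 0, fi = 0;
  for (int step = 0; step < n_steps; ++step) {
    const double t = t0 + step * dt;       // time at start of step
    // (1) synaptic increments from spikes of the previous step
    for (size_t s = 0; s < pend.size(); ++s) {
      const int i = pend[s];
      const int x = i % N, y = i / N;
      if (inh[i]) {
        for (int o = 0; o < K; ++o) {
          int tx = wrap(x + kdx[o], N), ty = wrap(y + kdy[o], N);
          gI[tx + N * ty] += jumpI[o];
        }
      } else {
        for (int o = 0; o < K; ++o) {
          int tx = wrap(x + kdx[o], N), ty = wrap(y + kdy[o], N);
          gE[tx + N * ty] += jumpE[o];
        }
      }
    }
    // (2) conductance decay
    for (int i = 0; i < M; ++i) { gE[i] *= decE; gI[i] *= decI; }
    // (3) membrane update
    const bool on = (t >= t_on);
    for (int i = 0; i < M; ++i) {
      if (refrac[i] > 0) { --refrac[i]; V[i] = VR; continue; }
      const double Iext = on ? I0 + stim_field[i] : I0;
      // conductance terms are nS*mV = pA; currents are nA, hence the 1e-3
      V[i] += dt_over_C * (1e-3 * (-gL * (V[i] - VL) - gE[i] * (V[i] - VE)
                                   - gI[i] * (V[i] - VI)) + Iext);
    }
    // (4) threshold crossing
    next.clear();
    const double t_spike = t0 + (step + 1) * dt;
    for (int i = 0; i < M; ++i) {
      if (refrac[i] == 0 && V[i] >= Vth) {
        sp_t.push_back(t_spike);
        sp_x.push_back(i % N);
        sp_y.push_back(i / N);
        V[i] = VR;
        refrac[i] = ref_steps;
        next.push_back(i);
      }
    }
    pend.swap(next);

    if (nP && sample_every > 0 && (step + 1) % sample_every == 0) {
      for (int p = 0; p < nP; ++p) {
        const int i = probe_idx[p];
        prV(p, si) = V[i]; prE(p, si) = gE[i]; prI(p, si) = gI[i];
      }
      pr_times[si++] = t_spike;
    }
    if (n_frames && (step + 1) % movie_stride == 0) {
      for (int i = 0; i < M; ++i) mvV(i, fi) = V[i];
      if (movie_conductances)
        for (int i = 0; i < M; ++i) { mvE(i, fi) = gE[i]; mvI(i, fi) = gI[i]; }
      mv_times[fi++] = t_spike;
    }
    if ((step & 1023) == 0) {
      for (int i = 0; i < M; i += 97)
        if (!std::isfinite(V[i]))
          stop("non-finite membrane potential at step %d", step);
    }
  }
  for (int i = 0; i < M; ++i)
    if (!std::isfinite(V[i]) || !std::isfinite(gE[i]) || !std::isfinite(gI[i]))
      stop("non-finite state at end of integration");

  return List::create(
    _["V"] = V, _["gE"] = gE, _["gI"] = gI, _["refrac"] = refrac,
    _["pending"] = IntegerVector(pend.begin(), pend.end()),
    _["t"] = t0 + (double) n_steps * dt,
    _["spike_t"] = NumericVector(sp_t.begin(), sp_t.end()),
    _["spike_x"] = IntegerVector(sp_x.begin(), sp_x.end()),
    _["spike_y"] = IntegerVector(sp_y.begin(), sp_y.end()),
    _["probe_times"] = pr_times, _["probe_V"] = prV,
    _["probe_gE"] = prE, _["probe_gI"] = prI,
    _["movie_times"] = mv_times, _["movie_V"] = mvV,
    _["movie_gE"] = mvE, _["movie_gI"] = mvI);
}

// Offline replay of the conductance dynamics for a single target neuron:
// identical Euler scheme and summation order as cpp_run_steps, so the
// result matches the recorded trace to machine precision. jump_step[k] is
// the step at whose start jump_val[k] is added (spikes sorted by step,
// ties in recording order).
// [[Rcpp::export]]
NumericVector cpp_reconstruct(IntegerVector jump_step, NumericVector jump_val,
                              int n_steps, double decay, double g0) {
  NumericVector out(n_steps + 1);
  double g = g0;
  out[0] = g;
  int k = 0;
  const int nj = jump_step.size();
  for (int step = 0; step < n_steps; ++step) {
    while (k < nj && jump_step[k] == step) g += jump_val[k++];
    g *= decay;
    out[step + 1] = g;
  }
  return out;
}

// Separable periodic Gaussian smoothing of an N x N field; kernel truncated
// at ceil(3*sigma) and normalized to unit sum.
// [[Rcpp::export]]
NumericMatrix cpp_blur_periodic(NumericMatrix m, double sigma) {
  const int N = m.nrow();
  if (m.ncol() != N) stop("field must be square");
  if (sigma <= 0) return clone(m);
  const int r = (int) std::ceil(3.0 * sigma);
  std::vector<double> w(2 * r + 1);
  double s = 0;
  for (int k = -r; k <= r; ++k) { w[k + r] = std::exp(-0.5 * k * k / (sigma * sigma)); s += w[k + r]; }
  for (int k = 0; k <= 2 * r; ++k) w[k] /= s;
  NumericMatrix tmp(N, N), out(N, N);
  for (int j = 0; j < N; ++j)        // along rows (first index)
    for (int i = 0; i < N; ++i) {
      double a = 0;
      for (int k = -r; k <= r; ++k) a += w[k + r] * m(wrap(i + k, N), j);
      tmp(i, j) = a;
    }
  for (int j = 0; j < N; ++j)        // along columns
    for (int i = 0; i < N; ++i) {
      double a = 0;
      for (int k = -r; k <= r; ++k) a += w[k + r] * tmp(i, wrap(j + k, N));
      out(i, j) = a;
    }
  return out;
}

// Periodic-aware 8-connected components of mask (non-zero entries).
// Returns integer labels (0 = background), labelling order row-major.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  const int N = mask.nrow();
  if (mask.ncol() != N) stop("mask must be square");
  IntegerMatrix lab(N, N);
  int next = 0;
  std::vector<std::pair<int,int> > stack;
  for (int j0 = 0; j0 < N; ++j0)
    for (int i0 = 0; i0 < N; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0)) continue;
      ++next;
      stack.push_back(std::make_pair(i0, j0));
      lab(i0, j0) = next;
      while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        for (int di = -1; di <= 1; ++di)
          for (int dj = -1; dj <= 1; ++dj) {
            if (!di && !dj) continue;
            int ii = wrap(i + di, N), jj = wrap(j + dj, N);
            if (mask(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              stack.push_back(std::make_pair(ii, jj));
            }
          }
      }
    }
  return lab;
}
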