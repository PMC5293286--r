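#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <utility>
using namespace Rcpp;

// Core integrator for the predictive-coding LIF network.
//
// Membrane update is forward Euler:
//   V_i += dt * (-lambda * V_i + sum_j w_ij s_j(t) + bias_i)
//          + sigma * sqrt(dt) * z          (Euler-Maruyama, z ~ N(0,1))
// A spike of neuron k subtracts the k-th column of phi = w w^T from the
// population, plus an extra mu from neuron k itself (spike-triggered
// adaptation). In delayed mode the lateral part of that subtraction is
// applied `delay_steps` later while the neuron's own reset (autapse + mu)
// is immediate unless self_delay is set; in instantaneous mode spikes are
// resolved one at a time within the step, largest threshold violation
// first, with the full column applied immediately.
//
// All randomness is drawn from R's RNG (norm_rand / unif_rand) so that
// set.seed() on the R side makes runs reproducible. Membrane-noise draws
// are consumed for every neuron at every step (when sigma > 0) in a fixed
// order, so two runs with the same seed but different cost parameters see
// an identical frozen noise realization (provided p_spike = 1, since
// spike-failure draws are only consumed at candidate spikes).

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(const NumericMatrix& w,
              const NumericMatrix& phi,
              const NumericVector& thres,
              const NumericMatrix& s,
              double dt, double lambda, double mu, double sigma,
              double p_spike, int delay_steps, bool instantaneous,
              bool self_delay,
              const NumericVector& v0,
              const NumericVector& bias,
              const IntegerVector& forced_step,
              const IntegerVector& forced_neuron,
              bool record_v)
{
  const int N = w.nrow(), J = w.ncol(), T = s.ncol();
  if (phi.nrow() != N || phi.ncol() != N)
    stop("phi must be N x N");
  if (s.nrow() != J)
    stop("input dimensionality does not match the network's signal count");

  std::vector<double> V(v0.begin(), v0.end());
  const double sqdt = std::sqrt(dt);
  const int nslot = delay_steps + 1;
  std::vector<double> pend(static_cast<size_t>(nslot) * N, 0.0);
  std::vector<int> sp_step, sp_id;
  NumericMatrix Vrec = record_v ? NumericMatrix(N, T) : NumericMatrix(0, 0);

  std::vector<std::pair<int, int> > forced;
  for (int k = 0; k < forced_step.size(); ++k)
    forced.push_back(std::make_pair(forced_step[k] - 1, forced_neuron[k] - 1));
  std::sort(forced.begin(), forced.end());
  size_t fptr = 0;

  std::vector<unsigned char> eligible(N);

  for (int t = 0; t < T; ++t) {
    // leak + feed-forward + bias, then membrane noise
    for (int i = 0; i < N; ++i) {
      double ff = 0.0;
      for (int j = 0; j < J; ++j) ff += w(i, j) * s(j, t);
      V[i] += dt * (-lambda * V[i] + ff + bias[i]);
    }
    if (sigma > 0.0)
      for (int i = 0; i < N; ++i) V[i] += sigma * sqdt * norm_rand();

    // delayed recurrent currents scheduled for this step
    {
      double* p = &pend[static_cast<size_t>(t % nslot) * N];
      for (int i = 0; i < N; ++i) { V[i] -= p[i]; p[i] = 0.0; }
    }

    // externally forced spikes (bypass threshold and spike failure)
    while (fptr < forced.size() && forced[fptr].first == t) {
      const int i = forced[fptr].second;
      sp_step.push_back(t + 1);
      sp_id.push_back(i + 1);
      if (instantaneous) {
        for (int k = 0; k < N; ++k) V[k] -= phi(k, i);
        V[i] -= mu;
      } else {
        double* q = &pend[static_cast<size_t>((t + delay_steps) % nslot) * N];
        if (self_delay) {
          for (int k = 0; k < N; ++k) q[k] += phi(k, i);
          q[i] += mu;
        } else {
          for (int k = 0; k < N; ++k) if (k != i) q[k] += phi(k, i);
          V[i] -= phi(i, i) + mu;
        }
      }
      ++fptr;
    }

    if (instantaneous) {
      // resolve within-step spikes sequentially, greedy order
      std::fill(eligible.begin(), eligible.end(), static_cast<unsigned char>(1));
      long guard = 10L * N + 1000L;
      for (;;) {
        int best = -1; double bestv = 0.0; int nties = 0;
        for (int i = 0; i < N; ++i) {
          if (!eligible[i]) continue;
          const double v = V[i] - thres[i];
          if (v <= 0.0) continue;
          if (best < 0 || v > bestv + 1e-12) {
            best = i; bestv = v; nties = 1;
          } else if (v >= bestv - 1e-12) {
            // tie: reservoir-sample uniformly among tied neurons
            ++nties;
            if (unif_rand() < 1.0 / nties) best = i;
          }
        }
        if (best < 0) break;
        if (p_spike < 1.0 && unif_rand() >= p_spike) {
          eligible[best] = 0;  // failed this step; V stays near threshold
          continue;
        }
        sp_step.push_back(t + 1);
        sp_id.push_back(best + 1);
        for (int k = 0; k < N; ++k) V[k] -= phi(k, best);
        V[best] -= mu;
        if (phi(best, best) + mu <= 0.0) eligible[best] = 0;
        if (--guard <= 0)
          stop("instantaneous spike resolution exceeded the per-step budget");
      }
    } else {
      // delayed mode: every suprathreshold neuron may fire within the step
      for (int i = 0; i < N; ++i) {
        if (V[i] <= thres[i]) continue;
        if (p_spike < 1.0 && unif_rand() >= p_spike) continue;
        sp_step.push_back(t + 1);
        sp_id.push_back(i + 1);
        double* q = &pend[static_cast<size_t>((t + delay_steps) % nslot) * N];
        if (self_delay) {
          for (int k = 0; k < N; ++k) q[k] += phi(k, i);
          q[i] += mu;
        } else {
          for (int k = 0; k < N; ++k) if (k != i) q[k] += phi(k, i);
          V[i] -= phi(i, i) + mu;
        }
      }
    }

    if (record_v)
      for (int i = 0; i < N; ++i) Vrec(i, t) = V[i];
  }

  return List::create(_["step"]   = IntegerVector(sp_step.begin(), sp_step.end()),
                      _["neuron"] = IntegerVector(sp_id.begin(), sp_id.end()),
                      _["V"]      = Vrec);
}
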