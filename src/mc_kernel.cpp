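#include <Rcpp.h>
using namespace Rcpp;

// Metropolis sampler for one (pH, potential) grid point of a coupled
// protonation/reduction site system.
//
// The caller pre-reduces the system to its unclamped sites: `g` holds each
// free site's one-body energy at this grid point (clamped neighbours folded
// in), `W` the pairwise interaction among free sites (symmetric, zero
// diagonal, kcal/mol, paid when both occupied). Moves are single-site flips
// plus optional two-site flips for strongly coupled pairs; all use R's RNG,
// so the caller controls seeding with set.seed().
//
// Returns production-phase occupancy means, batch-mean standard errors,
// thinned second moments (for correlations), optionally per-microstate
// counts (n <= 20), and optionally a thinned trajectory.

// [[Rcpp::export(name = ".mc_sample_point")]]
List mc_sample_point(NumericVector g, NumericMatrix W, double rt,
                     IntegerVector init_state, int n_steps, int n_equil,
                     IntegerMatrix pair_moves, int n_batches, int thin,
                     bool track_states, bool keep_trajectory) {
  const int n = g.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = init_state[i];

  const int n_pairs = pair_moves.nrow();
  const int n_moves = n + n_pairs;

  std::vector<double> batch_sum(n_batches * n, 0.0);
  std::vector<double> mom(n * n, 0.0);
  long mom_count = 0;
  const long batch_len = n_steps / n_batches;

  std::vector<double> state_counts;
  if (track_states) state_counts.assign(1L << n, 0.0);

  int traj_rows = keep_trajectory ? (n_steps / thin + 1) : 0;
  IntegerMatrix traj(traj_rows, keep_trajectory ? n : 0);
  int traj_i = 0;

  auto delta_single = [&](int k) {
    double d = g[k];
    for (int j = 0; j < n; ++j)
      if (j != k && s[j]) d += W(k, j);
    return (1 - 2 * s[k]) * d;
  };

  const long total = (long)n_equil + (long)n_steps;
  for (long step = 0; step < total; ++step) {
    int mv = (int)(unif_rand() * n_moves);
    if (mv >= n_moves) mv = n_moves - 1;
    if (mv < n) {
      double d = delta_single(mv);
      if (d <= 0.0 || unif_rand() < std::exp(-d / rt)) s[mv] = 1 - s[mv];
    } else {
      int k = pair_moves(mv - n, 0), l = pair_moves(mv - n, 1);
      double d = delta_single(k);
      s[k] = 1 - s[k];
      double d2 = delta_single(l);
      double dt = d + d2;
      if (dt <= 0.0 || unif_rand() < std::exp(-dt / rt)) {
        s[l] = 1 - s[l];
      } else {
        s[k] = 1 - s[k]; // reject: undo first half
      }
    }
    if (step < n_equil) continue;
    long p = step - n_equil;
    long b = p / batch_len;
    if (b >= n_batches) b = n_batches - 1;
    for (int i = 0; i < n; ++i)
      if (s[i]) batch_sum[b * n + i] += 1.0;
    if (track_states) {
      int idx = 0;
      for (int i = 0; i < n; ++i) idx |= (s[i] << i);
      state_counts[idx] += 1.0;
    }
    if (p % thin == 0) {
      ++mom_count;
      for (int i = 0; i < n; ++i) {
        if (!s[i]) continue;
        for (int j = i; j < n; ++j)
          if (s[j]) mom[i * n + j] += 1.0;
      }
      if (keep_trajectory && traj_i < traj_rows) {
        for (int i = 0; i < n; ++i) traj(traj_i, i) = s[i];
        ++traj_i;
      }
    }
  }

  NumericVector theta(n), se(n);
  NumericMatrix batch_means(n_batches, n);
  for (int b = 0; b < n_batches; ++b) {
    long len = (b == n_batches - 1) ? (n_steps - batch_len * (n_batches - 1))
                                    : batch_len;
    for (int i = 0; i < n; ++i)
      batch_means(b, i) = batch_sum[b * n + i] / (double)len;
  }
  for (int i = 0; i < n; ++i) {
    double m = 0.0;
    for (int b = 0; b < n_batches; ++b) m += batch_means(b, i);
    m /= n_batches;
    double v = 0.0;
    for (int b = 0; b < n_batches; ++b) {
      double d = batch_means(b, i) - m;
      v += d * d;
    }
    theta[i] = m;
    se[i] = n_batches > 1 ? std::sqrt(v / (n_batches - 1) / n_batches) : 0.0;
  }

  NumericMatrix moments(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double v = mom[i * n + j] / (double)mom_count;
      moments(i, j) = v;
      moments(j, i) = v;
    }

  IntegerVector final_state(n);
  for (int i = 0; i < n; ++i) final_state[i] = s[i];

  List out = List::create(
      _["theta"] = theta, _["se"] = se, _["moments"] = moments,
      _["n_moment_samples"] = (double)mom_count,
      _["final_state"] = final_state);
  if (track_states) out["state_counts"] = NumericVector(state_counts.begin(),
                                                        state_counts.end());
  if (keep_trajectory) out["trajectory"] = traj(Range(0, traj_i - 1), _);
  return out;
}
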