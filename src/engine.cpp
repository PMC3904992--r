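#include <Rcpp.h>
using namespace Rcpp;

// Strategies are coded 1 = honest (H), 0 = dishonest (D).
// Graphs arrive in CSR form: adj holds 0-based neighbor indices, ptr has
// length n+1 with neighbours of i in adj[ptr[i] .. ptr[i+1]-1].
// All randomness goes through R's RNG (unif_rand) so set.seed() on the R
// side makes every routine reproducible.

// Single pairwise Social Honesty interaction. One realization per
// unordered pair: both participants see the same draw.
// H-H: both receive R. H-D: honest gets 0; dishonest is punished (-s)
// with probability p_hd, otherwise collects b. D-D: a fair coin picks the
// winner (b vs 0), then each player is independently punished with
// probability p_dd, punishment overriding the coin outcome.
static inline void pair_payoff(int si, int sj,
                               double R, double b, double s,
                               double p_hd, double p_dd,
                               double &pi, double &pj) {
  if (si == 1 && sj == 1) { pi = R; pj = R; return; }
  if (si == 1 && sj == 0) {
    pi = 0.0;
    pj = (unif_rand() < p_hd) ? -s : b;
    return;
  }
  if (si == 0 && sj == 1) {
    pj = 0.0;
    pi = (unif_rand() < p_hd) ? -s : b;
    return;
  }
  // D-D
  if (unif_rand() < 0.5) { pi = b; pj = 0.0; } else { pi = 0.0; pj = b; }
  if (unif_rand() < p_dd) pi = -s;
  if (unif_rand() < p_dd) pj = -s;
}

// [[Rcpp::export]]
NumericVector cpp_play_round(IntegerVector state,
                             IntegerVector adj, IntegerVector ptr,
                             double R, double b, double s,
                             double p_hd, double p_dd) {
  int n = state.size();
  NumericVector pay(n, 0.0);
  double pi, pj;
  for (int i = 0; i < n; ++i) {
    for (int k = ptr[i]; k < ptr[i + 1]; ++k) {
      int j = adj[k];
      if (j <= i) continue;  // each unordered pair exactly once
      pair_payoff(state[i], state[j], R, b, s, p_hd, p_dd, pi, pj);
      pay[i] += pi;
      pay[j] += pj;
    }
  }
  return pay;
}

// Best-neighbor imitation decision for player i. Candidate set is
// self + neighbours; on a payoff tie the player keeps its own strategy if
// it attains the maximum, otherwise picks uniformly among maximal
// neighbours.
static inline int best_decision(int i, const IntegerVector &state,
                                const NumericVector &pay,
                                const IntegerVector &adj,
                                const IntegerVector &ptr,
                                std::vector<int> &buf,
                                bool include_self) {
  int lo = ptr[i], hi = ptr[i + 1];
  if (hi == lo) return state[i];
  double best;
  bool self_best;
  buf.clear();
  if (include_self) {
    best = pay[i];
    self_best = true;
  } else {
    best = R_NegInf;
    self_best = false;
  }
  for (int k = lo; k < hi; ++k) {
    int j = adj[k];
    if (pay[j] > best) {
      best = pay[j];
      self_best = false;
      buf.clear();
      buf.push_back(j);
    } else if (pay[j] == best && !self_best) {
      buf.push_back(j);
    }
  }
  if (self_best) return state[i];
  if (buf.size() == 1) return state[buf[0]];
  int pick = (int)(unif_rand() * buf.size());
  if (pick >= (int)buf.size()) pick = buf.size() - 1;
  return state[buf[pick]];
}

// [[Rcpp::export]]
IntegerVector cpp_imitate_best(IntegerVector state, NumericVector pay,
                               IntegerVector adj, IntegerVector ptr,
                               bool include_self) {
  int n = state.size();
  IntegerVector out(n);
  std::vector<int> buf;
  for (int i = 0; i < n; ++i)
    out[i] = best_decision(i, state, pay, adj, ptr, buf, include_self);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_imitate_best_myopic(IntegerVector state, NumericVector pay,
                                      IntegerVector adj, IntegerVector ptr,
                                      double q, bool include_self) {
  int n = state.size();
  IntegerVector out(n);
  std::vector<int> buf;
  for (int i = 0; i < n; ++i) {
    if (unif_rand() < q) {
      out[i] = best_decision(i, state, pay, adj, ptr, buf, include_self);
    } else {
      int deg = ptr[i + 1] - ptr[i];
      if (deg == 0) { out[i] = state[i]; continue; }
      int pick = (int)(unif_rand() * deg);
      if (pick >= deg) pick = deg - 1;
      out[i] = state[adj[ptr[i] + pick]];
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_imitate_best_fermi(IntegerVector state, NumericVector pay,
                                     IntegerVector adj, IntegerVector ptr,
                                     double K) {
  int n = state.size();
  IntegerVector out(n);
  std::vector<int> buf;
  for (int i = 0; i < n; ++i) {
    int lo = ptr[i], hi = ptr[i + 1];
    if (hi == lo) { out[i] = state[i]; continue; }
    double best = R_NegInf;
    buf.clear();
    for (int k = lo; k < hi; ++k) {
      int j = adj[k];
      if (pay[j] > best) { best = pay[j]; buf.clear(); buf.push_back(j); }
      else if (pay[j] == best) buf.push_back(j);
    }
    int jb = buf[0];
    if (buf.size() > 1) {
      int pick = (int)(unif_rand() * buf.size());
      if (pick >= (int)buf.size()) pick = buf.size() - 1;
      jb = buf[pick];
    }
    double prob = 1.0 / (1.0 + std::exp((pay[i] - best) / K));
    out[i] = (unif_rand() < prob) ? state[jb] : state[i];
  }
  return out;
}

// Full simulation: alternate interaction rounds and synchronous updates.
// rule: 0 = best, 1 = best_myopic, 2 = best_fermi.
// snapshot_rounds: sorted round indices (>= 1) at which to keep a copy of
// the state. If target_lo <= target_hi the loop stops at the first round
// whose honest rate falls inside [target_lo, target_hi] (stop_round in the
// result; -1 when no stop). Homogeneous states are absorbing under every
// rule, so when early_stop is true the loop exits there and the remaining
// honest rates are filled with the absorbed value.
// [[Rcpp::export]]
List cpp_run_simulation(IntegerVector state0,
                        IntegerVector adj, IntegerVector ptr,
                        double R, double b, double s,
                        double p_hd, double p_dd,
                        int rule, double q, double K,
                        bool include_self,
                        int rounds,
                        IntegerVector snapshot_rounds,
                        double target_lo, double target_hi,
                        bool early_stop) {
  int n = state0.size();
  IntegerVector state = clone(state0);
  NumericVector h_rate(rounds + 1);
  List snaps(snapshot_rounds.size());
  int snap_i = 0;
  double h0 = 0.0;
  for (int i = 0; i < n; ++i) h0 += state[i];
  h_rate[0] = h0 / n;
  int stop_round = -1;

  for (int r = 1; r <= rounds; ++r) {
    NumericVector pay = cpp_play_round(state, adj, ptr, R, b, s, p_hd, p_dd);
    if (rule == 0)      state = cpp_imitate_best(state, pay, adj, ptr, include_self);
    else if (rule == 1) state = cpp_imitate_best_myopic(state, pay, adj, ptr, q, include_self);
    else                state = cpp_imitate_best_fermi(state, pay, adj, ptr, K);

    double h = 0.0;
    for (int i = 0; i < n; ++i) h += state[i];
    h /= n;
    h_rate[r] = h;
    while (snap_i < snapshot_rounds.size() && snapshot_rounds[snap_i] == r) {
      snaps[snap_i] = clone(state);
      ++snap_i;
    }
    if (target_lo <= target_hi && h >= target_lo && h <= target_hi) {
      stop_round = r;
      for (int rr = r + 1; rr <= rounds; ++rr) h_rate[rr] = NA_REAL;
      break;
    }
    if (early_stop && (h == 0.0 || h == 1.0)) {
      for (int rr = r + 1; rr <= rounds; ++rr) h_rate[rr] = h;
      // absorbed: any remaining requested snapshots equal the current state
      while (snap_i < snapshot_rounds.size()) {
        snaps[snap_i] = clone(state);
        ++snap_i;
      }
      break;
    }
  }
  return List::create(_["h_rate"] = h_rate,
                      _["final_state"] = state,
                      _["snapshots"] = snaps,
                      _["stop_round"] = stop_round);
}
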