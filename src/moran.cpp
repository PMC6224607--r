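#include <Rcpp.h>
using namespace Rcpp;

// Non-spatial clonal competition at constant population size:
// a Moran process where division events occur at total rate lam * n_cells,
// the divider is drawn with probability proportional to count_i * (1 + delta_i),
// one uniformly random pre-division cell is removed, and with probability
// mut_rate the daughter founds a child clone whose fate bias adds an
// independent draw from the DFE to the parental bias (clipped to [-1, 1]).

struct Clones {
  std::vector<int> count, parent;
  std::vector<double> delta, birth;
  std::vector<bool> trans;
  int add(int par, double d, double t, bool tr) {
    count.push_back(1); parent.push_back(par);
    delta.push_back(d); birth.push_back(t); trans.push_back(tr);
    return (int) count.size() - 1;
  }
};

static double draw_dfe(double p_neutral, double p_deleterious,
                       double s_mean, double s_del_mean) {
  double u = R::unif_rand();
  if (u < p_neutral) return 0.0;
  if (u < p_neutral + p_deleterious) return -R::rexp(s_del_mean);
  return R::rexp(s_mean);
}

// [[Rcpp::export]]
List moran_competition_cpp(int n_cells, int n0_trans, double lam, double delta0,
                           double mut_rate, double p_neutral, double p_deleterious,
                           double s_mean, double s_del_mean,
                           double t_end, double record_interval,
                           int n_preseed) {
  Clones cl;
  cl.add(-1, 0.0, 0.0, false);  cl.count[0] = n_cells - n0_trans; // wild type
  cl.add(-1, delta0, 0.0, true); cl.count[1] = n0_trans;          // transgenic

  std::vector<int> alive = {0, 1};
  // optional mutagen pulse: standing single-cell mutant clones at t = 0
  for (int i = 0; i < n_preseed && cl.count[0] > 1; ++i) {
    double s = draw_dfe(p_neutral, p_deleterious, s_mean, s_del_mean);
    double d = (s < -1.0) ? -1.0 : (s > 1.0 ? 1.0 : s);
    int id = cl.add(0, d, 0.0, false);
    cl.count[0] -= 1;
    alive.push_back(id);
  }
  double W = 0.0;
  for (int ia : alive) W += cl.count[ia] * (1.0 + cl.delta[ia]);

  std::vector<double> rec_times;
  for (double tr = 0.0; tr <= t_end + 1e-12; tr += record_interval)
    rec_times.push_back(tr);
  std::vector< std::vector<int> > snaps;
  size_t next_rec = 0;
  long n_clipped = 0;

  double t = 0.0;
  double total_rate = lam * (double) n_cells;
  long events_since_compact = 0;

  auto snapshot = [&]() { snaps.push_back(cl.count); };

  for (;;) {
    double dt = (total_rate > 0.0) ? R::rexp(1.0 / total_rate) : R_PosInf;
    double t_next = t + dt;
    while (next_rec < rec_times.size() && rec_times[next_rec] < t_next) {
      snapshot(); ++next_rec;
    }
    if (t_next > t_end || !R_FINITE(t_next)) break;
    t = t_next;

    // divider ~ count_i * (1 + delta_i)
    double u = R::runif(0.0, W);
    int divider = alive.back();
    for (int ia : alive) {
      double wi = cl.count[ia] * (1.0 + cl.delta[ia]);
      if (u < wi) { divider = ia; break; }
      u -= wi;
    }
    // victim uniform among the n_cells pre-division cells
    double u2 = R::runif(0.0, (double) n_cells);
    int victim = alive.back();
    for (int ia : alive) {
      if (u2 < (double) cl.count[ia]) { victim = ia; break; }
      u2 -= (double) cl.count[ia];
    }
    cl.count[victim] -= 1;
    W -= (1.0 + cl.delta[victim]);

    if (mut_rate > 0.0 && R::unif_rand() < mut_rate) {
      double s = draw_dfe(p_neutral, p_deleterious, s_mean, s_del_mean);
      double d = cl.delta[divider] + s;
      if (d < -1.0) { d = -1.0; ++n_clipped; }
      if (d > 1.0)  { d = 1.0;  ++n_clipped; }
      int id = cl.add(divider, d, t, cl.trans[divider]);
      alive.push_back(id);
      W += (1.0 + d);
    } else {
      cl.count[divider] += 1;
      W += (1.0 + cl.delta[divider]);
    }

    if (++events_since_compact >= 20000) {
      std::vector<int> keep;
      keep.reserve(alive.size());
      W = 0.0;
      for (int ia : alive)
        if (cl.count[ia] > 0) { keep.push_back(ia); W += cl.count[ia] * (1.0 + cl.delta[ia]); }
      alive.swap(keep);
      events_since_compact = 0;
    }
  }
  while (next_rec < rec_times.size()) { snapshot(); ++next_rec; }

  int n_clones = (int) cl.count.size();
  int n_t = (int) snaps.size();
  IntegerMatrix counts(n_t, n_clones);
  for (int i = 0; i < n_t; ++i) {
    int m = (int) snaps[i].size();
    for (int j = 0; j < m; ++j) counts(i, j) = snaps[i][j];
  }
  return List::create(
    _["times"] = NumericVector(rec_times.begin(), rec_times.end()),
    _["counts"] = counts,
    _["parent"] = IntegerVector(cl.parent.begin(), cl.parent.end()),
    _["delta"] = NumericVector(cl.delta.begin(), cl.delta.end()),
    _["birth_time"] = NumericVector(cl.birth.begin(), cl.birth.end()),
    _["is_transgenic_lineage"] = LogicalVector(cl.trans.begin(), cl.trans.end()),
    _["n_clipped"] = (double) n_clipped);
}

// Two-clone Moran with selection run to absorption; returns 1 if the
// selected clone (initial size k0, advantage s) fixes, else 0, per replicate.
// [[Rcpp::export]]
IntegerVector moran_two_clone_fix_cpp(int n_cells, int k0, double s, int n_reps) {
  IntegerVector out(n_reps);
  for (int rep = 0; rep < n_reps; ++rep) {
    int k = k0;
    while (k > 0 && k < n_cells) {
      double W = k * (1.0 + s) + (double) (n_cells - k);
      bool div_fit = R::unif_rand() < k * (1.0 + s) / W;
      bool vic_fit = R::unif_rand() < (double) k / n_cells;
      if (div_fit && !vic_fit) ++k;
      else if (!div_fit && vic_fit) --k;
    }
    out[rep] = (k == n_cells) ? 1 : 0;
  }
  return out;
}
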