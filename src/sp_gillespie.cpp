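#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation of the single-progenitor clone process.
// Events: division at rate lam*n_p with outcomes PP/DD/PD, stratification
// at rate gamma*n_d, shedding at rate mu*n_s. Uses R's RNG so paths are
// reproducible under set.seed().

// [[Rcpp::export]]
NumericMatrix sp_gillespie_path_cpp(double lam, double p_pp, double p_dd,
                                    double gamma, double mu,
                                    int np, int nd, int ns, double t_end) {
  std::vector<double> ts;
  std::vector<int> vp, vd, vs;
  double t = 0.0;
  ts.push_back(t); vp.push_back(np); vd.push_back(nd); vs.push_back(ns);
  for (;;) {
    double r_div = lam * np, r_str = gamma * nd, r_shed = mu * ns;
    double r_tot = r_div + r_str + r_shed;
    if (r_tot <= 0.0) break;
    t += R::rexp(1.0 / r_tot);
    if (t > t_end) break;
    double u = R::runif(0.0, r_tot);
    if (u < r_div) {
      double v = R::unif_rand();
      if (v < p_pp) {
        np += 1;
      } else if (v < p_pp + p_dd) {
        np -= 1; nd += 2;
      } else {
        nd += 1;
      }
    } else if (u < r_div + r_str) {
      nd -= 1; ns += 1;
    } else {
      ns -= 1;
    }
    ts.push_back(t); vp.push_back(np); vd.push_back(nd); vs.push_back(ns);
  }
  // closing row at t_end (state unchanged since last event)
  ts.push_back(t_end); vp.push_back(np); vd.push_back(nd); vs.push_back(ns);
  int n = ts.size();
  NumericMatrix out(n, 4);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = ts[i]; out(i, 1) = vp[i]; out(i, 2) = vd[i]; out(i, 3) = vs[i];
  }
  colnames(out) = CharacterVector::create("t", "n_p", "n_d", "n_s");
  return out;
}

// Batch simulation returning only the state at t_end for each replicate.
// [[Rcpp::export]]
IntegerMatrix sp_gillespie_final_cpp(double lam, double p_pp, double p_dd,
                                     double gamma, double mu,
                                     int np0, int nd0, int ns0,
                                     double t_end, int n_reps) {
  IntegerMatrix out(n_reps, 3);
  for (int rep = 0; rep < n_reps; ++rep) {
    int np = np0, nd = nd0, ns = ns0;
    double t = 0.0;
    for (;;) {
      double r_div = lam * np, r_str = gamma * nd, r_shed = mu * ns;
      double r_tot = r_div + r_str + r_shed;
      if (r_tot <= 0.0) break;
      t += R::rexp(1.0 / r_tot);
      if (t > t_end) break;
      double u = R::runif(0.0, r_tot);
      if (u < r_div) {
        double v = R::unif_rand();
        if (v < p_pp) np += 1;
        else if (v < p_pp + p_dd) { np -= 1; nd += 2; }
        else nd += 1;
      } else if (u < r_div + r_str) {
        nd -= 1; ns += 1;
      } else {
        ns -= 1;
      }
    }
    out(rep, 0) = np; out(rep, 1) = nd; out(rep, 2) = ns;
  }
  colnames(out) = CharacterVector::create("n_p", "n_d", "n_s");
  return out;
}
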