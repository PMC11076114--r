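#include <Rcpp.h>
using namespace Rcpp;

// Continuous-time exclusion-process simulator with pool-coupled entry.
//
// Direct (Gillespie) event scheme: every enabled transition carries an
// exponential clock; at each event the total rate is accumulated, the
// waiting time drawn from Exp(total), and one transition chosen with
// probability proportional to its rate. Because exponential clocks are
// memoryless this is statistically identical to a next-reaction scheme
// in which pending clocks are redrawn whenever an enabling condition or
// a pool level changes.
//
// Transitions per chain (n sites): entry (pool -> site 1, rate
// lambda_0 * G(z_src), enabled when site 1 is empty and G(z) > 0),
// internal hops j -> j+1 (rate lambda_j, enabled when j occupied and
// j+1 empty), and exit (site n -> sink pool, rate lambda_n).
//
// Site occupancies and pool levels are time-averaged over the holding
// times of all states visited after the burn-in event count.

static inline double eval_g(int type, double param, double z) {
  if (z <= 0.0) return 0.0;
  switch (type) {
  case 0: return z;              // identity
  case 1: return std::tanh(z);   // tanh
  case 2: return param * z;      // scaled identity
  default: Rcpp::stop("unsupported input function in MC simulator");
  }
  return 0.0;
}

// [[Rcpp::export]]
List tasep_mc_run(IntegerVector ns, NumericVector rates,
                  IntegerVector rate_offset, IntegerVector site_offset,
                  IntegerVector src, IntegerVector snk,
                  IntegerVector gtype, NumericVector gparam,
                  IntegerVector pool_init,
                  double n_steps, double burn_in) {
  const int n_chains = ns.size();
  const int M = pool_init.size();
  int total_sites = 0;
  for (int i = 0; i < n_chains; ++i) total_sites += ns[i];

  std::vector<int> occ(total_sites, 0);
  std::vector<long long> z(M);
  long long total_particles = 0;
  for (int j = 0; j < M; ++j) { z[j] = pool_init[j]; total_particles += z[j]; }

  const long long steps = (long long) n_steps;
  const long long burn = (long long) burn_in;

  std::vector<double> occ_time(total_sites, 0.0);
  std::vector<double> pool_time(M, 0.0);
  double t_retained = 0.0;

  // transition layout: per chain, ns[i] + 1 transitions
  int n_trans = 0;
  std::vector<int> trans_offset(n_chains);
  for (int i = 0; i < n_chains; ++i) {
    trans_offset[i] = n_trans;
    n_trans += ns[i] + 1;
  }
  std::vector<double> rate_buf(n_trans);

  long long ev = 0;
  for (ev = 0; ev < steps; ++ev) {
    double tot = 0.0;
    for (int i = 0; i < n_chains; ++i) {
      const int n = ns[i];
      const int so = site_offset[i];
      const int ro = rate_offset[i];
      const int to = trans_offset[i];
      // entry
      double r0 = 0.0;
      if (occ[so] == 0) {
        r0 = rates[ro] * eval_g(gtype[i], gparam[i], (double) z[src[i]]);
      }
      rate_buf[to] = r0; tot += r0;
      // internal hops j -> j+1 (1-based site j)
      for (int j = 1; j < n; ++j) {
        double rj = (occ[so + j - 1] == 1 && occ[so + j] == 0)
          ? rates[ro + j] : 0.0;
        rate_buf[to + j] = rj; tot += rj;
      }
      // exit
      double rn = (occ[so + n - 1] == 1) ? rates[ro + n] : 0.0;
      rate_buf[to + n] = rn; tot += rn;
    }
    if (tot <= 0.0) break; // frozen (e.g. no particles)

    double dt = R::exp_rand() / tot;
    if (ev >= burn) {
      t_retained += dt;
      for (int s = 0; s < total_sites; ++s)
        if (occ[s]) occ_time[s] += dt;
      for (int j = 0; j < M; ++j) pool_time[j] += (double) z[j] * dt;
    }

    double u = R::unif_rand() * tot;
    double acc = 0.0;
    int chosen = n_trans - 1;
    for (int k = 0; k < n_trans; ++k) {
      acc += rate_buf[k];
      if (u <= acc && rate_buf[k] > 0.0) { chosen = k; break; }
    }
    // locate chain
    int ci = n_chains - 1;
    for (int i = 0; i < n_chains; ++i) {
      if (chosen < trans_offset[i] + ns[i] + 1) { ci = i; break; }
    }
    const int local = chosen - trans_offset[ci];
    const int so = site_offset[ci];
    const int n = ns[ci];
    if (local == 0) {            // entry
      if (z[src[ci]] <= 0) Rcpp::stop("entry from an empty pool (internal error)");
      z[src[ci]] -= 1;
      occ[so] = 1;
    } else if (local < n) {      // hop local -> local + 1
      occ[so + local - 1] = 0;
      occ[so + local] = 1;
    } else {                     // exit
      occ[so + n - 1] = 0;
      z[snk[ci]] += 1;
    }
  }

  // conservation check
  long long count = 0;
  for (int j = 0; j < M; ++j) count += z[j];
  for (int s = 0; s < total_sites; ++s) count += occ[s];
  if (count != total_particles) Rcpp::stop("particle count not conserved (internal error)");

  NumericVector site_means(total_sites), pool_means(M);
  if (t_retained > 0.0) {
    for (int s = 0; s < total_sites; ++s) site_means[s] = occ_time[s] / t_retained;
    for (int j = 0; j < M; ++j) pool_means[j] = pool_time[j] / t_retained;
  }
  return List::create(
    _["site_means"] = site_means,
    _["pool_means"] = pool_means,
    _["n_events"] = (double) ev,
    _["retained_time"] = t_retained
  );
}
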