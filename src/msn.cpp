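// Core samplers for the multisite neutral (MSN) model: a two-level
// hierarchical Dirichlet process in its Chinese-restaurant-franchise (CRF)
// representation.  Sites are restaurants with concentration I_j; tables are
// ancestral immigration events whose dishes (taxa) are drawn from a
// metacommunity-level CRP with concentration theta.
//
// All randomness goes through R's RNG (RNGScope) so that set.seed() in R
// gives bit-identical output.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

static inline double logaddexp(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  return (a > b) ? a + log1p(std::exp(b - a)) : b + log1p(std::exp(a - b));
}

// Ragged triangle of log |s(n, t)| (unsigned Stirling numbers of the first
// kind), rows n = 0..nmax, row n holding t = 0..n.  Recurrence
// |s(n+1, t)| = n |s(n, t)| + |s(n, t-1)| in log space.
typedef std::vector< std::vector<double> > LogStirling;

static LogStirling build_log_stirling(int nmax) {
  LogStirling S(nmax + 1);
  S[0].assign(1, 0.0);
  for (int n = 1; n <= nmax; ++n) {
    S[n].assign(n + 1, R_NegInf);
    const std::vector<double>& prev = S[n - 1];
    double logn1 = (n > 1) ? std::log((double)(n - 1)) : R_NegInf;
    for (int t = 1; t <= n; ++t) {
      double up = (t <= n - 1) ? logn1 + prev[t] : R_NegInf;
      S[n][t] = logaddexp(up, prev[t - 1]);
    }
  }
  return S;
}

// log |s(n, t)| with a documented normal-density fallback above the cap:
// since sum_t |s(n,t)| a^t = Gamma(a+n)/Gamma(a), the Antoniak pmf for the
// table count is approximated by a normal with the CRP mean/variance and the
// Stirling term recovered from it.  'a' is the concentration in force when
// the cell is evaluated.
static double log_stirling_at(const LogStirling& S, int cap, int n, int t, double a) {
  if (t < 0 || t > n) return R_NegInf;
  if (n <= cap) return S[n][t];
  double mu = a * (R::digamma(a + n) - R::digamma(a));
  double v  = mu + a * a * (R::trigamma(a + n) - R::trigamma(a));
  if (v < 1e-8) v = 1e-8;
  return R::dnorm(t, mu, std::sqrt(v), 1) +
         R::lgammafn(a + n) - R::lgammafn(a) - t * std::log(a);
}

// Draw the table count T for a cell with n customers and concentration a
// from the Antoniak distribution P(T = t) proportional to |s(n,t)| a^t.
static int sample_antoniak(int n, double a, const LogStirling& S, int cap) {
  if (n <= 1) return n;
  if (n > cap) {
    double mu = a * (R::digamma(a + n) - R::digamma(a));
    double v  = mu + a * a * (R::trigamma(a + n) - R::trigamma(a));
    if (v < 1e-8) v = 1e-8;
    int t = (int) std::lround(R::rnorm(mu, std::sqrt(v)));
    if (t < 1) t = 1;
    if (t > n) t = n;
    return t;
  }
  double la = std::log(a);
  std::vector<double> lw(n);
  double mx = R_NegInf;
  for (int t = 1; t <= n; ++t) {
    lw[t - 1] = S[n][t] + t * la;
    if (lw[t - 1] > mx) mx = lw[t - 1];
  }
  double tot = 0.0;
  for (int t = 0; t < n; ++t) { lw[t] = std::exp(lw[t] - mx); tot += lw[t]; }
  double u = unif_rand() * tot, acc = 0.0;
  for (int t = 0; t < n; ++t) {
    acc += lw[t];
    if (u <= acc) return t + 1;
  }
  return n;
}

// Collapsed (metacommunity-level) joint log-probability of a count table and
// its table counts: per-site multinomial ordering factor, CRP(I_j) seating
// with Stirling weights, the top-level CRP(theta) EPPF over pooled table
// counts with beta integrated out, and the multiset symmetry correction
// 1 / prod_g a_g! over groups of taxa whose (count row, table row) pairs are
// identical — taxa are exchangeable, so such rows are indistinguishable
// outcomes (this is the a_j! of the Ewens sampling formula, to which the
// single-site large-I limit reduces exactly).
static double loglik_meta(const std::vector< std::vector<int> >& n,
                          const std::vector< std::vector<int> >& T,
                          double theta, const std::vector<double>& I,
                          const LogStirling& S, int cap) {
  int K = (int) n.size();
  int Jn = K ? (int) n[0].size() : 0;
  double ll = 0.0;
  std::vector<double> Tcol(K, 0.0);
  for (int j = 0; j < Jn; ++j) {
    long Jj = 0; double Tj = 0.0, site = 0.0;
    for (int k = 0; k < K; ++k) {
      int njk = n[k][j];
      if (njk <= 0) continue;
      Jj += njk;
      Tj += T[k][j];
      Tcol[k] += T[k][j];
      double a = I[j]; // concentration in force for the fallback only
      site += log_stirling_at(S, cap, njk, T[k][j], a) - R::lgammafn(njk + 1.0);
    }
    site += R::lgammafn(Jj + 1.0) + R::lgammafn(I[j]) - R::lgammafn(I[j] + Jj) +
            Tj * std::log(I[j]);
    ll += site;
  }
  double Tdot = 0.0; int Kpos = 0;
  for (int k = 0; k < K; ++k) {
    if (Tcol[k] > 0) {
      ++Kpos;
      Tdot += Tcol[k];
      ll += R::lgammafn(Tcol[k]);
    }
  }
  ll += Kpos * std::log(theta) + R::lgammafn(theta) - R::lgammafn(theta + Tdot);
  // multiset correction for identical (n, T) rows
  {
    std::map< std::vector<int>, int > groups;
    std::vector<int> key(2 * Jn);
    for (int k = 0; k < K; ++k) {
      bool pos = false;
      for (int j = 0; j < Jn; ++j) {
        key[j] = n[k][j];
        key[Jn + j] = T[k][j];
        if (n[k][j] > 0) pos = true;
      }
      if (pos) groups[key] += 1;
    }
    for (std::map< std::vector<int>, int >::const_iterator it = groups.begin();
         it != groups.end(); ++it)
      ll -= R::lgammafn(it->second + 1.0);
  }
  return ll;
}

// Per-site local log-likelihood conditional on the drawn metacommunity
// weights beta (length K+1; last entry is the unseen stick, used for the
// pooled novel-taxon column of simulated replicates).
static void loglik_local_sites(const std::vector< std::vector<int> >& n,
                               const std::vector< std::vector<int> >& T,
                               const std::vector<double>& beta,
                               const std::vector<double>& I,
                               const LogStirling& S, int cap,
                               std::vector<double>& out) {
  int K = (int) n.size(); // includes the pooled unseen column as row K-1
  int Jn = K ? (int) n[0].size() : 0;
  for (int j = 0; j < Jn; ++j) {
    long Jj = 0; double site = 0.0;
    for (int k = 0; k < K; ++k) {
      int njk = n[k][j];
      if (njk <= 0) continue;
      Jj += njk;
      double b = beta[k];
      if (b < 1e-300) b = 1e-300;
      double a = I[j] * b;
      site += log_stirling_at(S, cap, njk, T[k][j], a) - R::lgammafn(njk + 1.0) +
              T[k][j] * std::log(a);
    }
    site += R::lgammafn(Jj + 1.0) + R::lgammafn(I[j]) - R::lgammafn(I[j] + Jj);
    out[j] = site;
  }
}

static std::vector< std::vector<int> > as_vecmat(const IntegerMatrix& m) {
  std::vector< std::vector<int> > v(m.nrow(), std::vector<int>(m.ncol()));
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < m.ncol(); ++j) v[i][j] = m(i, j);
  return v;
}

// [[Rcpp::export]]
NumericVector stirling_log_row_cpp(int n) {
  if (n < 0) stop("n must be non-negative");
  LogStirling S = build_log_stirling(n);
  NumericVector out(n + 1);
  for (int t = 0; t <= n; ++t) out[t] = S[n][t];
  return out;
}

// [[Rcpp::export]]
double crf_loglik_cpp(IntegerMatrix n, IntegerMatrix T, double theta,
                      NumericVector I, Nullable<NumericVector> beta,
                      int stirling_cap) {
  std::vector< std::vector<int> > nv = as_vecmat(n), Tv = as_vecmat(T);
  std::vector<double> Iv(I.begin(), I.end());
  int nmax = 0;
  for (int k = 0; k < n.nrow(); ++k)
    for (int j = 0; j < n.ncol(); ++j)
      if (n(k, j) > nmax) nmax = n(k, j);
  LogStirling S = build_log_stirling(std::min(nmax, stirling_cap));
  if (beta.isNull())
    return loglik_meta(nv, Tv, theta, Iv, S, stirling_cap);
  NumericVector b(beta);
  std::vector<double> bv(b.begin(), b.end());
  std::vector<double> site(n.ncol());
  loglik_local_sites(nv, Tv, bv, Iv, S, stirling_cap, site);
  double ll = 0.0;
  for (size_t j = 0; j < site.size(); ++j) ll += site[j];
  return ll;
}

// Gibbs sampler for the MSN model.  n is the taxa x sites count matrix.
// Sweep: (1) Antoniak update of each table count T_jk; (2) Dirichlet update
// of beta given column sums of T and theta; (3) Escobar-West auxiliary
// update of theta given the number of dishes and total tables; (4) Teh
// auxiliary update of each I_j given T_j. and J_j.
// [[Rcpp::export]]
List msn_gibbs_cpp(IntegerMatrix n, int iterations, int burn_in, int thin,
                   double prior_shape, double prior_rate,
                   double theta0, double I0, int stirling_cap) {
  int K = n.nrow(), Jn = n.ncol();
  std::vector<long> J(Jn, 0);
  int nmax = 0;
  for (int j = 0; j < Jn; ++j)
    for (int k = 0; k < K; ++k) {
      J[j] += n(k, j);
      if (n(k, j) > nmax) nmax = n(k, j);
    }
  LogStirling S = build_log_stirling(std::min(nmax, stirling_cap));

  std::vector< std::vector<int> > nv = as_vecmat(n);
  std::vector< std::vector<int> > T(K, std::vector<int>(Jn, 0));
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < Jn; ++j) T[k][j] = (nv[k][j] > 0) ? 1 : 0;

  double theta = theta0;
  std::vector<double> I(Jn, I0), beta(K + 1);
  { // initial beta from expected Dirichlet mass
    double tot = theta;
    std::vector<double> Tcol(K, 0.0);
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < Jn; ++j) Tcol[k] += T[k][j];
      tot += Tcol[k];
    }
    for (int k = 0; k < K; ++k) beta[k] = Tcol[k] / tot;
    beta[K] = theta / tot;
  }

  int ndraw = (iterations - burn_in) / thin;
  NumericVector theta_d(ndraw), ll_d(ndraw);
  NumericMatrix I_d(ndraw, Jn), beta_d(ndraw, K + 1);
  IntegerVector T_d(Dimension(K, Jn, ndraw));

  int stored = 0;
  for (int iter = 1; iter <= iterations; ++iter) {
    // (1) table counts
    for (int j = 0; j < Jn; ++j) {
      for (int k = 0; k < K; ++k) {
        int njk = nv[k][j];
        if (njk == 0) continue;
        double b = beta[k];
        if (b < 1e-300) b = 1e-300;
        T[k][j] = sample_antoniak(njk, I[j] * b, S, stirling_cap);
      }
    }
    std::vector<double> Tcol(K, 0.0), Trow(Jn, 0.0);
    double Tdot = 0.0;
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < Jn; ++j) {
        Tcol[k] += T[k][j];
        Trow[j] += T[k][j];
        Tdot += T[k][j];
      }
    // (2) beta | T, theta
    double btot = 0.0;
    for (int k = 0; k <= K; ++k) {
      double shape = (k < K) ? Tcol[k] : theta;
      double g = R::rgamma(shape, 1.0);
      if (g < 1e-300) g = 1e-300;
      beta[k] = g;
      btot += g;
    }
    for (int k = 0; k <= K; ++k) beta[k] /= btot;
    // (3) theta | K dishes, Tdot tables (Escobar-West)
    {
      double eta = R::rbeta(theta + 1.0, Tdot);
      if (eta < 1e-12) eta = 1e-12;
      if (eta > 1.0 - 1e-12) eta = 1.0 - 1e-12;
      double denom = prior_rate - std::log(eta);
      double odds = (prior_shape + K - 1.0) / (Tdot * denom);
      double pi = odds / (1.0 + odds);
      double shape = prior_shape + K - ((unif_rand() < pi) ? 0.0 : 1.0);
      theta = R::rgamma(shape, 1.0 / denom);
      if (theta < 1e-10) theta = 1e-10;
    }
    // (4) I_j | T_j., J_j (Teh auxiliary variables)
    for (int j = 0; j < Jn; ++j) {
      double w = R::rbeta(I[j] + 1.0, (double) J[j]);
      if (w < 1e-12) w = 1e-12;
      int s = (unif_rand() < (double) J[j] / ((double) J[j] + I[j])) ? 1 : 0;
      I[j] = R::rgamma(prior_shape + Trow[j] - s, 1.0 / (prior_rate - std::log(w)));
      if (I[j] < 1e-10) I[j] = 1e-10;
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      theta_d[stored] = theta;
      for (int j = 0; j < Jn; ++j) I_d(stored, j) = I[j];
      for (int k = 0; k <= K; ++k) beta_d(stored, k) = beta[k];
      for (int j = 0; j < Jn; ++j)
        for (int k = 0; k < K; ++k)
          T_d[k + K * (j + Jn * stored)] = T[k][j];
      double ll = loglik_meta(nv, T, theta, I, S, stirling_cap);
      if (!R_finite(ll))
        stop("non-finite log-likelihood in Gibbs trace (iteration %d)", iter);
      ll_d[stored] = ll;
      ++stored;
    }
  }

  return List::create(_["theta"] = theta_d, _["I"] = I_d, _["beta"] = beta_d,
                      _["T"] = T_d, _["loglik"] = ll_d);
}

// One CRF replicate for a single draw of (theta, I, beta).  Customers are
// seated sequentially: a new table with probability I_j/(I_j + i - 1), else
// the table of a uniformly chosen earlier customer (size-biased, O(1)).
// New tables draw a dish from beta; the unseen stick spawns novel dishes
// through a CRP(theta) among novel tables.  With beta_len == 0 the top level
// is fully collapsed: new tables copy the dish of a uniformly chosen
// existing table or create a new dish with probability theta/(theta + tau).
struct CrfRep {
  std::vector< std::vector<int> > counts; // [dish][site]
  std::vector< std::vector<int> > tables; // [dish][site]
  int n_obs_dishes;                       // dishes 0..n_obs-1 map to beta
};

static CrfRep simulate_crf(double theta, const std::vector<double>& I,
                           const std::vector<long>& J,
                           const std::vector<double>& beta /* may be empty */) {
  int Jn = (int) J.size();
  int Kobs = beta.empty() ? 0 : (int) beta.size() - 1;
  CrfRep rep;
  rep.n_obs_dishes = Kobs;
  rep.counts.assign(Kobs, std::vector<int>(Jn, 0));
  rep.tables.assign(Kobs, std::vector<int>(Jn, 0));
  // global top-level bookkeeping
  std::vector<int> top_count;      // per novel dish (beta mode) or per dish (collapsed)
  long top_total = 0;
  std::vector<int> all_dish;       // collapsed mode: dish of every table, in order
  for (int j = 0; j < Jn; ++j) {
    std::vector<int> table_of(J[j]);
    std::vector<int> dish_of_table;
    for (long i = 0; i < J[j]; ++i) {
      double pnew = I[j] / (I[j] + (double) i);
      if (unif_rand() < pnew) {
        int dish;
        if (!beta.empty()) {
          double u = unif_rand(), acc = 0.0;
          int pick = Kobs; // default to unseen stick
          for (int k = 0; k < Kobs; ++k) {
            acc += beta[k];
            if (u <= acc) { pick = k; break; }
          }
          if (pick < Kobs) {
            dish = pick;
          } else {
            // novel dish via CRP(theta) within the unseen mass
            int nd;
            if (top_total == 0 ||
                unif_rand() < theta / (theta + (double) top_total)) {
              top_count.push_back(0);
              nd = (int) top_count.size() - 1;
            } else {
              double u2 = unif_rand() * (double) top_total;
              double a2 = 0.0;
              nd = (int) top_count.size() - 1;
              for (size_t q = 0; q < top_count.size(); ++q) {
                a2 += top_count[q];
                if (u2 <= a2) { nd = (int) q; break; }
              }
            }
            top_count[nd] += 1;
            top_total += 1;
            dish = Kobs + nd;
          }
        } else {
          // fully collapsed top level
          if (top_total == 0 ||
              unif_rand() < theta / (theta + (double) top_total)) {
            top_count.push_back(0);
            dish = (int) top_count.size() - 1;
          } else {
            long r = (long) std::floor(unif_rand() * (double) top_total);
            if (r >= top_total) r = top_total - 1;
            dish = all_dish[r];
          }
          top_count[dish] += 1;
          top_total += 1;
          all_dish.push_back(dish);
        }
        if (dish >= (int) rep.counts.size()) {
          rep.counts.resize(dish + 1, std::vector<int>(Jn, 0));
          rep.tables.resize(dish + 1, std::vector<int>(Jn, 0));
        }
        dish_of_table.push_back(dish);
        table_of[i] = (int) dish_of_table.size() - 1;
        rep.tables[dish][j] += 1;
        rep.counts[dish][j] += 1;
      } else {
        long r = (long) std::floor(unif_rand() * (double) i);
        if (r >= i) r = i - 1;
        table_of[i] = table_of[r];
        rep.counts[dish_of_table[table_of[i]]][j] += 1;
      }
    }
  }
  return rep;
}

// [[Rcpp::export]]
List simulate_crf_cpp(double theta, NumericVector I, IntegerVector site_sizes,
                      Nullable<NumericVector> beta) {
  std::vector<double> Iv(I.begin(), I.end());
  std::vector<long> Jv(site_sizes.begin(), site_sizes.end());
  std::vector<double> bv;
  if (beta.isNotNull()) {
    NumericVector b(beta);
    bv.assign(b.begin(), b.end());
  }
  CrfRep rep = simulate_crf(theta, Iv, Jv, bv);
  int K = (int) rep.counts.size(), Jn = (int) Jv.size();
  IntegerMatrix counts(K, Jn), tables(K, Jn);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < Jn; ++j) {
      counts(k, j) = rep.counts[k][j];
      tables(k, j) = rep.tables[k][j];
    }
  return List::create(_["counts"] = counts, _["tables"] = tables,
                      _["n_obs_dishes"] = rep.n_obs_dishes);
}

// Posterior-predictive pseudo-p machinery: for each retained draw, simulate
// one replicate from that draw's parameters and compute the meta-level
// (collapsed joint) and per-site local (conditional on beta) log-likelihoods
// of both the replicate and the observed data under the same draw.
// [[Rcpp::export]]
List msn_pp_test_cpp(IntegerMatrix n, NumericVector theta_d, NumericMatrix I_d,
                     NumericMatrix beta_d, IntegerVector T_d, int stirling_cap) {
  int K = n.nrow(), Jn = n.ncol(), ndraw = theta_d.size();
  std::vector<long> J(Jn, 0);
  long maxJ = 0;
  for (int j = 0; j < Jn; ++j) {
    for (int k = 0; k < K; ++k) J[j] += n(k, j);
    if (J[j] > maxJ) maxJ = J[j];
  }
  LogStirling S = build_log_stirling((int) std::min(maxJ, (long) stirling_cap));
  std::vector< std::vector<int> > nv = as_vecmat(n);

  NumericVector L0_meta(ndraw), Lsim_meta(ndraw);
  NumericMatrix L0_local(ndraw, Jn), Lsim_local(ndraw, Jn);

  // observed data with an (empty) pooled unseen column appended for the
  // local likelihood
  std::vector< std::vector<int> > n_loc = nv;
  n_loc.push_back(std::vector<int>(Jn, 0));

  for (int i = 0; i < ndraw; ++i) {
    double theta = theta_d[i];
    std::vector<double> I(Jn), beta(K + 1);
    for (int j = 0; j < Jn; ++j) I[j] = I_d(i, j);
    for (int k = 0; k <= K; ++k) beta[k] = beta_d(i, k);
    std::vector< std::vector<int> > T(K, std::vector<int>(Jn));
    for (int j = 0; j < Jn; ++j)
      for (int k = 0; k < K; ++k)
        T[k][j] = T_d[k + K * (j + Jn * i)];

    // smoothed metacommunity weights for the local-level check: the
    // posterior mean of beta given this draw's table counts and theta.
    // Conditioning on a raw Dirichlet draw would charge the observed data
    // for the Monte Carlo noise in beta while replicates (generated from
    // that same draw) escape it, making the local pseudo-p anti-
    // conservative on truly neutral data.
    std::vector<double> beta_bar(K + 1);
    {
      double Tdot = 0.0;
      for (int k = 0; k < K; ++k) {
        double Tc = 0.0;
        for (int j = 0; j < Jn; ++j) Tc += T[k][j];
        beta_bar[k] = Tc;
        Tdot += Tc;
      }
      for (int k = 0; k < K; ++k) beta_bar[k] /= (Tdot + theta);
      beta_bar[K] = theta / (Tdot + theta);
    }

    L0_meta[i] = loglik_meta(nv, T, theta, I, S, stirling_cap);
    std::vector< std::vector<int> > T_loc = T;
    T_loc.push_back(std::vector<int>(Jn, 0));
    std::vector<double> site(Jn);
    loglik_local_sites(n_loc, T_loc, beta_bar, I, S, stirling_cap, site);
    for (int j = 0; j < Jn; ++j) L0_local(i, j) = site[j];

    // meta-level replicate from the drawn beta, scored collapsed
    CrfRep rep = simulate_crf(theta, I, J, beta);
    Lsim_meta[i] = loglik_meta(rep.counts, rep.tables, theta, I, S, stirling_cap);

    // local-level replicate from the smoothed weights, novel dishes pooled
    // into the unseen column
    CrfRep repl = simulate_crf(theta, I, J, beta_bar);
    int Krep = (int) repl.counts.size();
    std::vector< std::vector<int> > n_rep(K + 1, std::vector<int>(Jn, 0));
    std::vector< std::vector<int> > T_rep(K + 1, std::vector<int>(Jn, 0));
    for (int k = 0; k < Krep; ++k)
      for (int j = 0; j < Jn; ++j) {
        int row = (k < K) ? k : K;
        n_rep[row][j] += repl.counts[k][j];
        T_rep[row][j] += repl.tables[k][j];
      }
    loglik_local_sites(n_rep, T_rep, beta_bar, I, S, stirling_cap, site);
    for (int j = 0; j < Jn; ++j) Lsim_local(i, j) = site[j];
  }

  return List::create(_["L0_meta"] = L0_meta, _["Lsim_meta"] = Lsim_meta,
                      _["L0_local"] = L0_local, _["Lsim_local"] = Lsim_local);
}
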