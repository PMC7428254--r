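#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Propensity kinds shared by the generic single-cell kernel and the
// population loop.  All channels are mass-action except the
// pseudo-steady-state death channel (kind 4), which carries the closed
// form f2 = kd2 * kd*tmz / (kd*tmz + s*MGMT) (+ basal eps in p3).
//   0 const     a = rate
//   1 linear    a = rate * x[dep1]
//   2 bilinear  a = rate * x[dep1] * x[dep2]
//   3 damage    a = rate * tmz * (1 - x[dep1])        (dep1 = DNA_DAM)
//   4 death_pss a = p3 + rate * p1*tmz / (p1*tmz + p2*x[dep1])
struct Net {
  int ns, nc;
  IntegerMatrix stoich;          // nc x ns
  IntegerVector kind, dep1, dep2;
  NumericVector rate;
  NumericMatrix pmat;            // nc x 3
  LogicalVector is_death;
  LogicalVector partition;       // per species: split binomially at division?
};

static Net unpack_net(const List& net) {
  Net n;
  n.stoich = as<IntegerMatrix>(net["stoich"]);
  n.kind = as<IntegerVector>(net["kind"]);
  n.dep1 = as<IntegerVector>(net["dep1"]);
  n.dep2 = as<IntegerVector>(net["dep2"]);
  n.rate = as<NumericVector>(net["rate"]);
  n.pmat = as<NumericMatrix>(net["pmat"]);
  n.is_death = as<LogicalVector>(net["is_death"]);
  n.partition = as<LogicalVector>(net["partition"]);
  n.nc = n.stoich.nrow();
  n.ns = n.stoich.ncol();
  return n;
}

static inline double propensity(const Net& net, int c, const double* x,
                                double tmz) {
  const double rate = net.rate[c];
  switch (net.kind[c]) {
  case 0: return rate;
  case 1: return rate * x[net.dep1[c]];
  case 2: return rate * x[net.dep1[c]] * x[net.dep2[c]];
  case 3: return rate * tmz * (1.0 - x[net.dep1[c]]);
  case 4: {
    const double num = net.pmat(c, 0) * tmz;
    const double den = num + net.pmat(c, 1) * x[net.dep1[c]];
    const double f2 = (den > 0.0) ? rate * num / den : 0.0;
    return f2 + net.pmat(c, 2);
  }
  }
  return 0.0;
}

// Exact SSA over one window with the supplied frozen tmz.  Returns 1 if
// the death channel fired (death_time set, later events discarded),
// else 0.  x is updated in place.
static int advance_ssa(double* x, const Net& net, double tmz, double window,
                       double& death_time, double& n_events,
                       std::vector<double>* log_t, std::vector<int>* log_c) {
  std::vector<double> a(net.nc);
  double t = 0.0;
  for (;;) {
    double a0 = 0.0;
    for (int c = 0; c < net.nc; ++c) {
      a[c] = propensity(net, c, x, tmz);
      a0 += a[c];
    }
    if (a0 <= 0.0) return 0;
    t += R::rexp(1.0 / a0);
    if (t > window) return 0;
    double u = unif_rand() * a0;
    int c = 0;
    double cum = a[0];
    while (u > cum && c < net.nc - 1) cum += a[++c];
    if (log_t) { log_t->push_back(t); log_c->push_back(c); }
    if (net.is_death[c]) { death_time = t; return 1; }
    for (int s = 0; s < net.ns; ++s) x[s] += net.stoich(c, s);
    n_events += 1.0;
  }
}

// Fixed-step tau-leap over one window (n_sub leaps).  Poisson counts per
// channel per leap, propensities frozen at leap start.  Death is one
// more Poisson channel; if it fires the leap's other updates are
// discarded (the cell is dead).  Any negative species aborts the whole
// window: the caller restores the entry state and redoes it with SSA.
static int advance_tau(double* x, const Net& net, double tmz, double window,
                       int n_sub, double& death_time, double& n_events,
                       bool& negative) {
  negative = false;
  const double tau = window / n_sub;
  std::vector<double> a(net.nc);
  for (int l = 0; l < n_sub; ++l) {
    double adeath = 0.0;
    for (int c = 0; c < net.nc; ++c) {
      a[c] = propensity(net, c, x, tmz);
      if (net.is_death[c]) adeath += a[c];
    }
    if (adeath > 0.0 && R::rpois(adeath * tau) >= 1) {
      death_time = (l + 1) * tau;
      return 1;
    }
    for (int c = 0; c < net.nc; ++c) {
      if (net.is_death[c] || a[c] <= 0.0) continue;
      double n = R::rpois(a[c] * tau);
      if (n > 0) {
        for (int s = 0; s < net.ns; ++s) x[s] += n * net.stoich(c, s);
        n_events += n;
      }
    }
    for (int s = 0; s < net.ns; ++s) {
      if (x[s] < 0.0) { negative = true; return 0; }
    }
  }
  return 0;
}

// method: 0 = SSA, 1 = tau-leap with whole-window SSA fallback on
// negativity.  Returns (state, death_fired, death_time, n_events,
// fell_back[, events]).
// [[Rcpp::export]]
List advance_cell_cpp(NumericVector state, List net_list, double tmz,
                      double window, int method, int n_sub,
                      bool log_events = false) {
  Net net = unpack_net(net_list);
  if ((int) state.size() != net.ns) stop("state length != n species");
  std::vector<double> x(state.begin(), state.end());
  std::vector<double> entry(x);
  double death_time = NA_REAL, n_events = 0.0;
  bool fell_back = false;
  int died = 0;
  std::vector<double> log_t;
  std::vector<int> log_c;
  std::vector<double>* lt = log_events ? &log_t : (std::vector<double>*) 0;
  std::vector<int>* lc = log_events ? &log_c : (std::vector<int>*) 0;

  if (method == 0) {
    died = advance_ssa(x.data(), net, tmz, window, death_time, n_events,
                       lt, lc);
  } else {
    bool neg = false;
    died = advance_tau(x.data(), net, tmz, window, n_sub, death_time,
                       n_events, neg);
    if (neg) {
      fell_back = true;
      x = entry;
      n_events = 0.0;
      died = advance_ssa(x.data(), net, tmz, window, death_time, n_events,
                         lt, lc);
    }
  }
  List out = List::create(
    _["state"] = NumericVector(x.begin(), x.end()),
    _["death_fired"] = died == 1,
    _["death_time"] = death_time,
    _["n_events"] = n_events,
    _["fell_back"] = fell_back);
  if (log_events) {
    out["event_time"] = NumericVector(log_t.begin(), log_t.end());
    out["event_channel"] = IntegerVector(log_c.begin(), log_c.end());
  }
  return out;
}

// ---------------------------------------------------------------------
// Population layer

static inline double tmz_at_cpp(int kind, double dose, double t_in,
                                double t_out, double Q, double hill,
                                double t) {
  switch (kind) {
  case 0: return (t > t_in) ? dose : 0.0;                      // step
  case 1: return (t > t_in && t <= t_out) ? dose : 0.0;        // pulse
  case 2: {                                                    // sigmoid
    if (t <= 0.0) return 0.0;
    const double th = std::pow(t, hill);
    return dose * th / (std::pow(Q, hill) + th);
  }
  }
  return 0.0;
}

// Division-volume draw from the noisy linear map a*v + b + N(0, sigma1).
// In bounded mode the draw is the truncated normal on (lo, hi), sampled
// by inverse CDF (exactly the resampling distribution when the interval
// has mass; well-defined clamping when the map mean is far outside it).
static inline double draw_vf_cpp(double v, double a, double b, double sigma1,
                                 bool bounded, double lo, double hi) {
  const double m = a * v + b;
  if (!bounded) return (sigma1 > 0.0) ? R::rnorm(m, sigma1) : m;
  if (sigma1 <= 0.0) return std::min(std::max(m, lo), hi);
  const double plo = R::pnorm(lo, m, sigma1, 1, 0);
  const double phi = R::pnorm(hi, m, sigma1, 1, 0);
  if (phi - plo < 1e-12) return (m < lo) ? lo : hi;
  const double u = plo + unif_rand() * (phi - plo);
  return R::qnorm(u, m, sigma1, 1, 0);
}

static inline double draw_eta2(double sigma2) {
  if (sigma2 <= 0.0) return 0.5;
  for (;;) {  // redraw outside (0,1); preserves the symmetric mean 0.5
    double e = R::rnorm(0.5, sigma2);
    if (e > 0.0 && e < 1.0) return e;
  }
}

// Multi-scale loop: per outer step freeze tmz and volume, advance each
// live cell's reactions, remove cells whose death channel fired, grow
// volumes at the TMZ-inhibited exponential rate, and divide any cell at
// or past its division volume (daughter 1 keeps the slot, daughter 2
// displaces a random other slot).  policy: 0 = uniformly random among
// the K-1 other slots, 1 = dead slots first.
// [[Rcpp::export]]
List simulate_population_cpp(List net_list, List par, List sched,
                             NumericMatrix init_counts,
                             NumericVector init_vol, NumericVector init_vf,
                             LogicalVector init_alive,
                             double t0, double t_end, double outer_step,
                             int method, int n_sub, bool bounded_vf,
                             int policy, int record_every,
                             double snapshot_t) {
  Net net = unpack_net(net_list);
  const int K = init_counts.nrow();
  const int ns = net.ns;
  if (init_counts.ncol() != ns) stop("init_counts ncol != n species");

  const double mu0 = par["mu0"], I50 = par["I50"];
  const double sigma1 = par["sigma1"], sigma2 = par["sigma2"];
  const double a_map = par["a_map"], b_map = par["b_map"];
  const double vf_lo = par["vf_lo"], vf_hi = par["vf_hi"];

  const int skind = sched["kind"];
  const double dose = sched["dose"], s_tin = sched["t_in"];
  const double s_tout = sched["t_out"], Q = sched["Q"], hill = sched["hill"];

  const int n_steps = (int) std::lround((t_end - t0) / outer_step);

  std::vector<double> x(K * ns);
  for (int k = 0; k < K; ++k)
    for (int s = 0; s < ns; ++s) x[k * ns + s] = init_counts(k, s);
  std::vector<double> vol(init_vol.begin(), init_vol.end());
  std::vector<double> vf(init_vf.begin(), init_vf.end());
  std::vector<int> alive(K);
  for (int k = 0; k < K; ++k) alive[k] = init_alive[k] ? 1 : 0;
  std::vector<int> last_step(K, -1);

  const int n_rec = n_steps / record_every + 2;
  NumericVector rec_t(n_rec), rec_M(n_rec), rec_N(n_rec);
  NumericMatrix rec_means(n_rec, ns);
  NumericVector rec_ratio(n_rec);
  int ir = 0;
  double n_fallback = 0.0, n_divisions = 0.0, n_deaths = 0.0;

  NumericMatrix snap;           // taken at first recorded time >= snapshot_t
  double snap_time = NA_REAL;
  bool want_snap = R_finite(snapshot_t);

  // indices of MGMT protein column assumed by the network builder:
  // species order mRNA_MGMT, MGMT, mRNA_REF, REF [, DNA_DAM]
  auto record = [&](double t) {
    int M = 0;
    std::vector<double> mean_s(ns, 0.0);
    for (int k = 0; k < K; ++k) {
      if (!alive[k]) continue;
      ++M;
      for (int s = 0; s < ns; ++s) mean_s[s] += x[k * ns + s];
    }
    rec_t[ir] = t;
    rec_M[ir] = M;
    rec_N[ir] = (double) M / K;
    for (int s = 0; s < ns; ++s)
      rec_means(ir, s) = (M > 0) ? mean_s[s] / M : NA_REAL;
    // mean REF = 0 with MGMT present is unbounded upregulation (+Inf);
    // an empty or fully silent population has no defined ratio
    rec_ratio[ir] = (M == 0) ? NA_REAL
      : (mean_s[3] > 0.0) ? mean_s[1] / mean_s[3]
      : (mean_s[1] > 0.0) ? R_PosInf : NA_REAL;
    if (want_snap && t >= snapshot_t) {
      snap = NumericMatrix(M, ns + 1);
      int r = 0;
      for (int k = 0; k < K; ++k) {
        if (!alive[k]) continue;
        for (int s = 0; s < ns; ++s) snap(r, s) = x[k * ns + s];
        snap(r, ns) = vol[k];
        ++r;
      }
      snap_time = t;
      want_snap = false;
    }
    ++ir;
  };

  record(t0);
  for (int i = 0; i < n_steps; ++i) {
    const double t = t0 + i * outer_step;
    const double tmz = tmz_at_cpp(skind, dose, s_tin, s_tout, Q, hill, t);
    const double mu = mu0 / (1.0 + tmz / I50);
    const double gf = std::exp(mu * outer_step);
    for (int k = 0; k < K; ++k) {
      if (!alive[k] || last_step[k] == i) continue;
      last_step[k] = i;
      double* xk = &x[k * ns];
      double death_time = NA_REAL, nev = 0.0;
      int died;
      if (method == 0) {
        died = advance_ssa(xk, net, tmz, outer_step, death_time, nev, 0, 0);
      } else {
        std::vector<double> entry(xk, xk + ns);
        bool neg = false;
        died = advance_tau(xk, net, tmz, outer_step, n_sub, death_time,
                           nev, neg);
        if (neg) {
          n_fallback += 1.0;
          std::copy(entry.begin(), entry.end(), xk);
          died = advance_ssa(xk, net, tmz, outer_step, death_time, nev, 0, 0);
        }
      }
      if (died) {
        alive[k] = 0;
        n_deaths += 1.0;
        continue;
      }
      vol[k] *= gf;
      if (vol[k] >= vf[k]) {
        // division: binomial partitioning with probability eta2 to
        // daughter 1 (keeps the parent slot); non-partitioned species
        // (the binary gene-damage state) are copied to both daughters
        n_divisions += 1.0;
        const double VF = vol[k];
        const double eta2 = draw_eta2(sigma2);
        int j;
        bool placed = false;
        if (policy == 1) {
          int ndead = 0;
          for (int q = 0; q < K; ++q) ndead += (alive[q] == 0);
          if (ndead > 0) {
            int pick = (int) (unif_rand() * ndead);
            if (pick == ndead) pick = ndead - 1;
            j = 0;
            for (int q = 0; q < K; ++q) {
              if (!alive[q]) {
                if (pick == 0) { j = q; break; }
                --pick;
              }
            }
            placed = true;
          }
        }
        if (!placed) {
          j = (int) (unif_rand() * (K - 1));
          if (j >= K - 1) j = K - 2;
          if (j >= k) ++j;      // exclude the parent slot
        }
        double* xj = &x[j * ns];
        for (int s = 0; s < ns; ++s) {
          if (net.partition[s]) {
            double n1 = R::rbinom(xk[s], eta2);
            xj[s] = xk[s] - n1;
            xk[s] = n1;
          } else {
            xj[s] = xk[s];
          }
        }
        vol[k] = VF * eta2;
        vol[j] = VF * (1.0 - eta2);
        vf[k] = draw_vf_cpp(vol[k], a_map, b_map, sigma1, bounded_vf,
                            vf_lo, vf_hi);
        vf[j] = draw_vf_cpp(vol[j], a_map, b_map, sigma1, bounded_vf,
                            vf_lo, vf_hi);
        alive[j] = 1;
        last_step[j] = i;       // daughter 2 is done for this step
      }
    }
    if ((i + 1) % record_every == 0 || i == n_steps - 1) {
      record(t0 + (i + 1) * outer_step);
    }
  }

  NumericMatrix fin_counts(K, ns);
  for (int k = 0; k < K; ++k)
    for (int s = 0; s < ns; ++s) fin_counts(k, s) = x[k * ns + s];

  return List::create(
    _["t"] = rec_t[Range(0, ir - 1)],
    _["M"] = rec_M[Range(0, ir - 1)],
    _["N"] = rec_N[Range(0, ir - 1)],
    _["means"] = rec_means(Range(0, ir - 1), _),
    _["ratio"] = rec_ratio[Range(0, ir - 1)],
    _["counts"] = fin_counts,
    _["volume"] = NumericVector(vol.begin(), vol.end()),
    _["vf_target"] = NumericVector(vf.begin(), vf.end()),
    _["alive"] = LogicalVector(alive.begin(), alive.end()),
    _["snapshot"] = snap,
    _["snapshot_time"] = snap_time,
    _["n_fallback"] = n_fallback,
    _["n_divisions"] = n_divisions,
    _["n_deaths"] = n_deaths);
}
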