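#include <Rcpp.h>
using namespace Rcpp;

// Joint state of the single-receiver repeated game, ordered
//   0 = (c,t)  1 = (c,f)  2 = (n,t)  3 = (n,f)
// where the first index is the receiver's previous action (engage c / not n)
// and the second the true veracity of the previous story (t / f).
//
// Transmitter strategies are passed as the four evaluated action
// probabilities (r0t, r1t, r0f, r1f) = P(next story true | prev label, k)
// for k = 0, 1 engaged receivers (N = 1).  Receiver strategies are the
// seven-vector (a0, a1, p0, pct, pcf, pnt, pnf).

static inline double flip(double p, double e) { return (1.0 - e) * p + e * (1.0 - p); }

// Engagement probability q_ij^m: attention a0 to current veracity m,
// attention a1 to the memory component p_ij, baseline p0 otherwise.
static inline double qprob(const double *rcv, int i, int j, int m) {
  double a0 = rcv[0], a1 = rcv[1], p0 = rcv[2];
  double pij = rcv[3 + i * 2 + j];
  double dm = (m == 0) ? 1.0 : 0.0;
  return a0 * dm + (1.0 - a0) * (1.0 - a1) * p0 + (1.0 - a0) * a1 * pij;
}

// Row-stochastic one-round transition matrix.  From state (i,j): the
// transmitter recalls j but mislabels it with probability eta, applies its
// rule at k = 1{i==c}, and the chosen action is flipped with probability
// eps; the receiver's engagement draw from q is likewise eps-flipped.
static void build_T(double T[4][4], const double *tr, const double *rcv,
                    double eps, double eta) {
  const double rt[2] = {tr[0], tr[1]}, rf[2] = {tr[2], tr[3]};
  for (int s = 0; s < 4; ++s) {
    int i = s / 2;            // 0 = c, 1 = n
    int j = s % 2;            // 0 = t, 1 = f
    int k = (i == 0) ? 1 : 0; // engaged count last round
    double r_own = (j == 0) ? rt[k] : rf[k];
    double r_oth = (j == 0) ? rf[k] : rt[k];
    double ptrue = flip((1.0 - eta) * r_own + eta * r_oth, eps);
    for (int m = 0; m < 2; ++m) {
      double pm = (m == 0) ? ptrue : 1.0 - ptrue;
      double q = flip(qprob(rcv, i, j, m), eps);
      T[s][0 * 2 + m] = pm * q;         // to (c,m)
      T[s][1 * 2 + m] = pm * (1.0 - q); // to (n,m)
    }
  }
}

// Solve A x = b for 4x4 A by Gaussian elimination with partial pivoting.
static bool solve4(double A[4][4], double b[4], double x[4]) {
  int piv[4] = {0, 1, 2, 3};
  for (int c = 0; c < 4; ++c) {
    int best = c;
    for (int r = c + 1; r < 4; ++r)
      if (std::fabs(A[piv[r]][c]) > std::fabs(A[piv[best]][c])) best = r;
    std::swap(piv[c], piv[best]);
    double d = A[piv[c]][c];
    if (std::fabs(d) < 1e-13) return false;
    for (int r = c + 1; r < 4; ++r) {
      double f = A[piv[r]][c] / d;
      for (int cc = c; cc < 4; ++cc) A[piv[r]][cc] -= f * A[piv[c]][cc];
      b[piv[r]] -= f * b[piv[c]];
    }
  }
  for (int c = 3; c >= 0; --c) {
    double s = b[piv[c]];
    for (int cc = c + 1; cc < 4; ++cc) s -= A[piv[c]][cc] * x[cc];
    x[c] = s / A[piv[c]][c];
  }
  return true;
}

// Stationary distribution of a 4x4 row-stochastic matrix.  Direct linear
// solve of pi (T - I) = 0 with sum-to-one; if the system is singular
// (several recurrent classes, possible only at eps = 0) fall back to the
// Cesaro limit of power iteration started from the uniform distribution.
static void stationary(const double T[4][4], double v[4]) {
  double A[4][4], b[4] = {0.0, 0.0, 0.0, 1.0}, x[4];
  for (int r = 0; r < 4; ++r)
    for (int c = 0; c < 4; ++c) A[r][c] = T[c][r] - (r == c ? 1.0 : 0.0);
  for (int c = 0; c < 4; ++c) A[3][c] = 1.0;
  bool ok = solve4(A, b, x);
  if (ok) {
    double mn = 0.0, sum = 0.0;
    for (int c = 0; c < 4; ++c) { mn = std::min(mn, x[c]); sum += x[c]; }
    if (mn > -1e-9 && std::fabs(sum - 1.0) < 1e-6) {
      for (int c = 0; c < 4; ++c) v[c] = std::max(x[c], 0.0);
      double s2 = v[0] + v[1] + v[2] + v[3];
      for (int c = 0; c < 4; ++c) v[c] /= s2;
      return;
    }
  }
  // Cesaro power iteration from the uniform distribution.
  double cur[4] = {0.25, 0.25, 0.25, 0.25}, acc[4] = {0, 0, 0, 0};
  double prev[4] = {0.25, 0.25, 0.25, 0.25};
  long it = 0;
  const long maxit = 1000000;
  while (it < maxit) {
    for (int blk = 0; blk < 1000 && it < maxit; ++blk, ++it) {
      double nxt[4] = {0, 0, 0, 0};
      for (int s = 0; s < 4; ++s)
        for (int c = 0; c < 4; ++c) nxt[c] += cur[s] * T[s][c];
      for (int c = 0; c < 4; ++c) { cur[c] = nxt[c]; acc[c] += nxt[c]; }
    }
    double diff = 0.0;
    for (int c = 0; c < 4; ++c) {
      double m = acc[c] / (double)it;
      diff = std::max(diff, std::fabs(m - prev[c]));
      prev[c] = m;
    }
    if (diff < 1e-12) break;
  }
  double sum = 0.0;
  for (int c = 0; c < 4; ++c) sum += acc[c];
  for (int c = 0; c < 4; ++c) v[c] = acc[c] / sum;
}

// [[Rcpp::export]]
NumericMatrix cpp_transition(NumericVector trans, NumericVector rcv,
                             double eps, double eta) {
  double T[4][4];
  build_T(T, REAL(trans), REAL(rcv), eps, eta);
  NumericMatrix out(4, 4);
  for (int r = 0; r < 4; ++r)
    for (int c = 0; c < 4; ++c) out(r, c) = T[r][c];
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_stationary(NumericMatrix Tm) {
  double T[4][4], v[4];
  for (int r = 0; r < 4; ++r)
    for (int c = 0; c < 4; ++c) T[r][c] = Tm(r, c);
  stationary(T, v);
  return NumericVector::create(v[0], v[1], v[2], v[3]);
}

// Stationary outcome and receiver payoff for a given behavioural vector.
static void eval_receiver(const double *tr, const double *rcv, double eps,
                          double eta, double pit, double pif, double out[5]) {
  double T[4][4], v[4];
  build_T(T, tr, rcv, eps, eta);
  stationary(T, v);
  out[0] = v[0]; out[1] = v[1]; out[2] = v[2]; out[3] = v[3];
  out[4] = pit * v[0] + pif * v[1];
}

// Reflect x into [0,1].
static inline double reflect01(double x) {
  x = std::fabs(x);
  if (x > 1.0) x = 2.0 - x;
  if (x < 0.0) x = 0.0;
  if (x > 1.0) x = 1.0;
  return x;
}

// Propose a new value for one behavioural component: local symmetric step
// (uniform on +/- scale, reflected) or global uniform redraw.
static inline double propose_comp(double cur, double scale, bool global) {
  if (global) return unif_rand();
  return reflect01(cur + (2.0 * unif_rand() - 1.0) * scale);
}

// Myopic noisy optimization of the receiver's five behavioural components
// against a fixed transmitter (exact stationary payoffs, N = 1).
// [[Rcpp::export]]
List cpp_optimize_receiver(NumericVector trans, double a0, double a1,
                           NumericVector p_init, double pit, double pif,
                           double eps, double eta, double sigma, double scale,
                           bool global_prop, int burn, int meas,
                           int traj_thin) {
  const double *tr = REAL(trans);
  double rcv[7] = {a0, a1, p_init[0], p_init[1], p_init[2], p_init[3], p_init[4]};
  double cur[5];
  eval_receiver(tr, rcv, eps, eta, pit, pif, cur);
  int total = burn + meas;
  double acc[5] = {0, 0, 0, 0, 0};
  double pacc[5] = {0, 0, 0, 0, 0};
  int nrec = traj_thin > 0 ? total / traj_thin : 0;
  NumericMatrix traj(nrec, 7); // event, vtc, vfc, vtn, vfn, w, p-component mean
  int rec = 0;
  for (int it = 0; it < total; ++it) {
    int comp = (int)std::floor(unif_rand() * 5.0);
    if (comp > 4) comp = 4;
    double old = rcv[2 + comp];
    double cand_val = propose_comp(old, scale, global_prop);
    double cand[5];
    rcv[2 + comp] = cand_val;
    eval_receiver(tr, rcv, eps, eta, pit, pif, cand);
    double dw = sigma * (cur[4] - cand[4]);
    if (dw > 700.0) dw = 700.0;
    if (dw < -700.0) dw = -700.0;
    if (unif_rand() < 1.0 / (1.0 + std::exp(dw))) {
      for (int c = 0; c < 5; ++c) cur[c] = cand[c];
    } else {
      rcv[2 + comp] = old;
    }
    if (it >= burn) {
      for (int c = 0; c < 5; ++c) acc[c] += cur[c];
      for (int c = 0; c < 5; ++c) pacc[c] += rcv[2 + c];
    }
    if (traj_thin > 0 && (it + 1) % traj_thin == 0 && rec < nrec) {
      traj(rec, 0) = it + 1;
      for (int c = 0; c < 5; ++c) traj(rec, 1 + c) = cur[c];
      traj(rec, 6) = rcv[2];
      ++rec;
    }
  }
  NumericVector mean_v(4), mean_p(5), final_p(5);
  for (int c = 0; c < 4; ++c) mean_v[c] = acc[c] / meas;
  for (int c = 0; c < 5; ++c) mean_p[c] = pacc[c] / meas;
  for (int c = 0; c < 5; ++c) final_p[c] = rcv[2 + c];
  return List::create(_["mean_v"] = mean_v, _["mean_payoff"] = acc[4] / meas,
                      _["mean_p"] = mean_p, _["final_p"] = final_p,
                      _["trajectory"] = traj);
}

// Alternating co-optimization: one receiver update event then one
// transmitter update event per time-step.  Transmitter proposals perturb
// the four action probabilities (r0t, r1t, r0f, r1f) directly, so viability
// is preserved by construction.
// [[Rcpp::export]]
List cpp_co_optimize(NumericVector trans_init, double a0, double a1,
                     NumericVector p_init, double pit, double pif, double bt,
                     double bf, double eps, double eta, double sigma_R,
                     double scale_R, double sigma_T, double scale_T, int steps,
                     int burn) {
  double tr[4] = {trans_init[0], trans_init[1], trans_init[2], trans_init[3]};
  double rcv[7] = {a0, a1, p_init[0], p_init[1], p_init[2], p_init[3], p_init[4]};
  double cur[5];
  eval_receiver(tr, rcv, eps, eta, pit, pif, cur);
  double acc[4] = {0, 0, 0, 0};
  double wR_acc = 0.0, wT_acc = 0.0;
  int meas = 0;
  for (int it = 0; it < steps; ++it) {
    // receiver event
    int comp = (int)std::floor(unif_rand() * 5.0);
    if (comp > 4) comp = 4;
    double old = rcv[2 + comp];
    rcv[2 + comp] = propose_comp(old, scale_R, false);
    double cand[5];
    eval_receiver(tr, rcv, eps, eta, pit, pif, cand);
    double dw = sigma_R * (cur[4] - cand[4]);
    if (dw > 700.0) dw = 700.0;
    if (dw < -700.0) dw = -700.0;
    if (unif_rand() < 1.0 / (1.0 + std::exp(dw))) {
      for (int c = 0; c < 5; ++c) cur[c] = cand[c];
    } else {
      rcv[2 + comp] = old;
    }
    // transmitter event (payoff bt*vtc + bf*vfc)
    int tc = (int)std::floor(unif_rand() * 4.0);
    if (tc > 3) tc = 3;
    double oldt = tr[tc];
    double wT_cur = bt * cur[0] + bf * cur[1];
    tr[tc] = propose_comp(oldt, scale_T, false);
    eval_receiver(tr, rcv, eps, eta, pit, pif, cand);
    double wT_cand = bt * cand[0] + bf * cand[1];
    dw = sigma_T * (wT_cur - wT_cand);
    if (dw > 700.0) dw = 700.0;
    if (dw < -700.0) dw = -700.0;
    if (unif_rand() < 1.0 / (1.0 + std::exp(dw))) {
      for (int c = 0; c < 5; ++c) cur[c] = cand[c];
    } else {
      tr[tc] = oldt;
    }
    if (it >= burn) {
      for (int c = 0; c < 4; ++c) acc[c] += cur[c];
      wR_acc += cur[4];
      wT_acc += bt * cur[0] + bf * cur[1];
      ++meas;
    }
  }
  NumericVector mean_v(4), final_tr(4), final_p(5);
  for (int c = 0; c < 4; ++c) mean_v[c] = acc[c] / meas;
  for (int c = 0; c < 4; ++c) final_tr[c] = tr[c];
  for (int c = 0; c < 5; ++c) final_p[c] = rcv[2 + c];
  return List::create(_["mean_v"] = mean_v, _["mean_payoff_receiver"] = wR_acc / meas,
                      _["mean_payoff_transmitter"] = wT_acc / meas,
                      _["final_transmitter"] = final_tr, _["final_p"] = final_p);
}

// Direct simulation of T rounds with N receivers holding fixed strategies.
// rt, rf give P(next true | label, k) for k = 0..N; rcv is N x 7.
// [[Rcpp::export]]
List cpp_simulate_rounds(NumericVector rt, NumericVector rf, NumericMatrix rcv,
                         double eps, double eta, int T) {
  int N = rcv.nrow();
  IntegerVector veracity(T), kcount(T);
  IntegerMatrix counts(N, 4); // tc, fc, tn, fn per receiver
  std::vector<int> istate(N, 1); // start not engaged
  int jprev = 0;                 // previous story true
  int k = 0;
  for (int t = 0; t < T; ++t) {
    int jperc = (unif_rand() < eta) ? 1 - jprev : jprev;
    double r = (jperc == 0) ? rt[k] : rf[k];
    double ptrue = flip(r, eps);
    int m = (unif_rand() < ptrue) ? 0 : 1;
    int knew = 0;
    for (int n = 0; n < N; ++n) {
      double rc[7];
      for (int c = 0; c < 7; ++c) rc[c] = rcv(n, c);
      double q = flip(qprob(rc, istate[n], jprev, m), eps);
      int eng = (unif_rand() < q) ? 1 : 0;
      knew += eng;
      counts(n, (eng ? 0 : 2) + m) += 1; // 0 tc, 1 fc, 2 tn, 3 fn
      istate[n] = eng ? 0 : 1;
    }
    veracity[t] = m;
    kcount[t] = knew;
    jprev = m;
    k = knew;
  }
  return List::create(_["veracity"] = veracity, _["k"] = kcount,
                      _["counts"] = counts);
}

// Population-level optimization used for the sigmoid demonstration: N
// receivers share one behavioural strategy; per epoch the game runs E
// recorded rounds, then a candidate strategy is scored on E unrecorded
// rounds (simulated from a copy of the game state) and adopted via the
// Fermi rule.
// [[Rcpp::export]]
List cpp_population_optimize(NumericVector rt, NumericVector rf, int N,
                             double a0, double a1, NumericVector p_init,
                             double pit, double pif, double eps, double eta,
                             double sigma, double scale, int epochs,
                             int rounds_per_epoch) {
  double rcv[7] = {a0, a1, p_init[0], p_init[1], p_init[2], p_init[3], p_init[4]};
  std::vector<int> istate(N, 1);
  int jprev = 0, k = 0;
  int T = epochs * rounds_per_epoch;
  IntegerVector veracity(T), kcount(T);
  NumericVector p0_series(epochs);
  double eng_true = 0.0, eng_false = 0.0; // receiver-round engagement sums
  double n_true = 0.0, n_false = 0.0;     // story counts by veracity
  int t = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    double w_cur = 0.0;
    for (int e = 0; e < rounds_per_epoch; ++e, ++t) {
      int jperc = (unif_rand() < eta) ? 1 - jprev : jprev;
      double r = (jperc == 0) ? rt[k] : rf[k];
      int m = (unif_rand() < flip(r, eps)) ? 0 : 1;
      int knew = 0;
      for (int n = 0; n < N; ++n) {
        double q = flip(qprob(rcv, istate[n], jprev, m), eps);
        int eng = (unif_rand() < q) ? 1 : 0;
        knew += eng;
        istate[n] = eng ? 0 : 1;
      }
      w_cur += (double)knew * ((m == 0) ? pit : pif);
      if (m == 0) { n_true += 1.0; eng_true += knew; }
      else        { n_false += 1.0; eng_false += knew; }
      veracity[t] = m; kcount[t] = knew;
      jprev = m; k = knew;
    }
    w_cur /= (double)(rounds_per_epoch * N);
    // candidate scored on a hypothetical continuation from the same state
    int comp = (int)std::floor(unif_rand() * 5.0);
    if (comp > 4) comp = 4;
    double cand_rcv[7];
    for (int c = 0; c < 7; ++c) cand_rcv[c] = rcv[c];
    cand_rcv[2 + comp] = propose_comp(rcv[2 + comp], scale, false);
    std::vector<int> ist2 = istate;
    int j2 = jprev, k2 = k;
    double w_cand = 0.0;
    for (int e = 0; e < rounds_per_epoch; ++e) {
      int jperc = (unif_rand() < eta) ? 1 - j2 : j2;
      double r = (jperc == 0) ? rt[k2] : rf[k2];
      int m = (unif_rand() < flip(r, eps)) ? 0 : 1;
      int knew = 0;
      for (int n = 0; n < N; ++n) {
        double q = flip(qprob(cand_rcv, ist2[n], j2, m), eps);
        int eng = (unif_rand() < q) ? 1 : 0;
        knew += eng;
        ist2[n] = eng ? 0 : 1;
      }
      w_cand += (double)knew * ((m == 0) ? pit : pif);
      j2 = m; k2 = knew;
    }
    w_cand /= (double)(rounds_per_epoch * N);
    double dw = sigma * (w_cur - w_cand);
    if (dw > 700.0) dw = 700.0;
    if (dw < -700.0) dw = -700.0;
    if (unif_rand() < 1.0 / (1.0 + std::exp(dw)))
      for (int c = 0; c < 7; ++c) rcv[c] = cand_rcv[c];
    p0_series[ep] = rcv[2];
  }
  return List::create(
      _["veracity"] = veracity, _["k"] = kcount, _["p0_series"] = p0_series,
      _["engage_per_true"] = n_true > 0 ? eng_true / (n_true * N) : NA_REAL,
      _["engage_per_false"] = n_false > 0 ? eng_false / (n_false * N) : NA_REAL,
      _["n_true"] = n_true, _["n_false"] = n_false);
}

// Story sequence for the engagement-accuracy regression experiments: a
// fixed transmitter strategy plays against a population of receivers
// sharing one behavioural strategy. The population's memory-state
// distribution (fraction who engaged with the previous story) evolves
// deterministically up to one binomial draw per story, and the realized
// engaged fraction drives the transmitter's feedback for the next story.
// Between stories the shared receiver strategy continues its myopic noisy
// optimization (updates_per_story Fermi update events on the exact chain),
// reflecting the game's two-timescale structure.
// [[Rcpp::export]]
List cpp_story_sequence(NumericVector trans, NumericVector rcv_in, double eps,
                        double eta, int n_stories, int population,
                        bool realized_rate, int updates_per_story,
                        double pit, double pif, double sigma, double scale) {
  const double *tr = REAL(trans);
  double rcv[7];
  for (int c = 0; c < 7; ++c) rcv[c] = rcv_in[c];
  double cur[5];
  eval_receiver(tr, rcv, eps, eta, pit, pif, cur);
  int j = 0;             // previous story true
  double wc = 0.0;       // fraction of receivers who engaged with it
  double x_prev = 0.0;   // realized engaged fraction of previous story
  IntegerVector veracity(n_stories);
  NumericVector acc_perc(n_stories), rate(n_stories), qexp(n_stories);
  for (int s = 0; s < n_stories; ++s) {
    int jperc = (unif_rand() < eta) ? 1 - j : j;
    // linear interpolation between the k = 0 and k = 1 action probabilities
    // evaluates the linear feedback rule at fractional engagement x.
    double r = (jperc == 0) ? (tr[0] + (tr[1] - tr[0]) * x_prev)
                            : (tr[2] + (tr[3] - tr[2]) * x_prev);
    int m = (unif_rand() < flip(r, eps)) ? 0 : 1;
    // population engagement probability: engaged and non-engaged receivers
    // apply their respective memory components
    double q = wc * flip(qprob(rcv, 0, j, m), eps) +
               (1.0 - wc) * flip(qprob(rcv, 1, j, m), eps);
    double count = R::rbinom((double)population, q);
    double xr = count / (double)population;
    veracity[s] = m;
    qexp[s] = q;
    rate[s] = realized_rate ? xr : q;
    acc_perc[s] = ((m == 0) ? 1.0 : 0.0);
    if (unif_rand() < eta) acc_perc[s] = 1.0 - acc_perc[s];
    wc = xr;
    j = m;
    x_prev = xr;
    for (int u = 0; u < updates_per_story; ++u) {
      int comp = (int)std::floor(unif_rand() * 5.0);
      if (comp > 4) comp = 4;
      double old = rcv[2 + comp];
      rcv[2 + comp] = propose_comp(old, scale, false);
      double cand[5];
      eval_receiver(tr, rcv, eps, eta, pit, pif, cand);
      double dw = sigma * (cur[4] - cand[4]);
      if (dw > 700.0) dw = 700.0;
      if (dw < -700.0) dw = -700.0;
      if (unif_rand() < 1.0 / (1.0 + std::exp(dw))) {
        for (int c = 0; c < 5; ++c) cur[c] = cand[c];
      } else {
        rcv[2 + comp] = old;
      }
    }
  }
  return List::create(_["veracity"] = veracity, _["perceived_accuracy"] = acc_perc,
                      _["engagement_rate"] = rate, _["expected_q"] = qexp);
}
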