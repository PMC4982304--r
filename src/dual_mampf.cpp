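// Dual MAM-PF core: two one-dimensional particle spaces (respiratory and
// cardiac instantaneous frequency), each particle carrying a marginalized
// extended Kalman filter over the flattened sinusoidal-coefficient vector,
// with per-step Viterbi-style ancestor search and MAP state extraction.
//
// Coefficient layout (must match coef_layout() on the R side):
//   [ r1(1..nr) | r2(1..nr) | c1(1..nc) | c2(1..nc) |
//     m1(k outer, j inner)  | m2(k outer, j inner) ]

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;

static inline double wrap_angle(double th) {
  th -= TWO_PI * std::floor(th / TWO_PI);
  if (th >= TWO_PI) th = 0.0;  // guard against floor rounding
  return th;
}

// signed angular difference a - b wrapped to (-pi, pi]
static inline double ang_diff(double a, double b) {
  double d = a - b;
  d -= TWO_PI * std::floor(d / TWO_PI);
  if (d > TWO_PI / 2) d -= TWO_PI;
  return d;
}

static inline double clip_reflect(double f, double lo, double hi) {
  if (f > hi) f = 2.0 * hi - f;
  else if (f <= lo) f = 2.0 * lo - f;
  if (f > hi || f < lo) {
    stop("frequency overshoot beyond one reflection; "
         "frequency noise variance is probably mis-scaled");
  }
  return f;
}

struct Layout {
  int nr, nc, d;
  Layout(int nc_, int nr_) : nr(nr_), nc(nc_) {
    d = 2 * nr + 2 * nc + 2 * nc * nr;
  }
  inline int r1(int j) const { return j; }              // j in 0..nr-1
  inline int r2(int j) const { return nr + j; }
  inline int c1(int k) const { return 2 * nr + k; }     // k in 0..nc-1
  inline int c2(int k) const { return 2 * nr + nc + k; }
  inline int m1(int k, int j) const { return 2 * nr + 2 * nc + k * nr + j; }
  inline int m2(int k, int j) const {
    return 2 * nr + 2 * nc + nc * nr + k * nr + j;
  }
};

// noise-free measurement mean with decomposition
static double measure_parts(double th_r, double th_c, const arma::vec& x,
                            const Layout& L, double* gamma_out,
                            arma::vec* rho_out, arma::vec* kappa_out) {
  double gamma = 0.0;
  arma::vec cr(L.nr), sr(L.nr);
  for (int j = 0; j < L.nr; ++j) {
    cr[j] = std::cos((j + 1) * th_r);
    sr[j] = std::sin((j + 1) * th_r);
    gamma += x[L.r1(j)] * cr[j] + x[L.r2(j)] * sr[j];
  }
  double y = gamma;
  for (int k = 0; k < L.nc; ++k) {
    double kappa = x[L.c1(k)] * std::cos((k + 1) * th_c) +
                   x[L.c2(k)] * std::sin((k + 1) * th_c);
    double rho = 1.0;
    for (int j = 0; j < L.nr; ++j) {
      rho += x[L.m1(k, j)] * cr[j] + x[L.m2(k, j)] * sr[j];
    }
    y += rho * kappa;
    if (rho_out) (*rho_out)[k] = rho;
    if (kappa_out) (*kappa_out)[k] = kappa;
  }
  if (gamma_out) *gamma_out = gamma;
  return y;
}

// gradient of the measurement mean in the flattened coefficients
static void gradient(double th_r, double th_c, const arma::vec& x,
                     const Layout& L, arma::vec& H) {
  arma::vec cr(L.nr), sr(L.nr);
  for (int j = 0; j < L.nr; ++j) {
    cr[j] = std::cos((j + 1) * th_r);
    sr[j] = std::sin((j + 1) * th_r);
    H[L.r1(j)] = cr[j];
    H[L.r2(j)] = sr[j];
  }
  for (int k = 0; k < L.nc; ++k) {
    double ck = std::cos((k + 1) * th_c);
    double sk = std::sin((k + 1) * th_c);
    double kappa = x[L.c1(k)] * ck + x[L.c2(k)] * sk;
    double rho = 1.0;
    for (int j = 0; j < L.nr; ++j) {
      rho += x[L.m1(k, j)] * cr[j] + x[L.m2(k, j)] * sr[j];
    }
    H[L.c1(k)] = rho * ck;
    H[L.c2(k)] = rho * sk;
    for (int j = 0; j < L.nr; ++j) {
      H[L.m1(k, j)] = kappa * cr[j];
      H[L.m2(k, j)] = kappa * sr[j];
    }
  }
}

// EKF measurement update (Joseph-form covariance); returns the Gaussian
// log-likelihood of the innovation
static double ekf_update(arma::vec& mean, arma::mat& P, double th_r,
                         double th_c, double y, double r, const Layout& L,
                         double* innov_out, bool freeze_mod = false) {
  arma::vec H(L.d);
  gradient(th_r, th_c, mean, L, H);
  if (freeze_mod) {
    for (int k = 0; k < L.nc; ++k) {
      for (int j = 0; j < L.nr; ++j) {
        H[L.m1(k, j)] = 0.0;
        H[L.m2(k, j)] = 0.0;
      }
    }
  }
  double yhat = measure_parts(th_r, th_c, mean, L, nullptr, nullptr, nullptr);
  double innov = y - yhat;
  arma::vec PH = P * H;
  double S = arma::dot(H, PH) + r;
  if (S <= 0.0 || !std::isfinite(S)) {
    // covariance repair: re-symmetrize and floor eigenvalues at zero
    P = arma::symmatu(0.5 * (P + P.t()));
    arma::vec eigval;
    arma::mat eigvec;
    if (!arma::eig_sym(eigval, eigvec, P)) {
      stop("EKF covariance repair failed (eigendecomposition)");
    }
    eigval.transform([](double v) { return v < 0.0 ? 0.0 : v; });
    P = eigvec * arma::diagmat(eigval) * eigvec.t();
    PH = P * H;
    S = arma::dot(H, PH) + r;
    if (S <= 0.0 || !std::isfinite(S)) {
      stop("EKF innovation variance not positive after covariance repair");
    }
  }
  arma::vec K = PH / S;
  mean += K * innov;
  // Joseph form expanded: P - K (HP) - (HP)' K' + S K K'
  P -= K * PH.t() + PH * K.t() - S * (K * K.t());
  P = 0.5 * (P + P.t());
  if (innov_out) *innov_out = innov;
  return -0.5 * std::log(TWO_PI * S) - 0.5 * innov * innov / S;
}

// log transition density N(f_new; fbar_old + ar (f_old - fbar_old), q)
static inline double trans_logdens(double f_new, double f_old,
                                   double fbar_old, double ar, double q) {
  double mu = fbar_old + ar * (f_old - fbar_old);
  double dx = f_new - mu;
  if (q <= 0.0) return (std::abs(dx) < 1e-300) ? 0.0 : -1e30;
  return -0.5 * std::log(TWO_PI * q) - 0.5 * dx * dx / q;
}

//' Measurement mean and decomposition (C++ path)
//'
//' Internal single-sample version of the measurement model used inside the
//' tracker; exported for cross-checking against the R implementation.
//'
//' @param theta_r,theta_c angles (radians).
//' @param x flattened coefficient vector.
//' @param n_card,n_resp harmonic counts.
//' @return List with `y`, `gamma`, `rho`, `kappa`.
//' @keywords internal
// [[Rcpp::export]]
List cpp_measure(double theta_r, double theta_c, arma::vec x, int n_card,
                 int n_resp) {
  Layout L(n_card, n_resp);
  if ((int)x.n_elem != L.d) stop("coefficient vector has wrong length");
  double gamma;
  arma::vec rho(L.nc), kappa(L.nc);
  double y = measure_parts(theta_r, theta_c, x, L, &gamma, &rho, &kappa);
  return List::create(_["y"] = y, _["gamma"] = gamma, _["rho"] = rho,
                      _["kappa"] = kappa);
}

//' Measurement gradient (C++ path)
//' @inheritParams cpp_measure
//' @return Length-`d` gradient vector.
//' @keywords internal
// [[Rcpp::export]]
arma::vec cpp_gradient(double theta_r, double theta_c, arma::vec x,
                       int n_card, int n_resp) {
  Layout L(n_card, n_resp);
  if ((int)x.n_elem != L.d) stop("coefficient vector has wrong length");
  arma::vec H(L.d);
  gradient(theta_r, theta_c, x, L, H);
  return H;
}

//' EKF measurement update (C++ path)
//'
//' The exact update used per particle inside the tracker: innovation
//' against the linearized measurement, Kalman gain, Joseph-form covariance
//' update, Gaussian innovation log-likelihood.
//'
//' @param mean,P prior coefficient mean and covariance.
//' @param theta_r,theta_c fixed angles at the measurement time.
//' @param y measured (mean-centered) signal value.
//' @param r measurement noise variance.
//' @param n_card,n_resp harmonic counts.
//' @return List with posterior `mean`, `cov`, `loglik`, `innovation`, `S`.
//' @keywords internal
// [[Rcpp::export]]
List cpp_ekf_update(arma::vec mean, arma::mat P, double theta_r,
                    double theta_c, double y, double r, int n_card,
                    int n_resp) {
  Layout L(n_card, n_resp);
  if ((int)mean.n_elem != L.d || (int)P.n_rows != L.d || (int)P.n_cols != L.d)
    stop("mean/covariance dimensions inconsistent with the harmonic counts");
  arma::vec H(L.d);
  gradient(theta_r, theta_c, mean, L, H);
  arma::vec PH = P * H;
  double S = arma::dot(H, PH) + r;
  double innov;
  double ll = ekf_update(mean, P, theta_r, theta_c, y, r, L, &innov);
  return List::create(_["mean"] = mean, _["cov"] = P, _["loglik"] = ll,
                      _["innovation"] = innov, _["S"] = S);
}

//' Ancestor search (C++ path)
//'
//' For each proposed particle frequency, the best previous trajectory
//' maximizes accumulated MAP score plus Gaussian transition log-density;
//' ties break toward the lowest index.
//'
//' @param log_alpha previous accumulated (normalized) log scores.
//' @param f_prop proposed instantaneous frequencies at time n.
//' @param f_prev,fbar_prev previous instantaneous and mean frequencies.
//' @param ar autoregressive coefficient.
//' @param q frequency process noise variance.
//' @return 1-based ancestor index per proposed particle.
//' @keywords internal
// [[Rcpp::export]]
IntegerVector cpp_search_ancestors(arma::vec log_alpha, arma::vec f_prop,
                                   arma::vec f_prev, arma::vec fbar_prev,
                                   double ar, double q) {
  int np = f_prop.n_elem;
  int na = log_alpha.n_elem;
  if ((int)f_prev.n_elem != na || (int)fbar_prev.n_elem != na)
    stop("ancestor arrays must have equal length");
  IntegerVector out(np);
  for (int i = 0; i < np; ++i) {
    int best = 0;
    double best_score = -arma::datum::inf;
    for (int k = 0; k < na; ++k) {
      double s = log_alpha[k] +
        trans_logdens(f_prop[i], f_prev[k], fbar_prev[k], ar, q);
      if (s > best_score) {
        best_score = s;
        best = k;
      }
    }
    out[i] = best + 1;
  }
  return out;
}

struct Space {
  int np;
  double f_min, f_max, q_freq;
  arma::vec f, fbar, theta, log_alpha;
  arma::mat means;   // d x np
  arma::cube covs;   // d x d x np
  arma::mat cov0;    // initial prior covariance (respawn reset)
  int rejuv_counter = 0;
  int rejuv_events = 0;
};

static void init_space(Space& sp, const List& li, int d) {
  sp.f = as<arma::vec>(li["f"]);
  sp.fbar = as<arma::vec>(li["fbar"]);
  sp.theta = as<arma::vec>(li["theta"]);
  sp.log_alpha = as<arma::vec>(li["log_alpha"]);
  sp.means = as<arma::mat>(li["means"]);
  {
    // deep copy: as<arma::cube> aliases the R array memory, and the
    // filter must never mutate its caller's state
    NumericVector cv = li["covs"];
    IntegerVector dm = cv.attr("dim");
    sp.covs = arma::cube(cv.begin(), dm[0], dm[1], dm[2], true);
  }
  sp.cov0 = sp.covs.slice(0);
  sp.np = sp.f.n_elem;
  if ((int)sp.means.n_rows != d || (int)sp.means.n_cols != sp.np ||
      (int)sp.covs.n_rows != d || (int)sp.covs.n_slices != sp.np ||
      (int)sp.fbar.n_elem != sp.np || (int)sp.theta.n_elem != sp.np ||
      (int)sp.log_alpha.n_elem != sp.np) {
    stop("initial particle arrays have inconsistent dimensions");
  }
}

// advance one space by one sample; returns the logsumexp normalizer
static double step_space(Space& sp, double y_n, double th_oth, double f_oth,
                         bool space_is_resp, double ts, double ar, double r,
                         double discount, const arma::vec& qdiag,
                         const Layout& L,
                         const double* nz_fbar, const double* nz_f,
                         bool rejuv_enabled, double rejuv_gap,
                         int rejuv_steps, double* f_post_mean,
                         bool freeze_mod_in_resp = false) {
  int np = sp.np;
  arma::vec f_old = sp.f, fbar_old = sp.fbar, theta_old = sp.theta;
  arma::vec f_new(np), fbar_new(np), theta_new(np), score(np);
  // each particle proposes its next instantaneous frequency from its own
  // previous state; angle and mean frequency follow the ancestor selected
  // below, so that the whole trajectory (and the phase-locked coefficient
  // state inherited with it) stays self-consistent
  for (int i = 0; i < np; ++i) {
    f_new[i] = clip_reflect(
      fbar_old[i] + ar * (f_old[i] - fbar_old[i]) + nz_f[i],
      sp.f_min, sp.f_max);
  }
  // ancestor search + coefficient inheritance + EKF update
  arma::mat means_old = sp.means;
  arma::cube covs_old = sp.covs;
  arma::vec mu(np);
  for (int k = 0; k < np; ++k) {
    mu[k] = fbar_old[k] + ar * (f_old[k] - fbar_old[k]);
  }
  for (int i = 0; i < np; ++i) {
    int kstar = 0;
    double best = -arma::datum::inf;
    for (int k = 0; k < np; ++k) {
      double dx = f_new[i] - mu[k];
      double s;
      if (sp.q_freq > 0.0) {
        s = discount * sp.log_alpha[k] - 0.5 * dx * dx / sp.q_freq;
      } else {
        s = discount * sp.log_alpha[k] +
          ((std::abs(dx) < 1e-300) ? 0.0 : -1e30);
      }
      if (s > best) { best = s; kstar = k; }
    }
    double tld = trans_logdens(f_new[i], f_old[kstar], fbar_old[kstar], ar,
                               sp.q_freq);
    theta_new[i] = wrap_angle(theta_old[kstar] + TWO_PI * ts * f_old[kstar]);
    fbar_new[i] = clip_reflect(fbar_old[kstar] + nz_fbar[i],
                               sp.f_min, sp.f_max);
    arma::vec mean_i = means_old.col(kstar);
    arma::mat P_i = covs_old.slice(kstar);
    P_i.diag() += qdiag;
    double th_r = space_is_resp ? theta_new[i] : th_oth;
    double th_c = space_is_resp ? th_oth : theta_new[i];
    double ll = ekf_update(mean_i, P_i, th_r, th_c, y_n, r, L, nullptr,
                           space_is_resp && freeze_mod_in_resp);
    sp.means.col(i) = mean_i;
    sp.covs.slice(i) = P_i;
    score[i] = discount * sp.log_alpha[kstar] + tld + ll;
  }
  (void)f_oth;
  // normalize scores (logsumexp -> 0)
  double mx = score.max();
  if (!std::isfinite(mx)) {
    stop("degenerate filter: all particle scores are -Inf "
         "(check noise variances and signal scaling)");
  }
  double lse = mx + std::log(arma::sum(arma::exp(score - mx)));
  sp.log_alpha = score - lse;
  sp.f = f_new;
  sp.fbar = fbar_new;
  sp.theta = theta_new;
  // rejuvenation: re-spread chronically starved particles
  if (rejuv_enabled && np >= 10) {
    double gap = sp.log_alpha.max() - arma::median(sp.log_alpha);
    if (gap > rejuv_gap) sp.rejuv_counter++;
    else sp.rejuv_counter = 0;
    if (sp.rejuv_counter >= rejuv_steps) {
      int nlow = np / 10;
      if (nlow < 1) nlow = 1;
      arma::uvec ord = arma::sort_index(sp.log_alpha);  // ascending
      arma::uword ibest = sp.log_alpha.index_max();
      // respawned particles re-enter at the bottom of the kept scores and
      // must earn their ranking through better fit; their covariance is
      // reset to the initial prior so the coefficient state re-adapts to
      // the new frequency hypothesis quickly
      double respawn = sp.log_alpha[ord[nlow]];
      for (int s = 0; s < nlow; ++s) {
        arma::uword i = ord[s];
        double frac = (nlow == 1) ? 0.5 : (double)s / (double)(nlow - 1);
        double fnew = sp.f_min + frac * (sp.f_max - sp.f_min);
        if (fnew <= sp.f_min) fnew = sp.f_min + 1e-9 * (sp.f_max - sp.f_min);
        sp.f[i] = fnew;
        sp.fbar[i] = fnew;
        sp.theta[i] = sp.theta[ibest];
        sp.means.col(i) = sp.means.col(ibest);
        sp.covs.slice(i) = sp.cov0;
        sp.log_alpha[i] = respawn;
      }
      double m2 = sp.log_alpha.max();
      double lse2 = m2 + std::log(arma::sum(arma::exp(sp.log_alpha - m2)));
      sp.log_alpha -= lse2;
      sp.rejuv_counter = 0;
      sp.rejuv_events++;
    }
  }
  if (f_post_mean) {
    *f_post_mean = arma::dot(arma::exp(sp.log_alpha), sp.f);
  }
  return lse;
}

//' Dual MAM-PF tracking loop (C++ core)
//'
//' Runs the full per-sample recursion over a mean-centered signal:
//' kinematic propagation, ancestor search, coefficient inheritance, EKF
//' update and per-space normalization, then MAP extraction across the two
//' spaces.  All randomness enters through the pre-generated noise
//' matrices, so the run is a deterministic function of its inputs.
//'
//' @param y mean-centered signal samples.
//' @param cfg list of resolved scalar configuration values.
//' @param init initial filter state (per-space particle arrays and the
//'   frozen other-space kinematics used at the first sample).
//' @param nz_fbar_resp,nz_f_resp,nz_fbar_card,nz_f_card `np x NT` noise
//'   matrices for the mean-frequency and instantaneous-frequency walks.
//' @param return_particles also return the final per-particle state.
//' @return List of per-sample MAP traces and diagnostics.
//' @keywords internal
// [[Rcpp::export]]
List cpp_dual_mampf(arma::vec y, List cfg, List init,
                    arma::mat nz_fbar_resp, arma::mat nz_f_resp,
                    arma::mat nz_fbar_card, arma::mat nz_f_card,
                    bool return_particles = false) {
  int nc = as<int>(cfg["n_cardiac_harmonics"]);
  int nr = as<int>(cfg["n_resp_harmonics"]);
  double ts = as<double>(cfg["sample_period"]);
  double r = as<double>(cfg["meas_noise_var"]);
  double ar = as<double>(cfg["ar_coeff"]);
  double discount = as<double>(cfg["score_discount"]);
  double ref_phase_gain = as<double>(cfg["ref_phase_gain"]);
  bool freeze_mod_resp = cfg.containsElementNamed("freeze_mod_resp") ?
    as<bool>(cfg["freeze_mod_resp"]) : false;
  double ref_freq_gain = as<double>(cfg["ref_freq_gain"]);
  bool rejuv_enabled = as<bool>(cfg["rejuv_enabled"]);
  double rejuv_gap = as<double>(cfg["rejuv_gap"]);
  int rejuv_steps = as<int>(cfg["rejuv_steps"]);
  Layout L(nc, nr);

  Space resp, card;
  init_space(resp, init["resp"], L.d);
  init_space(card, init["card"], L.d);
  resp.f_min = as<double>(cfg["f_resp_min"]);
  resp.f_max = as<double>(cfg["f_resp_max"]);
  resp.q_freq = as<double>(cfg["q_freq_resp"]);
  card.f_min = as<double>(cfg["f_card_min"]);
  card.f_max = as<double>(cfg["f_card_max"]);
  card.q_freq = as<double>(cfg["q_freq_card"]);

  arma::vec qdiag(L.d);
  double q_r = as<double>(cfg["q_resp_coeff"]);
  double q_c = as<double>(cfg["q_card_coeff"]);
  double q_m = as<double>(cfg["q_mod_coeff"]);
  for (int j = 0; j < nr; ++j) { qdiag[L.r1(j)] = q_r; qdiag[L.r2(j)] = q_r; }
  for (int k = 0; k < nc; ++k) { qdiag[L.c1(k)] = q_c; qdiag[L.c2(k)] = q_c; }
  for (int k = 0; k < nc; ++k) {
    for (int j = 0; j < nr; ++j) {
      qdiag[L.m1(k, j)] = q_m;
      qdiag[L.m2(k, j)] = q_m;
    }
  }

  int NT = y.n_elem;
  if ((int)nz_fbar_resp.n_rows != resp.np || (int)nz_fbar_resp.n_cols != NT ||
      (int)nz_f_resp.n_rows != resp.np || (int)nz_f_resp.n_cols != NT ||
      (int)nz_fbar_card.n_rows != card.np || (int)nz_fbar_card.n_cols != NT ||
      (int)nz_f_card.n_rows != card.np || (int)nz_f_card.n_cols != NT) {
    stop("noise matrices must be np x NT");
  }

  // Dual-estimation contract: each space conditions on the opposite
  // space's *frequency* estimate.  The shared ("frozen") angle references
  // integrate the MAP frequencies continuously; a smooth reference angle
  // is essential because any fixed phase offset is absorbed by the
  // coefficient estimates, whereas reference-phase jumps (as would happen
  // if the raw MAP particle's angle were used, since MAP switches between
  // phase-divergent particles) poison every particle's Kalman state.
  List frozen = init["frozen"];
  double froz_f_resp = as<double>(frozen["f_resp"]);
  double froz_th_resp = as<double>(frozen["theta_resp"]);
  double froz_f_card = as<double>(frozen["f_card"]);
  double froz_th_card = as<double>(frozen["theta_card"]);
  double froz_th_resp_cum = froz_th_resp;  // unwrapped respiratory clock

  double cum_ev_resp = 0.0, cum_ev_card = 0.0;  // discounted evidence
  arma::vec out_fr(NT), out_fc(NT), out_thr(NT), out_thc(NT);
  arma::vec out_thr_used(NT), out_thc_used(NT), out_thr_clock(NT);
  arma::vec out_yhat(NT), out_gamma(NT), out_innov(NT);
  arma::vec out_la1(NT), out_la2(NT), ev1(NT), ev2(NT);
  IntegerVector out_winner(NT);
  arma::mat out_coef(NT, L.d);
  arma::mat out_coef_resp(NT, L.d), out_coef_card(NT, L.d);

  for (int n = 0; n < NT; ++n) {
    if (n > 0) {
      // advance the frozen references with the previous MAP frequencies
      froz_th_card = wrap_angle(froz_th_card + TWO_PI * ts * froz_f_card);
      froz_th_resp = wrap_angle(froz_th_resp + TWO_PI * ts * froz_f_resp);
      froz_th_resp_cum += TWO_PI * ts * froz_f_resp;
    }
    // respiratory space first, then cardiac (fixed order)
    double fpm_resp, fpm_card;
    ev1[n] = step_space(resp, y[n], froz_th_card, froz_f_card, true,
                        ts, ar, r, discount, qdiag, L,
                        nz_fbar_resp.colptr(n), nz_f_resp.colptr(n),
                        rejuv_enabled, rejuv_gap, rejuv_steps, &fpm_resp,
                        freeze_mod_resp);
    ev2[n] = step_space(card, y[n], froz_th_resp, froz_f_resp, false,
                        ts, ar, r, discount, qdiag, L,
                        nz_fbar_card.colptr(n), nz_f_card.colptr(n),
                        rejuv_enabled, rejuv_gap, rejuv_steps, &fpm_card);
    // per-space MAP extraction, then the winning space's Kalman state.
    // The per-space scores are kept normalized for numerical stability;
    // the cross-space comparison therefore re-adds each space's
    // (discounted) accumulated log-normalizers, so it compares the
    // accumulated MAP trajectory scores on a common scale.
    cum_ev_resp = discount * cum_ev_resp + ev1[n];
    cum_ev_card = discount * cum_ev_card + ev2[n];
    arma::uword i1 = resp.log_alpha.index_max();
    arma::uword i2 = card.log_alpha.index_max();
    double la1 = resp.log_alpha[i1] + cum_ev_resp;
    double la2 = card.log_alpha[i2] + cum_ev_card;
    int winner = (la1 >= la2) ? 1 : 2;
    out_fr[n] = resp.f[i1];
    out_thr[n] = resp.theta[i1];
    out_fc[n] = card.f[i2];
    out_thc[n] = card.theta[i2];
    out_la1[n] = la1;
    out_la2[n] = la2;
    out_winner[n] = winner;
    arma::vec coef = (winner == 1) ? resp.means.col(i1) : card.means.col(i2);
    out_coef.row(n) = coef.t();
    out_coef_resp.row(n) = resp.means.col(i1).t();
    out_coef_card.row(n) = card.means.col(i2).t();
    // reconstruct with the angle pair the winning Kalman state was
    // actually conditioned on (own-space particle angle + frozen other)
    double th_r_used = (winner == 1) ? resp.theta[i1] : froz_th_resp;
    double th_c_used = (winner == 1) ? froz_th_card : card.theta[i2];
    out_thr_used[n] = th_r_used;
    out_thc_used[n] = th_c_used;
    out_thr_clock[n] = froz_th_resp_cum;
    double gamma;
    out_yhat[n] = measure_parts(th_r_used, th_c_used, coef, L, &gamma,
                                nullptr, nullptr);
    out_gamma[n] = gamma;
    out_innov[n] = y[n] - out_yhat[n];
    // smooth update of the shared references.  Particle angles carry an
    // arbitrary phase (phase lives in the coefficients), so the reference
    // angle only needs to rotate smoothly at the right rate: its
    // frequency relaxes toward the posterior-mean frequency of the space
    // (much less jittery than the MAP particle's frequency); an optional
    // small phase nudge toward the MAP particle angle is available but
    // off by default.
    if (ref_phase_gain > 0) {
      froz_th_card = wrap_angle(
        froz_th_card + ref_phase_gain * ang_diff(out_thc[n], froz_th_card));
      froz_th_resp = wrap_angle(
        froz_th_resp + ref_phase_gain * ang_diff(out_thr[n], froz_th_resp));
    }
    froz_f_card += ref_freq_gain * (fpm_card - froz_f_card);
    froz_f_resp += ref_freq_gain * (fpm_resp - froz_f_resp);
  }

  List res = List::create(
    _["f_resp"] = out_fr, _["f_card"] = out_fc,
    _["theta_resp"] = out_thr, _["theta_card"] = out_thc,
    _["theta_resp_used"] = out_thr_used, _["theta_card_used"] = out_thc_used,
    _["theta_resp_clock"] = out_thr_clock,
    _["coef"] = out_coef, _["coef_resp"] = out_coef_resp,
    _["coef_card"] = out_coef_card,
    _["yhat"] = out_yhat, _["gamma_hat"] = out_gamma,
    _["innovation"] = out_innov, _["winner"] = out_winner,
    _["log_alpha_resp_max"] = out_la1, _["log_alpha_card_max"] = out_la2,
    _["evidence_resp"] = ev1, _["evidence_card"] = ev2,
    _["rejuv_events"] = IntegerVector::create(resp.rejuv_events,
                                              card.rejuv_events));
  if (return_particles) {
    res["particles"] = List::create(
      _["resp"] = List::create(_["f"] = resp.f, _["fbar"] = resp.fbar,
                               _["theta"] = resp.theta,
                               _["log_alpha"] = resp.log_alpha,
                               _["means"] = resp.means, _["covs"] = resp.covs),
      _["card"] = List::create(_["f"] = card.f, _["fbar"] = card.fbar,
                               _["theta"] = card.theta,
                               _["log_alpha"] = card.log_alpha,
                               _["means"] = card.means,
                               _["covs"] = card.covs));
  }
  return res;
}
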