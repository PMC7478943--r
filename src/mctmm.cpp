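#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// Probability floor applied to each grade probability before rate
// construction; keeps the generator finite at extreme logits.
static const double P_FLOOR = 1e-12;

inline double expit_d(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Proportional-odds grade probabilities (grades 0..3) at a given additive
// logit shift g (covariates + random effect), floored for rate construction.
static vec grade_probs_c(double a1, double b2, double b3, double g) {
  const double l1 = a1 + g;
  const double l2 = a1 + b2 + g;
  const double l3 = a1 + b2 + b3 + g;
  const double c1 = expit_d(l1), c2 = expit_d(l2), c3 = expit_d(l3);
  vec p = { 1.0 - c1, c1 - c2, c2 - c3, c3 };
  p = clamp(p, P_FLOOR, 1.0);
  return p / accu(p);
}

// Tridiagonal generator with adjacent rates
//   K(i->j) = p_j / (met * (p_i + p_j)),
// so each adjacent pair, taken in isolation, relaxes with time constant
// exactly met. Detailed balance p_i K(i->j) = p_j K(j->i) holds by
// construction, hence p is the stationary distribution.
static mat generator_c(const vec& p, double met) {
  mat Q(4, 4, fill::zeros);
  for (int i = 0; i < 3; ++i) {
    const double s = met * (p(i) + p(i + 1));
    Q(i, i + 1) = p(i + 1) / s;
    Q(i + 1, i) = p(i) / s;
  }
  Q.diag() = -sum(Q, 1);
  return Q;
}

struct Subj {
  vec dt;    // segment lengths (cycles)
  vec gadd;  // per-segment additive logit term X_int * beta_int
  vec metl;  // per-segment log MET multiplier X_met * beta_met
  ivec obs;  // grade observed at segment end, -1 if none
  int n;
};

static Subj parse_subject(const List& s, const vec& beta_int, const vec& beta_met) {
  Subj out;
  out.dt  = as<vec>(s["dt"]);
  out.obs = as<ivec>(s["obs"]);
  out.n   = out.dt.n_elem;
  mat Xint = as<mat>(s["Xint"]);
  mat Xmet = as<mat>(s["Xmet"]);
  if (Xint.n_cols > 0 && beta_int.n_elem == Xint.n_cols)
    out.gadd = Xint * beta_int;
  else
    out.gadd = vec(out.n, fill::zeros);
  if (Xmet.n_cols > 0 && beta_met.n_elem == Xmet.n_cols)
    out.metl = Xmet * beta_met;
  else
    out.metl = vec(out.n, fill::zeros);
  return out;
}

// -log L_i(eta): probability state starts as the grade-0 indicator, is
// propagated segment-wise by exp(Q dt) and reset to the observed indicator
// at each observation (Markov reset).
static double nll_core(const Subj& S, double a1, double b2, double b3,
                       double met, double ea, double em) {
  rowvec state = {1.0, 0.0, 0.0, 0.0};
  double ll = 0.0;
  for (int j = 0; j < S.n; ++j) {
    vec p = grade_probs_c(a1, b2, b3, S.gadd(j) + ea);
    double mi = met * std::exp(em + S.metl(j));
    mat T = expmat(generator_c(p, mi) * S.dt(j));
    state = state * T;
    int o = S.obs(j);
    if (o >= 0) {
      double pr = state(o);
      if (!(pr > 1e-300)) pr = 1e-300;
      ll += std::log(pr);
      state.zeros();
      state(o) = 1.0;
    }
  }
  return -ll;
}

struct HFun {
  const Subj& S;
  double a1, b2, b3, met, wa, wm;
  bool ua, um;
  // penalised deviance kernel: -log L_i(eta) + quadratic prior term
  double operator()(double xa, double xm) const {
    double ea = ua ? xa : 0.0, em = um ? xm : 0.0;
    double val = nll_core(S, a1, b2, b3, met, ea, em);
    if (ua) val += 0.5 * (ea * ea) / (wa * wa);
    if (um) val += 0.5 * (em * em) / (wm * wm);
    return val;
  }
};

// Laplace contribution -log integral L_i(eta) phi(eta) deta for one subject.
// Inner Newton (finite-difference gradient/Hessian) from eta = 0, gradient
// tolerance 1e-8. Returns mode and the d x d Hessian of the kernel.
static double subj_laplace(const Subj& S, double a1, double b2, double b3,
                           double met, double wa, double wm,
                           vec& mode_out, mat& H_out, int& d_out) {
  const bool ua = wa > 1e-8, um = wm > 1e-8;
  const int d = (ua ? 1 : 0) + (um ? 1 : 0);
  d_out = d;
  mode_out = vec(2, fill::zeros);
  HFun h{S, a1, b2, b3, met, wa, wm, ua, um};
  if (d == 0) {
    H_out = mat(0, 0);
    return h(0.0, 0.0);
  }

  auto hx = [&](const vec& x) {
    double xa = 0.0, xm = 0.0;
    int k = 0;
    if (ua) xa = x(k++);
    if (um) xm = x(k);
    return h(xa, xm);
  };

  vec x(d, fill::zeros);
  double h0 = hx(x);
  const double s = 1e-4;
  vec g(d);
  mat H(d, d, fill::zeros);

  for (int iter = 0; iter < 100; ++iter) {
    for (int i = 0; i < d; ++i) {
      vec xp = x, xm2 = x;
      xp(i) += s;
      xm2(i) -= s;
      double hp = hx(xp), hm = hx(xm2);
      g(i) = (hp - hm) / (2.0 * s);
      H(i, i) = (hp - 2.0 * h0 + hm) / (s * s);
    }
    if (d == 2) {
      vec xpp = x, xpm = x, xmp = x, xmm = x;
      xpp(0) += s; xpp(1) += s;
      xpm(0) += s; xpm(1) -= s;
      xmp(0) -= s; xmp(1) += s;
      xmm(0) -= s; xmm(1) -= s;
      double c = (hx(xpp) - hx(xpm) - hx(xmp) + hx(xmm)) / (4.0 * s * s);
      H(0, 1) = H(1, 0) = c;
    }
    if (norm(g) < 1e-8) break;

    mat Hr = H;
    double ridge = 0.0;
    for (int t = 0; t < 60; ++t) {
      bool pd = (d == 1)
        ? (Hr(0, 0) > 1e-12)
        : (Hr(0, 0) > 1e-12 && Hr(0, 0) * Hr(1, 1) - Hr(0, 1) * Hr(1, 0) > 1e-12);
      if (pd) break;
      ridge = (ridge == 0.0) ? 1e-4 : ridge * 10.0;
      Hr = H;
      Hr.diag() += ridge;
    }
    vec step;
    bool ok_solve = solve(step, Hr, g);
    if (!ok_solve) break;
    double sl = norm(step);
    if (sl > 5.0) step *= 5.0 / sl;

    double t = 1.0;
    bool ok = false;
    for (int ls = 0; ls < 40; ++ls) {
      vec xn = x - t * step;
      double hn = hx(xn);
      if (hn < h0) {
        x = xn;
        h0 = hn;
        ok = true;
        break;
      }
      t *= 0.5;
    }
    if (!ok) break;  // no descent possible: at the mode to FD precision
  }

  // positive-definite Hessian for the log-determinant
  mat Hf = H;
  for (int t = 0; t < 60; ++t) {
    double det2 = (d == 1) ? Hf(0, 0)
                           : Hf(0, 0) * Hf(1, 1) - Hf(0, 1) * Hf(1, 0);
    if ((d == 1 && Hf(0, 0) > 0) || (d == 2 && Hf(0, 0) > 0 && det2 > 0)) break;
    Hf.diag() += (t == 0 ? 1e-8 : std::pow(10.0, t) * 1e-8);
  }
  double logdet = (d == 1)
    ? std::log(Hf(0, 0))
    : std::log(Hf(0, 0) * Hf(1, 1) - Hf(0, 1) * Hf(1, 0));

  double res = h0 + 0.5 * logdet;
  if (ua) res += std::log(wa);
  if (um) res += std::log(wm);

  int k = 0;
  if (ua) mode_out(0) = x(k++);
  if (um) mode_out(1) = x(k);
  H_out = Hf;
  return res;
}

// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& Q, double t) {
  return expmat(Q * t);
}

// [[Rcpp::export]]
arma::mat cpp_transition_matrix(double alpha1, double b2, double b3,
                                double g, double met_i, double dt) {
  vec p = grade_probs_c(alpha1, b2, b3, g);
  return expmat(generator_c(p, met_i) * dt);
}

// [[Rcpp::export]]
double cpp_subject_nll(const List& subj, double alpha1, double b2, double b3,
                       double met, const arma::vec& beta_int,
                       const arma::vec& beta_met, double eta_a, double eta_m) {
  Subj S = parse_subject(subj, beta_int, beta_met);
  return nll_core(S, alpha1, b2, b3, met, eta_a, eta_m);
}

// [[Rcpp::export]]
double cpp_cohort_ofv_laplace(const List& subjects, double alpha1, double b2,
                              double b3, double met,
                              const arma::vec& beta_int,
                              const arma::vec& beta_met,
                              double omega_alpha, double omega_met) {
  double tot = 0.0;
  vec mode;
  mat H;
  int d;
  for (int i = 0; i < subjects.size(); ++i) {
    Subj S = parse_subject(subjects[i], beta_int, beta_met);
    tot += subj_laplace(S, alpha1, b2, b3, met, omega_alpha, omega_met,
                        mode, H, d);
  }
  return 2.0 * tot;
}

// [[Rcpp::export]]
List cpp_eta_mode(const List& subj, double alpha1, double b2, double b3,
                  double met, const arma::vec& beta_int,
                  const arma::vec& beta_met,
                  double omega_alpha, double omega_met) {
  Subj S = parse_subject(subj, beta_int, beta_met);
  vec mode;
  mat H;
  int d;
  double contrib = subj_laplace(S, alpha1, b2, b3, met,
                                omega_alpha, omega_met, mode, H, d);
  return List::create(_["eta"] = NumericVector::create(mode(0), mode(1)),
                      _["hessian"] = H,
                      _["d"] = d,
                      _["laplace_contrib"] = contrib);
}

// [[Rcpp::export]]
IntegerVector cpp_simulate_path(const List& subj, double alpha1, double b2,
                                double b3, double met,
                                const arma::vec& beta_int,
                                const arma::vec& beta_met,
                                double eta_a, double eta_m,
                                const arma::vec& u) {
  Subj S = parse_subject(subj, beta_int, beta_met);
  IntegerVector out(S.n);
  int cur = 0;
  for (int j = 0; j < S.n; ++j) {
    vec p = grade_probs_c(alpha1, b2, b3, S.gadd(j) + eta_a);
    double mi = met * std::exp(eta_m + S.metl(j));
    mat T = expmat(generator_c(p, mi) * S.dt(j));
    double cum = 0.0;
    int nxt = 3;
    for (int k = 0; k < 4; ++k) {
      cum += T(cur, k);
      if (u(j) <= cum) { nxt = k; break; }
    }
    out[j] = nxt;
    cur = nxt;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_simulate_cohort(const List& subjects, double alpha1, double b2,
                         double b3, double met, const arma::vec& beta_int,
                         const arma::vec& beta_met, const arma::mat& eta,
                         const List& u) {
  int n = subjects.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = cpp_simulate_path(subjects[i], alpha1, b2, b3, met, beta_int,
                               beta_met, eta(i, 0), eta(i, 1),
                               as<arma::vec>(u[i]));
  }
  return out;
}
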