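// Fast likelihood chains for OU / VAR(1) / stationary Gaussian models of
// irregularly sampled ESM series, plus the DE/rand/1/bin optimizer driving
// maximum-likelihood estimation. R-level counterparts in R/dynamics.R and
// R/state_space.R are the reference implementations; tests assert agreement.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);

// e^{-theta * dt}; closed forms for d = 1, 2 (hot path), Pade otherwise.
static mat expm_neg(const mat &theta, double dt) {
  const uword d = theta.n_rows;
  if (d == 1) {
    mat E(1, 1);
    E(0, 0) = std::exp(-theta(0, 0) * dt);
    return E;
  }
  if (d == 2) {
    mat M = -theta * dt;
    const double s = 0.5 * (M(0, 0) + M(1, 1));
    mat B = M;
    B(0, 0) -= s;
    B(1, 1) -= s;
    // traceless B: B^2 = disc * I
    const double disc = B(0, 0) * B(0, 0) + B(0, 1) * B(1, 0);
    double ch, shq;
    if (disc > 1e-24) {
      const double q = std::sqrt(disc);
      ch = std::cosh(q);
      shq = std::sinh(q) / q;
    } else if (disc < -1e-24) {
      const double q = std::sqrt(-disc);
      ch = std::cos(q);
      shq = std::sin(q) / q;
    } else {
      ch = 1.0;
      shq = 1.0;
    }
    mat E = ch * eye(2, 2) + shq * B;
    return std::exp(s) * E;
  }
  return expmat(-theta * dt);
}

static bool ou_stable(const mat &theta) {
  const uword d = theta.n_rows;
  if (d == 1) return theta(0, 0) > 0.0;
  if (d == 2)
    return (theta(0, 0) + theta(1, 1) > 0.0) &&
           (theta(0, 0) * theta(1, 1) - theta(0, 1) * theta(1, 0) > 0.0);
  cx_vec ev = eig_gen(theta);
  return all(real(ev) > 0.0);
}

// theta * S + S * theta' = Q ; returns false when S is not PD
static bool lyap_cont(const mat &theta, const mat &Q, mat &S) {
  const uword d = theta.n_rows;
  if (d == 1) {
    S.set_size(1, 1);
    S(0, 0) = Q(0, 0) / (2.0 * theta(0, 0));
    return S(0, 0) > 0.0;
  }
  if (d == 2) {
    mat M(3, 3);
    M(0, 0) = 2.0 * theta(0, 0); M(0, 1) = 2.0 * theta(0, 1); M(0, 2) = 0.0;
    M(1, 0) = theta(1, 0); M(1, 1) = theta(0, 0) + theta(1, 1); M(1, 2) = theta(0, 1);
    M(2, 0) = 0.0; M(2, 1) = 2.0 * theta(1, 0); M(2, 2) = 2.0 * theta(1, 1);
    vec b = {Q(0, 0), Q(0, 1), Q(1, 1)};
    vec s;
    if (!solve(s, M, b, solve_opts::no_approx)) return false;
    S.set_size(2, 2);
    S(0, 0) = s(0); S(0, 1) = s(1); S(1, 0) = s(1); S(1, 1) = s(2);
    return S(0, 0) > 0.0 && (s(0) * s(2) - s(1) * s(1)) > 0.0;
  }
  mat K = kron(eye(d, d), theta) + kron(theta, eye(d, d));
  vec v;
  if (!solve(v, K, vectorise(Q), solve_opts::no_approx)) return false;
  S = reshape(v, d, d);
  S = 0.5 * (S + S.t());
  mat L;
  return chol(L, S, "lower");
}

// S = A * S * A' + Q (discrete Lyapunov)
static bool lyap_disc(const mat &A, const mat &Q, mat &S) {
  const uword d = A.n_rows;
  mat K = eye(d * d, d * d) - kron(A, A);
  vec v;
  if (!solve(v, K, vectorise(Q), solve_opts::no_approx)) return false;
  S = reshape(v, d, d);
  S = 0.5 * (S + S.t());
  mat L;
  return chol(L, S, "lower");
}

// MVN negative log density with relative jitter on the diagonal
static double mvn_nll(const vec &x, const vec &m, mat C, bool &ok) {
  const uword d = C.n_rows;
  C = 0.5 * (C + C.t());
  double jit = 1e-10 * (trace(C) / d);
  if (!(jit > 0.0) || !std::isfinite(jit)) jit = 1e-12;
  C.diag() += jit;
  const vec e = x - m;
  if (d == 1) {
    if (!(C(0, 0) > 0.0)) { ok = false; return datum::inf; }
    ok = true;
    return 0.5 * (LOG2PI + std::log(C(0, 0)) + e(0) * e(0) / C(0, 0));
  }
  if (d == 2) {
    const double det = C(0, 0) * C(1, 1) - C(0, 1) * C(0, 1);
    if (!(det > 0.0) || !(C(0, 0) > 0.0)) { ok = false; return datum::inf; }
    const double quad =
        (e(0) * e(0) * C(1, 1) - 2.0 * e(0) * e(1) * C(0, 1) + e(1) * e(1) * C(0, 0)) / det;
    ok = true;
    return 0.5 * (2.0 * LOG2PI + std::log(det) + quad);
  }
  mat L;
  if (!chol(L, C, "lower")) { ok = false; return datum::inf; }
  vec z = solve(trimatl(L), e);
  double logdet = 2.0 * sum(log(L.diag()));
  ok = true;
  return 0.5 * (d * LOG2PI + logdet + dot(z, z));
}

struct SeriesData {
  mat X;          // N x d ratings (rows referenced by plan)
  ivec kind;      // 0 = stationary item, 1 = transition item
  ivec src;       // 1-based source row (0 when none)
  ivec tgt;       // 1-based target row
  vec elapsed;    // hours (OU) or pseudo-steps (VAR-as-OU / VAR)
  ivec retained;  // 1 = contributes to the sum
};

// ---- scalar fast path for the bivariate plain chain (the DE hot loop) ----

static inline double nll2(double e0, double e1, double c00, double c01,
                          double c11, bool &ok) {
  const double jit = 1e-10 * 0.5 * (c00 + c11);
  c00 += (jit > 0.0 ? jit : 1e-12);
  c11 += (jit > 0.0 ? jit : 1e-12);
  const double det = c00 * c11 - c01 * c01;
  if (!(det > 0.0) || !(c00 > 0.0)) { ok = false; return datum::inf; }
  const double quad = (e0 * e0 * c11 - 2.0 * e0 * e1 * c01 + e1 * e1 * c00) / det;
  ok = true;
  return 0.5 * (2.0 * LOG2PI + std::log(det) + quad);
}

// Lyapunov solve for d = 2 by Cramer's rule; false when SigY is not PD
static inline bool lyap_cont2(double t00, double t01, double t10, double t11,
                              double q00, double q01, double q11, double &s00,
                              double &s01, double &s11) {
  const double m00 = 2.0 * t00, m01 = 2.0 * t01;
  const double m10 = t10, m11 = t00 + t11, m12 = t01;
  const double m21 = 2.0 * t10, m22 = 2.0 * t11;
  const double det = m00 * (m11 * m22 - m12 * m21) - m01 * (m10 * m22);
  if (det == 0.0 || !std::isfinite(det)) return false;
  s00 = (q00 * (m11 * m22 - m12 * m21) - m01 * (q01 * m22 - q11 * m12)) / det;
  s01 = (m00 * (q01 * m22 - m12 * q11) - q00 * (m10 * m22)) / det;
  s11 = (m00 * (m11 * q11 - q01 * m21) - m01 * (m10 * q11) + q00 * (m10 * m21)) / det;
  return s00 > 0.0 && (s00 * s11 - s01 * s01) > 0.0;
}

static double chain2_plain(double mu0, double mu1, double t00, double t01,
                           double t10, double t11, double s00, double s01,
                           double s11, const SeriesData &s) {
  const double *x0 = s.X.colptr(0);
  const double *x1 = s.X.colptr(1);
  double total = 0.0;
  bool ok = true;
  const uword n = s.kind.n_elem;
  for (uword k = 0; k < n; ++k) {
    if (!s.retained(k)) continue;
    const int tg = s.tgt(k) - 1;
    if (s.kind(k) == 0) {
      total += nll2(x0[tg] - mu0, x1[tg] - mu1, s00, s01, s11, ok);
    } else {
      const double dt = s.elapsed(k);
      // E = exp(-theta * dt), closed form via the traceless split
      const double sm = -0.5 * (t00 + t11) * dt;
      const double b00 = -t00 * dt - sm, b01 = -t01 * dt, b10 = -t10 * dt;
      const double disc = b00 * b00 + b01 * b10;
      double ch, shq;
      if (disc > 1e-24) {
        const double q = std::sqrt(disc);
        ch = std::cosh(q);
        shq = std::sinh(q) / q;
      } else if (disc < -1e-24) {
        const double q = std::sqrt(-disc);
        ch = std::cos(q);
        shq = std::sin(q) / q;
      } else {
        ch = 1.0;
        shq = 1.0;
      }
      const double es = std::exp(sm);
      const double e00 = es * (ch + shq * b00), e01 = es * (shq * b01);
      const double e10 = es * (shq * b10), e11 = es * (ch - shq * b00);
      // C = SigY - E SigY E'
      const double a00 = e00 * s00 + e01 * s01, a01 = e00 * s01 + e01 * s11;
      const double a10 = e10 * s00 + e11 * s01, a11 = e10 * s01 + e11 * s11;
      const double c00 = s00 - (a00 * e00 + a01 * e01);
      const double c01 = s01 - (a00 * e10 + a01 * e11);
      const double c11 = s11 - (a10 * e10 + a11 * e11);
      const int sr = s.src(k) - 1;
      const double d0 = x0[sr] - mu0, d1 = x1[sr] - mu1;
      const double mx = mu0 + e00 * d0 + e01 * d1;
      const double my = mu1 + e10 * d0 + e11 * d1;
      total += nll2(x0[tg] - mx, x1[tg] - my, c00, c01, c11, ok);
    }
    if (!ok) return datum::inf;
  }
  return total;
}

static SeriesData as_series_data(const Rcpp::List &s) {
  SeriesData out;
  out.X = Rcpp::as<mat>(s["X"]);
  out.kind = Rcpp::as<ivec>(s["kind"]);
  out.src = Rcpp::as<ivec>(s["src"]);
  out.tgt = Rcpp::as<ivec>(s["tgt"]);
  out.elapsed = Rcpp::as<vec>(s["elapsed"]);
  out.retained = Rcpp::as<ivec>(s["retained"]);
  return out;
}

// Exponential-propagation chain (OU; also VAR fitted as OU on pseudo-time).
// With errvar present this is the Kalman marginal NLL (Joseph-form updates,
// filter restarted from the stationary prior at every stationary item);
// non-retained items update the filter but do not contribute to the sum.
static double chain_nll_exp(const vec &mu, const mat &theta, const mat &SigY,
                            const vec &errvar, const SeriesData &s) {
  const uword d = mu.n_elem;
  const bool noise = errvar.n_elem > 0;
  double total = 0.0;
  bool ok = true;
  if (!noise) {
    for (uword k = 0; k < s.kind.n_elem; ++k) {
      if (!s.retained(k)) continue;
      const vec x = s.X.row(s.tgt(k) - 1).t();
      if (s.kind(k) == 0) {
        total += mvn_nll(x, mu, SigY, ok);
      } else {
        const mat E = expm_neg(theta, s.elapsed(k));
        const vec xp = s.X.row(s.src(k) - 1).t();
        const vec m = mu + E * (xp - mu);
        const mat C = SigY - E * SigY * E.t();
        total += mvn_nll(x, m, C, ok);
      }
      if (!ok) return datum::inf;
    }
    return total;
  }
  const mat R = diagmat(errvar);
  const mat I = eye(d, d);
  vec fm(d, fill::zeros);
  mat fP(d, d, fill::zeros);
  for (uword k = 0; k < s.kind.n_elem; ++k) {
    if (s.kind(k) == 0) {
      fm = mu;
      fP = SigY;
    } else {
      const mat E = expm_neg(theta, s.elapsed(k));
      fm = mu + E * (fm - mu);
      fP = E * fP * E.t() + (SigY - E * SigY * E.t());
      fP = 0.5 * (fP + fP.t());
    }
    mat S = fP + R;
    S = 0.5 * (S + S.t());
    const vec x = s.X.row(s.tgt(k) - 1).t();
    if (s.retained(k)) {
      total += mvn_nll(x, fm, S, ok);
      if (!ok) return datum::inf;
    }
    mat Sj = S;
    double jit = 1e-12 * (trace(Sj) / d + 1.0);
    Sj.diag() += jit;
    mat Kt;
    if (!solve(Kt, Sj.t(), fP.t(), solve_opts::no_approx)) return datum::inf;
    const mat K = Kt.t();
    fm += K * (x - fm);
    const mat IK = I - K;
    fP = IK * fP * IK.t() + K * R * K.t();
    fP = 0.5 * (fP + fP.t());
  }
  return total;
}

// Direct VAR(1) chain with integer pseudo-steps
static double chain_nll_var(const vec &c, const mat &A, const mat &Se,
                            const vec &errvar, const SeriesData &s) {
  const uword d = c.n_elem;
  cx_vec ev = eig_gen(A);
  if (!(max(abs(ev)) < 1.0)) return datum::inf;
  mat Sig;
  if (!lyap_disc(A, Se, Sig)) return datum::inf;
  vec mu;
  if (!solve(mu, eye(d, d) - A, c, solve_opts::no_approx)) return datum::inf;
  const bool noise = errvar.n_elem > 0;
  double total = 0.0;
  bool ok = true;
  const mat R = diagmat(errvar);
  const mat I = eye(d, d);
  vec fm(d, fill::zeros);
  mat fP(d, d, fill::zeros);
  for (uword k = 0; k < s.kind.n_elem; ++k) {
    mat Ak = I;
    if (s.kind(k) == 1) {
      const int steps = (int)std::lround(s.elapsed(k));
      for (int j = 0; j < steps; ++j) Ak = Ak * A;
    }
    if (!noise) {
      if (!s.retained(k)) continue;
      const vec x = s.X.row(s.tgt(k) - 1).t();
      if (s.kind(k) == 0) {
        total += mvn_nll(x, mu, Sig, ok);
      } else {
        const vec xp = s.X.row(s.src(k) - 1).t();
        const vec m = mu + Ak * (xp - mu);
        const mat C = Sig - Ak * Sig * Ak.t();
        total += mvn_nll(x, m, C, ok);
      }
      if (!ok) return datum::inf;
      continue;
    }
    if (s.kind(k) == 0) {
      fm = mu;
      fP = Sig;
    } else {
      fm = mu + Ak * (fm - mu);
      fP = Ak * fP * Ak.t() + (Sig - Ak * Sig * Ak.t());
      fP = 0.5 * (fP + fP.t());
    }
    mat S = fP + R;
    S = 0.5 * (S + S.t());
    const vec x = s.X.row(s.tgt(k) - 1).t();
    if (s.retained(k)) {
      total += mvn_nll(x, fm, S, ok);
      if (!ok) return datum::inf;
    }
    mat Sj = S;
    Sj.diag() += 1e-12 * (trace(Sj) / d + 1.0);
    mat Kt;
    if (!solve(Kt, Sj.t(), fP.t(), solve_opts::no_approx)) return datum::inf;
    const mat K = Kt.t();
    fm += K * (x - fm);
    const mat IK = I - K;
    fP = IK * fP * IK.t() + K * R * K.t();
    fP = 0.5 * (fP + fP.t());
  }
  return total;
}

// [[Rcpp::export]]
double cpp_nll_ou(const arma::vec &mu, const arma::mat &theta,
                  const arma::mat &sigma, const arma::vec &errvar,
                  const Rcpp::List &series) {
  if (!ou_stable(theta)) return R_PosInf;
  mat SigY;
  if (!lyap_cont(theta, sigma * sigma.t(), SigY)) return R_PosInf;
  const SeriesData s = as_series_data(series);
  if (mu.n_elem == 2 && errvar.n_elem == 0)
    return chain2_plain(mu(0), mu(1), theta(0, 0), theta(0, 1), theta(1, 0),
                        theta(1, 1), SigY(0, 0), SigY(0, 1), SigY(1, 1), s);
  return chain_nll_exp(mu, theta, SigY, errvar, s);
}

// [[Rcpp::export]]
double cpp_nll_var(const arma::vec &intercept, const arma::mat &A,
                   const arma::mat &innov_cov, const arma::vec &errvar,
                   const Rcpp::List &series) {
  const SeriesData s = as_series_data(series);
  return chain_nll_var(intercept, A, innov_cov, errvar, s);
}

// [[Rcpp::export]]
double cpp_nll_stationary(const arma::vec &mu, const arma::mat &Sig,
                          const Rcpp::List &series) {
  const SeriesData s = as_series_data(series);
  double total = 0.0;
  bool ok = true;
  for (uword k = 0; k < s.kind.n_elem; ++k) {
    if (!s.retained(k)) continue;
    const vec x = s.X.row(s.tgt(k) - 1).t();
    total += mvn_nll(x, mu, Sig, ok);
    if (!ok) return R_PosInf;
  }
  return total;
}

// Decode a DE search vector into (mu, theta, sigma[, errvar]):
// layout mu (d), theta row-major (d*d), sigma lower triangle row-wise
// (d(d+1)/2), then d error variances when noise is on.
static void decode_ou(const vec &par, uword d, bool noise, vec &mu, mat &theta,
                      mat &sigma, vec &errvar) {
  uword pos = 0;
  mu = par.subvec(pos, pos + d - 1);
  pos += d;
  theta.set_size(d, d);
  for (uword i = 0; i < d; ++i)
    for (uword j = 0; j < d; ++j) theta(i, j) = par(pos++);
  sigma.zeros(d, d);
  for (uword i = 0; i < d; ++i)
    for (uword j = 0; j <= i; ++j) sigma(i, j) = par(pos++);
  if (noise) {
    errvar = par.subvec(pos, pos + d - 1);
  } else {
    errvar.set_size(0);
  }
}

static double ou_objective(const vec &par, uword d, bool noise,
                           const std::vector<SeriesData> &sers) {
  if (d == 2 && !noise) {
    // par = (mu0, mu1, t00, t01, t10, t11, l00, l10, l11)
    const double t00 = par(2), t01 = par(3), t10 = par(4), t11 = par(5);
    if (!(t00 + t11 > 0.0) || !(t00 * t11 - t01 * t10 > 0.0)) return datum::inf;
    const double l00 = par(6), l10 = par(7), l11 = par(8);
    const double q00 = l00 * l00, q01 = l00 * l10, q11 = l10 * l10 + l11 * l11;
    double s00, s01, s11;
    if (!lyap_cont2(t00, t01, t10, t11, q00, q01, q11, s00, s01, s11))
      return datum::inf;
    double total = 0.0;
    for (const SeriesData &s : sers) {
      total += chain2_plain(par(0), par(1), t00, t01, t10, t11, s00, s01, s11, s);
      if (!std::isfinite(total)) return datum::inf;
    }
    return total;
  }
  vec mu, errvar;
  mat theta, sigma;
  decode_ou(par, d, noise, mu, theta, sigma, errvar);
  if (!ou_stable(theta)) return datum::inf;
  mat SigY;
  if (!lyap_cont(theta, sigma * sigma.t(), SigY)) return datum::inf;
  double total = 0.0;
  for (const SeriesData &s : sers) {
    total += chain_nll_exp(mu, theta, SigY, errvar, s);
    if (!std::isfinite(total)) return datum::inf;
  }
  return total;
}

// DE/rand/1/bin with F ~ U(0, 2) redrawn per mutation; draws from the R RNG
// so results are reproducible under set.seed(). Synchronous generations;
// trial replaces target when no worse. Returns best vector, value, trace.
// [[Rcpp::export]]
Rcpp::List cpp_de_fit(const Rcpp::List &series_list, const arma::vec &lower,
                      const arma::vec &upper, int d, bool noise, int np,
                      double cr, int iters, int trace_every,
                      const arma::vec &init) {
  const uword npar = lower.n_elem;
  std::vector<SeriesData> sers;
  for (R_xlen_t i = 0; i < series_list.size(); ++i)
    sers.push_back(as_series_data(series_list[i]));

  mat pop(npar, np);
  vec fit(np);
  for (int i = 0; i < np; ++i) {
    // redraw a few times so the initial population is not all-unstable
    for (int attempt = 0; attempt < 100; ++attempt) {
      for (uword j = 0; j < npar; ++j)
        pop(j, i) = lower(j) + unif_rand() * (upper(j) - lower(j));
      fit(i) = ou_objective(pop.col(i), (uword)d, noise, sers);
      if (std::isfinite(fit(i))) break;
    }
  }
  if (init.n_elem == npar) {
    // moment-based warm start occupies one slot of the initial population
    pop.col(0) = init;
    fit(0) = ou_objective(init, (uword)d, noise, sers);
  }
  if (fit.min() == datum::inf)
    Rcpp::stop("differential evolution: no stable model inside the bounds at initialization");

  std::vector<double> trace;
  uword best = fit.index_min();
  trace.push_back(fit(best));

  // immediate replacement: a winning trial enters the population at once,
  // so later mutations in the same generation can already exploit it
  for (int it = 1; it <= iters; ++it) {
    for (int i = 0; i < np; ++i) {
      int r1, r2, r3;
      do { r1 = (int)(unif_rand() * np); } while (r1 == i || r1 == np);
      do { r2 = (int)(unif_rand() * np); } while (r2 == i || r2 == r1 || r2 == np);
      do { r3 = (int)(unif_rand() * np); } while (r3 == i || r3 == r1 || r3 == r2 || r3 == np);
      const double F = 2.0 * unif_rand();
      vec trial = pop.col(i);
      const uword jrand = (uword)(unif_rand() * npar) % npar;
      for (uword j = 0; j < npar; ++j) {
        if (unif_rand() < cr || j == jrand) {
          double v = pop(j, r1) + F * (pop(j, r2) - pop(j, r3));
          if (v < lower(j)) v = lower(j);
          if (v > upper(j)) v = upper(j);
          trial(j) = v;
        }
      }
      const double f = ou_objective(trial, (uword)d, noise, sers);
      if (f <= fit(i)) {
        pop.col(i) = trial;
        fit(i) = f;
      }
    }
    if (it % trace_every == 0 || it == iters) trace.push_back(fit.min());
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }
  best = fit.index_min();
  return Rcpp::List::create(Rcpp::Named("par") = pop.col(best),
                            Rcpp::Named("value") = fit(best),
                            Rcpp::Named("trace") = trace);
}
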