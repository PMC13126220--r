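// Marginal likelihood of the one-stage MASEM-with-means model.
//
// For study i with observed effect sizes y_i = [vech(S_i); ybar_i] (rows
// restricted to the study's `present` indices), the marginal model is
//   y_i ~ N( m(theta, x_i),  T2 + V_i )
// where m is either the saturated mean structure (linear in theta) or the
// CFA moments [vech(Lambda Phi Lambda' + Psi); tau + Lambda kappa] with every
// matrix entry an affine function A_i theta + c of the free parameters
// (baselines + moderator slopes). T2 is the between-study covariance:
// a diagonal block for the covariance effect sizes (log-SD parameters), a
// symmetric block for the means (Cholesky factor), zero cross-block.
//
// Gradients are analytic: mean part via the Jacobian of the CFA moments in
// the packed matrix entries, heterogeneity part via
// dNLL/dM = (M^-1 - M^-1 r r' M^-1) / 2 chained through the T2
// parameterization.
//
// Performance notes, relevant because the Monte-Carlo harness runs many
// thousands of fits: the prepared data live behind an external pointer so
// optimizer iterations do not re-copy them from R; studies sharing a
// moderator profile share the design matrix, the model-implied moments, and
// the moment Jacobian; and the order-20 Cholesky/triangular kernels are
// hand-rolled because BLAS/LAPACK dispatch overhead dominates at this size.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static const double LOG2PI = 1.837877066409345483560659472811;

struct MasemData {
  mat y;                    // nm x k
  std::vector<mat> V;       // per-study sampling covariance (present rows)
  std::vector<uvec> pres;   // 0-based present indices
  std::vector<bool> complete;
  std::vector<int> grp;     // index into unique moderator profiles
  std::vector<mat> A;       // one design matrix per unique profile
  vec cvec;
  int type, p, q, ntm, het_s, het_m, k, nm;
};

struct HetInfo {
  int het_s, het_m, ns, p;
};

// exchangeable correlation mapped from the real line onto the open
// interval (-1/(p-1), 1) that keeps compound symmetry positive definite
static inline double cs_rho(double b, int p) {
  double lo = -1.0 / (p - 1);
  double s = 1.0 / (1.0 + std::exp(-b));
  return lo + (1.0 - lo) * s;
}
static inline double cs_rho_deriv(double b, int p) {
  double lo = -1.0 / (p - 1);
  double s = 1.0 / (1.0 + std::exp(-b));
  return (1.0 - lo) * s * (1.0 - s);
}

// ---- small dense kernels (order <= a few dozen) ---------------------------

// lower Cholesky in place; returns false when not positive definite
static bool chol_lower(mat &A) {
  int n = A.n_rows;
  for (int j = 0; j < n; ++j) {
    double d = A(j, j);
    for (int k2 = 0; k2 < j; ++k2) d -= A(j, k2) * A(j, k2);
    if (d <= 0.0 || !std::isfinite(d)) return false;
    d = std::sqrt(d);
    A(j, j) = d;
    for (int i = j + 1; i < n; ++i) {
      double s = A(i, j);
      for (int k2 = 0; k2 < j; ++k2) s -= A(i, k2) * A(j, k2);
      A(i, j) = s / d;
    }
  }
  return true;
}

// solve C z = r with C lower triangular
static void fsolve(const mat &C, const vec &r, vec &z) {
  int n = C.n_rows;
  for (int i = 0; i < n; ++i) {
    double s = r[i];
    for (int j = 0; j < i; ++j) s -= C(i, j) * z[j];
    z[i] = s / C(i, i);
  }
}

// solve C' w = z with C lower triangular
static void bsolve(const mat &C, const vec &z, vec &w) {
  int n = C.n_rows;
  for (int i = n - 1; i >= 0; --i) {
    double s = z[i];
    for (int j = i + 1; j < n; ++j) s -= C(j, i) * w[j];
    w[i] = s / C(i, i);
  }
}

// Ci = C^{-1} for lower-triangular C
static void tri_inv(const mat &C, mat &Ci) {
  int n = C.n_rows;
  Ci.zeros(n, n);
  for (int j = 0; j < n; ++j) {
    Ci(j, j) = 1.0 / C(j, j);
    for (int i = j + 1; i < n; ++i) {
      double s = 0.0;
      for (int k2 = j; k2 < i; ++k2) s -= C(i, k2) * Ci(k2, j);
      Ci(i, j) = s / C(i, i);
    }
  }
}

// Minv = Ci' Ci (symmetric) from the inverse Cholesky factor
static void sympd_inv_from_chol(const mat &Ci, mat &Minv) {
  int n = Ci.n_rows;
  for (int j = 0; j < n; ++j)
    for (int i = j; i < n; ++i) {
      double s = 0.0;
      for (int k2 = i; k2 < n; ++k2) s += Ci(k2, i) * Ci(k2, j);
      Minv(i, j) = s;
      Minv(j, i) = s;
    }
}

// A -= w w'
static void sub_outer(mat &A, const vec &w) {
  int n = w.n_elem;
  for (int j = 0; j < n; ++j) {
    double wj = w[j];
    for (int i = 0; i < n; ++i) A(i, j) -= w[i] * wj;
  }
}

// ---- model pieces ---------------------------------------------------------

static mat build_T2(const vec &hp, const HetInfo &h, mat &Lm) {
  int nm = h.ns + h.p;
  mat T2(nm, nm, fill::zeros);
  int pos = 0;
  if (h.het_s == 1)
    for (int j = 0; j < h.ns; ++j) T2(j, j) = std::exp(2.0 * hp[pos++]);
  if (h.het_m == 1) {
    for (int j = 0; j < h.p; ++j)
      T2(h.ns + j, h.ns + j) = std::exp(2.0 * hp[pos++]);
  } else if (h.het_m == 2) {
    Lm.zeros(h.p, h.p);
    for (int j = 0; j < h.p; ++j)
      for (int i = j; i < h.p; ++i) Lm(i, j) = hp[pos++];
    T2.submat(h.ns, h.ns, nm - 1, nm - 1) = Lm * Lm.t();
  } else if (h.het_m == 3) {
    double v = std::exp(2.0 * hp[pos]);
    double rho = cs_rho(hp[pos + 1], h.p);
    for (int j = 0; j < h.p; ++j)
      for (int i = 0; i < h.p; ++i)
        T2(h.ns + i, h.ns + j) = (i == j) ? v : v * rho;
  }
  return T2;
}

// row of vech() holding element (i, j), i >= j, zero-based, order p
static inline int vech_row(int i, int j, int p) {
  return j * p - j * (j - 1) / 2 + (i - j);
}

// CFA moments m = [vech(Sigma); mu] from packed entries v, optionally with
// the Jacobian dm/dv
static void cfa_moments(const vec &v, int p, int q, vec &m, mat *Jv) {
  int pq = p * q, qh = q * (q + 1) / 2, ns = p * (p + 1) / 2, nm = ns + p;
  mat L = reshape(v.subvec(0, pq - 1), p, q);
  mat Phi(q, q);
  {
    int r = pq;
    for (int j = 0; j < q; ++j)
      for (int i = j; i < q; ++i) {
        Phi(i, j) = v[r];
        Phi(j, i) = v[r];
        ++r;
      }
  }
  vec psi = v.subvec(pq + qh, pq + qh + p - 1);
  vec tau = v.subvec(pq + qh + p, pq + qh + 2 * p - 1);
  vec kap = v.subvec(pq + qh + 2 * p, pq + qh + 2 * p + q - 1);

  mat LPhi = L * Phi;
  mat Sig = LPhi * L.t();
  Sig.diag() += psi;
  vec mu = tau + L * kap;

  m.set_size(nm);
  {
    int r = 0;
    for (int j = 0; j < p; ++j)
      for (int i = j; i < p; ++i) m[r++] = Sig(i, j);
  }
  m.subvec(ns, nm - 1) = mu;

  if (!Jv) return;
  int nv = pq + qh + 2 * p + q;
  Jv->zeros(nm, nv);
  // dSigma/dLambda_{ab} = e_a u' + u e_a' with u = Lambda Phi e_b;
  // dmu/dLambda_{ab} = kappa_b e_a
  for (int b = 0; b < q; ++b) {
    vec u = LPhi.col(b);
    for (int a = 0; a < p; ++a) {
      int col = b * p + a;
      for (int j = 0; j < p; ++j)
        for (int i = j; i < p; ++i) {
          double d = 0.0;
          if (i == a) d += u[j];
          if (j == a) d += u[i];
          if (d != 0.0) (*Jv)(vech_row(i, j, p), col) = d;
        }
      (*Jv)(ns + a, col) = kap[b];
    }
  }
  // dSigma/dPhi_{ab} = L_a L_b' + [a != b] L_b L_a'
  {
    int col = pq;
    for (int b = 0; b < q; ++b)
      for (int a = b; a < q; ++a, ++col) {
        vec La = L.col(a), Lb = L.col(b);
        for (int j = 0; j < p; ++j)
          for (int i = j; i < p; ++i)
            (*Jv)(vech_row(i, j, p), col) =
                (a == b) ? La[i] * La[j] : La[i] * Lb[j] + Lb[i] * La[j];
      }
  }
  for (int a = 0; a < p; ++a) (*Jv)(vech_row(a, a, p), pq + qh + a) = 1.0;
  for (int a = 0; a < p; ++a) (*Jv)(ns + a, pq + qh + p + a) = 1.0;
  for (int b = 0; b < q; ++b)
    for (int a = 0; a < p; ++a) (*Jv)(ns + a, pq + qh + 2 * p + b) = L(a, b);
}

static void het_grad_from_G(const mat &G, const vec &hp, const HetInfo &h,
                            const mat &Lm, vec &gh) {
  gh.set_size(hp.n_elem);
  int pos = 0, nm = h.ns + h.p;
  if (h.het_s == 1)
    for (int j = 0; j < h.ns; ++j, ++pos)
      gh[pos] = G(j, j) * 2.0 * std::exp(2.0 * hp[pos]);
  if (h.het_m == 1) {
    for (int j = 0; j < h.p; ++j, ++pos)
      gh[pos] = G(h.ns + j, h.ns + j) * 2.0 * std::exp(2.0 * hp[pos]);
  } else if (h.het_m == 2) {
    mat Gm = G.submat(h.ns, h.ns, nm - 1, nm - 1);
    mat GL = 2.0 * Gm * Lm;
    for (int j = 0; j < h.p; ++j)
      for (int i = j; i < h.p; ++i) gh[pos++] = GL(i, j);
  } else if (h.het_m == 3) {
    mat Gm = G.submat(h.ns, h.ns, nm - 1, nm - 1);
    double v = std::exp(2.0 * hp[pos]);
    double rho = cs_rho(hp[pos + 1], h.p);
    double sumG = accu(Gm), trG = trace(Gm);
    // dT/da = 2 T;  dT/db = v rho'(b) (J - I)
    gh[pos] = 2.0 * (v * (1.0 - rho) * trG + v * rho * sumG);
    gh[pos + 1] = v * cs_rho_deriv(hp[pos + 1], h.p) * (sumG - trG);
  }
}

// ---- entry points ---------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_make_data(const List &dat) {
  MasemData *d = new MasemData;
  d->y = as<mat>(dat["y"]);
  d->cvec = as<vec>(dat["cvec"]);
  d->type = dat["type"];
  d->p = dat["p"];
  d->q = dat["q"];
  d->ntm = dat["ntm"];
  d->het_s = dat["het_s"];
  d->het_m = dat["het_m"];
  d->k = d->y.n_cols;
  d->nm = d->y.n_rows;
  List presL = dat["pres"], AL = dat["A"];
  IntegerVector grp = dat["grp"];
  cube V = dat["V"];
  d->pres.resize(d->k);
  d->V.resize(d->k);
  d->complete.resize(d->k);
  d->grp.resize(d->k);
  for (int i = 0; i < d->k; ++i) {
    d->pres[i] = as<uvec>(presL[i]);
    d->complete[i] = ((int)d->pres[i].n_elem == d->nm);
    d->grp[i] = grp[i];
    mat Vi = V.slice(i);
    d->V[i] = d->complete[i] ? Vi : mat(Vi.submat(d->pres[i], d->pres[i]));
  }
  int ng = AL.size();
  d->A.resize(ng);
  for (int g = 0; g < ng; ++g) d->A[g] = as<mat>(AL[g]);
  XPtr<MasemData> ptr(d, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_masem_eval(const arma::vec &par, SEXP dptr, bool want_grad) {
  XPtr<MasemData> d(dptr);
  HetInfo h;
  h.het_s = d->het_s;
  h.het_m = d->het_m;
  h.p = d->p;
  h.ns = d->p * (d->p + 1) / 2;
  int ntm = d->ntm, nm = d->nm;

  vec thm = par.subvec(0, ntm - 1);
  vec hp;
  if ((int)par.n_elem > ntm) hp = par.subvec(ntm, par.n_elem - 1);
  mat Lm;
  mat T2 = build_T2(hp, h, Lm);

  double nll = 0.0;
  bool ok = true;
  vec gm(ntm, fill::zeros);
  mat G(nm, nm, fill::zeros);

  // per-profile cache of moments, Jacobians, and accumulated weights
  int ng = d->A.size();
  std::vector<vec> m_cache(ng), wsum(ng);
  std::vector<mat> J_cache(ng);
  std::vector<bool> cached(ng, false);

  mat C, Ci(nm, nm), Minv(nm, nm);
  vec z(nm), w(nm);

  for (int i = 0; i < d->k; ++i) {
    int g = d->grp[i];
    if (!cached[g]) {
      if (d->type == 1) {
        mat Jv;
        vec v = d->A[g] * thm + d->cvec;
        cfa_moments(v, d->p, d->q, m_cache[g],
                    want_grad ? &Jv : (mat *)nullptr);
        if (want_grad) J_cache[g] = Jv * d->A[g];
      } else {
        m_cache[g] = d->A[g] * thm;
        if (want_grad) J_cache[g] = d->A[g];
      }
      if (want_grad) wsum[g] = vec(nm, fill::zeros);
      cached[g] = true;
    }
    const uvec &pres = d->pres[i];
    bool full = d->complete[i];
    int ni = pres.n_elem;
    vec r = full ? vec(d->y.col(i) - m_cache[g])
                 : vec(vec(d->y.col(i))(pres) - m_cache[g](pres));
    C = d->V[i];
    if (full) {
      C += T2;
    } else {
      C += T2(pres, pres);
    }
    if (!chol_lower(C)) {
      ok = false;
      nll += 1e8;
      continue;
    }
    z.set_size(ni);
    fsolve(C, r, z);
    double ld = 0.0;
    for (int j = 0; j < ni; ++j) ld += std::log(C(j, j));
    nll += 0.5 * (2.0 * ld + dot(z, z) + ni * LOG2PI);
    if (want_grad) {
      w.set_size(ni);
      bsolve(C, z, w);
      tri_inv(C, Ci);
      if (full) {
        wsum[g] += w;
        // G += Minv - w w' (halved at the end)
        sympd_inv_from_chol(Ci, Minv);
        G += Minv;
        sub_outer(G, w);
      } else {
        gm -= J_cache[g].rows(pres).t() * w;
        mat Mi(ni, ni);
        sympd_inv_from_chol(Ci, Mi);
        mat Gi = Mi;
        sub_outer(Gi, w);
        G(pres, pres) += Gi;
      }
    }
  }

  vec grad;
  if (want_grad) {
    for (int g = 0; g < ng; ++g)
      if (cached[g] && wsum[g].n_elem) gm -= J_cache[g].t() * wsum[g];
    G *= 0.5;
    vec gh;
    if (hp.n_elem) het_grad_from_G(G, hp, h, Lm, gh);
    grad = join_cols(gm, gh);
    if (!ok) grad.zeros();
  }
  return List::create(_["nll"] = nll,
                      _["grad"] = NumericVector(grad.begin(), grad.end()),
                      _["ok"] = ok);
}

// Profiled saturated fit: for fixed heterogeneity parameters the saturated
// mean structure is linear in theta, so theta has the GLS closed form; the
// profiled gradient with respect to the heterogeneity parameters equals the
// partial gradient at the GLS solution (envelope theorem). For complete
// studies the kron structure of the saturated design ([I, x1 I, ...]) is
// exploited: only W and W y need accumulating per moderator profile.
// [[Rcpp::export]]
List cpp_sat_profile(const arma::vec &hp, SEXP dptr, bool want_grad) {
  XPtr<MasemData> d(dptr);
  HetInfo h;
  h.het_s = d->het_s;
  h.het_m = d->het_m;
  h.p = d->p;
  h.ns = d->p * (d->p + 1) / 2;
  int ntm = d->ntm, nm = d->nm, k = d->k;
  int nb = ntm / nm;  // 1 + number of moderators

  mat Lm;
  mat T2 = build_T2(hp, h, Lm);

  mat XtWX(ntm, ntm, fill::zeros);
  vec XtWy(ntm, fill::zeros);
  std::vector<mat> Ws(k);
  std::vector<double> lds(k);
  // per-profile accumulators for complete studies
  int ng = d->A.size();
  std::vector<mat> SW(ng), xg(ng);
  std::vector<vec> SWy(ng);
  std::vector<bool> seen(ng, false);

  mat C, Ci(nm, nm);
  bool ok = true;
  for (int i = 0; i < k; ++i) {
    const uvec &pres = d->pres[i];
    bool full = d->complete[i];
    int g = d->grp[i];
    C = d->V[i];
    if (full) {
      C += T2;
    } else {
      C += T2(pres, pres);
    }
    if (!chol_lower(C)) {
      ok = false;
      break;
    }
    int ni = pres.n_elem;
    double ld = 0.0;
    for (int j = 0; j < ni; ++j) ld += std::log(C(j, j));
    lds[i] = 2.0 * ld;
    tri_inv(C, Ci);
    Ws[i].set_size(ni, ni);
    sympd_inv_from_chol(Ci, Ws[i]);
    if (full) {
      if (!seen[g]) {
        SW[g] = mat(nm, nm, fill::zeros);
        SWy[g] = vec(nm, fill::zeros);
        // moderator profile (first row of each nm-block of A beyond I)
        xg[g] = mat(nb, 1);
        for (int b = 0; b < nb; ++b) xg[g](b, 0) = d->A[g](0, b * nm);
        seen[g] = true;
      }
      SW[g] += Ws[i];
      SWy[g] += Ws[i] * vec(d->y.col(i));
    } else {
      mat As = d->A[g].rows(pres);
      vec yip = vec(d->y.col(i))(pres);
      mat WA = Ws[i] * As;
      XtWX += As.t() * WA;
      XtWy += WA.t() * yip;
    }
  }
  if (ok) {
    for (int g = 0; g < ng; ++g) {
      if (!seen[g]) continue;
      for (int a = 0; a < nb; ++a) {
        XtWy.subvec(a * nm, (a + 1) * nm - 1) += xg[g](a, 0) * SWy[g];
        for (int b = 0; b < nb; ++b)
          XtWX.submat(a * nm, b * nm, (a + 1) * nm - 1, (b + 1) * nm - 1) +=
              xg[g](a, 0) * xg[g](b, 0) * SW[g];
      }
    }
  }
  vec theta;
  bool solved = ok && solve(theta, XtWX, XtWy, solve_opts::likely_sympd);
  if (!solved) {
    return List::create(_["nll"] = 1e10, _["theta"] = vec(ntm, fill::zeros),
                        _["grad"] = vec(hp.n_elem, fill::zeros),
                        _["ok"] = false);
  }

  double nll = 0.0;
  mat G(nm, nm, fill::zeros);
  for (int i = 0; i < k; ++i) {
    const uvec &pres = d->pres[i];
    bool full = d->complete[i];
    mat As = full ? d->A[d->grp[i]] : mat(d->A[d->grp[i]].rows(pres));
    vec yip = full ? vec(d->y.col(i)) : vec(vec(d->y.col(i))(pres));
    vec r = yip - As * theta;
    vec w = Ws[i] * r;
    nll += 0.5 * (lds[i] + dot(r, w) + pres.n_elem * LOG2PI);
    if (want_grad) {
      if (full) {
        G += Ws[i];
        sub_outer(G, w);
      } else {
        mat Gi = Ws[i];
        sub_outer(Gi, w);
        G(pres, pres) += Gi;
      }
    }
  }
  vec gh;
  if (want_grad && hp.n_elem) {
    G *= 0.5;
    het_grad_from_G(G, hp, h, Lm, gh);
  }
  return List::create(_["nll"] = nll,
                      _["theta"] = NumericVector(theta.begin(), theta.end()),
                      _["grad"] = NumericVector(gh.begin(), gh.end()),
                      _["ok"] = true);
}
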