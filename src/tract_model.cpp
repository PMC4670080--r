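// Fast engine for pulse-model tract-length spectra:
//  - migration schedules from 2- and 4-parameter demographic models, with
//    magnitudes pinned in closed/semi-closed form by the observed ancestry
//    proportions and non-integer times split across adjacent generations;
//  - expected tract-length spectra under the single-lineage Markov kernel
//    (state = (entry generation t, source), switch rate t-2 per Morgan,
//    redraw after a crossover at meiosis level s entering at generation >= s+2);
//  - Poisson composite log-likelihood and multi-start Nelder-Mead fitting.
// All positions are cM at the interface, Morgans internally.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

const double A_EPS = 1e-12;

// a[t][p] = m(t,p) * prod_{g=2}^{t-1} (1 - M(g)); lineage entry probabilities
arma::mat entry_probs(const arma::mat& m) {
  int T0 = m.n_rows, P = m.n_cols;
  arma::vec M = arma::sum(m, 1);
  arma::mat a(T0, P, arma::fill::zeros);
  double surv = 1.0;
  for (int t = 2; t <= T0; ++t) {
    for (int p = 0; p < P; ++p) a(t - 1, p) = m(t - 1, p) * surv;
    surv *= (1.0 - M(t - 1));
  }
  return a;
}

struct Kernel {
  std::vector<int> st_t, st_p;   // states (entry generation, source)
  arma::vec a;                   // stationary mass per state
  arma::mat R;                   // off-rate matrix R(x,y), x != y and self-jumps
  int K;
};

Kernel build_kernel(const arma::mat& m) {
  int T0 = m.n_rows, P = m.n_cols;
  arma::vec M = arma::sum(m, 1);
  arma::mat a = entry_probs(m);
  Kernel k; k.K = 0;
  for (int t = 2; t <= T0; ++t)
    for (int p = 0; p < P; ++p)
      if (a(t - 1, p) > A_EPS) { k.st_t.push_back(t); k.st_p.push_back(p); ++k.K; }
  k.a.set_size(k.K);
  for (int i = 0; i < k.K; ++i) k.a(i) = a(k.st_t[i] - 1, k.st_p[i]);
  // Cs(i,j) = prod_{g=i}^{j} (1-M(g)); precompute prefix products over g=1..T0
  arma::vec pref(T0 + 2); pref(0) = 1.0;
  for (int g = 1; g <= T0; ++g) pref(g) = pref(g - 1) * (1.0 - M(g - 1));
  auto Cs = [&](int i, int j) -> double {
    if (i > j) return 1.0;
    return (pref(i - 1) > 0) ? pref(j) / pref(i - 1) : 0.0;
  };
  k.R.zeros(k.K, k.K);
  for (int x = 0; x < k.K; ++x) {
    int t = k.st_t[x];
    for (int y = 0; y < k.K; ++y) {
      int u = k.st_t[y];
      int smax = std::min(t - 2, u - 2);
      if (smax < 1) continue;
      double tot = 0.0;
      for (int s = 1; s <= smax; ++s) {
        double c = 1.0;
        // product over g = s+2 .. u-1 (guard against zero prefix)
        if (s + 2 <= u - 1) {
          if (pref(s + 1) > 0) c = pref(u - 1) / pref(s + 1);
          else { c = 1.0; for (int g = s + 2; g <= u - 1; ++g) c *= (1.0 - M(g - 1)); }
        }
        tot += c;
      }
      k.R(x, y) = m(u - 1, k.st_p[y]) * tot;
    }
  }
  (void) Cs;
  return k;
}

// spectrum engine for one ancestry: complex-eigen representation of exp(T u)
struct AncEngine {
  bool present = false;
  bool degenerate = false;       // no exits (single-ancestry chain)
  arma::cx_vec ev;
  arma::cx_rowvec wB, wL;        // beta' V and lambda' V
  arma::cx_vec v1;               // V^{-1} 1
  double beta_tot = 0.0;
  bool fallback = false;
  arma::mat Tm;
  arma::vec beta, lam;
  double B(double u) const {     // P(at 0 in-q and still in-q at u), unnormalized
    if (!present) return 0.0;
    if (fallback) return arma::as_scalar(beta.t() * arma::expmat(Tm * u) *
                                         arma::ones(Tm.n_rows));
    arma::cx_double s(0, 0);
    for (arma::uword j = 0; j < ev.n_elem; ++j) s += wB(j) * std::exp(ev(j) * u) * v1(j);
    return s.real();
  }
  double S(double u) const {     // entry-rate-weighted survival, unnormalized
    if (!present) return 0.0;
    if (fallback) return arma::as_scalar(lam.t() * arma::expmat(Tm * u) *
                                         arma::ones(Tm.n_rows));
    arma::cx_double s(0, 0);
    for (arma::uword j = 0; j < ev.n_elem; ++j) s += wL(j) * std::exp(ev(j) * u) * v1(j);
    return s.real();
  }
};

AncEngine make_engine(const Kernel& k, int q) {
  AncEngine e;
  std::vector<int> idx;
  for (int i = 0; i < k.K; ++i) if (k.st_p[i] == q) idx.push_back(i);
  if (idx.empty()) return e;
  e.present = true;
  int n = idx.size();
  arma::mat Tm(n, n, arma::fill::zeros);
  arma::vec beta(n), lam(n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    int x = idx[i];
    beta(i) = k.a(x);
    for (int j = 0; j < n; ++j) Tm(i, j) = k.R(x, idx[j]);
    Tm(i, i) -= (k.st_t[x] - 2);
    for (int y = 0; y < k.K; ++y)
      if (k.st_p[y] != q) { /* exits implicit in diagonal */ }
  }
  for (int j = 0; j < n; ++j) {
    int y = idx[j];
    for (int x = 0; x < k.K; ++x)
      if (k.st_p[x] != q) lam(j) += k.a(x) * k.R(x, y);
  }
  e.beta_tot = arma::accu(beta);
  e.Tm = Tm; e.beta = beta; e.lam = lam;
  arma::cx_vec ev;
  arma::cx_mat V;
  bool ok = arma::eig_gen(ev, V, Tm);
  if (ok) {
    arma::cx_mat Vi;
    ok = arma::inv(Vi, V);
    if (ok) {
      double err = arma::norm(arma::real(V * arma::diagmat(ev) * Vi) - Tm, "fro");
      if (err < 1e-8 * (1.0 + arma::norm(Tm, "fro"))) {
        e.ev = ev;
        e.wB = arma::conv_to<arma::cx_rowvec>::from(beta.t()) * V;
        e.wL = arma::conv_to<arma::cx_rowvec>::from(lam.t()) * V;
        e.v1 = Vi * arma::cx_vec(arma::ones(n), arma::zeros(n));
        return e;
      }
    }
  }
  e.fallback = true;
  return e;
}

// expected per-haplotype counts for ancestry q across bins and chromosomes.
// edges, chrom lengths in Morgans; last edge may be Inf.
// B/S are evaluated once on the finite-edge grid and per chromosome end.
void fill_counts(const AncEngine& e, const arma::vec& edges, const arma::vec& chrL,
                 arma::rowvec& counts, arma::rowvec& full) {
  int nb = edges.n_elem - 1, nc = chrL.n_elem;
  counts.zeros(nb); full.zeros(nc);
  if (!e.present) return;
  int ne = edges.n_elem;
  std::vector<double> Be(ne), Se(ne);
  for (int i = 0; i < ne; ++i) {
    if (std::isfinite(edges(i))) { Be[i] = e.B(edges(i)); Se[i] = e.S(edges(i)); }
    else { Be[i] = 0.0; Se[i] = 0.0; }
  }
  for (int c = 0; c < nc; ++c) {
    double L = chrL(c);
    double BL = e.B(L);
    full(c) = BL;
    for (int b = 0; b < nb; ++b) {
      double l1 = edges(b), l2 = edges(b + 1);
      if (l1 >= L) continue;
      bool capped = !(l2 <= L);
      double Bl2c = capped ? BL : Be[b + 1];
      double cnt = Be[b] - Bl2c;
      double s1 = Se[b];
      if (std::isfinite(l2) && L > l2) cnt += (L - l2) * (s1 - Se[b + 1]);
      cnt += ((capped ? L : l2) - l1) * s1;
      counts(b) += cnt;
    }
  }
}

struct Spectrum {
  arma::mat counts;  // P x nb
  arma::mat full;    // P x nc
};

Spectrum expected_spectrum(const arma::mat& m, const arma::vec& chr_cM,
                           const arma::vec& edges_cM) {
  Kernel k = build_kernel(m);
  int P = m.n_cols, nb = edges_cM.n_elem - 1, nc = chr_cM.n_elem;
  arma::vec edges = edges_cM / 100.0, chrL = chr_cM / 100.0;
  Spectrum sp;
  sp.counts.zeros(P, nb); sp.full.zeros(P, nc);
  for (int q = 0; q < P; ++q) {
    AncEngine e = make_engine(k, q);
    arma::rowvec cnt, fl;
    fill_counts(e, edges, chrL, cnt, fl);
    sp.counts.row(q) = cnt;
    sp.full.row(q) = fl;
  }
  return sp;
}

double pois_ll(const arma::mat& mu, const arma::mat& obs) {
  double ll = 0.0;
  for (arma::uword i = 0; i < mu.n_elem; ++i) {
    double m = mu(i), o = obs(i);
    if (o > 0) {
      if (m <= 0) return -arma::datum::inf;
      ll += o * std::log(m) - m - std::lgamma(o + 1.0);
    } else ll -= m;
  }
  return ll;
}

// ---- demographic models ----
// model 0 (BASE):        params (t0, t_afr)
// model 1 (+EUR pulse):  params (t0, t_afr, t_pulse, m_pulse), pulse into column 0
// model 2 (+AFR pulse):  params (t0, t_afr, t_pulse, m_pulse), pulse into column 2
// columns: 0 = European-like founder, 1 = Native-like founder, 2 = African pulse.
struct SchedBuild { arma::mat m; bool ok; std::string why; };

void add_split_pulse(arma::mat& m, double t, double mag, int col) {
  int fl = (int) std::floor(t + 1e-9), ce = (int) std::ceil(t - 1e-9);
  double frac = t - fl;
  if (fl == ce) { m(fl - 1, col) += mag; return; }
  m(fl - 1, col) += mag * (1.0 - frac);
  m(ce - 1, col) += mag * frac;
}

SchedBuild assemble(int model, double t0, double tafr, double tp, double mp,
                    double pE, double pA, double mA, double f) {
  SchedBuild out; out.ok = false;
  int T0 = (int) std::ceil(t0 - 1e-9);
  int fl0 = (int) std::floor(t0 + 1e-9);
  arma::mat m(T0, 3, arma::fill::zeros);
  m(T0 - 1, 0) = f; m(T0 - 1, 1) = 1.0 - f;
  if (fl0 < T0) {
    double w0 = 1.0 - (t0 - fl0);  // refounding mass at floor(t0)
    m(fl0 - 1, 0) += w0 * f;
    m(fl0 - 1, 1) += w0 * (1.0 - f);
  }
  add_split_pulse(m, tafr, mA, 2);
  if (model == 1) add_split_pulse(m, tp, mp, 0);
  if (model == 2) add_split_pulse(m, tp, mp, 2);
  // validity: entries in [0,1], row sums <= 1 below T0, no migration at gen 1
  for (int t = 1; t <= T0; ++t) {
    double s = 0.0;
    for (int p = 0; p < 3; ++p) {
      if (m(t - 1, p) < -1e-12 || m(t - 1, p) > 1.0 + 1e-12) { out.why = "entry"; return out; }
      s += m(t - 1, p);
    }
    if (t == 1 && s > 0) { out.why = "gen1"; return out; }
    if (t < T0 && s > 1.0 + 1e-9) { out.why = "rowsum"; return out; }
  }
  out.m = m; out.ok = true;
  return out;
}

SchedBuild build_schedule(int model, const arma::vec& par, const arma::vec& props) {
  SchedBuild bad; bad.ok = false;
  double t0 = par(0), tafr = par(1);
  double tp = (model > 0) ? par(2) : 0.0, mp = (model > 0) ? par(3) : 0.0;
  double pE = props(0), pA = props(2);
  bad.why = "structure";
  if (!(t0 >= 2.0 && tafr >= 2.0)) return bad;
  int fl0 = (int) std::floor(t0 + 1e-9);
  if ((int) std::ceil(tafr - 1e-9) > fl0 - 1) return bad;   // pulse strictly after founding block
  if (model > 0) {
    if (!(tp >= 2.0) || (int) std::ceil(tp - 1e-9) > fl0 - 1) return bad;
    if (!(mp >= 0.0 && mp <= 0.999)) return bad;
  }
  // solve mA so that final African fraction equals pA (monotone -> bisection)
  auto afr_of = [&](double mA) -> double {
    SchedBuild s = assemble(model, t0, tafr, tp, mp, pE, pA, mA, 0.5);
    if (!s.ok) return arma::datum::nan;
    arma::mat a = entry_probs(s.m);
    return arma::accu(a.col(2));
  };
  double hi = 1.0, fhi = afr_of(hi);
  for (double h : {0.999, 0.99, 0.9, 0.75, 0.5, 0.25, 0.1}) {
    if (std::isfinite(fhi)) break;
    hi = h; fhi = afr_of(hi);
  }
  double flo = afr_of(0.0);
  if (!std::isfinite(flo) || !std::isfinite(fhi)) return bad;
  bad.why = "afr-pin";
  if (flo > pA + 1e-12 || fhi < pA - 1e-12) return bad;
  // the final African fraction is an exact quadratic in mA
  double y0 = flo, y1 = afr_of(0.5 * hi), y2 = fhi;
  double qa = (2.0 * y2 + 2.0 * y0 - 4.0 * y1) / (hi * hi);
  double qb = (y2 - y0) / hi - qa * hi;
  double mA = arma::datum::nan;
  if (std::abs(qa) < 1e-14) {
    if (std::abs(qb) > 1e-14) mA = (pA - y0) / qb;
  } else {
    double disc = qb * qb - 4.0 * qa * (y0 - pA);
    if (disc >= 0) {
      double r1 = (-qb + std::sqrt(disc)) / (2.0 * qa);
      double r2 = (-qb - std::sqrt(disc)) / (2.0 * qa);
      for (double r : {r1, r2})
        if (r >= -1e-12 && r <= hi + 1e-12 &&
            (!std::isfinite(mA) || std::abs(r - 0.5 * hi) < std::abs(mA - 0.5 * hi)))
          mA = r;
      if (std::isfinite(r1) && std::isfinite(r2) &&
          r1 >= -1e-12 && r1 <= hi + 1e-12 && r2 >= -1e-12 && r2 <= hi + 1e-12) {
        // both roots admissible: take the one matching the target
        mA = (std::abs(afr_of(std::min(std::max(r1, 0.0), hi)) - pA) <=
              std::abs(afr_of(std::min(std::max(r2, 0.0), hi)) - pA)) ? r1 : r2;
      }
    }
  }
  if (std::isfinite(mA)) mA = std::min(hi, std::max(0.0, mA));
  if (!std::isfinite(mA) || std::abs(afr_of(mA) - pA) > 1e-9) {
    // fallback: monotone bisection
    double lo = 0.0;
    for (int it = 0; it < 60; ++it) {
      double mid = 0.5 * (lo + hi), fm = afr_of(mid);
      if (!std::isfinite(fm)) return bad;
      if (fm < pA) lo = mid; else hi = mid;
    }
    mA = 0.5 * (lo + hi);
    if (std::abs(afr_of(mA) - pA) > 1e-7) return bad;
  }
  // founding fraction f: final European fraction is affine in f
  auto eur_of = [&](double f) -> double {
    SchedBuild s = assemble(model, t0, tafr, tp, mp, pE, pA, mA, f);
    if (!s.ok) return arma::datum::nan;
    arma::mat a = entry_probs(s.m);
    return arma::accu(a.col(0));
  };
  double e0 = eur_of(0.0), e1 = eur_of(1.0);
  bad.why = "eur-pin";
  if (!std::isfinite(e0) || !std::isfinite(e1) || std::abs(e1 - e0) < 1e-12) return bad;
  double f = (pE - e0) / (e1 - e0);
  if (f < -1e-9 || f > 1.0 + 1e-9) return bad;
  f = std::min(1.0, std::max(0.0, f));
  SchedBuild s = assemble(model, t0, tafr, tp, mp, pE, pA, mA, f);
  if (!s.ok) return s;
  arma::mat a = entry_probs(s.m);
  bad.why = "pin-check";
  if (std::abs(arma::accu(a.col(1)) - props(1)) > 1e-6) return bad;
  return s;
}

struct Objective {
  int model;
  arma::vec props, chr_cM, edges_cM;
  arma::mat obs_counts, obs_full;
  double n_hap;
  double lo_t = 2.0, hi_t = 25.0, lo_m = 0.001, hi_m = 0.999;
  double operator()(const arma::vec& par) const {
    double pen = 0.0;
    int k = par.n_elem;
    for (int i = 0; i < k; ++i) {
      double lo = (i == 3) ? lo_m : lo_t, hi = (i == 3) ? hi_m : hi_t;
      if (par(i) < lo) pen += lo - par(i);
      if (par(i) > hi) pen += par(i) - hi;
    }
    if (par(1) > par(0) - 1.0) pen += par(1) - (par(0) - 1.0);
    if (k > 2 && par(2) > par(0) - 1.0) pen += par(2) - (par(0) - 1.0);
    if (pen > 0) return 1e9 * (1.0 + pen);
    SchedBuild s = build_schedule(model, par, props);
    if (!s.ok) return 1e9;
    Spectrum sp = expected_spectrum(s.m, chr_cM, edges_cM);
    double ll = pois_ll(sp.counts * n_hap, obs_counts) +
                pois_ll(sp.full * n_hap, obs_full);
    if (!std::isfinite(ll)) return 1e9;
    return -ll;
  }
};

// compact Nelder-Mead
arma::vec nelder_mead(const Objective& fn, const arma::vec& x0, int maxit,
                      double tol, double& fbest, int& evals) {
  int n = x0.n_elem;
  arma::mat X(n, n + 1);
  arma::vec F(n + 1);
  X.col(0) = x0; F(0) = fn(x0); evals = 1;
  for (int i = 0; i < n; ++i) {
    arma::vec xi = x0;
    double step = (i == 3) ? 0.05 : 1.0;
    xi(i) += step;
    X.col(i + 1) = xi; F(i + 1) = fn(xi); ++evals;
  }
  for (int it = 0; it < maxit; ++it) {
    arma::uvec ord = arma::sort_index(F);
    X = X.cols(ord); F = F(ord);
    if (std::abs(F(n) - F(0)) < tol && F(0) < 1e8) break;
    arma::vec cen = arma::mean(X.cols(0, n - 1), 1);
    arma::vec xr = cen + (cen - X.col(n));
    double fr = fn(xr); ++evals;
    if (fr < F(0)) {
      arma::vec xe = cen + 2.0 * (cen - X.col(n));
      double fe = fn(xe); ++evals;
      if (fe < fr) { X.col(n) = xe; F(n) = fe; } else { X.col(n) = xr; F(n) = fr; }
    } else if (fr < F(n - 1)) {
      X.col(n) = xr; F(n) = fr;
    } else {
      arma::vec xc = cen + 0.5 * (X.col(n) - cen);
      double fc = fn(xc); ++evals;
      if (fc < F(n)) { X.col(n) = xc; F(n) = fc; }
      else {
        for (int i = 1; i <= n; ++i) {
          X.col(i) = X.col(0) + 0.5 * (X.col(i) - X.col(0));
          F(i) = fn(X.col(i)); ++evals;
        }
      }
    }
  }
  arma::uword ib = F.index_min();
  fbest = F(ib);
  return X.col(ib);
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix build_schedule_cpp(int model, NumericVector params, NumericVector props) {
  SchedBuild s = build_schedule(model, as<arma::vec>(params), as<arma::vec>(props));
  if (!s.ok) {
    NumericMatrix out(0, 0);
    out.attr("feasible") = false;
    out.attr("reason") = s.why;
    return out;
  }
  NumericMatrix out = wrap(s.m);
  out.attr("feasible") = true;
  return out;
}

// [[Rcpp::export]]
List expected_spectrum_markov_cpp(NumericMatrix sched, NumericVector chrom_cM,
                                  NumericVector edges_cM) {
  Spectrum sp = expected_spectrum(as<arma::mat>(sched), as<arma::vec>(chrom_cM),
                                  as<arma::vec>(edges_cM));
  return List::create(_["counts"] = wrap(sp.counts), _["full"] = wrap(sp.full));
}

// [[Rcpp::export]]
double poisson_loglik_cpp(NumericMatrix mu_counts, NumericMatrix mu_full,
                          NumericMatrix obs_counts, NumericMatrix obs_full) {
  return pois_ll(as<arma::mat>(mu_counts), as<arma::mat>(obs_counts)) +
         pois_ll(as<arma::mat>(mu_full), as<arma::mat>(obs_full));
}

// [[Rcpp::export]]
List fit_model_cpp(int model, NumericVector props, NumericVector chrom_cM,
                   NumericVector edges_cM, NumericMatrix obs_counts,
                   NumericMatrix obs_full, double n_hap, NumericMatrix starts,
                   int maxit = 400, double tol = 1e-6) {
  Objective fn;
  fn.model = model;
  fn.props = as<arma::vec>(props);
  fn.chr_cM = as<arma::vec>(chrom_cM);
  fn.edges_cM = as<arma::vec>(edges_cM);
  fn.obs_counts = as<arma::mat>(obs_counts);
  fn.obs_full = as<arma::mat>(obs_full);
  fn.n_hap = n_hap;
  int k = starts.nrow(), ns = starts.ncol();
  arma::vec best; double fbest = arma::datum::inf;
  NumericVector start_ll(ns);
  int tot_evals = 0;
  for (int s = 0; s < ns; ++s) {
    arma::vec x0(k);
    for (int i = 0; i < k; ++i) x0(i) = starts(i, s);
    double fv; int ev;
    arma::vec xb = nelder_mead(fn, x0, maxit, tol, fv, ev);
    tot_evals += ev;
    start_ll[s] = (fv < 1e8) ? -fv : NA_REAL;
    if (fv < fbest) { fbest = fv; best = xb; }
  }
  bool conv = fbest < 1e8;
  return List::create(_["par"] = conv ? wrap(best) : R_NilValue,
                      _["logLik"] = conv ? -fbest : NA_REAL,
                      _["converged"] = conv,
                      _["evals"] = tot_evals,
                      _["start_logLik"] = start_ll);
}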