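// Core loops for empirical mode decomposition (univariate and multivariate).
// Everything here is deterministic; randomness (noise channels, projection
// direction seeds) lives on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---- extrema -------------------------------------------------------------

// Strict local extrema; a flat plateau contributes its midpoint index.
// Endpoints are never extrema. Indices are 0-based.
static void extrema_core(const double* x, int T, std::vector<int>& mins,
                         std::vector<int>& maxs) {
  mins.clear(); maxs.clear();
  int prev = 0;    // sign of the last nonzero slope
  int previ = -1;  // slope index (between previ and previ+1)
  for (int i = 0; i + 1 < T; ++i) {
    double d = x[i + 1] - x[i];
    int s = (d > 0.0) - (d < 0.0);
    if (s == 0) continue;
    if (prev != 0 && s != prev) {
      int lo = previ + 1, hi = i;   // run of equal values (possibly length 1)
      int mid = (lo + hi) / 2;
      if (prev > 0) maxs.push_back(mid); else mins.push_back(mid);
    }
    prev = s;
    previ = i;
  }
}

// Zero crossings: sign changes between consecutive nonzero samples; runs of
// exact zeros are counted once.
static int zero_crossings(const arma::vec& x) {
  int prev = 0, n = 0;
  for (arma::uword i = 0; i < x.n_elem; ++i) {
    int s = (x[i] > 0.0) - (x[i] < 0.0);
    if (s == 0) continue;
    if (prev != 0 && s != prev) ++n;
    prev = s;
  }
  return n;
}

// ---- natural cubic spline through extrema, shared-knot evaluation --------

// The envelope spline knots are the extrema of one projection, so for a
// multichannel signal the knot positions (and hence the tridiagonal
// factorization and output segment lookup) are shared across channels; only
// the knot values change. The plan precomputes everything value-independent.
// The two edge-nearest extrema are mirrored about each signal end.
struct SplinePlan {
  int n;                       // knots incl. 4 mirrored
  std::vector<double> xs, h, l, mu;
  std::vector<int> gather;     // signal index supplying each knot value
  std::vector<int> seg;        // per output sample, active segment
  std::vector<double> dx;      // per output sample, offset into segment
};

// one mirrored edge knot: position (possibly outside [0, T-1]) plus the
// source sample index supplying its value
struct Knot { double pos; int gat; };

// Rilling-style extension for one side. `edge` is 0 (left) or T-1 (right).
// Mirrors up to nbsym=2 extrema about the edge-nearest extremum when the
// endpoint lies between the first envelopes, otherwise about the endpoint
// itself with the endpoint joining the opposite envelope's knots. Falls
// back to plain reflection about the endpoint when the mirrored knots fail
// to cover the edge.
static void extend_side(const double* p, int T, const std::vector<int>& maxs,
                        const std::vector<int>& mins, bool left,
                        std::vector<Knot>& ext_max, std::vector<Knot>& ext_min) {
  const int nbsym = 2;
  ext_max.clear(); ext_min.clear();
  const double edge = left ? 0.0 : (double)(T - 1);
  // index sequences ordered from the edge inwards
  auto pick = [&](const std::vector<int>& v, int from, int count) {
    std::vector<int> out;
    int n = (int)v.size();
    for (int j = from; j < n && (int)out.size() < count; ++j)
      out.push_back(left ? v[j] : v[n - 1 - j]);
    return out;
  };
  int fmax = left ? maxs.front() : maxs.back();
  int fmin = left ? mins.front() : mins.back();
  bool max_first = left ? (fmax < fmin) : (fmax > fmin);
  double sym;
  std::vector<int> lm, ln;
  bool endpoint_knot_min = false, endpoint_knot_max = false;
  int ei = left ? 0 : T - 1;
  if (max_first) {
    if ((left ? p[0] : p[T - 1]) > p[fmin]) {
      sym = fmax;
      lm = pick(maxs, 1, nbsym);
      ln = pick(mins, 0, nbsym);
    } else {
      sym = edge;
      lm = pick(maxs, 0, nbsym);
      ln = pick(mins, 0, nbsym - 1);
      endpoint_knot_min = true;
    }
  } else {
    if ((left ? p[0] : p[T - 1]) < p[fmax]) {
      sym = fmin;
      ln = pick(mins, 1, nbsym);
      lm = pick(maxs, 0, nbsym);
    } else {
      sym = edge;
      ln = pick(mins, 0, nbsym);
      lm = pick(maxs, 0, nbsym - 1);
      endpoint_knot_max = true;
    }
  }
  auto mirrored = [&](const std::vector<int>& src, bool endpoint,
                      std::vector<Knot>& out) {
    for (int g : src) out.push_back({2.0 * sym - (double)g, g});
    if (endpoint) out.push_back({edge, ei});
  };
  mirrored(lm, endpoint_knot_max, ext_max);
  mirrored(ln, endpoint_knot_min, ext_min);
  // coverage check: mirrored knots must reach past the edge
  auto covers = [&](const std::vector<Knot>& v) {
    for (const Knot& k : v)
      if (left ? (k.pos <= 0.0) : (k.pos >= (double)(T - 1))) return true;
    return false;
  };
  if (!covers(ext_max) || !covers(ext_min)) {
    // plain reflection about the endpoint always covers
    sym = edge;
    ext_max.clear(); ext_min.clear();
    for (int g : pick(maxs, 0, nbsym)) ext_max.push_back({2.0 * sym - g, g});
    for (int g : pick(mins, 0, nbsym)) ext_min.push_back({2.0 * sym - g, g});
  }
}

// assemble a spline plan from edge extensions plus interior extrema
static void finish_plan(const std::vector<Knot>& lft,
                        const std::vector<int>& interior,
                        const std::vector<Knot>& rgt, int T, SplinePlan& P) {
  std::vector<Knot> all;
  all.reserve(lft.size() + interior.size() + rgt.size());
  for (const Knot& k : lft) all.push_back(k);
  for (int g : interior) all.push_back({(double)g, g});
  for (const Knot& k : rgt) all.push_back(k);
  std::sort(all.begin(), all.end(),
            [](const Knot& a, const Knot& b) { return a.pos < b.pos; });
  // enforce strictly increasing positions
  std::vector<Knot> keep;
  for (const Knot& k : all)
    if (keep.empty() || k.pos > keep.back().pos + 1e-9) keep.push_back(k);
  P.n = (int)keep.size();
  P.xs.resize(P.n); P.gather.resize(P.n);
  for (int i = 0; i < P.n; ++i) { P.xs[i] = keep[i].pos; P.gather[i] = keep[i].gat; }
  P.h.resize(P.n - 1);
  for (int i = 0; i < P.n - 1; ++i) P.h[i] = P.xs[i + 1] - P.xs[i];
  P.l.resize(P.n); P.mu.resize(P.n);
  P.l[0] = 1.0; P.mu[0] = 0.0;
  for (int i = 1; i < P.n - 1; ++i) {
    P.l[i] = 2.0 * (P.xs[i + 1] - P.xs[i - 1]) - P.h[i - 1] * P.mu[i - 1];
    P.mu[i] = P.h[i] / P.l[i];
  }
  P.seg.resize(T); P.dx.resize(T);
  int s = 0;
  for (int t = 0; t < T; ++t) {
    while (s < P.n - 2 && P.xs[s + 1] < (double)t) ++s;
    P.seg[t] = s;
    P.dx[t] = (double)t - P.xs[s];
  }
}

// Scratch buffers reused across evaluations to avoid reallocation.
struct SplineScratch { std::vector<double> ys, z, M; };

// Natural cubic spline (Burden-Faires form) with the plan's factorization;
// values are gathered from `v` at the plan's knot indices.
static void plan_eval(const SplinePlan& P, const double* v, int stride,
                      double* out, int T, SplineScratch& S) {
  const int n = P.n;
  S.ys.resize(n); S.z.resize(n); S.M.resize(n);
  for (int i = 0; i < n; ++i) S.ys[i] = v[(size_t)P.gather[i] * stride];
  S.z[0] = 0.0;
  for (int i = 1; i < n - 1; ++i) {
    double alpha = 3.0 * ((S.ys[i + 1] - S.ys[i]) / P.h[i] -
                          (S.ys[i] - S.ys[i - 1]) / P.h[i - 1]);
    S.z[i] = (alpha - P.h[i - 1] * S.z[i - 1]) / P.l[i];
  }
  S.M[n - 1] = 0.0;
  for (int i = n - 2; i >= 0; --i) S.M[i] = S.z[i] - P.mu[i] * S.M[i + 1];
  for (int t = 0; t < T; ++t) {
    int s = P.seg[t];
    double dx = P.dx[t];
    double b = (S.ys[s + 1] - S.ys[s]) / P.h[s] -
               P.h[s] * (S.M[s + 1] + 2.0 * S.M[s]) / 3.0;
    double d = (S.M[s + 1] - S.M[s]) / (3.0 * P.h[s]);
    out[t] = S.ys[s] + dx * (b + dx * (S.M[s] + dx * d));
  }
}

// build upper (maxima) and lower (minima) envelope plans with shared edge
// logic driven by the projection/signal p
static void build_plans(const double* p, int T, const std::vector<int>& maxs,
                        const std::vector<int>& mins, SplinePlan& Pu,
                        SplinePlan& Pl) {
  std::vector<Knot> lmax, lmin, rmax, rmin;
  extend_side(p, T, maxs, mins, true, lmax, lmin);
  extend_side(p, T, maxs, mins, false, rmax, rmin);
  finish_plan(lmax, maxs, rmax, T, Pu);
  finish_plan(lmin, mins, rmin, T, Pl);
}

// ---- exported helpers ----------------------------------------------------

// [[Rcpp::export]]
List cpp_find_extrema(const arma::vec& x) {
  std::vector<int> mins, maxs;
  extrema_core(x.memptr(), (int)x.n_elem, mins, maxs);
  return List::create(_["minima"] = wrap(mins), _["maxima"] = wrap(maxs));
}

// [[Rcpp::export]]
int cpp_zero_crossings(const arma::vec& x) { return zero_crossings(x); }

// [[Rcpp::export]]
List cpp_envelopes(const arma::vec& x) {
  std::vector<int> mins, maxs;
  const int T = (int)x.n_elem;
  extrema_core(x.memptr(), T, mins, maxs);
  if ((int)maxs.size() < 2 || (int)mins.size() < 2)
    return List::create(_["ok"] = false,
                        _["n_min"] = (int)mins.size(),
                        _["n_max"] = (int)maxs.size());
  SplinePlan Pu, Pl; SplineScratch S;
  build_plans(x.memptr(), T, maxs, mins, Pu, Pl);
  arma::vec eu(T), el(T);
  plan_eval(Pu, x.memptr(), 1, eu.memptr(), T, S);
  plan_eval(Pl, x.memptr(), 1, el.memptr(), T, S);
  return List::create(_["ok"] = true, _["upper"] = eu, _["lower"] = el,
                      _["mean"] = (eu + el) / 2.0,
                      _["n_min"] = (int)mins.size(),
                      _["n_max"] = (int)maxs.size());
}

// ---- univariate sifting --------------------------------------------------

// Rilling-style three-threshold stopping: stop when the envelope-mean to
// envelope-amplitude ratio |m|/a is below th1 on a fraction >= 1 - tol_frac
// of samples and below th2 everywhere. With check_counts, additionally
// require |#zero crossings - #extrema| <= 1.
struct SiftResult { arma::vec imf; bool converged; int iters; };

static SiftResult sift_uni(const arma::vec& x, double th1, double th2,
                           double tol_frac, int max_iter, bool check_counts) {
  const int T = (int)x.n_elem;
  arma::vec d = x;
  SiftResult res; res.converged = false; res.iters = 0;
  std::vector<int> mins, maxs;
  SplinePlan Pu, Pl; SplineScratch S;
  arma::vec eu(T), el(T);
  for (int it = 0; it < max_iter; ++it) {
    extrema_core(d.memptr(), T, mins, maxs);
    if ((int)mins.size() < 2 || (int)maxs.size() < 2) break;  // trend: keep d
    build_plans(d.memptr(), T, maxs, mins, Pu, Pl);
    plan_eval(Pu, d.memptr(), 1, eu.memptr(), T, S);
    plan_eval(Pl, d.memptr(), 1, el.memptr(), T, S);
    arma::vec m = (eu + el) / 2.0;
    arma::vec a = arma::abs(eu - el) / 2.0;
    double floora = 1e-12 * (arma::abs(d).max() + 1e-300);
    arma::vec sx = arma::abs(m) / arma::clamp(a, floora, arma::datum::inf);
    bool rill = (arma::mean(arma::conv_to<arma::vec>::from(sx > th1)) < tol_frac) &&
                (sx.max() < th2);
    bool counts = true;
    if (check_counts) {
      int ne = (int)(mins.size() + maxs.size());
      counts = std::abs(zero_crossings(d) - ne) <= 1;
    }
    res.iters = it + 1;
    if (rill && counts) { res.converged = true; break; }
    d -= m;
  }
  res.imf = d;
  return res;
}

// [[Rcpp::export]]
List cpp_sift(const arma::vec& x, double th1, double th2, double tol_frac,
              int max_iter, bool check_counts) {
  SiftResult r = sift_uni(x, th1, th2, tol_frac, max_iter, check_counts);
  return List::create(_["imf"] = r.imf, _["converged"] = r.converged,
                      _["iters"] = r.iters);
}

// [[Rcpp::export]]
List cpp_emd(const arma::vec& x, int max_imfs, double th1, double th2,
             double tol_frac, int max_iter) {
  const int T = (int)x.n_elem;
  arma::vec res = x;
  std::vector<arma::vec> imfs;
  std::vector<int> mins, maxs;
  bool all_conv = true;
  while ((int)imfs.size() < max_imfs) {
    extrema_core(res.memptr(), T, mins, maxs);
    if ((int)mins.size() < 2 || (int)maxs.size() < 2) break;
    SiftResult r = sift_uni(res, th1, th2, tol_frac, max_iter, true);
    all_conv = all_conv && r.converged;
    imfs.push_back(r.imf);
    res -= r.imf;
  }
  arma::mat M(imfs.size(), T);
  for (size_t w = 0; w < imfs.size(); ++w) M.row(w) = imfs[w].t();
  return List::create(_["imfs"] = M, _["residual"] = res,
                      _["all_converged"] = all_conv);
}

// ---- multivariate sifting ------------------------------------------------

// Local mean per the K-projection scheme: project onto each direction,
// locate the projection's extrema in time, interpolate every channel at
// those times, and average upper+lower envelopes over directions. Returns
// false when no direction yields >=2 minima and >=2 maxima.
static bool local_mean_multi(const arma::mat& X, const arma::mat& dirs,
                             arma::mat& mean_out, arma::vec& amp_out,
                             int& n_used) {
  const int n = (int)X.n_rows, T = (int)X.n_cols, K = (int)dirs.n_rows;
  mean_out.zeros(n, T);
  amp_out.zeros(T);
  n_used = 0;
  std::vector<int> mins, maxs;
  SplinePlan Pu, Pl; SplineScratch S;
  arma::vec proj(T), eu(T), el(T), sq(T);
  for (int k = 0; k < K; ++k) {
    proj = (dirs.row(k) * X).t();
    extrema_core(proj.memptr(), T, mins, maxs);
    if ((int)mins.size() < 2 || (int)maxs.size() < 2) continue;
    build_plans(proj.memptr(), T, maxs, mins, Pu, Pl);
    sq.zeros();
    for (int c = 0; c < n; ++c) {
      // arma matrices are column-major: row c strides by n
      plan_eval(Pu, X.memptr() + c, n, eu.memptr(), T, S);
      plan_eval(Pl, X.memptr() + c, n, el.memptr(), T, S);
      mean_out.row(c) += (eu + el).t();
      sq += arma::square(eu - el);
    }
    amp_out += arma::sqrt(sq) / 2.0;
    ++n_used;
  }
  if (n_used == 0) return false;
  mean_out /= (2.0 * n_used);
  amp_out /= n_used;
  return true;
}

// [[Rcpp::export]]
List cpp_local_mean_multi(const arma::mat& X, const arma::mat& dirs) {
  arma::mat m; arma::vec a; int used = 0;
  bool ok = local_mean_multi(X, dirs, m, a, used);
  return List::create(_["ok"] = ok, _["mean"] = m, _["amplitude"] = a,
                      _["n_directions_used"] = used);
}

// Multivariate sifting keeps only the envelope-mean stopping criterion; the
// extrema/zero-crossing count condition is not imposed (extrema of a
// multichannel signal are not well defined).
static arma::mat sift_multi(const arma::mat& X, const arma::mat& dirs,
                            double th1, double th2, double tol_frac,
                            int max_iter, bool& converged) {
  arma::mat d = X;
  converged = false;
  arma::mat m; arma::vec a; int used = 0;
  for (int it = 0; it < max_iter; ++it) {
    if (!local_mean_multi(d, dirs, m, a, used)) break;
    arma::vec mnorm = arma::sqrt(arma::sum(arma::square(m), 0)).t();
    double floora = 1e-12 * (arma::abs(d).max() + 1e-300);
    arma::vec sx = mnorm / arma::clamp(a, floora, arma::datum::inf);
    if ((arma::mean(arma::conv_to<arma::vec>::from(sx > th1)) < tol_frac) &&
        (sx.max() < th2)) { converged = true; break; }
    d -= m;
  }
  return d;
}

// [[Rcpp::export]]
List cpp_memd(const arma::mat& X, const arma::mat& dirs, int max_imfs,
              double th1, double th2, double tol_frac, int max_iter) {
  arma::mat res = X;
  std::vector<arma::mat> imfs;
  bool all_conv = true;
  arma::mat m; arma::vec a; int used = 0;
  while ((int)imfs.size() < max_imfs) {
    // stop when every projection of the residual is monotone/trend
    if (!local_mean_multi(res, dirs, m, a, used)) break;
    bool conv = false;
    arma::mat imf = sift_multi(res, dirs, th1, th2, tol_frac, max_iter, conv);
    all_conv = all_conv && conv;
    imfs.push_back(imf);
    res -= imf;
    if (arma::abs(res).max() < 1e-14 * (arma::abs(X).max() + 1e-300)) break;
  }
  List li(imfs.size());
  for (size_t w = 0; w < imfs.size(); ++w) li[w] = imfs[w];
  return List::create(_["imfs"] = li, _["residual"] = res,
                      _["all_converged"] = all_conv);
}

// ---- cluster permutation helper -------------------------------------------

// For each column of t-scores: maximum over contiguous supra-threshold runs
// of the run's sum (0 when no sample exceeds the threshold). NaN entries
// never join a run.
// [[Rcpp::export]]
arma::vec cpp_max_cluster_sums(const arma::mat& tmat, double thresh) {
  const int T = (int)tmat.n_rows, P = (int)tmat.n_cols;
  arma::vec out(P, arma::fill::zeros);
  for (int p = 0; p < P; ++p) {
    double best = 0.0, cur = 0.0;
    bool in_run = false;
    for (int t = 0; t < T; ++t) {
      double v = tmat(t, p);
      if (std::isfinite(v) && v > thresh) {
        cur = in_run ? cur + v : v;
        in_run = true;
        if (cur > best) best = cur;
      } else {
        in_run = false;
      }
    }
    out[p] = best;
  }
  return out;
}
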