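// Registration potential, analytic gradient, topology-guarded minimizer and
// point-in-mesh location.  Coordinates are n x 2; all indices arrive 1-based
// from R and are converted here.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

namespace {

const double PI_ = 3.14159265358979323846;

struct PotParts {
  double fe, fth, fp, fphi, f;
  double he, ge, hth, gth;      // unnormalised harmonic / well components
  bool admissible;
  double minAngle, maxAngle, minEdge, maxEdgeFrac; // diagnostics
};

// Evaluate the four potential terms at x.  If grad is non-null it must be a
// zero-initialised 2n vector (x-components first, then y) which receives the
// analytic gradient of F = Fe + Fth + Fp + Fphi.
PotParts evalPotential(const NumericMatrix &x,
                       const IntegerMatrix &E, const NumericVector &r0,
                       double q0, const NumericVector &q1,
                       const IntegerMatrix &Th, const NumericVector &a0,
                       const IntegerVector &P, const NumericMatrix &x0,
                       const IntegerVector &av, const NumericMatrix &ay,
                       const NumericVector &asig, const NumericVector &aw,
                       std::vector<double> *grad) {
  const int n = x.nrow();
  const int nE = E.nrow(), nT = Th.nrow(), nP = P.size(), nA = av.size();
  PotParts out;
  out.fe = out.fth = out.fp = out.fphi = out.f = 0.0;
  out.he = out.ge = out.hth = out.gth = 0.0;
  out.admissible = true;
  out.minAngle = PI_;
  out.maxAngle = 0.0;
  out.minEdge = std::numeric_limits<double>::infinity();
  out.maxEdgeFrac = 0.0;

  // --- edge term: (He + Ge) / |E| ---
  double He = 0.0, Ge = 0.0;
  for (int e = 0; e < nE; ++e) {
    const int u = E(e, 0) - 1, v = E(e, 1) - 1;
    const double dx = x(u, 0) - x(v, 0), dy = x(u, 1) - x(v, 1);
    const double r = std::sqrt(dx * dx + dy * dy);
    const double qe = q1[e];
    if (r <= q0 || (R_finite(qe) && r >= qe)) { out.admissible = false; return out; }
    if (r - q0 < out.minEdge) out.minEdge = r - q0;
    if (R_finite(qe) && r / qe > out.maxEdgeFrac) out.maxEdgeFrac = r / qe;
    const double dr = r - r0[e];
    He += 0.5 * dr * dr;
    const double A = r0[e] - q0;
    const double ta = A / (r - q0) - 1.0;
    double dGdr = -ta * A / ((r - q0) * (r - q0));
    double g2 = 0.0;
    if (R_finite(qe)) {
      const double B = qe - r0[e];
      const double tb = B / (qe - r) - 1.0;
      g2 = 0.5 * tb * tb;
      dGdr += tb * B / ((qe - r) * (qe - r));
    }
    Ge += 0.5 * ta * ta + g2;
    if (grad && nE > 0) {
      const double dFdr = (dr + dGdr) / nE;
      const double gx = dFdr * dx / r, gy = dFdr * dy / r;
      (*grad)[u] += gx;       (*grad)[n + u] += gy;
      (*grad)[v] -= gx;       (*grad)[n + v] -= gy;
    }
  }
  out.fe = (nE > 0) ? (He + Ge) / nE : 0.0;
  out.he = He; out.ge = Ge;

  // --- angle term: (Hth + Gth) / |Th| ---
  double Hth = 0.0, Gth = 0.0;
  for (int t = 0; t < nT; ++t) {
    const int a = Th(t, 0) - 1, b = Th(t, 1) - 1, c = Th(t, 2) - 1;
    const double ux = x(b, 0) - x(a, 0), uy = x(b, 1) - x(a, 1);
    const double vx = x(c, 0) - x(a, 0), vy = x(c, 1) - x(a, 1);
    const double cross = ux * vy - uy * vx, dot = ux * vx + uy * vy;
    const double al = std::atan2(cross, dot);
    if (al <= 0.0 || al >= PI_) { out.admissible = false; return out; }
    if (al < out.minAngle) out.minAngle = al;
    if (al > out.maxAngle) out.maxAngle = al;
    const double da = al - a0[t];
    Hth += 0.5 * da * da;
    const double ra = a0[t] / al - 1.0;
    const double rb = (PI_ - a0[t]) / (PI_ - al) - 1.0;
    Gth += 0.5 * (ra * ra + rb * rb);
    if (grad) {
      double dFda = (da - ra * a0[t] / (al * al) +
                     rb * (PI_ - a0[t]) / ((PI_ - al) * (PI_ - al))) / nT;
      const double nu = ux * ux + uy * uy, nv = vx * vx + vy * vy;
      const double dbx = uy / nu, dby = -ux / nu;   // d(alpha)/d(x_b)
      const double dcx = -vy / nv, dcy = vx / nv;   // d(alpha)/d(x_c)
      (*grad)[b] += dFda * dbx;       (*grad)[n + b] += dFda * dby;
      (*grad)[c] += dFda * dcx;       (*grad)[n + c] += dFda * dcy;
      (*grad)[a] -= dFda * (dbx + dcx);
      (*grad)[n + a] -= dFda * (dby + dcy);
    }
  }
  out.fth = (nT > 0) ? (Hth + Gth) / nT : 0.0;
  out.hth = Hth; out.gth = Gth;

  // --- perimeter term ---
  double Fp = 0.0;
  for (int i = 0; i < nP; ++i) {
    const int u = P[i] - 1;
    const double dx = x(u, 0) - x0(u, 0), dy = x(u, 1) - x0(u, 1);
    Fp += 0.5 * (dx * dx + dy * dy);
    if (grad) { (*grad)[u] += dx; (*grad)[n + u] += dy; }
  }
  out.fp = Fp;

  // --- anchor term: inverted-Gaussian wells ---
  double Fphi = 0.0;
  for (int i = 0; i < nA; ++i) {
    const int u = av[i] - 1;
    const double dx = x(u, 0) - ay(i, 0), dy = x(u, 1) - ay(i, 1);
    const double s2 = asig[i] * asig[i];
    const double g = std::exp(-(dx * dx + dy * dy) / s2);
    Fphi -= aw[i] * g;
    if (grad) {
      const double k = 2.0 * aw[i] * g / (s2 * nA);
      (*grad)[u] += k * dx;
      (*grad)[n + u] += k * dy;
    }
  }
  out.fphi = (nA > 0) ? Fphi / nA : 0.0;

  out.f = out.fe + out.fth + out.fp + out.fphi;
  return out;
}

} // namespace

// [[Rcpp::export]]
List cpp_potential(NumericMatrix x, IntegerMatrix E, NumericVector r0,
                   double q0, NumericVector q1, IntegerMatrix Th,
                   NumericVector a0, IntegerVector P, NumericMatrix x0,
                   IntegerVector av, NumericMatrix ay, NumericVector asig,
                   NumericVector aw, bool wantGrad) {
  std::vector<double> grad;
  std::vector<double> *gp = NULL;
  if (wantGrad) { grad.assign(2 * x.nrow(), 0.0); gp = &grad; }
  PotParts p = evalPotential(x, E, r0, q0, q1, Th, a0, P, x0,
                             av, ay, asig, aw, gp);
  List out = List::create(
    _["fe"] = p.fe, _["ftheta"] = p.fth, _["fp"] = p.fp, _["fphi"] = p.fphi,
    _["f"] = p.f, _["he"] = p.he, _["ge"] = p.ge, _["htheta"] = p.hth,
    _["gtheta"] = p.gth, _["admissible"] = p.admissible,
    _["minAngle"] = p.minAngle, _["maxAngle"] = p.maxAngle,
    _["minEdge"] = p.minEdge, _["maxEdgeFrac"] = p.maxEdgeFrac);
  if (wantGrad && p.admissible) {
    NumericMatrix g(x.nrow(), 2);
    for (int i = 0; i < x.nrow(); ++i) { g(i, 0) = grad[i]; g(i, 1) = grad[x.nrow() + i]; }
    out["grad"] = g;
  }
  return out;
}

// Gradient descent with a per-vertex displacement cap, multiplicative
// exponential gradient noise (direction preserved), and backtracking whenever
// a proposed step crosses an edge-length or angle singularity or fails to
// decrease the potential.
// [[Rcpp::export]]
List cpp_minimize(NumericMatrix xstart, IntegerMatrix E, NumericVector r0,
                  double q0, NumericVector q1, IntegerMatrix Th,
                  NumericVector a0, IntegerVector P, NumericMatrix x0,
                  IntegerVector av, NumericMatrix ay, NumericVector asig,
                  NumericVector aw, int steps, double maxStep,
                  double noiseScale, double backtrackFactor, int maxRetries,
                  double gradTol, double fluctTol) {
  const int n = xstart.nrow();
  NumericMatrix x = clone(xstart);
  std::vector<double> grad(2 * n, 0.0);
  PotParts cur = evalPotential(x, E, r0, q0, q1, Th, a0, P, x0,
                               av, ay, asig, aw, &grad);
  if (!cur.admissible)
    stop("starting configuration is not admissible");

  NumericVector pot(steps + 1);
  pot[0] = cur.f;
  NumericMatrix xBest = clone(x);
  double fBest = cur.f;
  int backtracks = 0, skipped = 0;
  double minAngleSeen = cur.minAngle, maxAngleSeen = cur.maxAngle;
  double minEdgeSeen = cur.minEdge, maxEdgeFracSeen = cur.maxEdgeFrac;
  std::vector<double> gn(2 * n);
  NumericMatrix xprop(n, 2);
  bool stalled = false;
  double hWarm = -1.0;  // last accepted global step scale

  for (int s = 1; s <= steps; ++s) {
    // noisy gradient: scale each vertex's magnitude, keep its direction
    double maxMag = 0.0;
    for (int i = 0; i < n; ++i) {
      double f = 1.0;
      if (noiseScale > 0.0) f += noiseScale * R::rexp(1.0);
      gn[i] = grad[i] * f;
      gn[n + i] = grad[n + i] * f;
      const double m = std::sqrt(gn[i] * gn[i] + gn[n + i] * gn[n + i]);
      if (m > maxMag) maxMag = m;
    }
    if (maxMag == 0.0 || (gradTol > 0.0 && maxMag < gradTol)) {
      for (int k = s; k <= steps; ++k) pot[k] = cur.f;
      stalled = (maxMag == 0.0);
      break;
    }
    // warm-started global scale; each vertex's displacement h * |g_u| is
    // individually clipped to the per-vertex cap, so vertices with small
    // gradients are not starved by a few steep ones
    double h = (hWarm > 0.0) ? hWarm * 2.0 : maxStep / maxMag;
    bool accepted = false;
    for (int k = 0; k <= maxRetries; ++k) {
      for (int i = 0; i < n; ++i) {
        const double m = std::sqrt(gn[i] * gn[i] + gn[n + i] * gn[n + i]);
        const double sc = (m * h > maxStep) ? maxStep / m : h;
        xprop(i, 0) = x(i, 0) - sc * gn[i];
        xprop(i, 1) = x(i, 1) - sc * gn[n + i];
      }
      PotParts pr = evalPotential(xprop, E, r0, q0, q1, Th, a0, P, x0,
                                  av, ay, asig, aw, NULL);
      // with noise enabled, small potential increases (the injected-noise
      // tolerance) are accepted; without noise descent is strictly monotone
      const double slack = (noiseScale > 0.0)
        ? fluctTol * (1.0 + std::fabs(cur.f)) : 0.0;
      if (pr.admissible && pr.f <= cur.f + slack) {
        std::copy(xprop.begin(), xprop.end(), x.begin());
        std::fill(grad.begin(), grad.end(), 0.0);
        cur = evalPotential(x, E, r0, q0, q1, Th, a0, P, x0,
                            av, ay, asig, aw, &grad);
        if (cur.minAngle < minAngleSeen) minAngleSeen = cur.minAngle;
        if (cur.maxAngle > maxAngleSeen) maxAngleSeen = cur.maxAngle;
        if (cur.minEdge < minEdgeSeen) minEdgeSeen = cur.minEdge;
        if (cur.maxEdgeFrac > maxEdgeFracSeen) maxEdgeFracSeen = cur.maxEdgeFrac;
        accepted = true;
        hWarm = h;
        if (cur.f < fBest) { fBest = cur.f; xBest = clone(x); }
        break;
      }
      ++backtracks;
      h *= backtrackFactor;
    }
    if (!accepted) ++skipped;
    pot[s] = cur.f;
  }

  // under the noise tolerance the trajectory may fluctuate; report the
  // best (lowest-potential) configuration visited
  if (fBest < cur.f) {
    std::copy(xBest.begin(), xBest.end(), x.begin());
    std::fill(grad.begin(), grad.end(), 0.0);
    cur = evalPotential(x, E, r0, q0, q1, Th, a0, P, x0,
                        av, ay, asig, aw, &grad);
  }
  double gnorm = 0.0;
  for (int i = 0; i < 2 * n; ++i) gnorm += grad[i] * grad[i];
  return List::create(
    _["x"] = x, _["potential"] = pot, _["backtracks"] = backtracks,
    _["skipped"] = skipped, _["finalGradNorm"] = std::sqrt(gnorm),
    _["minAngle"] = minAngleSeen, _["maxAngle"] = maxAngleSeen,
    _["minEdge"] = minEdgeSeen, _["maxEdgeFrac"] = maxEdgeFracSeen,
    _["stalled"] = stalled);
}

// Locate 2D points in a triangulation via a uniform grid over face bounding
// boxes.  Ties (point on a shared edge) resolve to the lowest face index.
// [[Rcpp::export]]
List cpp_locate(NumericMatrix coords, IntegerMatrix faces, NumericMatrix pts,
                double tol) {
  const int nf = faces.nrow(), np = pts.nrow();
  IntegerVector hit(np, 0);
  NumericMatrix bary(np, 3);
  std::fill(bary.begin(), bary.end(), NA_REAL);
  if (nf == 0 || np == 0) return List::create(_["face"] = hit, _["bary"] = bary);

  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  std::vector<double> fx0(nf), fx1(nf), fy0(nf), fy1(nf);
  for (int f = 0; f < nf; ++f) {
    double a = R_PosInf, b = R_NegInf, c = R_PosInf, d = R_NegInf;
    for (int k = 0; k < 3; ++k) {
      const int v = faces(f, k) - 1;
      const double px = coords(v, 0), py = coords(v, 1);
      if (px < a) a = px;
      if (px > b) b = px;
      if (py < c) c = py;
      if (py > d) d = py;
    }
    fx0[f] = a; fx1[f] = b; fy0[f] = c; fy1[f] = d;
    if (a < xmin) xmin = a; if (b > xmax) xmax = b;
    if (c < ymin) ymin = c; if (d > ymax) ymax = d;
  }
  int ng = (int)std::ceil(std::sqrt((double)nf));
  if (ng < 1) ng = 1;
  const double wx = (xmax - xmin) / ng + 1e-300;
  const double wy = (ymax - ymin) / ng + 1e-300;

  // two-pass bucket fill; faces inserted in ascending order per cell
  std::vector<int> count(ng * ng, 0);
  for (int f = 0; f < nf; ++f) {
    int i0 = (int)((fx0[f] - xmin) / wx), i1 = (int)((fx1[f] - xmin) / wx);
    int j0 = (int)((fy0[f] - ymin) / wy), j1 = (int)((fy1[f] - ymin) / wy);
    if (i1 >= ng) i1 = ng - 1;
    if (j1 >= ng) j1 = ng - 1;
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j) ++count[i * ng + j];
  }
  std::vector<int> start(ng * ng + 1, 0);
  for (int c = 0; c < ng * ng; ++c) start[c + 1] = start[c] + count[c];
  std::vector<int> bucket(start[ng * ng]);
  std::vector<int> fill(ng * ng, 0);
  for (int f = 0; f < nf; ++f) {
    int i0 = (int)((fx0[f] - xmin) / wx), i1 = (int)((fx1[f] - xmin) / wx);
    int j0 = (int)((fy0[f] - ymin) / wy), j1 = (int)((fy1[f] - ymin) / wy);
    if (i1 >= ng) i1 = ng - 1;
    if (j1 >= ng) j1 = ng - 1;
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j) {
        const int c = i * ng + j;
        bucket[start[c] + fill[c]++] = f;
      }
  }

  for (int p = 0; p < np; ++p) {
    const double px = pts(p, 0), py = pts(p, 1);
    if (!R_finite(px) || !R_finite(py)) continue;
    if (px < xmin - tol || px > xmax + tol || py < ymin - tol || py > ymax + tol)
      continue;
    int i = (int)((px - xmin) / wx), j = (int)((py - ymin) / wy);
    if (i < 0) i = 0;
    if (i >= ng) i = ng - 1;
    if (j < 0) j = 0;
    if (j >= ng) j = ng - 1;
    const int c = i * ng + j;
    for (int k = start[c]; k < start[c + 1]; ++k) {
      const int f = bucket[k];
      if (px < fx0[f] - tol || px > fx1[f] + tol ||
          py < fy0[f] - tol || py > fy1[f] + tol) continue;
      const int v1 = faces(f, 0) - 1, v2 = faces(f, 1) - 1, v3 = faces(f, 2) - 1;
      const double x1 = coords(v1, 0), y1 = coords(v1, 1);
      const double det = (coords(v2, 0) - x1) * (coords(v3, 1) - y1) -
                         (coords(v3, 0) - x1) * (coords(v2, 1) - y1);
      if (std::fabs(det) < 1e-300) continue;
      const double w2 = ((px - x1) * (coords(v3, 1) - y1) -
                         (py - y1) * (coords(v3, 0) - x1)) / det;
      const double w3 = ((py - y1) * (coords(v2, 0) - x1) -
                         (px - x1) * (coords(v2, 1) - y1)) / det;
      const double w1 = 1.0 - w2 - w3;
      if (w1 >= -tol && w2 >= -tol && w3 >= -tol) {
        hit[p] = f + 1;
        bary(p, 0) = w1; bary(p, 1) = w2; bary(p, 2) = w3;
        break;
      }
    }
  }
  return List::create(_["face"] = hit, _["bary"] = bary);
}
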