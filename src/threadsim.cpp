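#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
#include "quat.h"

using namespace Rcpp;

// ---------------------------------------------------------------------------
// small linear algebra

static bool solve3(double A[3][3], const double b[3], double x[3]) {
  // Gaussian elimination with partial pivoting on a 3x3 system.
  double M[3][4];
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) M[i][j] = A[i][j];
    M[i][3] = b[i];
  }
  for (int c = 0; c < 3; ++c) {
    int piv = c;
    for (int r = c + 1; r < 3; ++r)
      if (std::fabs(M[r][c]) > std::fabs(M[piv][c])) piv = r;
    if (std::fabs(M[piv][c]) < 1e-14) return false;
    if (piv != c)
      for (int j = c; j < 4; ++j) std::swap(M[c][j], M[piv][j]);
    for (int r = c + 1; r < 3; ++r) {
      double f = M[r][c] / M[c][c];
      for (int j = c; j < 4; ++j) M[r][j] -= f * M[c][j];
    }
  }
  for (int r = 2; r >= 0; --r) {
    double s = M[r][3];
    for (int j = r + 1; j < 3; ++j) s -= M[r][j] * x[j];
    x[r] = s / M[r][r];
  }
  return true;
}

static inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static inline double norm3(const double *a) { return std::sqrt(dot3(a, a)); }

// ---------------------------------------------------------------------------
// constraint values and Jacobians

// shear-stretch: C = (1/l)(p2 - p1) - R(q) e3
static void shear_stretch_value(const double *p1, const double *p2,
                                const Quat &q, double l, double out[3]) {
  double e3[3] = {0.0, 0.0, 1.0};
  double d3[3];
  qrotate(q, e3, d3);
  for (int i = 0; i < 3; ++i) out[i] = (p2[i] - p1[i]) / l - d3[i];
}

// Jacobian of the shear-stretch constraint w.r.t. the 4 raw components of q.
static void shear_stretch_jac_q(const Quat &q, double Jq[3][4]) {
  double e3[3] = {0.0, 0.0, 1.0};
  for (int i = 0; i < 4; ++i) {
    double col[3];
    qrotate_dq(q, e3, i, col);
    for (int r = 0; r < 3; ++r) Jq[r][i] = -col[r];
  }
}

// bend-twist: C = Im(conj(q) u) - Im(conj(q0) u0); the rest product
// Im-part is precomputed and passed as rest[3].
static void bend_twist_value(const Quat &q, const Quat &u,
                             const double rest[3], double out[3]) {
  Quat p = qmul(qconj(q), u);
  out[0] = p.x - rest[0];
  out[1] = p.y - rest[1];
  out[2] = p.z - rest[2];
}

// d Im(conj(q) u) / dq and / du, each 3x4, w.r.t. raw components.
static void bend_twist_jacs(const Quat &q, const Quat &u,
                            double Jq[3][4], double Ju[3][4]) {
  for (int i = 0; i < 4; ++i) {
    Quat e = qmake(i == 0, i == 1, i == 2, i == 3);
    Quat a = qmul(qconj(e), u);   // d/dq_i
    Quat b = qmul(qconj(q), e);   // d/du_i
    Jq[0][i] = a.x; Jq[1][i] = a.y; Jq[2][i] = a.z;
    Ju[0][i] = b.x; Ju[1][i] = b.y; Ju[2][i] = b.z;
  }
}

// friction: C = k * | unit(p1 - p2) x normal |
static double friction_value(const double *p1, const double *p2,
                             const double *n, double k) {
  double d[3] = {p1[0] - p2[0], p1[1] - p2[1], p1[2] - p2[2]};
  double nd = norm3(d);
  if (nd < 1e-15) return NA_REAL;
  double u[3] = {d[0] / nd, d[1] / nd, d[2] / nd};
  double c[3] = {u[1] * n[2] - u[2] * n[1],
                 u[2] * n[0] - u[0] * n[2],
                 u[0] * n[1] - u[1] * n[0]};
  return k * norm3(c);
}

// central finite differences; the analytic gradient lives in a derivation
// we do not reproduce, so the numeric gradient is the contract.
static void friction_grad(const double *p1, const double *p2,
                          const double *n, double k,
                          double g1[3], double g2[3]) {
  double d[3] = {p1[0] - p2[0], p1[1] - p2[1], p1[2] - p2[2]};
  double h = 1e-8 + 1e-6 * norm3(d);
  double a[3], b[3];
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) { a[j] = p1[j]; b[j] = p2[j]; }
    a[i] = p1[i] + h;
    double fp = friction_value(a, p2, n, k);
    a[i] = p1[i] - h;
    double fm = friction_value(a, p2, n, k);
    g1[i] = (fp - fm) / (2.0 * h);
    b[i] = p2[i] + h;
    fp = friction_value(p1, b, n, k);
    b[i] = p2[i] - h;
    fm = friction_value(p1, b, n, k);
    g2[i] = (fp - fm) / (2.0 * h);
  }
}

// ---------------------------------------------------------------------------
// exported constraint primitives

// [[Rcpp::export]]
NumericVector cpp_shear_stretch(NumericVector p1, NumericVector p2,
                                NumericVector q, double l) {
  Quat Q = qmake(q[0], q[1], q[2], q[3]);
  double out[3];
  shear_stretch_value(&p1[0], &p2[0], Q, l, out);
  return NumericVector::create(out[0], out[1], out[2]);
}

// [[Rcpp::export]]
NumericMatrix cpp_shear_stretch_jac(NumericVector q, double l) {
  // columns: p1 (3), p2 (3), q (4)
  Quat Q = qmake(q[0], q[1], q[2], q[3]);
  double Jq[3][4];
  shear_stretch_jac_q(Q, Jq);
  NumericMatrix J(3, 10);
  for (int r = 0; r < 3; ++r) {
    J(r, r) = -1.0 / l;
    J(r, 3 + r) = 1.0 / l;
    for (int c = 0; c < 4; ++c) J(r, 6 + c) = Jq[r][c];
  }
  return J;
}

// [[Rcpp::export]]
NumericVector cpp_bend_twist(NumericVector q, NumericVector u,
                             NumericVector q0, NumericVector u0) {
  Quat Q = qmake(q[0], q[1], q[2], q[3]);
  Quat U = qmake(u[0], u[1], u[2], u[3]);
  Quat R = qmul(qconj(qmake(q0[0], q0[1], q0[2], q0[3])),
                qmake(u0[0], u0[1], u0[2], u0[3]));
  double rest[3] = {R.x, R.y, R.z};
  double out[3];
  bend_twist_value(Q, U, rest, out);
  return NumericVector::create(out[0], out[1], out[2]);
}

// [[Rcpp::export]]
NumericMatrix cpp_bend_twist_jac(NumericVector q, NumericVector u) {
  // columns: q (4), u (4)
  Quat Q = qmake(q[0], q[1], q[2], q[3]);
  Quat U = qmake(u[0], u[1], u[2], u[3]);
  double Jq[3][4], Ju[3][4];
  bend_twist_jacs(Q, U, Jq, Ju);
  NumericMatrix J(3, 8);
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 4; ++c) {
      J(r, c) = Jq[r][c];
      J(r, 4 + c) = Ju[r][c];
    }
  return J;
}

// [[Rcpp::export]]
double cpp_friction_value(NumericVector p1, NumericVector p2,
                          NumericVector normal, double k) {
  return friction_value(&p1[0], &p2[0], &normal[0], k);
}

// [[Rcpp::export]]
NumericMatrix cpp_friction_grad(NumericVector p1, NumericVector p2,
                                NumericVector normal, double k) {
  double g1[3], g2[3];
  friction_grad(&p1[0], &p2[0], &normal[0], k, g1, g2);
  NumericMatrix G(2, 3);
  for (int i = 0; i < 3; ++i) { G(0, i) = g1[i]; G(1, i) = g2[i]; }
  return G;
}

// ---------------------------------------------------------------------------
// direct distance constraint (tridiagonal solve)

// [[Rcpp::export]]
NumericVector cpp_distance_values(NumericMatrix pos, double d) {
  int n = pos.nrow();
  NumericVector C(n - 1);
  for (int i = 0; i < n - 1; ++i) {
    double dx = pos(i, 0) - pos(i + 1, 0);
    double dy = pos(i, 1) - pos(i + 1, 1);
    double dz = pos(i, 2) - pos(i + 1, 2);
    C[i] = std::sqrt(dx * dx + dy * dy + dz * dz) - d;
  }
  return C;
}

struct Tridiag {
  std::vector<double> sub, diag, sup, rhs;
};

// Bands of grad(C) W grad(C)^T for the chained distance constraints, and
// rhs = -C. n_i = (p_i - p_{i+1}) / |p_i - p_{i+1}|:
//   diag_i = w_i + w_{i+1}
//   offdiag(i, i+1) = -w_{i+1} (n_i . n_{i+1})
// A w = 0 particle zeroes every coupling through it, so sub-chains held by
// an instrument decouple without explicit splitting.
static bool assemble_ddc(const std::vector<double> &px,
                         const std::vector<double> &py,
                         const std::vector<double> &pz,
                         const std::vector<double> &w,
                         double d, Tridiag &T) {
  int n = (int)px.size();
  int k = n - 1;
  T.sub.assign(k - 1 > 0 ? k - 1 : 0, 0.0);
  T.sup.assign(k - 1 > 0 ? k - 1 : 0, 0.0);
  T.diag.assign(k, 0.0);
  T.rhs.assign(k, 0.0);
  std::vector<double> nx(k), ny(k), nz(k);
  for (int i = 0; i < k; ++i) {
    double dx = px[i] - px[i + 1];
    double dy = py[i] - py[i + 1];
    double dz = pz[i] - pz[i + 1];
    double len = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (len < 1e-15) return false;  // coincident particles: degenerate
    nx[i] = dx / len; ny[i] = dy / len; nz[i] = dz / len;
    T.diag[i] = w[i] + w[i + 1];
    T.rhs[i] = -(len - d);
  }
  for (int i = 0; i + 1 < k; ++i) {
    double nn = nx[i] * nx[i + 1] + ny[i] * ny[i + 1] + nz[i] * nz[i + 1];
    double off = -w[i + 1] * nn;
    T.sup[i] = off;
    T.sub[i] = off;
  }
  return true;
}

// Thomas sweep; rows whose effective pivot vanishes (segment with both ends
// held) are skipped with lambda = 0 rather than treated as fatal.
static void thomas_guarded(Tridiag &T, std::vector<double> &lambda) {
  int k = (int)T.diag.size();
  lambda.assign(k, 0.0);
  std::vector<double> cp(k, 0.0), dp(k, 0.0);
  double denom = T.diag[0];
  bool live = std::fabs(denom) > 1e-12;
  cp[0] = live ? (k > 1 ? T.sup[0] / denom : 0.0) : 0.0;
  dp[0] = live ? T.rhs[0] / denom : 0.0;
  for (int i = 1; i < k; ++i) {
    denom = T.diag[i] - T.sub[i - 1] * cp[i - 1];
    if (std::fabs(denom) <= 1e-12) {
      cp[i] = 0.0; dp[i] = 0.0;
      continue;
    }
    cp[i] = (i < k - 1) ? T.sup[i] / denom : 0.0;
    dp[i] = (T.rhs[i] - T.sub[i - 1] * dp[i - 1]) / denom;
  }
  lambda[k - 1] = dp[k - 1];
  for (int i = k - 2; i >= 0; --i) lambda[i] = dp[i] - cp[i] * lambda[i + 1];
}

// [[Rcpp::export]]
NumericVector cpp_thomas(NumericVector sub, NumericVector diag,
                         NumericVector sup, NumericVector rhs) {
  int k = diag.size();
  std::vector<double> cp(k, 0.0), dp(k, 0.0), x(k, 0.0);
  double denom = diag[0];
  if (std::fabs(denom) <= 1e-12) stop("singular tridiagonal system (vanishing pivot)");
  cp[0] = (k > 1) ? sup[0] / denom : 0.0;
  dp[0] = rhs[0] / denom;
  for (int i = 1; i < k; ++i) {
    denom = diag[i] - sub[i - 1] * cp[i - 1];
    if (std::fabs(denom) <= 1e-12) stop("singular tridiagonal system (vanishing pivot)");
    cp[i] = (i < k - 1) ? sup[i] / denom : 0.0;
    dp[i] = (rhs[i] - sub[i - 1] * dp[i - 1]) / denom;
  }
  NumericVector x_out(k);
  x_out[k - 1] = dp[k - 1];
  for (int i = k - 2; i >= 0; --i) x_out[i] = dp[i] - cp[i] * x_out[i + 1];
  return x_out;
}

// [[Rcpp::export]]
List cpp_assemble_tridiag(NumericMatrix pos, NumericVector w, double d) {
  int n = pos.nrow();
  std::vector<double> px(n), py(n), pz(n), wi(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2); wi[i] = w[i];
  }
  Tridiag T;
  if (!assemble_ddc(px, py, pz, wi, d, T))
    stop("degenerate geometry: coincident consecutive particles");
  return List::create(_["sub"] = wrap(T.sub), _["diag"] = wrap(T.diag),
                      _["super"] = wrap(T.sup), _["rhs"] = wrap(T.rhs));
}

static double max_length_violation(const std::vector<double> &px,
                                   const std::vector<double> &py,
                                   const std::vector<double> &pz, double d) {
  double res = 0.0;
  for (size_t i = 0; i + 1 < px.size(); ++i) {
    double dx = px[i] - px[i + 1], dy = py[i] - py[i + 1],
           dz = pz[i] - pz[i + 1];
    res = std::max(res,
                   std::fabs(std::sqrt(dx * dx + dy * dy + dz * dz) - d));
  }
  return res;
}

// One linearized direct solve + correction on a chain (in place on copies).
// The Newton direction is backtracked on the max length violation: a full
// step is exact for near-collinear chains, but overshoots when the
// violation spans many segment lengths on a curved chain.
static bool ddc_once(std::vector<double> &px, std::vector<double> &py,
                     std::vector<double> &pz, const std::vector<double> &w,
                     double d) {
  int n = (int)px.size();
  int k = n - 1;
  Tridiag T;
  if (!assemble_ddc(px, py, pz, w, d, T)) return false;
  std::vector<double> lambda;
  thomas_guarded(T, lambda);
  // dp_i = w_i (n_i lambda_i - n_{i-1} lambda_{i-1})
  std::vector<double> nx(k), ny(k), nz(k);
  for (int i = 0; i < k; ++i) {
    double dx = px[i] - px[i + 1];
    double dy = py[i] - py[i + 1];
    double dz = pz[i] - pz[i + 1];
    double len = std::sqrt(dx * dx + dy * dy + dz * dz);
    nx[i] = dx / len; ny[i] = dy / len; nz[i] = dz / len;
  }
  std::vector<double> dx(n, 0.0), dy(n, 0.0), dz(n, 0.0);
  for (int i = 0; i < n; ++i) {
    if (w[i] == 0.0) continue;
    double gx = 0.0, gy = 0.0, gz = 0.0;
    if (i < k) { gx += nx[i] * lambda[i]; gy += ny[i] * lambda[i]; gz += nz[i] * lambda[i]; }
    if (i > 0) { gx -= nx[i - 1] * lambda[i - 1]; gy -= ny[i - 1] * lambda[i - 1]; gz -= nz[i - 1] * lambda[i - 1]; }
    dx[i] = w[i] * gx; dy[i] = w[i] * gy; dz[i] = w[i] * gz;
  }
  double res0 = max_length_violation(px, py, pz, d);
  std::vector<double> qx(n), qy(n), qz(n);
  double alpha = 1.0;
  for (int bt = 0; bt < 8; ++bt) {
    for (int i = 0; i < n; ++i) {
      qx[i] = px[i] + alpha * dx[i];
      qy[i] = py[i] + alpha * dy[i];
      qz[i] = pz[i] + alpha * dz[i];
    }
    if (max_length_violation(qx, qy, qz, d) < res0 || bt == 7) break;
    alpha *= 0.5;
  }
  px.swap(qx); py.swap(qy); pz.swap(qz);
  return true;
}

// [[Rcpp::export]]
NumericMatrix cpp_apply_ddc(NumericMatrix pos, NumericVector w, double d) {
  int n = pos.nrow();
  std::vector<double> px(n), py(n), pz(n), wi(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2); wi[i] = w[i];
  }
  if (!ddc_once(px, py, pz, wi, d))
    stop("degenerate geometry: coincident consecutive particles");
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i, 0) = px[i]; out(i, 1) = py[i]; out(i, 2) = pz[i]; }
  return out;
}

// ---------------------------------------------------------------------------
// continuous collision detection

// Earliest t in [0,1] with |(xa + t da) - (xb + t db)| = ra + rb; -1 on miss.
static double sphere_toi(const double *xa, const double *xap,
                         const double *xb, const double *xbp,
                         double ra, double rb) {
  double p0[3], dd[3];
  for (int i = 0; i < 3; ++i) {
    p0[i] = xa[i] - xb[i];
    dd[i] = (xap[i] - xa[i]) - (xbp[i] - xb[i]);
  }
  double R = ra + rb;
  double c0 = dot3(p0, p0) - R * R;
  if (c0 <= 0.0) return 0.0;  // already touching or overlapping
  double a = dot3(dd, dd);
  if (a < 1e-30) return -1.0;
  double b = 2.0 * dot3(p0, dd);
  if (b >= 0.0) return -1.0;  // separating
  double disc = b * b - 4.0 * a * c0;
  if (disc < 0.0) return -1.0;
  double t = (-b - std::sqrt(disc)) / (2.0 * a);
  if (t >= 0.0 && t <= 1.0) return t;
  return -1.0;
}

// [[Rcpp::export]]
double cpp_sphere_toi(NumericVector xa, NumericVector xa_pred,
                      NumericVector xb, NumericVector xb_pred,
                      double ra, double rb) {
  return sphere_toi(&xa[0], &xa_pred[0], &xb[0], &xb_pred[0], ra, rb);
}

static inline int64_t cell_key(int cx, int cy, int cz) {
  // pack three 21-bit signed cell coordinates into one key
  const int64_t B = 1 << 20;
  return (((int64_t)(cx + B)) << 42) | (((int64_t)(cy + B)) << 21) |
         ((int64_t)(cz + B));
}

// Candidate pairs whose swept AABBs share a hash cell; excludes same-rod
// neighbors within two chain positions (permanently overlapping spheres).
// [[Rcpp::export]]
IntegerMatrix cpp_broad_phase(NumericMatrix pos, NumericMatrix pos_pred,
                              NumericVector radius, double cell_size,
                              IntegerVector rod_id, IntegerVector chain_pos) {
  int n = pos.nrow();
  std::vector<int> lo(3 * n), hi(3 * n);
  std::vector<double> blo(3 * n), bhi(3 * n);
  double total_cells = 0.0;
  for (int i = 0; i < n; ++i) {
    double cells_i = 1.0;
    for (int a = 0; a < 3; ++a) {
      double mn = std::min(pos(i, a), pos_pred(i, a)) - radius[i];
      double mx = std::max(pos(i, a), pos_pred(i, a)) + radius[i];
      blo[3 * i + a] = mn; bhi[3 * i + a] = mx;
      lo[3 * i + a] = (int)std::floor(mn / cell_size);
      hi[3 * i + a] = (int)std::floor(mx / cell_size);
      cells_i *= (hi[3 * i + a] - lo[3 * i + a] + 1);
    }
    total_cells += cells_i;
  }
  auto aabb_overlap = [&](int i, int j) {
    for (int a = 0; a < 3; ++a)
      if (blo[3 * i + a] > bhi[3 * j + a] ||
          blo[3 * j + a] > bhi[3 * i + a])
        return false;
    return true;
  };
  auto excluded = [&](int i, int j) {
    return rod_id[i] == rod_id[j] &&
           std::abs(chain_pos[i] - chain_pos[j]) <= 2;
  };
  std::vector<std::pair<int, int>> pairs;
  if (!(total_cells <= 2e6)) {  // also catches NaN from runaway geometry
    // degenerate cell size or runaway geometry: all-pairs AABB test keeps
    // the superset guarantee without unbounded hashing cost
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (!excluded(i, j) && aabb_overlap(i, j))
          pairs.push_back(std::make_pair(i, j));
  } else {
    std::unordered_map<int64_t, std::vector<int>> grid;
    for (int i = 0; i < n; ++i)
      for (int cx = lo[3 * i]; cx <= hi[3 * i]; ++cx)
        for (int cy = lo[3 * i + 1]; cy <= hi[3 * i + 1]; ++cy)
          for (int cz = lo[3 * i + 2]; cz <= hi[3 * i + 2]; ++cz)
            grid[cell_key(cx, cy, cz)].push_back(i);
    for (auto &kv : grid) {
      std::vector<int> &ids = kv.second;
      for (size_t a = 0; a + 1 < ids.size(); ++a)
        for (size_t b = a + 1; b < ids.size(); ++b) {
          int i = std::min(ids[a], ids[b]);
          int j = std::max(ids[a], ids[b]);
          if (i == j || excluded(i, j)) continue;
          if (aabb_overlap(i, j)) pairs.push_back(std::make_pair(i, j));
        }
    }
  }
  std::sort(pairs.begin(), pairs.end());
  pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());
  IntegerMatrix out((int)pairs.size(), 2);
  for (size_t m = 0; m < pairs.size(); ++m) {
    out(m, 0) = pairs[m].first + 1;  // 1-based for R
    out(m, 1) = pairs[m].second + 1;
  }
  return out;
}

// static collider TOI; colliders matrix row: type, a,b,c, d,e,f, R
//   type 0 plane:    unit normal (a,b,c), offset d         (n.x = d surface)
//   type 1 sphere:   center (a,b,c), radius R
//   type 2 cylinder: axis point (a,b,c), unit axis (d,e,f), radius R
// Returns toi in [0,1] or -1; fills normal and surface anchor point at toi.
static double collider_toi(const double *x, const double *xp,
                           const double *row, double r,
                           double nrm[3], double anchor[3]) {
  int type = (int)row[0];
  if (type == 0) {
    const double *n = row + 1;
    double off = row[4];
    double s0 = dot3(n, x) - off - r;
    double s1 = dot3(n, xp) - off - r;
    double t;
    if (s0 <= 0.0) t = 0.0;
    else if (s1 < 0.0) t = s0 / (s0 - s1);
    else return -1.0;
    double xc[3];
    for (int i = 0; i < 3; ++i) xc[i] = x[i] + t * (xp[i] - x[i]);
    double h = dot3(n, xc) - off;
    for (int i = 0; i < 3; ++i) {
      nrm[i] = n[i];
      anchor[i] = xc[i] - h * n[i];
    }
    return t;
  } else if (type == 1) {
    const double *c = row + 1;
    double R = row[7];
    double cp[3] = {c[0], c[1], c[2]};
    double t = sphere_toi(x, xp, cp, cp, r, R);
    if (t < 0.0) return -1.0;
    double xc[3];
    for (int i = 0; i < 3; ++i) xc[i] = x[i] + t * (xp[i] - x[i]);
    double d[3] = {xc[0] - c[0], xc[1] - c[1], xc[2] - c[2]};
    double nd = norm3(d);
    if (nd < 1e-15) return -1.0;
    for (int i = 0; i < 3; ++i) {
      nrm[i] = d[i] / nd;
      anchor[i] = c[i] + R * nrm[i];
    }
    return t;
  } else {
    const double *a = row + 1;
    const double *u = row + 4;
    double R = row[7];
    // radial components relative to axis
    double ra0[3], ra1[3];
    double d0[3] = {x[0] - a[0], x[1] - a[1], x[2] - a[2]};
    double d1[3] = {xp[0] - a[0], xp[1] - a[1], xp[2] - a[2]};
    double h0 = dot3(d0, u), h1 = dot3(d1, u);
    for (int i = 0; i < 3; ++i) {
      ra0[i] = d0[i] - h0 * u[i];
      ra1[i] = d1[i] - h1 * u[i];
    }
    double zero[3] = {0.0, 0.0, 0.0};
    double t = sphere_toi(ra0, ra1, zero, zero, r, R);
    if (t < 0.0) return -1.0;
    double rc[3], xc[3];
    for (int i = 0; i < 3; ++i) {
      rc[i] = ra0[i] + t * (ra1[i] - ra0[i]);
      xc[i] = x[i] + t * (xp[i] - x[i]);
    }
    double nd = norm3(rc);
    if (nd < 1e-15) return -1.0;
    double hc = h0 + t * (h1 - h0);
    for (int i = 0; i < 3; ++i) {
      nrm[i] = rc[i] / nd;
      anchor[i] = a[i] + hc * u[i] + R * nrm[i];
    }
    return t;
  }
}

// ---------------------------------------------------------------------------
// the simulation step

struct Contact {
  int ia;          // particle index
  int ib;          // partner particle, or -1 for a static collider
  double anchor[3];  // fixed partner point when ib < 0
  double normal[3];
  double sep;      // required separation along normal
  double toi;
  double k;        // friction strength
};

struct World {
  int n, k;                      // particles, elements
  std::vector<double> px, py, pz, vx, vy, vz, w;
  std::vector<Quat> q;
  std::vector<double> ox, oy, oz, wq;  // angular velocity, inverse inertia
  // per-particle rod membership
  std::vector<int> rod_of, chain_pos;
  // rods
  std::vector<int> p0, np, q0;
  std::vector<double> d, r, Kb, Kt, dv, da, fc;
  std::vector<Quat> rest_pair;   // conj(q0_j) q0_{j+1} per element j (within rod)
};

static void project_shear_stretch_all(World &W, std::vector<double> &Px,
                                      std::vector<double> &Py,
                                      std::vector<double> &Pz,
                                      std::vector<Quat> &Q) {
  for (size_t rd = 0; rd < W.p0.size(); ++rd) {
    int base = W.p0[rd], qb = W.q0[rd], ne = W.np[rd] - 1;
    double l = W.d[rd];
    for (int e = 0; e < ne; ++e) {
      int i1 = base + e, i2 = base + e + 1, j = qb + e;
      double p1[3] = {Px[i1], Py[i1], Pz[i1]};
      double p2[3] = {Px[i2], Py[i2], Pz[i2]};
      double C[3];
      shear_stretch_value(p1, p2, Q[j], l, C);
      double Jq[3][4];
      shear_stretch_jac_q(Q[j], Jq);
      // the frame-coupling factor scales the frame's effective inverse
      // inertia inside this constraint only: frames track the centerline
      // over a few steps yet stay governed by the bend-twist constraints,
      // which is what lets bending stress move positions
      double w1 = W.w[i1], w2 = W.w[i2], wq = W.fc[rd] * W.wq[j];
      double S[3][3];
      double wp = (w1 + w2) / (l * l);
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) {
          double s = (a == b) ? wp : 0.0;
          for (int c = 0; c < 4; ++c) s += wq * Jq[a][c] * Jq[b][c];
          S[a][b] = s;
        }
      double mC[3] = {-C[0], -C[1], -C[2]};
      double lam[3];
      if (!solve3(S, mC, lam)) continue;  // both ends and frame held
      if (w1 > 0.0) {
        Px[i1] += w1 * (-1.0 / l) * lam[0];
        Py[i1] += w1 * (-1.0 / l) * lam[1];
        Pz[i1] += w1 * (-1.0 / l) * lam[2];
      }
      if (w2 > 0.0) {
        Px[i2] += w2 * (1.0 / l) * lam[0];
        Py[i2] += w2 * (1.0 / l) * lam[1];
        Pz[i2] += w2 * (1.0 / l) * lam[2];
      }
      if (wq > 0.0) {
        Quat dq = qmake(0, 0, 0, 0);
        for (int c = 0; c < 4; ++c) {
          double s = Jq[0][c] * lam[0] + Jq[1][c] * lam[1] + Jq[2][c] * lam[2];
          if (c == 0) dq.w = wq * s;
          if (c == 1) dq.x = wq * s;
          if (c == 2) dq.y = wq * s;
          if (c == 3) dq.z = wq * s;
        }
        Q[j] = qnormalize(qadd(Q[j], dq));
      }
    }
  }
}

static void project_bend_twist_all(World &W, std::vector<Quat> &Q) {
  for (size_t rd = 0; rd < W.p0.size(); ++rd) {
    int qb = W.q0[rd], ne = W.np[rd] - 1;
    double Kb = W.Kb[rd], Kt = W.Kt[rd];
    for (int e = 0; e + 1 < ne; ++e) {
      int j = qb + e, j2 = qb + e + 1;
      double rest[3] = {W.rest_pair[j].x, W.rest_pair[j].y, W.rest_pair[j].z};
      double C[3];
      bend_twist_value(Q[j], Q[j2], rest, C);
      double Jq[3][4], Ju[3][4];
      bend_twist_jacs(Q[j], Q[j2], Jq, Ju);
      double wq = W.wq[j], wu = W.wq[j2];
      if (wq == 0.0 && wu == 0.0) continue;
      double S[3][3];
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) {
          double s = 0.0;
          for (int c = 0; c < 4; ++c)
            s += wq * Jq[a][c] * Jq[b][c] + wu * Ju[a][c] * Ju[b][c];
          S[a][b] = s;
        }
      double mC[3] = {-C[0], -C[1], -C[2]};
      double lam[3];
      if (!solve3(S, mC, lam)) continue;
      // bend components scaled by Kb, twist component by Kt
      lam[0] *= Kb; lam[1] *= Kb; lam[2] *= Kt;
      if (wq > 0.0) {
        Quat dq;
        dq.w = wq * (Jq[0][0] * lam[0] + Jq[1][0] * lam[1] + Jq[2][0] * lam[2]);
        dq.x = wq * (Jq[0][1] * lam[0] + Jq[1][1] * lam[1] + Jq[2][1] * lam[2]);
        dq.y = wq * (Jq[0][2] * lam[0] + Jq[1][2] * lam[1] + Jq[2][2] * lam[2]);
        dq.z = wq * (Jq[0][3] * lam[0] + Jq[1][3] * lam[1] + Jq[2][3] * lam[2]);
        Q[j] = qnormalize(qadd(Q[j], dq));
      }
      if (wu > 0.0) {
        Quat du;
        du.w = wu * (Ju[0][0] * lam[0] + Ju[1][0] * lam[1] + Ju[2][0] * lam[2]);
        du.x = wu * (Ju[0][1] * lam[0] + Ju[1][1] * lam[1] + Ju[2][1] * lam[2]);
        du.y = wu * (Ju[0][2] * lam[0] + Ju[1][2] * lam[1] + Ju[2][2] * lam[2]);
        du.z = wu * (Ju[0][3] * lam[0] + Ju[1][3] * lam[1] + Ju[2][3] * lam[2]);
        Q[j2] = qnormalize(qadd(Q[j2], du));
      }
    }
  }
}

static void project_contacts(World &W, std::vector<Contact> &contacts,
                             std::vector<double> &Px, std::vector<double> &Py,
                             std::vector<double> &Pz) {
  for (size_t m = 0; m < contacts.size(); ++m) {
    Contact &ct = contacts[m];
    int i = ct.ia;
    double p1[3] = {Px[i], Py[i], Pz[i]};
    double p2[3];
    double w1 = W.w[i], w2;
    if (ct.ib >= 0) {
      p2[0] = Px[ct.ib]; p2[1] = Py[ct.ib]; p2[2] = Pz[ct.ib];
      w2 = W.w[ct.ib];
    } else {
      p2[0] = ct.anchor[0]; p2[1] = ct.anchor[1]; p2[2] = ct.anchor[2];
      w2 = 0.0;
    }
    double rel[3] = {p1[0] - p2[0], p1[1] - p2[1], p1[2] - p2[2]};
    double Cc = dot3(rel, ct.normal) - ct.sep;
    double wsum = w1 + w2;
    // touching within a small margin of the separation target: the
    // contact solve parks the pair at gap ~ 0+, so an exact-zero test
    // would make friction fire only on penetrating iterations
    bool active = Cc <= 0.02 * ct.sep;
    if (Cc < 0.0 && wsum > 0.0) {
      double lam = -Cc / wsum;
      if (w1 > 0.0)
        for (int a = 0; a < 3; ++a) {
          double dp = w1 * ct.normal[a] * lam;
          if (a == 0) Px[i] += dp; else if (a == 1) Py[i] += dp; else Pz[i] += dp;
        }
      if (w2 > 0.0 && ct.ib >= 0)
        for (int a = 0; a < 3; ++a) {
          double dp = -w2 * ct.normal[a] * lam;
          if (a == 0) Px[ct.ib] += dp; else if (a == 1) Py[ct.ib] += dp; else Pz[ct.ib] += dp;
        }
    }
    // friction: only while the paired contact is active
    if (!active || ct.k <= 0.0) continue;
    double q1[3] = {Px[i], Py[i], Pz[i]};
    double q2[3];
    if (ct.ib >= 0) { q2[0] = Px[ct.ib]; q2[1] = Py[ct.ib]; q2[2] = Pz[ct.ib]; }
    else { q2[0] = p2[0]; q2[1] = p2[1]; q2[2] = p2[2]; }
    double Cf = friction_value(q1, q2, ct.normal, ct.k);
    if (!(Cf > 1e-12)) continue;
    double g1[3], g2[3];
    friction_grad(q1, q2, ct.normal, ct.k, g1, g2);
    double S = w1 * dot3(g1, g1) + w2 * dot3(g2, g2);
    if (S < 1e-18) continue;
    // k also acts as the PBD stiffness of the correction: projecting the
    // raw scalar constraint is scale-invariant in k (value and gradient
    // norm both carry it), which would make any k > 0 equally sticky
    double lam = -ct.k * Cf / S;
    // clamp the correction to a fraction of the pair distance: the
    // constraint is non-convex in the positions and a full Gauss-Seidel
    // step can overshoot violently when other constraints move the pair
    double rel2[3] = {q1[0] - q2[0], q1[1] - q2[1], q1[2] - q2[2]};
    double step1 = w1 * std::fabs(lam) * norm3(g1);
    double step2 = w2 * std::fabs(lam) * norm3(g2);
    double step_max = std::max(step1, step2);
    double cap = 0.25 * norm3(rel2);
    if (step_max > cap && step_max > 0.0) lam *= cap / step_max;
    if (w1 > 0.0) {
      Px[i] += w1 * g1[0] * lam;
      Py[i] += w1 * g1[1] * lam;
      Pz[i] += w1 * g1[2] * lam;
    }
    if (w2 > 0.0 && ct.ib >= 0) {
      Px[ct.ib] += w2 * g2[0] * lam;
      Py[ct.ib] += w2 * g2[1] * lam;
      Pz[ct.ib] += w2 * g2[2] * lam;
    }
  }
}

// Sequential (Gauss-Seidel) distance pass: each pairwise constraint solved
// exactly in turn. Linear convergence only, but robust far from the
// constraint manifold where the linearized direct solve overshoots.
static void gs_distance_pass(std::vector<double> &px, std::vector<double> &py,
                             std::vector<double> &pz,
                             const std::vector<double> &w, double d) {
  int n = (int)px.size();
  for (int i = 0; i + 1 < n; ++i) {
    double wsum = w[i] + w[i + 1];
    if (wsum <= 0.0) continue;
    double dx = px[i] - px[i + 1], dy = py[i] - py[i + 1],
           dz = pz[i] - pz[i + 1];
    double len = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (len < 1e-15) continue;
    double s = (len - d) / (len * wsum);
    px[i] -= w[i] * s * dx; py[i] -= w[i] * s * dy; pz[i] -= w[i] * s * dz;
    px[i + 1] += w[i + 1] * s * dx; py[i + 1] += w[i + 1] * s * dy;
    pz[i + 1] += w[i + 1] * s * dz;
  }
}

// Follow-the-leader sweep: exact nonlinear length enforcement propagating
// outward from held particles (the discrete taut-chain limit). Not
// mass-weighted, so it is only the last-resort fallback when the direct
// solve and relaxation stall on a long-range transport correction; chains
// with no held particle are left to the mass-consistent paths.
static void ftl_pass(std::vector<double> &px, std::vector<double> &py,
                     std::vector<double> &pz, const std::vector<double> &w,
                     double d) {
  int n = (int)px.size();
  int first_held = -1;
  for (int i = 0; i < n; ++i)
    if (w[i] == 0.0) { first_held = i; break; }
  if (first_held < 0) return;
  auto step_to = [&](int from, int to) {
    double dx = px[to] - px[from], dy = py[to] - py[from],
           dz = pz[to] - pz[from];
    double len = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (len < 1e-15) return;
    double s = d / len;
    px[to] = px[from] + dx * s;
    py[to] = py[from] + dy * s;
    pz[to] = pz[from] + dz * s;
  };
  for (int i = first_held; i + 1 < n; ++i)
    if (w[i + 1] > 0.0) step_to(i, i + 1);
  for (int i = first_held; i > 0; --i)
    if (w[i - 1] > 0.0) step_to(i, i - 1);
}

// One linearized solve per call; on the final outer iteration the solve is
// repeated until the length residual vanishes, so the step always ends
// inextensible even when the predicted violation spans many segments. Far
// from the manifold a full Gauss-Newton step on a curved chain overshoots
// (the segment directions it linearized around rotate), so each polish
// repeat alternates the direct solve with a sequential distance pass that
// is nonlinearly exact per constraint.
static int project_ddc(World &W, std::vector<double> &Px,
                       std::vector<double> &Py, std::vector<double> &Pz,
                       bool polish) {
  int ftl_used = 0;
  for (size_t rd = 0; rd < W.p0.size(); ++rd) {
    int base = W.p0[rd], n = W.np[rd];
    std::vector<double> px(n), py(n), pz(n), w(n);
    for (int i = 0; i < n; ++i) {
      px[i] = Px[base + i]; py[i] = Py[base + i]; pz[i] = Pz[base + i];
      w[i] = W.w[base + i];
    }
    int repeats = polish ? 40 : 1;
    double tol = 1e-9 * W.d[rd];
    for (int rep = 0; rep < repeats; ++rep) {
      if (!ddc_once(px, py, pz, w, W.d[rd])) break;
      if (repeats > 1) {
        if (max_length_violation(px, py, pz, W.d[rd]) < tol) break;
        gs_distance_pass(px, py, pz, w, W.d[rd]);
        if (max_length_violation(px, py, pz, W.d[rd]) < tol) break;
      }
    }
    if (polish && max_length_violation(px, py, pz, W.d[rd]) > 1e-6 * W.d[rd]) {
      ftl_pass(px, py, pz, w, W.d[rd]);
      ++ftl_used;
    }
    for (int i = 0; i < n; ++i) {
      Px[base + i] = px[i]; Py[base + i] = py[i]; Pz[base + i] = pz[i];
    }
  }
  return ftl_used;
}

static World world_from_args(NumericMatrix pos, NumericMatrix vel,
                             NumericVector w, NumericMatrix quat,
                             NumericMatrix angvel, NumericVector wq,
                             IntegerVector rod_p0, IntegerVector rod_np,
                             IntegerVector rod_q0, NumericVector rod_d,
                             NumericVector rod_r, NumericVector rod_Kb,
                             NumericVector rod_Kt, NumericVector rod_dv,
                             NumericVector rod_da, NumericVector rod_fc,
                             NumericMatrix rest_pair) {
  World W;
  W.n = pos.nrow();
  W.k = quat.nrow();
  W.px.resize(W.n); W.py.resize(W.n); W.pz.resize(W.n);
  W.vx.resize(W.n); W.vy.resize(W.n); W.vz.resize(W.n);
  W.w.resize(W.n);
  W.rod_of.assign(W.n, -1);
  W.chain_pos.assign(W.n, 0);
  for (int i = 0; i < W.n; ++i) {
    W.px[i] = pos(i, 0); W.py[i] = pos(i, 1); W.pz[i] = pos(i, 2);
    W.vx[i] = vel(i, 0); W.vy[i] = vel(i, 1); W.vz[i] = vel(i, 2);
    W.w[i] = w[i];
  }
  W.q.resize(W.k); W.ox.resize(W.k); W.oy.resize(W.k); W.oz.resize(W.k);
  W.wq.resize(W.k);
  W.rest_pair.resize(W.k);
  for (int j = 0; j < W.k; ++j) {
    W.q[j] = qmake(quat(j, 0), quat(j, 1), quat(j, 2), quat(j, 3));
    W.ox[j] = angvel(j, 0); W.oy[j] = angvel(j, 1); W.oz[j] = angvel(j, 2);
    W.wq[j] = wq[j];
    W.rest_pair[j] = qmake(rest_pair(j, 0), rest_pair(j, 1),
                           rest_pair(j, 2), rest_pair(j, 3));
  }
  int nr = rod_p0.size();
  for (int rd = 0; rd < nr; ++rd) {
    W.p0.push_back(rod_p0[rd]); W.np.push_back(rod_np[rd]);
    W.q0.push_back(rod_q0[rd]);
    W.d.push_back(rod_d[rd]); W.r.push_back(rod_r[rd]);
    W.Kb.push_back(rod_Kb[rd]); W.Kt.push_back(rod_Kt[rd]);
    W.dv.push_back(rod_dv[rd]); W.da.push_back(rod_da[rd]);
    W.fc.push_back(rod_fc[rd]);
    for (int i = 0; i < rod_np[rd]; ++i) {
      W.rod_of[rod_p0[rd] + i] = rd;
      W.chain_pos[rod_p0[rd] + i] = i;
    }
  }
  return W;
}

// residual maxima over constraint families, on the given state
static void residuals(World &W, const std::vector<double> &Px,
                      const std::vector<double> &Py,
                      const std::vector<double> &Pz,
                      const std::vector<Quat> &Q,
                      double out[3]) {
  double rs = 0.0, rb = 0.0, rd = 0.0;
  for (size_t r = 0; r < W.p0.size(); ++r) {
    int base = W.p0[r], qb = W.q0[r], ne = W.np[r] - 1;
    for (int e = 0; e < ne; ++e) {
      int i1 = base + e, i2 = base + e + 1;
      double p1[3] = {Px[i1], Py[i1], Pz[i1]};
      double p2[3] = {Px[i2], Py[i2], Pz[i2]};
      double C[3];
      shear_stretch_value(p1, p2, Q[qb + e], W.d[r], C);
      for (int a = 0; a < 3; ++a) rs = std::max(rs, std::fabs(C[a]));
      double seg[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
      rd = std::max(rd, std::fabs(norm3(seg) - W.d[r]));
      if (e + 1 < ne) {
        double rest[3] = {W.rest_pair[qb + e].x, W.rest_pair[qb + e].y,
                          W.rest_pair[qb + e].z};
        double Cb[3];
        bend_twist_value(Q[qb + e], Q[qb + e + 1], rest, Cb);
        for (int a = 0; a < 3; ++a) rb = std::max(rb, std::fabs(Cb[a]));
      }
    }
  }
  out[0] = rs; out[1] = rb; out[2] = rd;
}

// [[Rcpp::export]]
List cpp_step(NumericMatrix pos, NumericMatrix vel, NumericVector w,
              NumericMatrix quat, NumericMatrix angvel, NumericVector wq,
              IntegerVector rod_p0, IntegerVector rod_np,
              IntegerVector rod_q0, NumericVector rod_d, NumericVector rod_r,
              NumericVector rod_Kb, NumericVector rod_Kt,
              NumericVector rod_dv, NumericVector rod_da,
              NumericVector rod_fc,
              NumericMatrix rest_pair, NumericMatrix colliders,
              NumericVector collider_k, List cfg) {
  World W = world_from_args(pos, vel, w, quat, angvel, wq, rod_p0, rod_np,
                            rod_q0, rod_d, rod_r, rod_Kb, rod_Kt, rod_dv,
                            rod_da, rod_fc, rest_pair);
  double dt = as<double>(cfg["dt"]);
  int iterations = as<int>(cfg["iterations"]);
  bool use_ddc = as<bool>(cfg["use_ddc"]);
  NumericVector gravity = cfg["gravity"];
  double friction_k = as<double>(cfg["friction_k"]);
  double cell_size = as<double>(cfg["cell_size"]);
  bool collision_enabled = as<bool>(cfg["collision_enabled"]);
  bool report_min_sep = cfg.containsElementNamed("report_min_separation")
                            ? as<bool>(cfg["report_min_separation"]) : false;

  // --- predict (symplectic Euler on positions; first-order on quaternions)
  std::vector<double> Px(W.n), Py(W.n), Pz(W.n);
  for (int i = 0; i < W.n; ++i) {
    if (W.w[i] > 0.0) {
      W.vx[i] += dt * gravity[0];
      W.vy[i] += dt * gravity[1];
      W.vz[i] += dt * gravity[2];
      Px[i] = W.px[i] + dt * W.vx[i];
      Py[i] = W.py[i] + dt * W.vy[i];
      Pz[i] = W.pz[i] + dt * W.vz[i];
    } else {
      Px[i] = W.px[i]; Py[i] = W.py[i]; Pz[i] = W.pz[i];
    }
  }
  std::vector<Quat> Q(W.k);
  for (int j = 0; j < W.k; ++j) {
    if (W.wq[j] > 0.0) {
      Quat om = qmake(0.0, W.ox[j], W.oy[j], W.oz[j]);
      Quat dq = qscale(qmul(om, W.q[j]), 0.5 * dt);
      Q[j] = qnormalize(qadd(W.q[j], dq));
    } else {
      Q[j] = W.q[j];
    }
  }

  // --- continuous collision detection on current -> predicted trajectories
  std::vector<Contact> contacts;
  if (collision_enabled) {
    NumericMatrix cur(W.n, 3), pred(W.n, 3);
    NumericVector rad(W.n);
    IntegerVector rid(W.n), cpos(W.n);
    for (int i = 0; i < W.n; ++i) {
      cur(i, 0) = W.px[i]; cur(i, 1) = W.py[i]; cur(i, 2) = W.pz[i];
      pred(i, 0) = Px[i]; pred(i, 1) = Py[i]; pred(i, 2) = Pz[i];
      rad[i] = W.r[W.rod_of[i]];
      rid[i] = W.rod_of[i];
      cpos[i] = W.chain_pos[i];
    }
    double cs = cell_size > 0.0 ? cell_size : 4.0 * rad[0];
    IntegerMatrix cand = cpp_broad_phase(cur, pred, rad, cs, rid, cpos);
    for (int m = 0; m < cand.nrow(); ++m) {
      int i = cand(m, 0) - 1, j = cand(m, 1) - 1;
      double xa[3] = {W.px[i], W.py[i], W.pz[i]};
      double xap[3] = {Px[i], Py[i], Pz[i]};
      double xb[3] = {W.px[j], W.py[j], W.pz[j]};
      double xbp[3] = {Px[j], Py[j], Pz[j]};
      double t = sphere_toi(xa, xap, xb, xbp, rad[i], rad[j]);
      if (t < 0.0) continue;
      Contact ct;
      ct.ia = i; ct.ib = j; ct.toi = t;
      ct.sep = rad[i] + rad[j];
      ct.k = friction_k;
      double na[3], nb[3];
      for (int a = 0; a < 3; ++a) {
        na[a] = xa[a] + t * (xap[a] - xa[a]);
        nb[a] = xb[a] + t * (xbp[a] - xb[a]);
      }
      double dvec[3] = {na[0] - nb[0], na[1] - nb[1], na[2] - nb[2]};
      double nd = norm3(dvec);
      if (nd < 1e-15) continue;
      for (int a = 0; a < 3; ++a) ct.normal[a] = dvec[a] / nd;
      ct.anchor[0] = ct.anchor[1] = ct.anchor[2] = 0.0;
      contacts.push_back(ct);
    }
    // static colliders: every particle against every collider
    for (int i = 0; i < W.n; ++i) {
      if (W.w[i] == 0.0) continue;
      double xa[3] = {W.px[i], W.py[i], W.pz[i]};
      double xap[3] = {Px[i], Py[i], Pz[i]};
      for (int c = 0; c < colliders.nrow(); ++c) {
        double row[8];
        for (int a = 0; a < 8; ++a) row[a] = colliders(c, a);
        double nrm[3], anchor[3];
        double rr = W.r[W.rod_of[i]];
        double t = collider_toi(xa, xap, row, rr, nrm, anchor);
        if (t < 0.0) continue;
        Contact ct;
        ct.ia = i; ct.ib = -1; ct.toi = t;
        ct.sep = rr;
        ct.k = collider_k[c];
        for (int a = 0; a < 3; ++a) { ct.normal[a] = nrm[a]; ct.anchor[a] = anchor[a]; }
        contacts.push_back(ct);
      }
    }
  }

  // --- Gauss-Seidel projection; DDC runs last in every iteration so that
  // inextensibility is the binding constraint
  int n_ftl = 0;
  for (int it = 0; it < iterations; ++it) {
    project_shear_stretch_all(W, Px, Py, Pz, Q);
    project_bend_twist_all(W, Q);
    project_contacts(W, contacts, Px, Py, Pz);
    if (use_ddc) {
      n_ftl += project_ddc(W, Px, Py, Pz, it == iterations - 1);
    } else {
      // iterative distance handling: one Gauss-Seidel pass over the
      // chained distance constraints (what the direct solve replaces)
      for (size_t rd = 0; rd < W.p0.size(); ++rd) {
        int base = W.p0[rd], n = W.np[rd];
        std::vector<double> px(n), py(n), pz(n), w(n);
        for (int i = 0; i < n; ++i) {
          px[i] = Px[base + i]; py[i] = Py[base + i]; pz[i] = Pz[base + i];
          w[i] = W.w[base + i];
        }
        gs_distance_pass(px, py, pz, w, W.d[rd]);
        for (int i = 0; i < n; ++i) {
          Px[base + i] = px[i]; Py[base + i] = py[i]; Pz[base + i] = pz[i];
        }
      }
    }
  }

  // --- re-attach material frames to the deformed centerline: the minimal
  // (twist-free) rotation taking each frame's d3 onto its segment. The
  // frames' angular velocities then measure actual material rotation, so
  // the per-second angular damping acts on the bending motion it models.
  for (size_t rd = 0; rd < W.p0.size(); ++rd) {
    int base = W.p0[rd], qb = W.q0[rd], ne = W.np[rd] - 1;
    for (int e = 0; e < ne; ++e) {
      int j = qb + e;
      if (W.wq[j] <= 0.0) continue;
      int i1 = base + e, i2 = base + e + 1;
      double t[3] = {Px[i2] - Px[i1], Py[i2] - Py[i1], Pz[i2] - Pz[i1]};
      double tn = norm3(t);
      if (tn < 1e-15) continue;
      for (int a = 0; a < 3; ++a) t[a] /= tn;
      double e3[3] = {0.0, 0.0, 1.0};
      double d3[3];
      qrotate(Q[j], e3, d3);
      double c = dot3(d3, t);
      if (c < -1.0 + 1e-12) continue;  // antiparallel: leave to constraints
      double ax[3] = {d3[1] * t[2] - d3[2] * t[1],
                      d3[2] * t[0] - d3[0] * t[2],
                      d3[0] * t[1] - d3[1] * t[0]};
      Quat r = qnormalize(qmake(1.0 + c, ax[0], ax[1], ax[2]));
      Q[j] = qnormalize(qmul(r, Q[j]));
    }
  }

  // --- velocity update and damping
  NumericMatrix pos_out(W.n, 3), vel_out(W.n, 3);
  for (int i = 0; i < W.n; ++i) {
    int rd = W.rod_of[i];
    double fv = std::pow(1.0 - W.dv[rd], dt);
    if (W.w[i] > 0.0) {
      W.vx[i] = (Px[i] - W.px[i]) / dt;
      W.vy[i] = (Py[i] - W.py[i]) / dt;
      W.vz[i] = (Pz[i] - W.pz[i]) / dt;
      W.vx[i] *= fv; W.vy[i] *= fv; W.vz[i] *= fv;
    } else {
      W.vx[i] = 0.0; W.vy[i] = 0.0; W.vz[i] = 0.0;
    }
    pos_out(i, 0) = Px[i]; pos_out(i, 1) = Py[i]; pos_out(i, 2) = Pz[i];
    vel_out(i, 0) = W.vx[i]; vel_out(i, 1) = W.vy[i]; vel_out(i, 2) = W.vz[i];
  }
  NumericMatrix quat_out(W.k, 4), angvel_out(W.k, 3);
  for (int j = 0; j < W.k; ++j) {
    int rd = 0;
    // element j belongs to the rod whose q-range contains it
    for (size_t r = 0; r < W.q0.size(); ++r)
      if (j >= W.q0[r] && j < W.q0[r] + W.np[r] - 1) { rd = (int)r; break; }
    double fa = std::pow(1.0 - W.da[rd], dt);
    if (W.wq[j] > 0.0) {
      Quat rel = qmul(Q[j], qconj(W.q[j]));
      double ox = 2.0 * rel.x / dt, oy = 2.0 * rel.y / dt, oz = 2.0 * rel.z / dt;
      if (rel.w < 0.0) { ox = -ox; oy = -oy; oz = -oz; }
      W.ox[j] = ox * fa; W.oy[j] = oy * fa; W.oz[j] = oz * fa;
    } else {
      W.ox[j] = 0.0; W.oy[j] = 0.0; W.oz[j] = 0.0;
    }
    quat_out(j, 0) = Q[j].w; quat_out(j, 1) = Q[j].x;
    quat_out(j, 2) = Q[j].y; quat_out(j, 3) = Q[j].z;
    angvel_out(j, 0) = W.ox[j]; angvel_out(j, 1) = W.oy[j];
    angvel_out(j, 2) = W.oz[j];
  }

  double res[3];
  residuals(W, Px, Py, Pz, Q, res);
  double min_sep = NA_REAL;
  if (report_min_sep) {
    min_sep = R_PosInf;
    for (int i = 0; i < W.n; ++i)
      for (int j = i + 1; j < W.n; ++j) {
        if (W.rod_of[i] == W.rod_of[j] &&
            std::abs(W.chain_pos[i] - W.chain_pos[j]) <= 2)
          continue;
        double dvec[3] = {Px[i] - Px[j], Py[i] - Py[j], Pz[i] - Pz[j]};
        min_sep = std::min(min_sep, norm3(dvec));
      }
    if (!R_finite(min_sep)) min_sep = NA_REAL;
  }

  return List::create(
      _["pos"] = pos_out, _["vel"] = vel_out, _["quat"] = quat_out,
      _["angvel"] = angvel_out,
      _["report"] = List::create(
          _["residual_stretch"] = res[0], _["residual_bend"] = res[1],
          _["residual_distance"] = res[2],
          _["n_contacts"] = (int)contacts.size(),
          _["n_ftl"] = n_ftl,
          _["min_separation"] = min_sep));
}

// [[Rcpp::export]]
double cpp_min_separation(NumericMatrix pos, IntegerVector rod_id,
                          IntegerVector chain_pos) {
  int n = pos.nrow();
  double min_sep = R_PosInf;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (rod_id[i] == rod_id[j] && std::abs(chain_pos[i] - chain_pos[j]) <= 2)
        continue;
      double d[3] = {pos(i, 0) - pos(j, 0), pos(i, 1) - pos(j, 1),
                     pos(i, 2) - pos(j, 2)};
      min_sep = std::min(min_sep, norm3(d));
    }
  return R_finite(min_sep) ? min_sep : NA_REAL;
}
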