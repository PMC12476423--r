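// Compiled kernels: generalized winding number, triangle/axis-aligned-box
// overlap (separating axis test), polar rotation extraction, and the
// position-based-dynamics step with per-cube shape-matching constraints.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Generalized winding number of each query point with respect to a closed
// triangle mesh (van Oosterom & Strackee solid-angle form). ~0 outside,
// ~1 inside for a consistently oriented watertight mesh; sign-insensitive
// callers should use fabs().
// [[Rcpp::export]]
arma::vec winding_number_cpp(const arma::mat& P, const arma::mat& V,
                             const arma::imat& F) {
  const arma::uword np = P.n_rows, nf = F.n_rows;
  arma::vec wn(np, arma::fill::zeros);
  for (arma::uword i = 0; i < np; ++i) {
    const arma::rowvec p = P.row(i);
    double total = 0.0;
    for (arma::uword t = 0; t < nf; ++t) {
      arma::rowvec a = V.row(F(t, 0)) - p;
      arma::rowvec b = V.row(F(t, 1)) - p;
      arma::rowvec c = V.row(F(t, 2)) - p;
      double la = arma::norm(a), lb = arma::norm(b), lc = arma::norm(c);
      double det = a(0) * (b(1) * c(2) - b(2) * c(1))
                 - a(1) * (b(0) * c(2) - b(2) * c(0))
                 + a(2) * (b(0) * c(1) - b(1) * c(0));
      double denom = la * lb * lc + arma::dot(a, b) * lc
                   + arma::dot(b, c) * la + arma::dot(c, a) * lb;
      total += 2.0 * std::atan2(det, denom);
    }
    wn(i) = total / (4.0 * M_PI);
  }
  return wn;
}

static inline bool axis_test(double ax, double ay, double az,
                             const arma::rowvec& v0, const arma::rowvec& v1,
                             const arma::rowvec& v2, double h) {
  double p0 = ax * v0(0) + ay * v0(1) + az * v0(2);
  double p1 = ax * v1(0) + ay * v1(1) + az * v1(2);
  double p2 = ax * v2(0) + ay * v2(1) + az * v2(2);
  double mn = std::min(p0, std::min(p1, p2));
  double mx = std::max(p0, std::max(p1, p2));
  double rad = h * (std::fabs(ax) + std::fabs(ay) + std::fabs(az));
  return (mn > rad) || (mx < -rad);  // true => separating axis found
}

static bool tri_box_overlap_one(const arma::rowvec& a, const arma::rowvec& b,
                                const arma::rowvec& c, const arma::rowvec& ctr,
                                double h) {
  arma::rowvec v0 = a - ctr, v1 = b - ctr, v2 = c - ctr;
  // box axes (AABB of the triangle vs the box)
  for (int k = 0; k < 3; ++k) {
    double mn = std::min(v0(k), std::min(v1(k), v2(k)));
    double mx = std::max(v0(k), std::max(v1(k), v2(k)));
    if (mn > h || mx < -h) return false;
  }
  arma::rowvec e0 = v1 - v0, e1 = v2 - v1, e2 = v0 - v2;
  // 9 cross-product axes
  if (axis_test(0, -e0(2), e0(1), v0, v1, v2, h)) return false;
  if (axis_test(e0(2), 0, -e0(0), v0, v1, v2, h)) return false;
  if (axis_test(-e0(1), e0(0), 0, v0, v1, v2, h)) return false;
  if (axis_test(0, -e1(2), e1(1), v0, v1, v2, h)) return false;
  if (axis_test(e1(2), 0, -e1(0), v0, v1, v2, h)) return false;
  if (axis_test(-e1(1), e1(0), 0, v0, v1, v2, h)) return false;
  if (axis_test(0, -e2(2), e2(1), v0, v1, v2, h)) return false;
  if (axis_test(e2(2), 0, -e2(0), v0, v1, v2, h)) return false;
  if (axis_test(-e2(1), e2(0), 0, v0, v1, v2, h)) return false;
  // triangle plane vs box
  arma::rowvec n = arma::cross(e0, e1);
  double d = arma::dot(n, v0);
  double rad = h * (std::fabs(n(0)) + std::fabs(n(1)) + std::fabs(n(2)));
  return std::fabs(d) <= rad;
}

// Which of the triangles indexed by `tri` (0-based rows of F) overlap the
// axis-aligned cube [lo, lo + L]^3.
// [[Rcpp::export]]
LogicalVector tri_box_overlap_cpp(const arma::mat& V, const arma::imat& F,
                                  const arma::ivec& tri, const arma::rowvec& lo,
                                  double L) {
  const double h = L / 2.0;
  const arma::rowvec ctr = lo + h;
  LogicalVector out(tri.n_elem);
  for (arma::uword k = 0; k < tri.n_elem; ++k) {
    int t = tri(k);
    out[k] = tri_box_overlap_one(V.row(F(t, 0)), V.row(F(t, 1)),
                                 V.row(F(t, 2)), ctr, h);
  }
  return out;
}

// Rotation (polar) factor of a 3x3 covariance, reflection-corrected to
// det +1. Rank < 2 gives no unique rotation: return identity, flag it.
// [[Rcpp::export]]
List polar_rotation_cpp(const arma::mat& A) {
  arma::mat U, Vt;
  arma::vec s;
  bool ok = arma::svd(U, s, Vt, A);
  if (!ok) stop("SVD failed in rotation extraction");
  bool degenerate = (s(0) <= 0) || (s(1) <= 1e-12 * s(0));
  arma::mat R;
  if (degenerate) {
    R = arma::eye(3, 3);
  } else {
    R = U * Vt.t();
    if (arma::det(R) < 0) {
      U.col(2) *= -1.0;
      R = U * Vt.t();
    }
  }
  return List::create(_["R"] = R, _["degenerate"] = degenerate);
}

// One PBD frame: predict under gravity, then `iterations` Gauss-Seidel
// sweeps (shape-matching projection over cubes in ascending id order, then
// tray-plane projection), then the velocity update. rest_off stores the 8
// centered rest offsets of cube i in rows 8*i .. 8*i+7.
// [[Rcpp::export]]
List pbd_step_cpp(arma::mat pos, arma::mat vel, const arma::vec& inv_mass,
                  const arma::imat& corners, const arma::mat& rest_off,
                  double stiffness, double dt, int iterations,
                  const arma::rowvec& gravity, bool has_tray,
                  const arma::rowvec& tray_p, const arma::rowvec& tray_n) {
  const arma::uword n = pos.n_rows, m = corners.n_rows;
  for (arma::uword i = 0; i < n; ++i)
    if (inv_mass(i) > 0) vel.row(i) += dt * gravity;
  arma::mat pred = pos + dt * vel;
  for (arma::uword i = 0; i < n; ++i)
    if (inv_mass(i) == 0) pred.row(i) = pos.row(i);

  arma::mat cur(8, 3), U, Vt, R;
  arma::vec s;
  for (int it = 0; it < iterations; ++it) {
    for (arma::uword ci = 0; ci < m; ++ci) {
      for (int j = 0; j < 8; ++j) cur.row(j) = pred.row(corners(ci, j));
      arma::rowvec cen = arma::mean(cur, 0);
      arma::mat A(3, 3, arma::fill::zeros);
      for (int j = 0; j < 8; ++j)
        A += (cur.row(j) - cen).t() * rest_off.row(8 * ci + j);
      if (!arma::svd(U, s, Vt, A)) stop("SVD failed in shape matching");
      if ((s(0) <= 0) || (s(1) <= 1e-12 * s(0))) {
        R = arma::eye(3, 3);
      } else {
        R = U * Vt.t();
        if (arma::det(R) < 0) {
          U.col(2) *= -1.0;
          R = U * Vt.t();
        }
      }
      for (int j = 0; j < 8; ++j) {
        int id = corners(ci, j);
        if (inv_mass(id) > 0) {
          arma::rowvec goal = (R * rest_off.row(8 * ci + j).t()).t() + cen;
          pred.row(id) += stiffness * (goal - pred.row(id));
        }
      }
    }
    if (has_tray) {
      for (arma::uword i = 0; i < n; ++i) {
        if (inv_mass(i) == 0) continue;
        double d = arma::dot(pred.row(i) - tray_p, tray_n);
        if (d < 0) pred.row(i) -= d * tray_n;
      }
    }
  }

  if (!pred.is_finite()) {
    for (arma::uword i = 0; i < n; ++i)
      if (!pred.row(i).is_finite())
        stop("numerical divergence: corner %d is non-finite", (int)(i + 1));
  }
  for (arma::uword i = 0; i < n; ++i) {
    if (inv_mass(i) > 0) {
      vel.row(i) = (pred.row(i) - pos.row(i)) / dt;
      pos.row(i) = pred.row(i);
    } else {
      vel.row(i).zeros();
    }
  }
  return List::create(_["positions"] = pos, _["velocities"] = vel);
}
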