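// Finite-strain FE kernels for linear tetrahedra with single-point quadrature,
// plus image-analysis helpers (connected components, distance transform,
// local maxima, trilinear sampling) and barycentric point location.
//
// Units convention throughout: lengths in um, stresses in kPa (== nN/um^2),
// forces in nN, energies in nN*um.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;

// Reference shape-function gradients G (3x4) and volume of one tet.
// Returns false on non-positive volume.
static bool tet_grads(const mat& X, mat& G, double& V0) {
  mat D(3, 3);
  for (int c = 0; c < 3; ++c) D.col(c) = X.col(c + 1) - X.col(0);
  double detD = arma::det(D);
  V0 = detD / 6.0;
  if (V0 <= 0.0) return false;
  mat Dinv = arma::inv(D);
  G.set_size(3, 4);
  for (int a = 1; a < 4; ++a) G.col(a) = Dinv.row(a - 1).t();
  G.col(0) = -(G.col(1) + G.col(2) + G.col(3));
  return true;
}

// Second Piola-Kirchhoff stress and (optionally) the material tangent
// Cmat = 2 dS/dC for the compressible Neo-Hookean energy
//   Psi = C10*(J^{-2/3} I1 - 3) + (1/D1)*(J - 1)^2.
static void neo_hookean_S(const mat& C, double J, double C10, double D1,
                          mat& S, double* Cmat /* 81 or nullptr */) {
  mat I = arma::eye(3, 3);
  mat Ci = arma::inv_sympd(arma::symmatu(C));
  double I1 = arma::trace(C);
  double A = std::pow(J, -2.0 / 3.0);
  S = 2.0 * C10 * A * (I - (I1 / 3.0) * Ci)
    + (2.0 / D1) * (J * J - J) * Ci;
  if (Cmat) {
    const double c_iso = 4.0 * C10 * A;
    const double v1 = (4.0 / D1) * (J * J - 0.5 * J);
    const double v2 = (4.0 / D1) * (J * J - J);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        for (int k = 0; k < 3; ++k)
          for (int l = 0; l < 3; ++l) {
            double CiCi = 0.5 * (Ci(i, k) * Ci(j, l) + Ci(i, l) * Ci(j, k));
            double iso = c_iso * (-(I(i, j) * Ci(k, l) + Ci(i, j) * I(k, l)) / 3.0
                                  + (I1 / 9.0) * Ci(i, j) * Ci(k, l)
                                  + (I1 / 3.0) * CiCi);
            double vol = v1 * Ci(i, j) * Ci(k, l) - v2 * CiCi;
            Cmat[((i * 3 + j) * 3 + k) * 3 + l] = iso + vol;
          }
  }
}

// Assemble internal forces (and optionally the consistent tangent triplets)
// for the current displacement u on the reference mesh `nodes`.
// tets is 1-based Mx4. Returns fint (3N, dof = 3*(node-1)+comp, 1-based in R),
// total strain energy, per-element J, and triplets (i, j, x) if want_K.
// Hand-unrolled 3x3 algebra: this is the innermost hot loop of every Newton
// iteration.
// [[Rcpp::export]]
List cpp_assemble(const arma::mat& nodes, const arma::imat& tets,
                  const arma::mat& u, double C10, double D1, bool want_K) {
  const int M = tets.n_rows, N = nodes.n_rows;
  vec fint(3 * N, arma::fill::zeros);
  vec Jel(M);
  double energy = 0.0;
  double minJ = arma::datum::inf;
  bool ok = true;

  IntegerVector ti, tj;
  NumericVector tx;
  if (want_K) {
    ti = IntegerVector(144 * M);
    tj = IntegerVector(144 * M);
    tx = NumericVector(144 * M);
  }
  const double* nd_ptr = nodes.memptr();
  const double* u_ptr = u.memptr();
  const int* t_ptr = tets.memptr();

  double Cmat[81];
  for (int e = 0; e < M; ++e) {
    int nd[4];
    double X[3][4], Ue[3][4];
    for (int a = 0; a < 4; ++a) {
      nd[a] = t_ptr[a * M + e] - 1;
      for (int c = 0; c < 3; ++c) {
        X[c][a] = nd_ptr[c * N + nd[a]];
        Ue[c][a] = u_ptr[c * N + nd[a]];
      }
    }
    // edge matrix D and its inverse (adjugate)
    double D[3][3];
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r) D[r][c] = X[r][c + 1] - X[r][0];
    double detD =
      D[0][0] * (D[1][1] * D[2][2] - D[1][2] * D[2][1]) -
      D[0][1] * (D[1][0] * D[2][2] - D[1][2] * D[2][0]) +
      D[0][2] * (D[1][0] * D[2][1] - D[1][1] * D[2][0]);
    double V0 = detD / 6.0;
    if (V0 <= 0.0) { ok = false; Jel(e) = -1; minJ = -1; continue; }
    double Di[3][3];
    double inv = 1.0 / detD;
    Di[0][0] = (D[1][1] * D[2][2] - D[1][2] * D[2][1]) * inv;
    Di[0][1] = (D[0][2] * D[2][1] - D[0][1] * D[2][2]) * inv;
    Di[0][2] = (D[0][1] * D[1][2] - D[0][2] * D[1][1]) * inv;
    Di[1][0] = (D[1][2] * D[2][0] - D[1][0] * D[2][2]) * inv;
    Di[1][1] = (D[0][0] * D[2][2] - D[0][2] * D[2][0]) * inv;
    Di[1][2] = (D[0][2] * D[1][0] - D[0][0] * D[1][2]) * inv;
    Di[2][0] = (D[1][0] * D[2][1] - D[1][1] * D[2][0]) * inv;
    Di[2][1] = (D[0][1] * D[2][0] - D[0][0] * D[2][1]) * inv;
    Di[2][2] = (D[0][0] * D[1][1] - D[0][1] * D[1][0]) * inv;
    // shape gradients G (3x4): G[.][a>=1] = row a-1 of Di; G[.][0] = -sum
    double G[3][4];
    for (int r = 0; r < 3; ++r) {
      G[r][1] = Di[0][r]; G[r][2] = Di[1][r]; G[r][3] = Di[2][r];
      G[r][0] = -(G[r][1] + G[r][2] + G[r][3]);
    }
    // F = I + Ue * G^T
    double F[3][3];
    for (int i = 0; i < 3; ++i)
      for (int Jd = 0; Jd < 3; ++Jd) {
        double s = (i == Jd) ? 1.0 : 0.0;
        for (int a = 0; a < 4; ++a) s += Ue[i][a] * G[Jd][a];
        F[i][Jd] = s;
      }
    double J =
      F[0][0] * (F[1][1] * F[2][2] - F[1][2] * F[2][1]) -
      F[0][1] * (F[1][0] * F[2][2] - F[1][2] * F[2][0]) +
      F[0][2] * (F[1][0] * F[2][1] - F[1][1] * F[2][0]);
    Jel(e) = J;
    if (J < minJ) minJ = J;
    if (J <= 0.0) { ok = false; continue; }
    // C = F^T F, its inverse, invariants
    double C[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        C[i][j] = F[0][i] * F[0][j] + F[1][i] * F[1][j] + F[2][i] * F[2][j];
    double detC = J * J;
    double invC = 1.0 / detC;
    double Ci[3][3];
    Ci[0][0] = (C[1][1] * C[2][2] - C[1][2] * C[2][1]) * invC;
    Ci[0][1] = (C[0][2] * C[2][1] - C[0][1] * C[2][2]) * invC;
    Ci[0][2] = (C[0][1] * C[1][2] - C[0][2] * C[1][1]) * invC;
    Ci[1][0] = Ci[0][1];
    Ci[1][1] = (C[0][0] * C[2][2] - C[0][2] * C[2][0]) * invC;
    Ci[1][2] = (C[0][2] * C[1][0] - C[0][0] * C[1][2]) * invC;
    Ci[2][0] = Ci[0][2];
    Ci[2][1] = Ci[1][2];
    Ci[2][2] = (C[0][0] * C[1][1] - C[0][1] * C[1][0]) * invC;
    double I1 = C[0][0] + C[1][1] + C[2][2];
    double A = std::pow(J, -2.0 / 3.0);
    energy += V0 * (C10 * (A * I1 - 3.0) + (1.0 / D1) * (J - 1.0) * (J - 1.0));
    // S = 2 C10 A (I - I1/3 Ci) + (2/D1)(J^2 - J) Ci
    double volS = (2.0 / D1) * (J * J - J);
    double S[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        S[i][j] = 2.0 * C10 * A * ((i == j ? 1.0 : 0.0) - (I1 / 3.0) * Ci[i][j])
                + volS * Ci[i][j];
    // P = F S; fint contribution fe = P G V0
    double P[3][3];
    for (int i = 0; i < 3; ++i)
      for (int Jd = 0; Jd < 3; ++Jd)
        P[i][Jd] = F[i][0] * S[0][Jd] + F[i][1] * S[1][Jd] + F[i][2] * S[2][Jd];
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i)
        fint(3 * nd[a] + i) +=
          (P[i][0] * G[0][a] + P[i][1] * G[1][a] + P[i][2] * G[2][a]) * V0;

    if (want_K) {
      const double c_iso = 4.0 * C10 * A;
      const double v1 = (4.0 / D1) * (J * J - 0.5 * J);
      const double v2 = (4.0 / D1) * (J * J - J);
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          for (int k = 0; k < 3; ++k)
            for (int l = 0; l < 3; ++l) {
              double CiCi = 0.5 * (Ci[i][k] * Ci[j][l] + Ci[i][l] * Ci[j][k]);
              double del_ij = (i == j) ? 1.0 : 0.0;
              double del_kl = (k == l) ? 1.0 : 0.0;
              double iso = c_iso * (-(del_ij * Ci[k][l] + Ci[i][j] * del_kl) / 3.0
                                    + (I1 / 9.0) * Ci[i][j] * Ci[k][l]
                                    + (I1 / 3.0) * CiCi);
              Cmat[((i * 3 + j) * 3 + k) * 3 + l] =
                iso + v1 * Ci[i][j] * Ci[k][l] - v2 * CiCi;
            }
      // H[i][Jd][k][L] = d P_iJ / d F_kL = del_ik S_JL + F_iI F_kM Cmat_IJ,LM
      double H[3][3][3][3];
      for (int i = 0; i < 3; ++i)
        for (int Jd = 0; Jd < 3; ++Jd)
          for (int k = 0; k < 3; ++k)
            for (int L = 0; L < 3; ++L) {
              double s = (i == k) ? S[Jd][L] : 0.0;
              for (int Ii = 0; Ii < 3; ++Ii) {
                double fi = F[i][Ii];
                if (fi == 0.0) continue;
                const double* cm = &Cmat[((Ii * 3 + Jd) * 3 + L) * 3];
                s += fi * (F[k][0] * cm[0] + F[k][1] * cm[1] + F[k][2] * cm[2]);
              }
              H[i][Jd][k][L] = s;
            }
      std::size_t base = (std::size_t)e * 144;
      int q = 0;
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i)
          for (int b = 0; b < 4; ++b)
            for (int k = 0; k < 3; ++k) {
              double kij = 0.0;
              for (int Jd = 0; Jd < 3; ++Jd)
                kij += G[Jd][a] * (H[i][Jd][k][0] * G[0][b] +
                                   H[i][Jd][k][1] * G[1][b] +
                                   H[i][Jd][k][2] * G[2][b]);
              ti[base + q] = 3 * nd[a] + i + 1;
              tj[base + q] = 3 * nd[b] + k + 1;
              tx[base + q] = kij * V0;
              ++q;
            }
    }
  }

  List out = List::create(
    _["fint"] = fint, _["energy"] = energy, _["J"] = Jel,
    _["minJ"] = minJ, _["ok"] = ok);
  if (want_K) { out["ti"] = ti; out["tj"] = tj; out["tx"] = tx; }
  return out;
}

// Map each COO triplet (1-based ti/tj) to its slot in a dgCMatrix with
// column pointers p and 0-based sorted row indices ri; computed once per
// sparsity pattern so repeated assemblies reduce to an indexed add.
// [[Rcpp::export]]
IntegerVector cpp_csc_slots(const IntegerVector& ti, const IntegerVector& tj,
                            const IntegerVector& p, const IntegerVector& ri) {
  IntegerVector slots(ti.size());
  for (R_xlen_t s = 0; s < ti.size(); ++s) {
    int row = ti[s] - 1, col = tj[s] - 1;
    int lo = p[col], hi = p[col + 1] - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (ri[mid] < row) lo = mid + 1; else hi = mid;
    }
    if (ri[lo] != row) stop("triplet outside cached sparsity pattern");
    slots[s] = lo;
  }
  return slots;
}

// Accumulate triplet values into slot positions (0-based), nnz total slots.
// [[Rcpp::export]]
NumericVector cpp_slot_accumulate(const IntegerVector& slots,
                                  const NumericVector& tx, int nnz) {
  NumericVector x(nnz);
  for (R_xlen_t s = 0; s < slots.size(); ++s) x[slots[s]] += tx[s];
  return x;
}

// Per-element deformation state for displacement u: deformation gradient F
// (3x3xM), J, and the logarithmic (Hencky) strain lnV = 0.5*log(F F^T),
// stored in symmetric Voigt order (11,22,33,12,13,23).
// [[Rcpp::export]]
List cpp_def_states(const arma::mat& nodes, const arma::imat& tets,
                    const arma::mat& u) {
  const int M = tets.n_rows;
  cube Fall(3, 3, M);
  vec Jel(M);
  mat logV(M, 6);
  mat G, X(3, 4), Ue(3, 4);
  for (int e = 0; e < M; ++e) {
    for (int a = 0; a < 4; ++a) {
      int nd = tets(e, a) - 1;
      X.col(a) = nodes.row(nd).t();
      Ue.col(a) = u.row(nd).t();
    }
    double V0;
    tet_grads(X, G, V0);
    mat F = arma::eye(3, 3) + Ue * G.t();
    Fall.slice(e) = F;
    Jel(e) = arma::det(F);
    mat b = arma::symmatu(F * F.t());
    vec eval; mat evec;
    arma::eig_sym(eval, evec, b);
    vec lam = 0.5 * arma::log(eval);
    mat L = evec * arma::diagmat(lam) * evec.t();
    logV(e, 0) = L(0, 0); logV(e, 1) = L(1, 1); logV(e, 2) = L(2, 2);
    logV(e, 3) = L(0, 1); logV(e, 4) = L(0, 2); logV(e, 5) = L(1, 2);
  }
  return List::create(_["F"] = Fall, _["J"] = Jel, _["logV"] = logV);
}

// Signed volumes and radius-edge quality ratios of all tets.
// [[Rcpp::export]]
List cpp_tet_quality(const arma::mat& nodes, const arma::imat& tets) {
  const int M = tets.n_rows;
  vec vol(M), ratio(M);
  mat X(3, 4);
  for (int e = 0; e < M; ++e) {
    for (int a = 0; a < 4; ++a) X.col(a) = nodes.row(tets(e, a) - 1).t();
    vec a = X.col(1) - X.col(0), b = X.col(2) - X.col(0), c = X.col(3) - X.col(0);
    double v6 = arma::dot(a, arma::cross(b, c));
    vol(e) = v6 / 6.0;
    // circumradius from the standard determinant formula
    vec u = arma::cross(b, c) * arma::dot(a, a)
          + arma::cross(c, a) * arma::dot(b, b)
          + arma::cross(a, b) * arma::dot(c, c);
    double R = arma::norm(u) / (2.0 * std::abs(v6));
    double emin = arma::datum::inf;
    for (int p = 0; p < 4; ++p)
      for (int q = p + 1; q < 4; ++q) {
        double d = arma::norm(X.col(p) - X.col(q));
        if (d < emin) emin = d;
      }
    ratio(e) = R / emin;
  }
  return List::create(_["volume"] = vol, _["radius_edge"] = ratio);
}

// Locate query points in a tet mesh: returns 1-based element id and
// barycentric coordinates; falls back to the element with the least-negative
// barycentric minimum (nearest-element extrapolation), flagged via inside.
// [[Rcpp::export]]
List cpp_point_locate(const arma::mat& nodes, const arma::imat& tets,
                      const arma::mat& queries, double tol = 1e-9) {
  const int M = tets.n_rows, Q = queries.n_rows;
  // uniform grid over the mesh bounding box, tets binned by their bbox
  vec lo = arma::min(nodes, 0).t(), hi = arma::max(nodes, 0).t();
  int ng = std::max(1, (int)std::floor(std::cbrt((double)M / 4.0)));
  vec h = (hi - lo) / ng;
  for (int d = 0; d < 3; ++d) if (h(d) <= 0) h(d) = 1.0;
  auto cell_of = [&](double x, int d) {
    int c = (int)std::floor((x - lo(d)) / h(d));
    return std::min(std::max(c, 0), ng - 1);
  };
  std::vector<std::vector<int>> bins(ng * ng * ng);
  for (int e = 0; e < M; ++e) {
    vec bmin(3, arma::fill::value(arma::datum::inf)), bmax = -bmin;
    for (int a = 0; a < 4; ++a) {
      const arma::rowvec x = nodes.row(tets(e, a) - 1);
      for (int d = 0; d < 3; ++d) {
        bmin(d) = std::min(bmin(d), x(d));
        bmax(d) = std::max(bmax(d), x(d));
      }
    }
    int c0[3], c1[3];
    for (int d = 0; d < 3; ++d) {
      c0[d] = cell_of(bmin(d), d);
      c1[d] = cell_of(bmax(d), d);
    }
    for (int i = c0[0]; i <= c1[0]; ++i)
      for (int j = c0[1]; j <= c1[1]; ++j)
        for (int k = c0[2]; k <= c1[2]; ++k)
          bins[i + ng * (j + ng * k)].push_back(e);
  }

  IntegerVector elem(Q);
  NumericMatrix bary(Q, 4);
  LogicalVector inside(Q);
  mat D(3, 3);
  auto bary_of = [&](int e, const vec& p, vec& bc) {
    for (int c = 0; c < 3; ++c)
      D.col(c) = nodes.row(tets(e, c + 1) - 1).t() - nodes.row(tets(e, 0) - 1).t();
    vec rhs = p - nodes.row(tets(e, 0) - 1).t();
    vec xi;
    if (!arma::solve(xi, D, rhs, arma::solve_opts::no_approx)) return false;
    bc = {1.0 - xi(0) - xi(1) - xi(2), xi(0), xi(1), xi(2)};
    return true;
  };

  for (int q = 0; q < Q; ++q) {
    vec p = queries.row(q).t();
    int best_e = -1;
    double best_min = -arma::datum::inf;
    vec best_bc(4);
    bool found = false;
    int ci = cell_of(p(0), 0), cj = cell_of(p(1), 1), ck = cell_of(p(2), 2);
    for (int ring = 0; ring <= ng && !found; ++ring) {
      for (int i = std::max(0, ci - ring); i <= std::min(ng - 1, ci + ring) && !found; ++i)
        for (int j = std::max(0, cj - ring); j <= std::min(ng - 1, cj + ring) && !found; ++j)
          for (int k = std::max(0, ck - ring); k <= std::min(ng - 1, ck + ring) && !found; ++k) {
            if (ring > 0 && std::abs(i - ci) != ring && std::abs(j - cj) != ring &&
                std::abs(k - ck) != ring) continue;
            for (int e : bins[i + ng * (j + ng * k)]) {
              vec bc;
              if (!bary_of(e, p, bc)) continue;
              double bmin = bc.min();
              if (bmin > best_min) { best_min = bmin; best_e = e; best_bc = bc; }
              if (bmin >= -tol) { found = true; break; }
            }
          }
      if (best_e >= 0 && ring >= 1 && !found && ring >= 2) break;  // settle for nearest
    }
    if (best_e < 0) {  // brute force (degenerate grid cases)
      for (int e = 0; e < M; ++e) {
        vec bc;
        if (!bary_of(e, p, bc)) continue;
        double bmin = bc.min();
        if (bmin > best_min) { best_min = bmin; best_e = e; best_bc = bc; }
        if (bmin >= -tol) break;
      }
    }
    elem[q] = best_e + 1;
    inside[q] = best_min >= -1e-6;
    for (int a = 0; a < 4; ++a) bary(q, a) = best_e >= 0 ? best_bc(a) : NA_REAL;
  }
  return List::create(_["element"] = elem, _["bary"] = bary, _["inside"] = inside);
}

// 6-connected component labelling of a 3D logical array.
// [[Rcpp::export]]
IntegerVector cpp_label3d(const LogicalVector& mask, const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(mask.size(), 0);
  int cur = 0;
  std::vector<int> stack;
  auto idx = [&](int i, int j, int k) { return i + nx * (j + ny * k); };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int s = idx(i, j, k);
        if (!mask[s] || lab[s]) continue;
        lab[s] = ++cur;
        stack.push_back(s);
        while (!stack.empty()) {
          int t = stack.back(); stack.pop_back();
          int ti = t % nx, tj = (t / nx) % ny, tk = t / (nx * ny);
          const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
          for (auto& o : off) {
            int ni = ti + o[0], nj = tj + o[1], nk = tk + o[2];
            if (ni < 0 || nj < 0 || nk < 0 || ni >= nx || nj >= ny || nk >= nz) continue;
            int u = idx(ni, nj, nk);
            if (mask[u] && !lab[u]) { lab[u] = cur; stack.push_back(u); }
          }
        }
      }
  lab.attr("dim") = dims;
  return lab;
}

// 1D squared-distance lower-envelope transform (Felzenszwalb & Huttenlocher)
// with physical sample positions p_i = i * dx.
static void edt1d(const std::vector<double>& f, std::vector<double>& d,
                  double dx, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -arma::datum::inf; z[1] = arma::datum::inf;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double pq = q * dx, pv = v[k] * dx;
      s = ((f[q] + pq * pq) - (f[v[k]] + pv * pv)) / (2 * pq - 2 * pv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = arma::datum::inf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double pq = q * dx;
    while (z[k + 1] < pq) ++k;
    double diff = pq - v[k] * dx;
    d[q] = diff * diff + f[v[k]];
  }
}

// Euclidean distance (um) from every voxel to the nearest TRUE voxel.
// [[Rcpp::export]]
NumericVector cpp_edt3d(const LogicalVector& mask, const IntegerVector& dims,
                        const NumericVector& spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = 1e30;
  std::vector<double> d((std::size_t)nx * ny * nz);
  for (int s = 0; s < mask.size(); ++s) d[s] = mask[s] ? 0.0 : INF;
  auto idx = [&](int i, int j, int k) { return (std::size_t)i + nx * ((std::size_t)j + (std::size_t)ny * k); };
  std::vector<double> f(std::max({nx, ny, nz})), g(std::max({nx, ny, nz}));
  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = d[idx(i, j, k)];
      edt1d(f, g, spacing[0], nx);
      for (int i = 0; i < nx; ++i) d[idx(i, j, k)] = g[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = d[idx(i, j, k)];
      edt1d(f, g, spacing[1], ny);
      for (int j = 0; j < ny; ++j) d[idx(i, j, k)] = g[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = d[idx(i, j, k)];
      edt1d(f, g, spacing[2], nz);
      for (int k = 0; k < nz; ++k) d[idx(i, j, k)] = g[k];
    }
  NumericVector out(mask.size());
  for (int s = 0; s < mask.size(); ++s) out[s] = std::sqrt(d[s]);
  out.attr("dim") = dims;
  return out;
}

// Voxel indices (1-based triples) of strict-threshold local maxima over the
// 26-neighbourhood (>= against neighbours, > threshold).
// [[Rcpp::export]]
IntegerMatrix cpp_local_maxima(const NumericVector& vol, const IntegerVector& dims,
                               double threshold) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto idx = [&](int i, int j, int k) { return i + nx * (j + ny * k); };
  std::vector<std::array<int, 3>> hits;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double v = vol[idx(i, j, k)];
        if (!(v > threshold)) continue;
        bool is_max = true;
        for (int dk = -1; dk <= 1 && is_max; ++dk)
          for (int dj = -1; dj <= 1 && is_max; ++dj)
            for (int di = -1; di <= 1 && is_max; ++di) {
              if (!di && !dj && !dk) continue;
              int ni = i + di, nj = j + dj, nk = k + dk;
              if (ni < 0 || nj < 0 || nk < 0 || ni >= nx || nj >= ny || nk >= nz)
                continue;
              if (vol[idx(ni, nj, nk)] > v) is_max = false;
            }
        if (is_max) hits.push_back({i + 1, j + 1, k + 1});
      }
  IntegerMatrix out(hits.size(), 3);
  for (std::size_t r = 0; r < hits.size(); ++r)
    for (int c = 0; c < 3; ++c) out(r, c) = hits[r][c];
  return out;
}

// Accumulate COO triplets (1-based ti/tj) into the numeric slot vector of a
// dgCMatrix with column pointers p and 0-based sorted row indices ri.
// [[Rcpp::export]]
NumericVector cpp_csc_accumulate(const IntegerVector& ti, const IntegerVector& tj,
                                 const NumericVector& tx, const IntegerVector& p,
                                 const IntegerVector& ri) {
  NumericVector x(ri.size());
  for (R_xlen_t s = 0; s < ti.size(); ++s) {
    int row = ti[s] - 1, col = tj[s] - 1;
    int lo = p[col], hi = p[col + 1] - 1;
    while (lo < hi) {  // binary search for row in this column
      int mid = (lo + hi) / 2;
      if (ri[mid] < row) lo = mid + 1; else hi = mid;
    }
    if (ri[lo] != row) stop("triplet outside cached sparsity pattern");
    x[lo] += tx[s];
  }
  return x;
}

// Trilinear sampling of a 3D array at continuous 0-based voxel-index
// coordinates (value at integer index (i,j,k) equals vol[i,j,k]).
// Out-of-range coordinates are clamped to the boundary.
// [[Rcpp::export]]
NumericVector cpp_trilinear(const NumericVector& vol, const IntegerVector& dims,
                            const NumericMatrix& pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto at = [&](int i, int j, int k) {
    i = std::min(std::max(i, 0), nx - 1);
    j = std::min(std::max(j, 0), ny - 1);
    k = std::min(std::max(k, 0), nz - 1);
    return vol[i + nx * (j + ny * k)];
  };
  NumericVector out(pts.nrow());
  for (int q = 0; q < pts.nrow(); ++q) {
    double x = pts(q, 0), y = pts(q, 1), z = pts(q, 2);
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double v = 0.0;
    for (int di = 0; di <= 1; ++di)
      for (int dj = 0; dj <= 1; ++dj)
        for (int dk = 0; dk <= 1; ++dk) {
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          if (w != 0.0) v += w * at(i0 + di, j0 + dj, k0 + dk);
        }
    out[q] = v;
  }
  return out;
}
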