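#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Stabilized P1-P1 finite-element assembly for the incompressible
// Navier-Stokes momentum/continuity system, linearized about an advection
// field a (semi-implicit convection). Supports d = 2 (triangles) and d = 3
// (tetrahedra). Unknown ordering: velocity components blockwise then
// pressure: dof(node i, comp k) = k*N + i, pressure dof = d*N + i.
//
// Per time step (backward Euler, idt = 1/dt; idt = 0 gives the steady
// system):
//   rho*idt*(u - u_n, w) + rho*(a.grad u, w) + mu*(grad u, grad w)
//     - (p, div w) + SUPG + grad-div = 0
//   (div u, q) + PSPG = 0
// with the elementwise momentum residual R_m = rho*idt*(u - u_n)
// + rho*(a.grad u) + grad p (viscous part vanishes for linear elements):
//   SUPG  = sum_K int tau (a.grad w) . R_m
//   PSPG  = sum_K int (tau/rho) grad q . R_m
//   tau   = ((2*idt)^2 + (2*|a|/h)^2 + (12*nu/h^2)^2)^(-1/2), nu = mu/rho
//   grad-div: gd_scale * rho*|a|*h/2 * (div u, div w)
// Natural (do-nothing) outlet: traction RHS and backflow terms are appended
// by the caller.
// theta: time-weighting of the viscous+convective operator (1 = backward
// Euler, 0.5 = Crank-Nicolson); pressure and stabilization stay implicit.
// [[Rcpp::export]]
List assemble_ns_system(NumericMatrix nodes, IntegerMatrix cells,
                        double rho, double mu, double idt,
                        NumericMatrix uprev, NumericMatrix uadv,
                        bool supg, double gd_scale, double theta = 1.0) {
  const int d = nodes.ncol();
  const int nv = d + 1;
  const int N = nodes.nrow();
  const int M = cells.nrow();
  const int ndof = (d + 1) * N;
  const double nu = mu / rho;

  std::vector<int> ti; std::vector<int> tj; std::vector<double> tx;
  const size_t guess = (size_t)M * nv * nv * (d * (d + 2) + 2);
  ti.reserve(guess); tj.reserve(guess); tx.reserve(guess);
  NumericVector rhs(ndof);

  double J[3][3], Jin[3][3], G[4][3];
  int vid[4];

  for (int e = 0; e < M; ++e) {
    for (int a = 0; a < nv; ++a) vid[a] = cells(e, a) - 1;
    for (int r = 0; r < d; ++r)
      for (int c = 0; c < d; ++c)
        J[r][c] = nodes(vid[r + 1], c) - nodes(vid[0], c);
    double det;
    if (d == 2) {
      det = J[0][0] * J[1][1] - J[0][1] * J[1][0];
      Jin[0][0] =  J[1][1] / det; Jin[0][1] = -J[0][1] / det;
      Jin[1][0] = -J[1][0] / det; Jin[1][1] =  J[0][0] / det;
    } else {
      double c00 =  (J[1][1] * J[2][2] - J[1][2] * J[2][1]);
      double c01 = -(J[1][0] * J[2][2] - J[1][2] * J[2][0]);
      double c02 =  (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      det = J[0][0] * c00 + J[0][1] * c01 + J[0][2] * c02;
      double c10 = -(J[0][1] * J[2][2] - J[0][2] * J[2][1]);
      double c11 =  (J[0][0] * J[2][2] - J[0][2] * J[2][0]);
      double c12 = -(J[0][0] * J[2][1] - J[0][1] * J[2][0]);
      double c20 =  (J[0][1] * J[1][2] - J[0][2] * J[1][1]);
      double c21 = -(J[0][0] * J[1][2] - J[0][2] * J[1][0]);
      double c22 =  (J[0][0] * J[1][1] - J[0][1] * J[1][0]);
      Jin[0][0] = c00 / det; Jin[0][1] = c10 / det; Jin[0][2] = c20 / det;
      Jin[1][0] = c01 / det; Jin[1][1] = c11 / det; Jin[1][2] = c21 / det;
      Jin[2][0] = c02 / det; Jin[2][1] = c12 / det; Jin[2][2] = c22 / det;
    }
    const double V = std::fabs(det) / (d == 2 ? 2.0 : 6.0);
    // gradients of the barycentric shape functions: reference gradients of
    // shape a>=1 are unit vectors, so G[a] = row (a-1) of inv(J); G[0] closes
    // the partition of unity
    for (int k = 0; k < d; ++k) {
      G[0][k] = 0.0;
      for (int a = 1; a < nv; ++a) {
        G[a][k] = Jin[k][a - 1];
        G[0][k] -= G[a][k];
      }
    }
    double ab[3] = {0, 0, 0}, ub[3] = {0, 0, 0};
    for (int a = 0; a < nv; ++a)
      for (int k = 0; k < d; ++k) {
        ab[k] += uadv(vid[a], k) / nv;
        ub[k] += uprev(vid[a], k) / nv;
      }
    double amag = 0; for (int k = 0; k < d; ++k) amag += ab[k] * ab[k];
    amag = std::sqrt(amag);
    double h = 0, hmin2 = 1e300;   // longest and shortest edges
    for (int a = 0; a < nv; ++a)
      for (int b = a + 1; b < nv; ++b) {
        double s = 0;
        for (int k = 0; k < d; ++k) {
          double dxk = nodes(vid[a], k) - nodes(vid[b], k);
          s += dxk * dxk;
        }
        if (s > h) h = s;
        if (s < hmin2) hmin2 = s;
      }
    h = std::sqrt(h);
    // two stabilization lengths for anisotropic boundary-layer cells: the
    // advective term uses the streamwise element length (h_ugn), the
    // viscous/PSPG limit the shortest edge, so tau stays small near walls
    // and does not pollute the wall shear
    const double ht = std::sqrt(hmin2);
    const double t1 = 2.0 * idt;
    double t2 = 0.0;
    {
      double sum_adg = 0.0;
      for (int b = 0; b < nv; ++b) {
        double s = 0;
        for (int k = 0; k < d; ++k) s += ab[k] * G[b][k];
        sum_adg += std::fabs(s);
      }
      t2 = sum_adg;   // = 2*|a| / h_ugn
    }
    const double t3 = 12.0 * nu / (ht * ht);
    const double tau = 1.0 / std::sqrt(t1 * t1 + t2 * t2 + t3 * t3);
    const double gd = gd_scale * rho * amag * ht / 2.0;

    const double Vnv = V / nv;
    const double mfac = V / ((double)(d + 1) * (d + 2));
    double adG[4], adGp[4];
    for (int b = 0; b < nv; ++b) {
      adG[b] = 0; adGp[b] = 0;
      for (int k = 0; k < d; ++k) {
        adG[b] += ab[k] * G[b][k];
        adGp[b] += ub[k] * G[b][k];   // advection by the old velocity
      }
    }

    for (int a = 0; a < nv; ++a) {
      const int ia = vid[a];
      const double wsu = supg ? tau * adG[a] : 0.0;   // SUPG test weight
      for (int k = 0; k < d; ++k) {
        const int row = k * N + ia;
        for (int b = 0; b < nv; ++b) {
          const int ib = vid[b];
          const double mab = mfac * (a == b ? 2.0 : 1.0);
          double gg = 0;
          for (int q = 0; q < d; ++q) gg += G[a][q] * G[b][q];
          // same-component velocity block (theta-weighted operator)
          double val = rho * idt * mab
                     + theta * (rho * adG[b] * Vnv + mu * V * gg)
                     + wsu * rho * (idt * Vnv + adG[b] * V);
          // grad-div (all component pairs)
          if (gd > 0) val += gd * V * G[a][k] * G[b][k];
          ti.push_back(row); tj.push_back(k * N + ib); tx.push_back(val);
          if (gd > 0) {
            for (int l = 0; l < d; ++l) {
              if (l == k) continue;
              ti.push_back(row); tj.push_back(l * N + ib);
              tx.push_back(gd * V * G[a][k] * G[b][l]);
            }
          }
          // pressure column: -(p, d_k w) + SUPG grad p
          double pv = -G[a][k] * Vnv + wsu * G[b][k] * V;
          ti.push_back(row); tj.push_back(d * N + ib); tx.push_back(pv);
        }
        if (idt > 0) {
          double g = 0;
          for (int b = 0; b < nv; ++b)
            g += mfac * (a == b ? 2.0 : 1.0) * uprev(vid[b], k);
          rhs[row] += rho * idt * g + wsu * rho * idt * V * ub[k];
          if (theta < 1.0) {
            // explicit part of the theta-weighted operator on u^n
            double ex = 0;
            for (int b = 0; b < nv; ++b) {
              double gg = 0;
              for (int q = 0; q < d; ++q) gg += G[a][q] * G[b][q];
              ex += (rho * adGp[b] * Vnv + mu * V * gg) * uprev(vid[b], k);
            }
            rhs[row] -= (1.0 - theta) * ex;
          }
        }
      }
      // continuity row
      const int prow = d * N + ia;
      for (int b = 0; b < nv; ++b) {
        const int ib = vid[b];
        for (int l = 0; l < d; ++l) {
          double val = G[b][l] * Vnv
                     + tau * (idt * G[a][l] * Vnv + G[a][l] * adG[b] * V);
          ti.push_back(prow); tj.push_back(l * N + ib); tx.push_back(val);
        }
        double gg = 0;
        for (int q = 0; q < d; ++q) gg += G[a][q] * G[b][q];
        ti.push_back(prow); tj.push_back(d * N + ib);
        tx.push_back(tau / rho * V * gg);
      }
      if (idt > 0) {
        double g = 0;
        for (int k = 0; k < d; ++k) g += G[a][k] * ub[k];
        rhs[prow] += tau * idt * V * g;
      }
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["x"] = wrap(tx), _["rhs"] = rhs,
                      _["ndof"] = ndof);
}

// Cell gradient of a nodal vector field, per requested cell.
// Returns an nc x (d*d) matrix: row-major L[k][l] = d u_k / d x_l.
// [[Rcpp::export]]
NumericMatrix cell_velocity_gradients(NumericMatrix nodes, IntegerMatrix cells,
                                      IntegerVector which_cells,
                                      NumericMatrix U) {
  const int d = nodes.ncol();
  const int nv = d + 1;
  const int nc = which_cells.size();
  NumericMatrix out(nc, d * d);
  double J[3][3], Jin[3][3], G[4][3];
  int vid[4];
  for (int ee = 0; ee < nc; ++ee) {
    int e = which_cells[ee] - 1;
    for (int a = 0; a < nv; ++a) vid[a] = cells(e, a) - 1;
    for (int r = 0; r < d; ++r)
      for (int c = 0; c < d; ++c)
        J[r][c] = nodes(vid[r + 1], c) - nodes(vid[0], c);
    double det;
    if (d == 2) {
      det = J[0][0] * J[1][1] - J[0][1] * J[1][0];
      Jin[0][0] =  J[1][1] / det; Jin[0][1] = -J[0][1] / det;
      Jin[1][0] = -J[1][0] / det; Jin[1][1] =  J[0][0] / det;
    } else {
      double c00 =  (J[1][1] * J[2][2] - J[1][2] * J[2][1]);
      double c01 = -(J[1][0] * J[2][2] - J[1][2] * J[2][0]);
      double c02 =  (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      det = J[0][0] * c00 + J[0][1] * c01 + J[0][2] * c02;
      double c10 = -(J[0][1] * J[2][2] - J[0][2] * J[2][1]);
      double c11 =  (J[0][0] * J[2][2] - J[0][2] * J[2][0]);
      double c12 = -(J[0][0] * J[2][1] - J[0][1] * J[2][0]);
      double c20 =  (J[0][1] * J[1][2] - J[0][2] * J[1][1]);
      double c21 = -(J[0][0] * J[1][2] - J[0][2] * J[1][0]);
      double c22 =  (J[0][0] * J[1][1] - J[0][1] * J[1][0]);
      Jin[0][0] = c00 / det; Jin[0][1] = c10 / det; Jin[0][2] = c20 / det;
      Jin[1][0] = c01 / det; Jin[1][1] = c11 / det; Jin[1][2] = c21 / det;
      Jin[2][0] = c02 / det; Jin[2][1] = c12 / det; Jin[2][2] = c22 / det;
    }
    for (int k = 0; k < d; ++k) {
      G[0][k] = 0.0;
      for (int a = 1; a < nv; ++a) {
        G[a][k] = Jin[k][a - 1];
        G[0][k] -= G[a][k];
      }
    }
    for (int k = 0; k < d; ++k)
      for (int l = 0; l < d; ++l) {
        double s = 0;
        for (int a = 0; a < nv; ++a) s += U(vid[a], k) * G[a][l];
        out(ee, k * d + l) = s;
      }
  }
  return out;
}

// Quadratic least-squares (patch-recovery) velocity gradient at each wall
// facet midpoint: fit u ~ c0 + c.x + x^T Q x over the node patch around the
// wall-adjacent cell and return the linear part evaluated at the midpoint.
// patches: list of 1-based node index vectors, one per facet; mids: nf x d.
// Falls back to the normal-equation solve with a tiny ridge for stability.
// [[Rcpp::export]]
NumericMatrix patch_velocity_gradients(NumericMatrix nodes, List patches,
                                       NumericMatrix mids, NumericMatrix U,
                                       double hscale) {
  const int d = nodes.ncol();
  const int nf = patches.size();
  const int ncoef = (d == 2) ? 6 : 10;
  NumericMatrix out(nf, d * d);
  std::vector<double> A, rhsv;
  for (int f = 0; f < nf; ++f) {
    IntegerVector pn = patches[f];
    const int np = pn.size();
    if (np < ncoef) { // too few points for a quadratic fit: linear fallback
      for (int k = 0; k < d * d; ++k) out(f, k) = NA_REAL;
      continue;
    }
    // monomial design matrix in scaled local coordinates
    A.assign((size_t)np * ncoef, 0.0);
    for (int i = 0; i < np; ++i) {
      double x[3] = {0, 0, 0};
      for (int k = 0; k < d; ++k)
        x[k] = (nodes(pn[i] - 1, k) - mids(f, k)) / hscale;
      double* row = &A[(size_t)i * ncoef];
      int c = 0;
      row[c++] = 1.0;
      for (int k = 0; k < d; ++k) row[c++] = x[k];
      for (int k = 0; k < d; ++k)
        for (int l = k; l < d; ++l) row[c++] = x[k] * x[l];
    }
    // normal equations M = A^T A (+ridge), one Cholesky per facet
    double M[10][10], bvec[10][3];
    for (int a = 0; a < ncoef; ++a) {
      for (int b = 0; b < ncoef; ++b) {
        double s = 0;
        for (int i = 0; i < np; ++i)
          s += A[(size_t)i * ncoef + a] * A[(size_t)i * ncoef + b];
        M[a][b] = s;
      }
      M[a][a] *= (1.0 + 1e-12);
      M[a][a] += 1e-12;
      for (int k = 0; k < d; ++k) {
        double s = 0;
        for (int i = 0; i < np; ++i)
          s += A[(size_t)i * ncoef + a] * U(pn[i] - 1, k);
        bvec[a][k] = s;
      }
    }
    // Cholesky M = LL^T
    bool ok = true;
    for (int a = 0; a < ncoef && ok; ++a) {
      for (int b = 0; b <= a; ++b) {
        double s = M[a][b];
        for (int q = 0; q < b; ++q) s -= M[a][q] * M[b][q];
        if (a == b) {
          if (s <= 0) { ok = false; break; }
          M[a][a] = std::sqrt(s);
        } else {
          M[a][b] = s / M[b][b];
        }
      }
    }
    if (!ok) {
      for (int k = 0; k < d * d; ++k) out(f, k) = NA_REAL;
      continue;
    }
    for (int k = 0; k < d; ++k) {
      double y[10];
      for (int a = 0; a < ncoef; ++a) {
        double s = bvec[a][k];
        for (int q = 0; q < a; ++q) s -= M[a][q] * y[q];
        y[a] = s / M[a][a];
      }
      double cvec[10];
      for (int a = ncoef - 1; a >= 0; --a) {
        double s = y[a];
        for (int q = a + 1; q < ncoef; ++q) s -= M[q][a] * cvec[q];
        cvec[a] = s / M[a][a];
      }
      // gradient at the midpoint = linear coefficients / hscale
      for (int l = 0; l < d; ++l) out(f, k * d + l) = cvec[1 + l] / hscale;
    }
  }
  return out;
}
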