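// Compiled kernels for the coupled huddle simulation.
//
// Conventions shared with the R layer:
//  * Grids are R matrices with nx rows (x, across the domain) and ny columns
//    (y, along the flow axis). Cell centres sit at ((i+0.5)dx, (j+0.5)dx) for
//    0-based (i, j).
//  * Staggered (MAC) layout: u is (nx+1) x ny on vertical faces, v is
//    nx x (ny+1) on horizontal faces, p/theta/mask are nx x ny at centres.
//  * The solver always works with inflow on the j = 0 edge flowing in +y;
//    the R layer transposes fields for an x-axis inflow.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Cubic spline kernel (2D), W(r) = sigma * spline(q), q = r/h.
// sigma is passed in so the R layer controls the normalisation convention.
// ---------------------------------------------------------------------------
static inline double kern_w(double r, double h, double sigma) {
  double q = r / h;
  if (q < 1.0) return sigma * (1.0 - 1.5 * q * q + 0.75 * q * q * q);
  if (q < 2.0) { double t = 2.0 - q; return sigma * 0.25 * t * t * t; }
  return 0.0;
}

// dW/dr
static inline double kern_dw(double r, double h, double sigma) {
  double q = r / h;
  if (q < 1.0) return sigma * (-3.0 * q + 2.25 * q * q) / h;
  if (q < 2.0) { double t = 2.0 - q; return -0.75 * sigma * t * t / h; }
  return 0.0;
}

// ---------------------------------------------------------------------------
// Uniform cell list with cell size 2h (exactness vs brute force is tested
// at the R level; the list only prunes pairs beyond the support radius).
// ---------------------------------------------------------------------------
struct CellList {
  double x0, y0, cs;
  int ncx, ncy;
  std::vector<std::vector<int>> bins;

  CellList(const NumericVector& x, const NumericVector& y, double cell) {
    int n = x.size();
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
    for (int i = 1; i < n; ++i) {
      if (x[i] < xmin) xmin = x[i];
      if (x[i] > xmax) xmax = x[i];
      if (y[i] < ymin) ymin = y[i];
      if (y[i] > ymax) ymax = y[i];
    }
    cs = cell;
    x0 = xmin; y0 = ymin;
    ncx = (int)std::floor((xmax - x0) / cs) + 1;
    ncy = (int)std::floor((ymax - y0) / cs) + 1;
    bins.assign((size_t)ncx * ncy, {});
    for (int i = 0; i < n; ++i) bins[index_of(x[i], y[i])].push_back(i);
  }
  inline size_t index_of(double px, double py) const {
    int cx = (int)std::floor((px - x0) / cs);
    int cy = (int)std::floor((py - y0) / cs);
    if (cx < 0) cx = 0; if (cx >= ncx) cx = ncx - 1;
    if (cy < 0) cy = 0; if (cy >= ncy) cy = ncy - 1;
    return (size_t)cy * ncx + cx;
  }
  // visit all particles in the 3x3 block of cells around (px, py)
  template <typename F>
  void visit(double px, double py, F f) const {
    int cx = (int)std::floor((px - x0) / cs);
    int cy = (int)std::floor((py - y0) / cs);
    for (int dy = -1; dy <= 1; ++dy) {
      int yy = cy + dy;
      if (yy < 0 || yy >= ncy) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = cx + dx;
        if (xx < 0 || xx >= ncx) continue;
        for (int id : bins[(size_t)yy * ncx + xx]) f(id);
      }
    }
  }
};

// [[Rcpp::export]]
NumericVector cpp_sph_density(NumericVector x, NumericVector y,
                              NumericVector m, double h, double sigma) {
  int n = x.size();
  NumericVector rho(n);
  double r2max = 4.0 * h * h;
  CellList cl(x, y, 2.0 * h);
  for (int j = 0; j < n; ++j) {
    double s = 0.0, xj = x[j], yj = y[j];
    cl.visit(xj, yj, [&](int i) {
      double dx = xj - x[i], dy = yj - y[i];
      double r2 = dx * dx + dy * dy;
      if (r2 < r2max) s += m[i] * kern_w(std::sqrt(r2), h, sigma);
    });
    rho[j] = s;
  }
  return rho;
}

// Continuity-equation density rate: d(rho_j)/dt = sum_i m_i (v_j - v_i) . grad_j W_ji
// [[Rcpp::export]]
NumericVector cpp_sph_density_rate(NumericVector x, NumericVector y,
                                   NumericVector vx, NumericVector vy,
                                   NumericVector m, double h, double sigma) {
  int n = x.size();
  NumericVector drho(n);
  double r2max = 4.0 * h * h;
  CellList cl(x, y, 2.0 * h);
  for (int j = 0; j < n; ++j) {
    double s = 0.0, xj = x[j], yj = y[j];
    cl.visit(xj, yj, [&](int i) {
      if (i == j) return;
      double dx = xj - x[i], dy = yj - y[i];
      double r2 = dx * dx + dy * dy;
      if (r2 >= r2max || r2 == 0.0) return;
      double r = std::sqrt(r2);
      double dw = kern_dw(r, h, sigma) / r; // grad_j W = (r_j - r_i) * dw
      s += m[i] * ((vx[j] - vx[i]) * dx + (vy[j] - vy[i]) * dy) * dw;
    });
    drho[j] = s;
  }
  return drho;
}

// Symmetric SPH pressure-gradient acceleration:
//   a_j = -sum_i m_i (P_i/rho_i^2 + P_j/rho_j^2) grad_j W_ji
// [[Rcpp::export]]
NumericMatrix cpp_sph_repulsion(NumericVector x, NumericVector y,
                                NumericVector m, NumericVector rho,
                                NumericVector P, double h, double sigma) {
  int n = x.size();
  NumericMatrix a(n, 2);
  double r2max = 4.0 * h * h;
  for (int j = 0; j < n; ++j) {
    if (rho[j] <= 0.0) stop("sph density must be positive");
  }
  for (int j = 0; j < n; ++j) {
    double pj = P[j] / (rho[j] * rho[j]);
    for (int i = j + 1; i < n; ++i) {
      double dx = x[j] - x[i], dy = y[j] - y[i];
      double r2 = dx * dx + dy * dy;
      if (r2 >= r2max || r2 == 0.0) continue;
      double r = std::sqrt(r2);
      double S = P[i] / (rho[i] * rho[i]) + pj;
      double f = -S * kern_dw(r, h, sigma) / r; // repulsive when S > 0
      a(j, 0) += m[i] * f * dx;
      a(j, 1) += m[i] * f * dy;
      a(i, 0) -= m[j] * f * dx;
      a(i, 1) -= m[j] * f * dy;
    }
  }
  return a;
}

// Weighted kernel sum at arbitrary query points: out_q = sum_i w_i W(|q - p_i|)
// [[Rcpp::export]]
NumericVector cpp_kernel_sum_at(NumericVector qx, NumericVector qy,
                                NumericVector px, NumericVector py,
                                NumericVector w, double h, double sigma) {
  int nq = qx.size(), np = px.size();
  NumericVector out(nq);
  double r2max = 4.0 * h * h;
  if (np == 0) return out;
  CellList cl(px, py, 2.0 * h);
  for (int q = 0; q < nq; ++q) {
    double s = 0.0, xq = qx[q], yq = qy[q];
    cl.visit(xq, yq, [&](int i) {
      double dx = xq - px[i], dy = yq - py[i];
      double r2 = dx * dx + dy * dy;
      if (r2 < r2max) s += w[i] * kern_w(std::sqrt(r2), h, sigma);
    });
    out[q] = s;
  }
  return out;
}

// Deposit weighted kernel mass onto cell centres of an (nx, ny) grid.
// [[Rcpp::export]]
NumericMatrix cpp_kernel_sum_grid(NumericVector px, NumericVector py,
                                  NumericVector w, double h, double sigma,
                                  int nx, int ny, double dx) {
  NumericMatrix out(nx, ny);
  int np = px.size();
  int win = (int)std::ceil(2.0 * h / dx) + 1;
  for (int k = 0; k < np; ++k) {
    int ic = (int)std::floor(px[k] / dx);
    int jc = (int)std::floor(py[k] / dx);
    int i0 = std::max(0, ic - win), i1 = std::min(nx - 1, ic + win);
    int j0 = std::max(0, jc - win), j1 = std::min(ny - 1, jc + win);
    for (int j = j0; j <= j1; ++j) {
      double cy = (j + 0.5) * dx - py[k];
      for (int i = i0; i <= i1; ++i) {
        double cx = (i + 0.5) * dx - px[k];
        double r = std::sqrt(cx * cx + cy * cy);
        if (r < 2.0 * h) out(i, j) += w[k] * kern_w(r, h, sigma);
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Wind solver (projection method on the MAC grid, inflow at j = 0 in +y).
// ---------------------------------------------------------------------------

static inline bool face_u_masked(const IntegerMatrix& mask, int i, int j, int nx) {
  // u face i between cells (i-1, j) and (i, j); boundary faces are walls
  if (i == 0 || i == nx) return true;
  return mask(i - 1, j) != 0 || mask(i, j) != 0;
}
static inline bool face_v_masked(const IntegerMatrix& mask, int i, int j, int ny) {
  if (j == 0) return mask(i, 0) != 0;          // inflow face blocked by a body
  if (j == ny) return false;                   // outflow face (copied)
  return mask(i, j - 1) != 0 || mask(i, j) != 0;
}

// One explicit predictor step: donor-cell advection + viscous diffusion,
// no pressure gradient. Returns list(u, v, cfl).
// [[Rcpp::export]]
List cpp_predictor(NumericMatrix u, NumericMatrix v, IntegerMatrix mask,
                   double dt, double dx, double nu, double vin) {
  int nx = mask.nrow(), ny = mask.ncol();
  NumericMatrix us(clone(u)), vs(clone(v));
  double cfl = 0.0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i <= nx; ++i)
      cfl = std::max(cfl, std::fabs(u(i, j)) * dt / dx);
  for (int j = 0; j <= ny; ++j)
    for (int i = 0; i < nx; ++i)
      cfl = std::max(cfl, std::fabs(v(i, j)) * dt / dx);

  // u faces (tangential ghost at inflow: u = 0 on the boundary line)
  for (int j = 0; j < ny; ++j) {
    for (int i = 1; i < nx; ++i) {
      if (face_u_masked(mask, i, j, nx)) { us(i, j) = 0.0; continue; }
      double uc = u(i, j);
      double uE = u(i + 1, j), uW = u(i - 1, j);
      double uN = (j + 1 < ny) ? u(i, j + 1) : uc;        // outflow: zero gradient
      double uS = (j > 0) ? u(i, j - 1) : -uc;            // inflow: u = 0 at edge
      double ce = 0.5 * (uc + uE), cw = 0.5 * (uW + uc);
      double Fe = ce * (ce > 0 ? uc : uE);
      double Fw = cw * (cw > 0 ? uW : uc);
      double vn = 0.5 * (v(i - 1, j + 1) + v(i, j + 1));
      double vsf = 0.5 * (v(i - 1, j) + v(i, j));
      double Fn = vn * (vn > 0 ? uc : uN);
      double Fs = vsf * (vsf > 0 ? uS : uc);
      double adv = (Fe - Fw) / dx + (Fn - Fs) / dx;
      double lap = (uE - 2 * uc + uW + uN - 2 * uc + uS) / (dx * dx);
      us(i, j) = uc + dt * (-adv + nu * lap);
    }
    us(0, j) = 0.0; us(nx, j) = 0.0;
  }

  // v faces (free-slip lateral ghosts: dv/dx = 0)
  for (int j = 1; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (face_v_masked(mask, i, j, ny)) { vs(i, j) = 0.0; continue; }
      double vc = v(i, j);
      double vE = (i + 1 < nx) ? v(i + 1, j) : vc;
      double vW = (i > 0) ? v(i - 1, j) : vc;
      double vN = v(i, j + 1), vS = v(i, j - 1);
      double ue = 0.5 * (u(i + 1, j - 1) + u(i + 1, j));
      double uw = 0.5 * (u(i, j - 1) + u(i, j));
      double Fe = ue * (ue > 0 ? vc : vE);
      double Fw = uw * (uw > 0 ? vW : vc);
      double cn = 0.5 * (vc + vN), cs = 0.5 * (vS + vc);
      double Fn = cn * (cn > 0 ? vc : vN);
      double Fs = cs * (cs > 0 ? vS : vc);
      double adv = (Fe - Fw) / dx + (Fn - Fs) / dx;
      double lap = (vE - 2 * vc + vW + vN - 2 * vc + vS) / (dx * dx);
      vs(i, j) = vc + dt * (-adv + nu * lap);
    }
  }
  for (int i = 0; i < nx; ++i) {
    vs(i, 0) = mask(i, 0) ? 0.0 : vin;    // inflow
    vs(i, ny) = vs(i, ny - 1);            // outflow: zero gradient
  }
  return List::create(_["u"] = us, _["v"] = vs, _["cfl"] = cfl);
}

// Discrete divergence at cell centres (masked cells reported as 0).
// [[Rcpp::export]]
NumericMatrix cpp_divergence(NumericMatrix u, NumericMatrix v,
                             IntegerMatrix mask, double dx) {
  int nx = mask.nrow(), ny = mask.ncol();
  NumericMatrix d(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (!mask(i, j))
        d(i, j) = (u(i + 1, j) - u(i, j) + v(i, j + 1) - v(i, j)) / dx;
  return d;
}

// Red-black SOR for the pressure Poisson equation with Neumann conditions on
// walls, inflow, and obstacle cells, and p = 0 (ghost Dirichlet) past the
// outflow edge. The stencil structure (fluid-cell lists, neighbour flags,
// counts) is precomputed once per solve so the sweep loops touch flat arrays
// only. Returns list(p, iters, converged, max_residual).
// [[Rcpp::export]]
List cpp_poisson_sor(NumericMatrix rhs, NumericMatrix p0, IntegerMatrix mask,
                     double dx, double tol, int maxit, double omega) {
  int nx = mask.nrow(), ny = mask.ncol();
  NumericMatrix p(clone(p0));
  double dx2 = dx * dx;
  double* P = p.begin();
  const double* RHS = rhs.begin();
  const int* M = mask.begin();
  int ncell = nx * ny;

  // stencil setup: flags bit 0..3 = W,E,S,N fluid neighbour; bit 4 = outflow ghost
  std::vector<unsigned char> flags(ncell, 0);
  std::vector<double> invcnt(ncell, 0.0);
  std::vector<int> red, black, fluid;
  red.reserve(ncell / 2 + 1); black.reserve(ncell / 2 + 1);
  fluid.reserve(ncell);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      int idx = i + nx * j;
      if (M[idx]) continue;
      unsigned char f = 0; int cnt = 0;
      if (i > 0 && !M[idx - 1]) { f |= 1; ++cnt; }
      if (i + 1 < nx && !M[idx + 1]) { f |= 2; ++cnt; }
      if (j > 0 && !M[idx - nx]) { f |= 4; ++cnt; }
      if (j + 1 < ny) { if (!M[idx + nx]) { f |= 8; ++cnt; } }
      else { f |= 16; ++cnt; }  // outflow ghost p = 0
      if (cnt == 0) continue;
      flags[idx] = f;
      invcnt[idx] = 1.0 / cnt;
      fluid.push_back(idx);
      if (((i + j) & 1) == 0) red.push_back(idx); else black.push_back(idx);
    }
  }
  auto sweep = [&](const std::vector<int>& cells) {
    for (int idx : cells) {
      unsigned char f = flags[idx];
      double s = 0.0;
      if (f & 1) s += P[idx - 1];
      if (f & 2) s += P[idx + 1];
      if (f & 4) s += P[idx - nx];
      if (f & 8) s += P[idx + nx];
      P[idx] += omega * ((s - dx2 * RHS[idx]) * invcnt[idx] - P[idx]);
    }
  };
  auto residual = [&]() {
    double mr = 0.0;
    for (int idx : fluid) {
      unsigned char f = flags[idx];
      double s = 0.0;
      if (f & 1) s += P[idx - 1];
      if (f & 2) s += P[idx + 1];
      if (f & 4) s += P[idx - nx];
      if (f & 8) s += P[idx + nx];
      double r = std::fabs((s - P[idx] / invcnt[idx]) / dx2 - RHS[idx]);
      if (r > mr) mr = r;
    }
    return mr;
  };

  double maxres = R_PosInf;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    sweep(red);
    sweep(black);
    if ((it & 7) == 7 || it == maxit - 1) {
      maxres = residual();
      if (maxres <= tol) { ++it; break; }
    }
  }
  return List::create(_["p"] = p, _["iters"] = it,
                      _["converged"] = (maxres <= tol),
                      _["max_residual"] = maxres);
}

// Pressure-correct the intermediate velocity; re-zero masked faces.
// [[Rcpp::export]]
List cpp_project(NumericMatrix us, NumericMatrix vs, NumericMatrix p,
                 IntegerMatrix mask, double dt, double dx, double rho) {
  int nx = mask.nrow(), ny = mask.ncol();
  NumericMatrix u(clone(us)), v(clone(vs));
  double c = dt / (rho * dx);
  for (int j = 0; j < ny; ++j)
    for (int i = 1; i < nx; ++i)
      u(i, j) = face_u_masked(mask, i, j, nx) ? 0.0
              : u(i, j) - c * (p(i, j) - p(i - 1, j));
  for (int j = 1; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      v(i, j) = face_v_masked(mask, i, j, ny) ? 0.0
              : v(i, j) - c * (p(i, j) - p(i, j - 1));
  for (int i = 0; i < nx; ++i) {
    // outflow: correct with the ghost Dirichlet (p = 0 outside)
    v(i, ny) = v(i, ny) - c * (0.0 - p(i, ny - 1));
  }
  double maxdiv = 0.0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (!mask(i, j)) {
        double d = std::fabs(u(i + 1, j) - u(i, j) + v(i, j + 1) - v(i, j)) / dx;
        if (d > maxdiv) maxdiv = d;
      }
  return List::create(_["u"] = u, _["v"] = v, _["max_div"] = maxdiv);
}

// nsub full predictor/PPE/projection cycles (quasi-steady continuation).
// [[Rcpp::export]]
List cpp_wind_substeps(NumericMatrix u0, NumericMatrix v0, NumericMatrix p0,
                       IntegerMatrix mask, double dt, double dx, double nu,
                       double rho, double vin, int nsub, double tol,
                       int maxit, double omega) {
  NumericMatrix u(clone(u0)), v(clone(v0)), p(clone(p0));
  int nx = mask.nrow(), ny = mask.ncol();
  double maxdiv = 0.0, cfl = 0.0;
  int total_iters = 0;
  bool all_converged = true;

  // Fluid cells not connected to the inflow through open faces (pockets
  // enclosed by the stamped huddle) are frozen: they would otherwise form
  // pure-Neumann islands for the pressure solve and trap recirculating
  // momentum with no outlet. Treat them as obstacles for this update.
  IntegerMatrix emask(clone(mask));
  {
    std::vector<int> stack;
    std::vector<unsigned char> seen((size_t)nx * ny, 0);
    for (int i = 0; i < nx; ++i)
      if (!mask(i, 0)) { seen[i] = 1; stack.push_back(i); }
    while (!stack.empty()) {
      int idx = stack.back(); stack.pop_back();
      int i = idx % nx, j = idx / nx;
      const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
      for (int d = 0; d < 4; ++d) {
        int ii = i + di[d], jj = j + dj[d];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
        int nidx = ii + nx * jj;
        if (seen[nidx] || mask(ii, jj)) continue;
        seen[nidx] = 1; stack.push_back(nidx);
      }
    }
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (!mask(i, j) && !seen[i + nx * j]) emask(i, j) = 1;
  }
  IntegerMatrix& msk = emask;

  // enforce face masking on entry (the mask may have changed)
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i <= nx; ++i)
      if (face_u_masked(msk, i, j, nx)) u(i, j) = 0.0;
  for (int j = 0; j <= ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (face_v_masked(msk, i, j, ny)) v(i, j) = 0.0;
  for (int i = 0; i < nx; ++i) v(i, 0) = msk(i, 0) ? 0.0 : vin;

  for (int s = 0; s < nsub; ++s) {
    List pred = cpp_predictor(u, v, msk, dt, dx, nu, vin);
    cfl = std::max(cfl, as<double>(pred["cfl"]));
    NumericMatrix us = pred["u"], vs = pred["v"];
    NumericMatrix rhs(nx, ny);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (!msk(i, j))
          rhs(i, j) = rho * (us(i + 1, j) - us(i, j) + vs(i, j + 1) - vs(i, j)) /
                      (dx * dt);
    List sol = cpp_poisson_sor(rhs, p, msk, dx, tol * rho / dt, maxit, omega);
    p = as<NumericMatrix>(sol["p"]);
    total_iters += as<int>(sol["iters"]);
    if (!as<bool>(sol["converged"])) all_converged = false;
    List prj = cpp_project(us, vs, p, msk, dt, dx, rho);
    u = as<NumericMatrix>(prj["u"]);
    v = as<NumericMatrix>(prj["v"]);
    maxdiv = as<double>(prj["max_div"]);
  }
  return List::create(_["u"] = u, _["v"] = v, _["p"] = p,
                      _["max_div"] = maxdiv, _["cfl"] = cfl,
                      _["ppe_iters"] = total_iters,
                      _["converged"] = all_converged);
}

// ---------------------------------------------------------------------------
// Temperature-anomaly transport: dimensionally split, flux-form *implicit*
// (backward Euler) upwind sweeps plus explicit diffusion. Each 1D sweep is a
// tridiagonal M-matrix solve (Thomas algorithm), so the scheme is
// unconditionally stable, conservative up to boundary fluxes, and
// positivity-preserving regardless of the local CFL number — which matters
// because stair-step corner jets around the stamped huddle reach several
// times the free-stream speed. Masked faces carry zero velocity so masked
// (huddle) cells exchange heat by diffusion only.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_advect_theta(NumericMatrix theta0, NumericMatrix u,
                               NumericMatrix v, IntegerMatrix mask,
                               double dx, double total_t, double kappa,
                               int nsub) {
  int nx = mask.nrow(), ny = mask.ncol();
  NumericMatrix th(clone(theta0));
  if (total_t <= 0) return th;
  if (nsub < 1) nsub = 1;
  // explicit diffusion needs its own substep bound (kappa is tiny for air,
  // so this rarely binds)
  if (kappa > 0) {
    int nd = (int)std::ceil(total_t / (0.2 * dx * dx / kappa));
    if (nd > nsub) nsub = nd;
  }
  double dt = total_t / nsub;
  double r = dt / dx;
  double* T = th.begin();
  std::vector<double> b(std::max(nx, ny)), rhsv(std::max(nx, ny)),
      cp(std::max(nx, ny));
  NumericMatrix dif(nx, ny);

  for (int s = 0; s < nsub; ++s) {
    // x-sweep: per grid column j, tridiagonal solve along i
    for (int j = 0; j < ny; ++j) {
      int off = nx * j;
      // faces: u(i, j) between cells i-1 and i; u(0)=u(nx)=0 (walls)
      for (int i = 0; i < nx; ++i) {
        double uw = u(i, j), ue = u(i + 1, j);
        double uwp = uw > 0 ? uw : 0, uwm = uw < 0 ? uw : 0;
        double uep = ue > 0 ? ue : 0, uem = ue < 0 ? ue : 0;
        b[i] = 1.0 + r * (uep - uwm);
        rhsv[i] = T[off + i];
        // sub-diagonal a_i = -r*uwp, super-diagonal c_i = r*uem
        cp[i] = r * uem;
      }
      // Thomas forward elimination (a_i recomputed on the fly)
      for (int i = 1; i < nx; ++i) {
        double uw = u(i, j);
        double a = -(uw > 0 ? r * uw : 0.0);
        double m = a / b[i - 1];
        b[i] -= m * cp[i - 1];
        rhsv[i] -= m * rhsv[i - 1];
      }
      T[off + nx - 1] = rhsv[nx - 1] / b[nx - 1];
      for (int i = nx - 2; i >= 0; --i)
        T[off + i] = (rhsv[i] - cp[i] * T[off + i + 1]) / b[i];
    }
    // y-sweep: per grid row i, tridiagonal solve along j
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) {
        double vs = v(i, j), vn = v(i, j + 1);
        double vsm = vs < 0 ? vs : 0;
        double vnp = vn > 0 ? vn : 0, vnm = vn < 0 ? vn : 0;
        // inflow face (j = 0) carries theta = 0; outflow face (j = ny-1's
        // north) lets vnp*theta leave and brings nothing in
        if (j + 1 == ny) vnm = 0;
        b[j] = 1.0 + r * (vnp - vsm);
        rhsv[j] = T[i + nx * j];
        cp[j] = r * vnm;
      }
      for (int j = 1; j < ny; ++j) {
        double vs = v(i, j);
        double a = -(vs > 0 ? r * vs : 0.0);
        double m = a / b[j - 1];
        b[j] -= m * cp[j - 1];
        rhsv[j] -= m * rhsv[j - 1];
      }
      T[i + nx * (ny - 1)] = rhsv[ny - 1] / b[ny - 1];
      for (int j = ny - 2; j >= 0; --j)
        T[i + nx * j] = (rhsv[j] - cp[j] * T[i + nx * (j + 1)]) / b[j];
    }
    // explicit diffusion, zero-flux domain boundaries, mask ignored
    if (kappa > 0) {
      double kd = kappa * dt / (dx * dx);
      for (int j = 0; j < ny; ++j) {
        int off = nx * j;
        for (int i = 0; i < nx; ++i) {
          double t = T[off + i];
          double tE = (i + 1 < nx) ? T[off + i + 1] : t;
          double tW = (i > 0) ? T[off + i - 1] : t;
          double tN = (j + 1 < ny) ? T[off + nx + i] : t;
          double tS = (j > 0) ? T[off - nx + i] : t;
          dif(i, j) = kd * (tE + tW + tN + tS - 4 * t);
        }
      }
      for (int k = 0; k < nx * ny; ++k) {
        double val = T[k] + dif.begin()[k];
        T[k] = (val > 0) ? val : 0.0;
      }
    }
  }
  return th;
}

// ---------------------------------------------------------------------------
// Behaviour substeps over one coupling interval. Wind-chill drive b is frozen
// for the interval; SPH density/pressure/repulsion and the colony centre of
// mass are refreshed every substep. Overdamped update: v = dt * a, speed-capped.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_behavior_interval(NumericVector x0, NumericVector y0,
                           NumericVector b, NumericVector m,
                           double h, double sigma, double k, double rho0,
                           double dt, int nsub, double vmax,
                           double Lx, double Ly, double body_radius) {
  int n = x0.size();
  NumericVector x(clone(x0)), y(clone(y0));
  NumericVector vx(n), vy(n), rho(n), P(n);
  double lo = body_radius;
  for (int s = 0; s < nsub; ++s) {
    rho = cpp_sph_density(x, y, m, h, sigma);
    for (int i = 0; i < n; ++i) {
      double ex = rho[i] - rho0;
      P[i] = ex > 0 ? k * ex : 0.0;
    }
    NumericMatrix ar = cpp_sph_repulsion(x, y, m, rho, P, h, sigma);
    double cx = 0.0, cy = 0.0;
    for (int i = 0; i < n; ++i) { cx += x[i]; cy += y[i]; }
    cx /= n; cy /= n;
    for (int i = 0; i < n; ++i) {
      double dxc = cx - x[i], dyc = cy - y[i];
      double d = std::sqrt(dxc * dxc + dyc * dyc);
      double ax = ar(i, 0), ay = ar(i, 1);
      if (d > body_radius) { ax += b[i] * dxc / d; ay += b[i] * dyc / d; }
      double nvx = dt * ax, nvy = dt * ay;
      double sp = std::sqrt(nvx * nvx + nvy * nvy);
      if (sp > vmax) { nvx *= vmax / sp; nvy *= vmax / sp; }
      vx[i] = nvx; vy[i] = nvy;
    }
    for (int i = 0; i < n; ++i) {
      double nxp = x[i] + dt * vx[i], nyp = y[i] + dt * vy[i];
      if (nxp < lo) { nxp = lo; if (vx[i] < 0) vx[i] = 0; }
      if (nxp > Lx - lo) { nxp = Lx - lo; if (vx[i] > 0) vx[i] = 0; }
      if (nyp < lo) { nyp = lo; if (vy[i] < 0) vy[i] = 0; }
      if (nyp > Ly - lo) { nyp = Ly - lo; if (vy[i] > 0) vy[i] = 0; }
      if (!std::isfinite(nxp) || !std::isfinite(nyp))
        stop("non-finite position for agent %d", i + 1);
      x[i] = nxp; y[i] = nyp;
    }
  }
  return List::create(_["x"] = x, _["y"] = y, _["vx"] = vx, _["vy"] = vy);
}
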