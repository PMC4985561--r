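#include <Rcpp.h>
#include <Rmath.h>
using namespace Rcpp;

// ---- circular helpers -------------------------------------------------

// scaled modified Bessel: bessel_i(x, nu, 2) = I_nu(x) * exp(-x)
static inline double i0e(double x) { return R::bessel_i(x, 0.0, 2.0); }
static inline double i1e(double x) { return R::bessel_i(x, 1.0, 2.0); }

// A(kappa) = I1(kappa)/I0(kappa), the mean resultant length of a von Mises
static inline double bessel_ratio(double k) {
  if (k <= 0.0) return 0.0;
  return i1e(k) / i0e(k);
}

// invert A(kappa) = r: Best-Fisher start + Newton, machine-precision
// accurate for r in [0, 1).
// [[Rcpp::export]]
double cpp_mrl_to_kappa(double r) {
  if (r <= 0.0) return 0.0;
  if (r >= 1.0) Rcpp::stop("mean resultant length must be < 1");
  double k;
  if (r < 0.53) k = 2.0 * r + r * r * r + 5.0 * r * r * r * r * r / 6.0;
  else if (r < 0.85) k = -0.4 + 1.39 * r + 0.43 / (1.0 - r);
  else k = 1.0 / (r * r * r - 4.0 * r * r + 3.0 * r);
  for (int i = 0; i < 8; ++i) {
    double a = bessel_ratio(k);
    double da = 1.0 - a * a - a / k; // d A / d kappa
    if (da <= 0.0) break;
    double step = (a - r) / da;
    k -= step;
    if (k <= 0.0) k = 1e-10;
    if (std::fabs(step) < 1e-12 * (1.0 + k)) break;
  }
  return k;
}

// log von Mises density at deviation x from the mean (x already centred)
static inline double log_vm(double x, double kappa) {
  if (kappa <= 0.0) return -std::log(2.0 * M_PI);
  // log I0(k) = log(i0e(k)) + k
  return kappa * std::cos(x) - std::log(2.0 * M_PI) -
         (std::log(i0e(kappa)) + kappa);
}

// BPRW mixture log-likelihood over steps.
// beta:  heading deviation from the biased (up-gradient / toward-wound)
//        direction; NA allowed when has_dir is false.
// alpha: heading deviation from the previous heading.
// b:     per-step bias mean resultant length (effective bias).
// p, w:  persistence MRL and biased-step probability (scalars).
// has_dir: whether a biased direction is defined for the step; if not the
//        step is pure-persistence.
// [[Rcpp::export]]
double cpp_bprw_loglik(NumericVector beta, NumericVector alpha,
                       NumericVector b, double p, double w,
                       LogicalVector has_dir) {
  int n = beta.size();
  double kp = cpp_mrl_to_kappa(p);
  double log_ip = std::log(i0e(kp)) + kp;
  double ll = 0.0;
  // cache kappa for repeated b values (common: constant b per cluster)
  double last_b = -1.0, last_kb = 0.0, last_likb = 0.0;
  for (int i = 0; i < n; ++i) {
    double lp = kp * std::cos(alpha[i]) - std::log(2.0 * M_PI) - log_ip;
    if (!has_dir[i]) { ll += lp; continue; }
    double bi = b[i];
    double kb, likb;
    if (bi == last_b) { kb = last_kb; likb = last_likb; }
    else {
      kb = cpp_mrl_to_kappa(bi);
      likb = std::log(i0e(kb)) + kb;
      last_b = bi; last_kb = kb; last_likb = likb;
    }
    double lb = kb * std::cos(beta[i]) - std::log(2.0 * M_PI) - likb;
    // log( w exp(lb) + (1-w) exp(lp) )
    double m = lb > lp ? lb : lp;
    double mix;
    if (w <= 0.0) mix = lp;
    else if (w >= 1.0) mix = lb;
    else mix = m + std::log(w * std::exp(lb - m) + (1.0 - w) * std::exp(lp - m));
    ll += mix;
  }
  return ll;
}

// per-step log-density version (for WAIC pointwise likelihoods)
// [[Rcpp::export]]
NumericVector cpp_bprw_loglik_pointwise(NumericVector beta, NumericVector alpha,
                                        NumericVector b, double p, double w,
                                        LogicalVector has_dir) {
  int n = beta.size();
  NumericVector out(n);
  double kp = cpp_mrl_to_kappa(p);
  double log_ip = std::log(i0e(kp)) + kp;
  double last_b = -1.0, last_kb = 0.0, last_likb = 0.0;
  for (int i = 0; i < n; ++i) {
    double lp = kp * std::cos(alpha[i]) - std::log(2.0 * M_PI) - log_ip;
    if (!has_dir[i]) { out[i] = lp; continue; }
    double bi = b[i];
    double kb, likb;
    if (bi == last_b) { kb = last_kb; likb = last_likb; }
    else {
      kb = cpp_mrl_to_kappa(bi);
      likb = std::log(i0e(kb)) + kb;
      last_b = bi; last_kb = kb; last_likb = likb;
    }
    double lb = kb * std::cos(beta[i]) - std::log(2.0 * M_PI) - likb;
    double m = lb > lp ? lb : lp;
    if (w <= 0.0) out[i] = lp;
    else if (w >= 1.0) out[i] = lb;
    else out[i] = m + std::log(w * std::exp(lb - m) + (1.0 - w) * std::exp(lp - m));
  }
  return out;
}

// ---- attractant field kernels -----------------------------------------

// instantaneous ring-source kernel at radial distance r, emission age u,
// unit source strength per unit length: total emission rate 2 pi R.
// g(r, u) = R/(2 D u) * exp(-(r-R)^2/(4 D u)) * I0e(r R / (2 D u))
static inline double ring_kernel(double r, double u, double Rw, double D) {
  if (u <= 0.0) return 0.0;
  double du = D * u;
  double z = r * Rw / (2.0 * du);
  double ex = -(r - Rw) * (r - Rw) / (4.0 * du);
  return Rw / (2.0 * du) * std::exp(ex) * i0e(z);
}

// cumulative ring-source integral G(r, s) = int_0^s g(r, u) du on a lattice,
// unit strength; trapezoidal in the (graded) s grid.
// [[Rcpp::export]]
NumericMatrix cpp_ring_G(NumericVector rgrid, NumericVector sgrid,
                         double Rw, double D, double lambda) {
  int nr = rgrid.size(), ns = sgrid.size();
  NumericMatrix G(nr, ns);
  for (int i = 0; i < nr; ++i) {
    double r = rgrid[i];
    double acc = 0.0;
    double gprev = ring_kernel(r, sgrid[0], Rw, D) * std::exp(-lambda * sgrid[0]);
    // from 0 to first node: kernel vanishes at u -> 0 for r != Rw
    acc = 0.5 * sgrid[0] * gprev;
    G(i, 0) = acc;
    for (int j = 1; j < ns; ++j) {
      double g = ring_kernel(r, sgrid[j], Rw, D) * std::exp(-lambda * sgrid[j]);
      acc += 0.5 * (g + gprev) * (sgrid[j] - sgrid[j - 1]);
      G(i, j) = acc;
      gprev = g;
    }
  }
  return G;
}

// disc-source kernel: integral of ring kernels of radius rho over [0, Rw],
// unit strength per unit area; Gauss-Legendre nodes/weights supplied.
// [[Rcpp::export]]
NumericMatrix cpp_disc_G(NumericVector rgrid, NumericVector sgrid,
                         double Rw, double D, double lambda,
                         NumericVector gl_nodes, NumericVector gl_wts) {
  int nr = rgrid.size(), ns = sgrid.size(), nq = gl_nodes.size();
  NumericMatrix G(nr, ns);
  std::vector<double> rho(nq), wq(nq);
  for (int q = 0; q < nq; ++q) { // map [-1,1] -> [0,Rw]
    rho[q] = 0.5 * Rw * (gl_nodes[q] + 1.0);
    wq[q] = 0.5 * Rw * gl_wts[q];
  }
  for (int i = 0; i < nr; ++i) {
    double r = rgrid[i];
    double acc = 0.0, gprev = 0.0;
    {
      // an annulus of width drho has per-unit-length strength q_a * drho,
      // so the ring kernel is reused unchanged with Rw = rho
      double g = 0.0;
      for (int q = 0; q < nq; ++q)
        g += wq[q] * ring_kernel(r, sgrid[0], rho[q], D);
      g *= std::exp(-lambda * sgrid[0]);
      gprev = g;
      acc = 0.5 * sgrid[0] * gprev;
      G(i, 0) = acc;
    }
    for (int j = 1; j < ns; ++j) {
      double g = 0.0;
      for (int q = 0; q < nq; ++q)
        g += wq[q] * ring_kernel(r, sgrid[j], rho[q], D);
      g *= std::exp(-lambda * sgrid[j]);
      acc += 0.5 * (g + gprev) * (sgrid[j] - sgrid[j - 1]);
      G(i, j) = acc;
      gprev = g;
    }
  }
  return G;
}

// bilinear interpolation of a lattice M over (xgrid, ygrid) at points (x, y);
// clamps to the lattice edges.
// [[Rcpp::export]]
NumericVector cpp_bilinear(NumericVector xgrid, NumericVector ygrid,
                           NumericMatrix M, NumericVector x, NumericVector y) {
  int nx = xgrid.size(), ny = ygrid.size(), n = x.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double xv = x[k], yv = y[k];
    if (xv <= xgrid[0]) xv = xgrid[0];
    if (xv >= xgrid[nx - 1]) xv = xgrid[nx - 1];
    if (yv <= ygrid[0]) yv = ygrid[0];
    if (yv >= ygrid[ny - 1]) yv = ygrid[ny - 1];
    int i = std::upper_bound(xgrid.begin(), xgrid.end(), xv) - xgrid.begin() - 1;
    int j = std::upper_bound(ygrid.begin(), ygrid.end(), yv) - ygrid.begin() - 1;
    if (i >= nx - 1) i = nx - 2;
    if (j >= ny - 1) j = ny - 2;
    double tx = (xv - xgrid[i]) / (xgrid[i + 1] - xgrid[i]);
    double ty = (yv - ygrid[j]) / (ygrid[j + 1] - ygrid[j]);
    out[k] = (1 - tx) * (1 - ty) * M(i, j) + tx * (1 - ty) * M(i + 1, j) +
             (1 - tx) * ty * M(i, j + 1) + tx * ty * M(i + 1, j + 1);
  }
  return out;
}

// ---- bounded diffusion (FTCS, masked no-flux) --------------------------

// One chunk of explicit diffusion steps on a masked grid. mask: 1 inside
// domain, 0 outside. Flux only between pairs of interior cells, which makes
// the scheme exactly conservative (zero-flux boundaries). src_idx are
// 0-based linear indices (column-major) receiving src_inc concentration per
// time step while active.
// [[Rcpp::export]]
NumericMatrix cpp_diffuse(NumericMatrix C0, IntegerMatrix mask, double D,
                          double h, double dt, int nsteps,
                          IntegerVector src_idx, NumericVector src_inc,
                          double lambda = 0.0) {
  int nx = C0.nrow(), ny = C0.ncol();
  double lam = D * dt / (h * h);
  if (lam > 0.25)
    Rcpp::stop("unstable time step: D*dt/h^2 = %f > 0.25 (CFL bound)", lam);
  NumericMatrix C = clone(C0);
  NumericMatrix Cn(nx, ny);
  int nsrc = src_idx.size();
  for (int s = 0; s < nsteps; ++s) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        if (!mask(i, j)) { Cn(i, j) = 0.0; continue; }
        double c = C(i, j), acc = 0.0;
        if (i > 0 && mask(i - 1, j)) acc += C(i - 1, j) - c;
        if (i < nx - 1 && mask(i + 1, j)) acc += C(i + 1, j) - c;
        if (j > 0 && mask(i, j - 1)) acc += C(i, j - 1) - c;
        if (j < ny - 1 && mask(i, j + 1)) acc += C(i, j + 1) - c;
        Cn(i, j) = c + lam * acc;
      }
    }
    if (lambda > 0.0) {
      double f = std::exp(-lambda * dt);
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) Cn(i, j) *= f;
    }
    for (int k = 0; k < nsrc; ++k) {
      int idx = src_idx[k];
      Cn[idx] += src_inc[k];
    }
    std::swap(C, Cn);
  }
  return C;
}

// ---- geometry ----------------------------------------------------------

// even-odd ray casting; boundary points count as inside
// [[Rcpp::export]]
LogicalVector cpp_point_in_polygon(NumericVector px, NumericVector py,
                                   NumericVector vx, NumericVector vy) {
  int n = px.size(), m = vx.size();
  LogicalVector out(n);
  for (int k = 0; k < n; ++k) {
    double x = px[k], y = py[k];
    bool inside = false, on_edge = false;
    for (int i = 0, j = m - 1; i < m; j = i++) {
      double xi = vx[i], yi = vy[i], xj = vx[j], yj = vy[j];
      // on-edge check
      double cross = (xj - xi) * (y - yi) - (yj - yi) * (x - xi);
      if (std::fabs(cross) < 1e-9 &&
          x >= std::min(xi, xj) - 1e-9 && x <= std::max(xi, xj) + 1e-9 &&
          y >= std::min(yi, yj) - 1e-9 && y <= std::max(yi, yj) + 1e-9) {
        on_edge = true; break;
      }
      if (((yi > y) != (yj > y)) &&
          (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
        inside = !inside;
    }
    out[k] = inside || on_edge;
  }
  return out;
}

// pairwise contact detection within radius; returns 2-column matrix of
// 1-based index pairs (i < j). Used by the CIL variant of the simulator.
// [[Rcpp::export]]
IntegerMatrix cpp_contacts(NumericVector x, NumericVector y, double radius) {
  int n = x.size();
  std::vector<int> ii, jj;
  double r2 = radius * radius;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx * dx + dy * dy <= r2) { ii.push_back(i + 1); jj.push_back(j + 1); }
    }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) { out(k, 0) = ii[k]; out(k, 1) = jj[k]; }
  return out;
}

// ---- fused gradient-model likelihood ----------------------------------

// One pass over the steps of a dataset: master-cache field lookup in the
// similarity variable v = D*t, receptor-occupancy link, and BPRW mixture
// log-density. r-axis lookups (row index + fraction) are precomputed once
// per fit because step positions never change across proposals; kappa(b)
// and log I0(kappa(b)) come from a lookup table on the bias scale.
static inline double mat_at(const NumericMatrix &M, int i0, double rf,
                            int j0, double vf) {
  return (1 - rf) * (1 - vf) * M(i0, j0) + rf * (1 - vf) * M(i0 + 1, j0) +
         (1 - rf) * vf * M(i0, j0 + 1) + rf * vf * M(i0 + 1, j0 + 1);
}

// [[Rcpp::export]]
NumericVector cpp_gradient_loglik(NumericVector vgrid, NumericMatrix Gv,
                                  NumericMatrix dGdr, IntegerVector ri,
                                  NumericVector rfrac, NumericVector rel_t,
                                  NumericVector beta, NumericVector alpha,
                                  double D, double Tp, double q,
                                  double b0, double p, double w,
                                  double Kd, double lsense, double s,
                                  double bmax,
                                  NumericVector btab_kappa,
                                  NumericVector btab_logi0,
                                  double btab_max, bool pointwise) {
  int n = rel_t.size(), nv = vgrid.size();
  int ntab = btab_kappa.size();
  double v_max = vgrid[nv - 1];
  double kp = cpp_mrl_to_kappa(p);
  double log_ip = std::log(i0e(kp)) + kp;
  double ll = 0.0;
  NumericVector out(pointwise ? n : 1);
  auto vlook = [&](double v, int &j0, double &vf) {
    if (v <= vgrid[0]) { j0 = 0; vf = 0.0; return; }
    if (v >= v_max) { j0 = nv - 2; vf = 1.0; return; }
    int lo = 0, hi = nv - 1;
    while (hi - lo > 1) { int mid = (lo + hi) / 2;
      if (vgrid[mid] <= v) lo = mid; else hi = mid; }
    j0 = lo;
    vf = (v - vgrid[lo]) / (vgrid[lo + 1] - vgrid[lo]);
  };
  for (int i = 0; i < n; ++i) {
    double t = rel_t[i];
    double C = 0.0, g = 0.0;
    if (t > 0.0) {
      int j0; double vf;
      double vc = D * t; if (vc > v_max) vc = v_max;
      vlook(vc, j0, vf);
      double Gc = mat_at(Gv, ri[i], rfrac[i], j0, vf);
      double gc = mat_at(dGdr, ri[i], rfrac[i], j0, vf);
      double tl = t - Tp;
      double Gl = 0.0, gl = 0.0;
      if (tl > 0.0) {
        double vl = D * tl; if (vl > v_max) vl = v_max;
        vlook(vl, j0, vf);
        Gl = mat_at(Gv, ri[i], rfrac[i], j0, vf);
        gl = mat_at(dGdr, ri[i], rfrac[i], j0, vf);
      }
      C = q * (Gc - Gl) / D; if (C < 0.0) C = 0.0;
      g = q * (gc - gl) / D;
    }
    double lp = kp * std::cos(alpha[i]) - std::log(2.0 * M_PI) - log_ip;
    double contrib;
    if (std::fabs(g) <= 1e-12) {
      contrib = lp;             // no defined biased direction
    } else {
      double du = lsense * std::fabs(g) * Kd / ((C + Kd) * (C + Kd));
      double be = b0 + s * du; if (be > bmax) be = bmax;
      // kappa(b) lookup
      double x = be / btab_max * (ntab - 1);
      int k0 = (int)x; if (k0 >= ntab - 1) k0 = ntab - 2;
      double xf = x - k0;
      double kb = (1 - xf) * btab_kappa[k0] + xf * btab_kappa[k0 + 1];
      double likb = (1 - xf) * btab_logi0[k0] + xf * btab_logi0[k0 + 1];
      double bf = g < 0.0 ? beta[i] : beta[i] + M_PI; // up-gradient direction
      double lb = kb * std::cos(bf) - std::log(2.0 * M_PI) - likb;
      double m = lb > lp ? lb : lp;
      if (w <= 0.0) contrib = lp;
      else if (w >= 1.0) contrib = lb;
      else contrib = m + std::log(w * std::exp(lb - m) +
                                  (1.0 - w) * std::exp(lp - m));
    }
    if (pointwise) out[i] = contrib; else ll += contrib;
  }
  if (!pointwise) out[0] = ll;
  return out;
}
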