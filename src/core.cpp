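// Core numerics: spectral Stokes solve for the stream function and
// Peaceman-Rachford ADI stepping of the director angle on a doubly
// periodic unit square.  FFTW3 is used directly with plans cached per
// grid size; all other per-step work is fused into a few passes.
//
// Unit conventions inside this file:
//   * theta is dimensionless (radians), grid spacing dx = 1/n.
//   * psi and its derivatives are in tau_a units (the units of the
//     dimensionless Stokes balance).  Callers rescale to tau_r.
//   * dt and nsteps advance the tau_r-rescaled director equation
//     d theta/dt = A * (advection - lap(psi)/2) + lap(theta),
//     i.e. the elastic diffusion coefficient is exactly 1.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <fftw3.h>
#include <map>
#include <vector>
#include <cmath>

using namespace arma;

namespace {

struct Workspace {
  int n;
  size_t N;
  std::vector<double> f_s2, f_c2;   // active-stress factors (mask/N folded in)
  std::vector<double> maskN;        // dealias mask / N (for the theta term)
  std::vector<double> k2;           // |k|^2
  std::vector<double> g1re, g1im;   // gradient-pack factor (-ky + i kx)
  std::vector<size_t> revlin;       // linear index of -k
  fftw_complex *c1, *c2, *c3;
  fftw_plan pf, pb;

  explicit Workspace(int n_) : n(n_), N(size_t(n_) * size_t(n_)) {
    std::vector<double> f(n);
    for (int i = 0; i < n; ++i) f[i] = (i <= n / 2) ? i : i - n;
    const double twopi = 2.0 * M_PI;
    const double lim = n / 3.0;
    f_s2.resize(N); f_c2.resize(N); maskN.resize(N);
    k2.resize(N); g1re.resize(N); g1im.resize(N); revlin.resize(N);
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < n; ++i) {
        size_t idx = size_t(i) + size_t(n) * j;
        double kx = twopi * f[i], ky = twopi * f[j];
        double kk = kx * kx + ky * ky;
        double k4 = kk * kk;
        bool keep = std::abs(f[i]) < lim && std::abs(f[j]) < lim && kk > 0.0;
        double m = keep ? 1.0 / double(N) : 0.0;
        k2[idx] = kk;
        maskN[idx] = m;
        f_s2[idx] = keep ? m * 0.5 * (kx * kx - ky * ky) / k4 : 0.0;
        f_c2[idx] = keep ? -m * kx * ky / k4 : 0.0;
        g1re[idx] = -ky;
        g1im[idx] = kx;
        int ri = (n - i) % n, rj = (n - j) % n;
        revlin[idx] = size_t(ri) + size_t(n) * rj;
      }
    }
    c1 = fftw_alloc_complex(N);
    c2 = fftw_alloc_complex(N);
    c3 = fftw_alloc_complex(N);
    // FFTW_ESTIMATE keeps plan selection deterministic across processes.
    pf = fftw_plan_dft_2d(n, n, c1, c2, FFTW_FORWARD, FFTW_ESTIMATE);
    pb = fftw_plan_dft_2d(n, n, c1, c2, FFTW_BACKWARD, FFTW_ESTIMATE);
  }
  ~Workspace() {
    fftw_destroy_plan(pf); fftw_destroy_plan(pb);
    fftw_free(c1); fftw_free(c2); fftw_free(c3);
  }

  // Solve Stokes for the current theta.  On return:
  //   c2 holds (psi_x, psi_y) interleaved, c1 holds (lap psi, psi).
  void stokes(const double* theta, double A, double R, double S,
              bool flow_on) {
    if (!flow_on) {
      std::fill(&c1[0][0], &c1[0][0] + 2 * N, 0.0);
      std::fill(&c2[0][0], &c2[0][0] + 2 * N, 0.0);
      return;
    }
    for (size_t q = 0; q < N; ++q) {
      double s, c;
      sincos(2.0 * theta[q], &s, &c);
      c1[q][0] = s; c1[q][1] = c;
    }
    fftw_execute_dft(pf, c1, c2);                 // Z = fft(sin2t + i cos2t)
    for (size_t q = 0; q < N; ++q) { c1[q][0] = theta[q]; c1[q][1] = 0.0; }
    fftw_execute_dft(pf, c1, c3);                 // T = fft(theta)
    const double cth = -R / (2.0 * A);
    for (size_t q = 0; q < N; ++q) {
      size_t r = revlin[q];
      double zr = c2[q][0], zi = c2[q][1];
      double wr = c2[r][0], wi = c2[r][1];
      // Hermitian unpack: S2h = (Z + conj(Zrev))/2, C2h = -i(Z - conj(Zrev))/2
      double s2r = 0.5 * (zr + wr), s2i = 0.5 * (zi - wi);
      double c2r = 0.5 * (zi + wi), c2i = -0.5 * (zr - wr);
      double m = maskN[q];
      double pr = cth * m * c3[q][0] + S * (f_s2[q] * s2r + f_c2[q] * c2r);
      double pi = cth * m * c3[q][1] + S * (f_s2[q] * s2i + f_c2[q] * c2i);
      // gradient pack: (i kx - ky) * psi_hat  ->  ifft = psi_x + i psi_y
      c1[q][0] = g1re[q] * pr - g1im[q] * pi;
      c1[q][1] = g1re[q] * pi + g1im[q] * pr;
      // laplacian + psi pack: (-k2 + i) * psi_hat -> ifft = lap psi + i psi
      c3[q][0] = -k2[q] * pr - pi;
      c3[q][1] = -k2[q] * pi + pr;
    }
    fftw_execute_dft(pb, c1, c2);                 // c2: (psi_x, psi_y)
    std::copy(&c3[0][0], &c3[0][0] + 2 * N, &c1[0][0]);
    fftw_execute_dft(pb, c1, c3);
    std::copy(&c3[0][0], &c3[0][0] + 2 * N, &c1[0][0]); // c1: (lap psi, psi)
  }
};

std::map<int, Workspace*>& ws_cache() {
  static std::map<int, Workspace*> cache;
  return cache;
}

Workspace& get_ws(int n) {
  auto& cache = ws_cache();
  auto it = cache.find(n);
  if (it == cache.end()) {
    Workspace* w = new Workspace(n);
    cache[n] = w;
    return *w;
  }
  return *it->second;
}

// Cyclic (periodic) tridiagonal solver for (I - r D2) x = b with constant
// coefficients, via Thomas elimination plus a Sherman-Morrison correction.
struct CyclicTri {
  int n; double r, gamma, vzfac;
  std::vector<double> cp, denom, z;
  CyclicTri(int n_, double r_) : n(n_), r(r_) {
    double a = -r, b = 1.0 + 2.0 * r, c = -r;
    gamma = -b;
    std::vector<double> diag(n, b);
    diag[0] = b - gamma;
    diag[n - 1] = b - a * c / gamma;
    cp.assign(n, 0.0); denom.assign(n, 0.0);
    denom[0] = diag[0];
    cp[0] = c / denom[0];
    for (int i = 1; i < n; ++i) {
      denom[i] = diag[i] - a * cp[i - 1];
      cp[i] = c / denom[i];
    }
    std::vector<double> u(n, 0.0);
    u[0] = gamma; u[n - 1] = a;
    z = u;
    z[0] = u[0] / denom[0];
    for (int i = 1; i < n; ++i) z[i] = (u[i] - a * z[i - 1]) / denom[i];
    for (int i = n - 2; i >= 0; --i) z[i] -= cp[i] * z[i + 1];
    vzfac = 1.0 + z[0] + (c / gamma) * z[n - 1];
  }
  // solve nsys systems; element stride es within a system, system stride ss
  void solve(double* base, long es, long ss, int nsys) const {
    double a = -r, c = -r;
    for (int s = 0; s < nsys; ++s) {
      double* x = base + long(s) * ss;
      x[0] /= denom[0];
      for (int i = 1; i < n; ++i)
        x[i * es] = (x[i * es] - a * x[(i - 1) * es]) / denom[i];
      for (int i = n - 2; i >= 0; --i)
        x[i * es] -= cp[i] * x[(i + 1) * es];
      double vy = x[0] + (c / gamma) * x[(n - 1) * es];
      double fac = vy / vzfac;
      for (int i = 0; i < n; ++i) x[i * es] -= fac * z[i];
    }
  }
};

} // namespace

// One Peaceman-Rachford ADI macro-step driver, with optional MSV sampling.
// Returns theta', plus per-chunk max |v| (tau_a units) and sampled MSV
// components (tau_a units) at the *start* of the sampled steps.
// [[Rcpp::export]]
Rcpp::List cpp_evolve(arma::mat theta, double A, double R, double S,
                      double dt, int nsteps, int sample_every = 0,
                      bool flow_on = true, int check_every = 200) {
  const int n = theta.n_rows;
  if ((int)theta.n_cols != n) Rcpp::stop("theta must be square");
  const double dx = 1.0 / n;
  const double dt2 = dt / 2.0;
  const double idx2 = 1.0 / (dx * dx);
  const double i2dx = 1.0 / (2.0 * dx);
  Workspace& ws = get_ws(n);
  CyclicTri tri(n, dt2 * idx2);
  mat work1(n, n), work2(n, n);
  double maxv = 0.0;
  bool finite = true;
  int done = 0;
  std::vector<int> s_steps;
  std::vector<double> s_msvx, s_msvy;

  for (int s = 0; s < nsteps; ++s) {
    ws.stokes(theta.memptr(), A, R, S, flow_on);
    const bool sample = sample_every > 0 && (s % sample_every == 0);
    double sumx = 0.0, sumy = 0.0, mv = 0.0;
    // first half-step rhs: theta + dt2 * (Dyy theta + N(theta))
    for (int j = 0; j < n; ++j) {
      int jp = (j + 1 == n) ? 0 : j + 1;
      int jm = (j == 0) ? n - 1 : j - 1;
      const double* th = theta.colptr(j);
      const double* thp = theta.colptr(jp);
      const double* thm = theta.colptr(jm);
      double* out = work1.colptr(j);
      const fftw_complex* g = ws.c2 + size_t(n) * j;
      const fftw_complex* l = ws.c1 + size_t(n) * j;
      for (int i = 0; i < n; ++i) {
        int ip = (i + 1 == n) ? 0 : i + 1;
        int im = (i == 0) ? n - 1 : i - 1;
        double px = g[i][0], py = g[i][1], lp = l[i][0];
        double ax = std::max(std::abs(px), std::abs(py));
        if (ax > mv) mv = ax;
        if (sample) { sumx += py * py; sumy += px * px; }
        double dxth = (th[ip] - th[im]) * i2dx;
        double dyth = (thp[i] - thm[i]) * i2dx;
        double adv = A * (-py * dxth + px * dyth - 0.5 * lp);
        double dyy = (thp[i] - 2.0 * th[i] + thm[i]) * idx2;
        out[i] = th[i] + dt2 * (dyy + adv);
      }
    }
    if (mv > maxv) maxv = mv;
    if (sample) {
      s_steps.push_back(s);
      s_msvx.push_back(sumx / double(ws.N));
      s_msvy.push_back(sumy / double(ws.N));
    }
    // implicit in x: systems are contiguous columns
    tri.solve(work1.memptr(), 1, n, n);
    // second half-step rhs: theta* + dt2 * (Dxx theta* + N(theta*))
    for (int j = 0; j < n; ++j) {
      int jp = (j + 1 == n) ? 0 : j + 1;
      int jm = (j == 0) ? n - 1 : j - 1;
      const double* th = work1.colptr(j);
      const double* thp = work1.colptr(jp);
      const double* thm = work1.colptr(jm);
      double* out = work2.colptr(j);
      const fftw_complex* g = ws.c2 + size_t(n) * j;
      const fftw_complex* l = ws.c1 + size_t(n) * j;
      for (int i = 0; i < n; ++i) {
        int ip = (i + 1 == n) ? 0 : i + 1;
        int im = (i == 0) ? n - 1 : i - 1;
        double px = g[i][0], py = g[i][1], lp = l[i][0];
        double dxth = (th[ip] - th[im]) * i2dx;
        double dyth = (thp[i] - thm[i]) * i2dx;
        double adv = A * (-py * dxth + px * dyth - 0.5 * lp);
        double dxx = (th[ip] - 2.0 * th[i] + th[im]) * idx2;
        out[i] = th[i] + dt2 * (dxx + adv);
      }
    }
    // implicit in y: element stride n, system stride 1
    tri.solve(work2.memptr(), n, 1, n);
    theta = work2;
    ++done;
    if ((s + 1) % check_every == 0 || s + 1 == nsteps) {
      if (!theta.is_finite()) { finite = false; break; }
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("theta") = theta,
      Rcpp::Named("maxv") = maxv,
      Rcpp::Named("finite") = finite,
      Rcpp::Named("steps_done") = done,
      Rcpp::Named("sample_steps") = s_steps,
      Rcpp::Named("msv_x") = s_msvx,
      Rcpp::Named("msv_y") = s_msvy);
}

// Stream function and derived flow fields for a given theta (tau_a units).
// [[Rcpp::export]]
Rcpp::List cpp_stream(const arma::mat& theta, double A, double R, double S) {
  const int n = theta.n_rows;
  if ((int)theta.n_cols != n) Rcpp::stop("theta must be square");
  Workspace& ws = get_ws(n);
  ws.stokes(theta.memptr(), A, R, S, true);
  mat psi(n, n), vx(n, n), vy(n, n), omega(n, n);
  for (int j = 0; j < n; ++j) {
    const fftw_complex* g = ws.c2 + size_t(n) * j;
    const fftw_complex* l = ws.c1 + size_t(n) * j;
    for (int i = 0; i < n; ++i) {
      vx(i, j) = g[i][1];        // psi_y
      vy(i, j) = -g[i][0];       // -psi_x
      omega(i, j) = -l[i][0];    // -lap psi
      psi(i, j) = l[i][1];
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("psi") = psi, Rcpp::Named("vx") = vx,
      Rcpp::Named("vy") = vy, Rcpp::Named("omega") = omega);
}
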