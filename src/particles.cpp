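#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Brownian dynamics of point tracers among reflecting rasterized obstacles.
// Geometry convention matches the R side: mask element (ix, iy) is the cell
// whose centre sits at (ox + ix*dx, oy + iy*dx), 0-based.

struct MaskGeom {
  const int* m;   // nullptr = no obstacles
  int nx, ny;
  double ox, oy, dx;
  bool blocked(double px, double py) const {
    if (m == nullptr) return false;
    const int ix = (int)std::floor((px - ox) / dx + 0.5);
    const int iy = (int)std::floor((py - oy) / dx + 0.5);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) return false;
    return m[ix + (size_t)nx * iy] != 0;
  }
  // x-coordinate of the face of the cell containing px that is crossed when
  // arriving with sign s (+1 moving in +x)
  double xface(double px, int s) const {
    const int ix = (int)std::floor((px - ox) / dx + 0.5);
    return ox + (ix - 0.5 * s) * dx;
  }
  double yface(double py, int s) const {
    const int iy = (int)std::floor((py - oy) / dx + 0.5);
    return oy + (iy - 0.5 * s) * dx;
  }
};

// One Gaussian displacement with specular reflection handled per axis
// against obstacle cell faces and the outer box walls. Returns false when a
// move had to be rejected in place (blocked after reflection, e.g. corners).
static inline bool move_particle(double& x, double& y, const MaskGeom& g,
                                 double sd,
                                 double xmin, double xmax,
                                 double ymin, double ymax) {
  const double x0 = x, y0 = y;
  double nxp = x + sd * norm_rand();
  if (nxp < xmin) nxp = 2 * xmin - nxp;
  if (nxp > xmax) nxp = 2 * xmax - nxp;
  if (g.blocked(nxp, y)) {
    const int s = nxp > x ? 1 : -1;
    nxp = 2 * g.xface(nxp, s) - nxp;
    if (g.blocked(nxp, y)) nxp = x;
  }
  x = nxp;
  double nyp = y + sd * norm_rand();
  if (nyp < ymin) nyp = 2 * ymin - nyp;
  if (nyp > ymax) nyp = 2 * ymax - nyp;
  if (g.blocked(x, nyp)) {
    const int s = nyp > y ? 1 : -1;
    nyp = 2 * g.yface(nyp, s) - nyp;
    if (g.blocked(x, nyp)) nyp = y;
  }
  y = nyp;
  return !(x == x0 && nxp == x0 && y == y0 && nyp == y0);
}

static MaskGeom make_geom(Nullable<IntegerMatrix>& mask_, IntegerMatrix& keep,
                          double ox, double oy, double dx) {
  MaskGeom g{nullptr, 0, 0, ox, oy, dx};
  if (mask_.isNotNull()) {
    keep = mask_.get();
    g.m = INTEGER(keep);
    g.nx = keep.nrow();
    g.ny = keep.ncol();
  }
  return g;
}

// [[Rcpp::export]]
List cpp_brownian_evolve(NumericVector x, NumericVector y,
                         Nullable<IntegerMatrix> mask_,
                         double ox, double oy, double dx,
                         double xmin, double xmax, double ymin, double ymax,
                         double D, double dt, int nsteps) {
  IntegerMatrix keep;
  MaskGeom g = make_geom(mask_, keep, ox, oy, dx);
  const double sd = std::sqrt(2.0 * D * dt);
  NumericVector xo = clone(x), yo = clone(y);
  const int n = xo.size();
  long long nreject = 0;
  for (int s = 0; s < nsteps; ++s) {
    for (int i = 0; i < n; ++i)
      if (!move_particle(xo[i], yo[i], g, sd, xmin, xmax, ymin, ymax))
        ++nreject;
    if (s % 256 == 0) checkUserInterrupt();
  }
  return List::create(_["x"] = xo, _["y"] = yo,
                      _["n_reject"] = (double)nreject);
}

// Binned FCS intensity trace: particles evolve `substeps` Brownian steps per
// sample; each sample is the summed 2D Gaussian detection weight
// exp(-2 r^2 / w^2) around the beam centre.
// [[Rcpp::export]]
List cpp_fcs_trace(NumericVector x, NumericVector y,
                   Nullable<IntegerMatrix> mask_,
                   double ox, double oy, double dx,
                   double xmin, double xmax, double ymin, double ymax,
                   double D, double dt, int nsamples, int substeps,
                   double cx, double cy, double w) {
  IntegerMatrix keep;
  MaskGeom g = make_geom(mask_, keep, ox, oy, dx);
  const double sd = std::sqrt(2.0 * D * dt);
  const double inv = 2.0 / (w * w);
  NumericVector xo = clone(x), yo = clone(y);
  const int n = xo.size();
  NumericVector I(nsamples);
  long long nreject = 0;
  for (int s = 0; s < nsamples; ++s) {
    for (int k = 0; k < substeps; ++k)
      for (int i = 0; i < n; ++i)
        if (!move_particle(xo[i], yo[i], g, sd, xmin, xmax, ymin, ymax))
          ++nreject;
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      const double rx = xo[i] - cx, ry = yo[i] - cy;
      const double r2 = rx * rx + ry * ry;
      if (r2 * inv < 40.0) acc += std::exp(-r2 * inv);
    }
    I[s] = acc;
    if (s % 256 == 0) checkUserInterrupt();
  }
  return List::create(_["intensity"] = I, _["x"] = xo, _["y"] = yo,
                      _["n_reject"] = (double)nreject);
}

// Fraction of particles inside a disk (cx, cy, r) recorded at the given
// step counts (sorted; 0 records the initial state). Oracle for the PDE
// FRAP recovery curve.
// [[Rcpp::export]]
List cpp_occupancy(NumericVector x, NumericVector y,
                   Nullable<IntegerMatrix> mask_,
                   double ox, double oy, double dx,
                   double xmin, double xmax, double ymin, double ymax,
                   double D, double dt, IntegerVector record_steps,
                   double cx, double cy, double r) {
  IntegerMatrix keep;
  MaskGeom g = make_geom(mask_, keep, ox, oy, dx);
  const double sd = std::sqrt(2.0 * D * dt);
  const double r2 = r * r;
  NumericVector xo = clone(x), yo = clone(y);
  const int n = xo.size();
  const int nrec = record_steps.size();
  NumericVector frac(nrec);
  int rec = 0;
  const int nsteps = nrec > 0 ? record_steps[nrec - 1] : 0;
  for (int s = 0; s <= nsteps; ++s) {
    if (s > 0)
      for (int i = 0; i < n; ++i)
        move_particle(xo[i], yo[i], g, sd, xmin, xmax, ymin, ymax);
    while (rec < nrec && record_steps[rec] == s) {
      int cnt = 0;
      for (int i = 0; i < n; ++i) {
        const double rx = xo[i] - cx, ry = yo[i] - cy;
        if (rx * rx + ry * ry <= r2) ++cnt;
      }
      frac[rec] = (double)cnt / n;
      ++rec;
    }
    if (s % 256 == 0) checkUserInterrupt();
  }
  return List::create(_["fraction"] = frac, _["x"] = xo, _["y"] = yo);
}

// First-passage (narrow-escape) sampler on the analytic disk of radius R:
// reflecting circle except n_arcs absorbing arcs of total angular fraction
// sigma, centred at angles 2*pi*k/n_arcs. Steps are Gaussian; a step ending
// outside the disk is traced to its boundary crossing, absorbed if the
// crossing angle lies in an arc, otherwise specularly reflected off the
// local tangent.
// [[Rcpp::export]]
List cpp_escape_times(NumericVector x0, NumericVector y0,
                      double R, double D, double dt,
                      double sigma, int n_arcs, double max_time) {
  const int n = x0.size();
  const double sd = std::sqrt(2.0 * D * dt);
  const double half = M_PI * sigma / n_arcs;   // arc half-angle
  const double spacing = 2.0 * M_PI / n_arcs;
  const long long max_steps = (long long)std::ceil(max_time / dt);
  NumericVector times(n);
  LogicalVector censored(n);
  for (int i = 0; i < n; ++i) {
    double x = x0[i], y = y0[i];
    bool done = false;
    for (long long s = 1; s <= max_steps && !done; ++s) {
      const double px = x, py = y;
      x += sd * norm_rand();
      y += sd * norm_rand();
      double r2 = x * x + y * y;
      int guard = 0;
      while (r2 > R * R && guard++ < 8) {
        // segment-circle crossing: |p + t d| = R, t in (0, 1]
        const double dxs = x - px, dys = y - py;
        const double a = dxs * dxs + dys * dys;
        const double b = 2.0 * (px * dxs + py * dys);
        const double cc = px * px + py * py - R * R;
        double t = 1.0;
        const double disc = b * b - 4.0 * a * cc;
        if (a > 0 && disc >= 0) t = (-b + std::sqrt(disc)) / (2.0 * a);
        if (t < 0) t = 0; else if (t > 1) t = 1;
        const double qx = px + t * dxs, qy = py + t * dys;
        const double th = std::atan2(qy, qx);
        const double dth = std::remainder(th, spacing);
        if (std::fabs(dth) <= half) {           // crossed an escape channel
          times[i] = (s - 1 + t) * dt;
          done = true;
          break;
        }
        // reflect the overshoot across the tangent at the crossing point
        const double nxn = qx / R, nyn = qy / R;
        const double vx = x - qx, vy = y - qy;
        const double dot = vx * nxn + vy * nyn;
        x = qx + vx - 2.0 * dot * nxn;
        y = qy + vy - 2.0 * dot * nyn;
        r2 = x * x + y * y;
      }
      if (!done && r2 > R * R) {                // grazing pathologies: clamp
        const double rr = std::sqrt(r2);
        x *= (R * (1.0 - 1e-12)) / rr;
        y *= (R * (1.0 - 1e-12)) / rr;
      }
    }
    if (!done) {
      times[i] = max_time;
      censored[i] = true;
    }
    if (i % 16 == 0) checkUserInterrupt();
  }
  return List::create(_["time"] = times, _["censored"] = censored);
}
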