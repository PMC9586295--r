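#include <Rcpp.h>
using namespace Rcpp;

// wrap an angle into (-pi, pi]
static inline double wrap_ang(double a) {
  return a - 2.0 * M_PI * std::ceil((a - M_PI) / (2.0 * M_PI));
}

// Bilinear interpolation of a coefficient grid sampled at bin centres.
// Position axis: clamped at the first/last centre (constant extrapolation
// into the half-bin next to each wall). Heading axis: periodic.
struct GridInterp {
  const double *v;        // n_pos x n_ang, column-major
  int n_pos, n_ang;
  double p0, dp;          // first position centre, spacing
  double a0, da;          // first heading centre, spacing
  bool constant;
  double cval;

  double at(double y, double phi) const {
    if (constant) return cval;
    double u = (y - p0) / dp;
    if (u < 0.0) u = 0.0;
    if (u > n_pos - 1.0) u = n_pos - 1.0;
    int i = (int)std::floor(u);
    if (i > n_pos - 2) i = n_pos - 2;
    double fu = u - i;
    if (n_pos == 1) { i = 0; fu = 0.0; }

    double w = (phi - a0) / da;
    double period = (double)n_ang;
    w = w - period * std::floor(w / period);   // in [0, n_ang)
    int j = (int)std::floor(w);
    double fw = w - j;
    int j1 = (j + 1) % n_ang;
    if (n_ang == 1) { j = 0; j1 = 0; fw = 0.0; }

    int i1 = (n_pos == 1) ? 0 : i + 1;
    double v00 = v[j * n_pos + i];
    double v10 = v[j * n_pos + i1];
    double v01 = v[j1 * n_pos + i];
    double v11 = v[j1 * n_pos + i1];
    return (1 - fu) * (1 - fw) * v00 + fu * (1 - fw) * v10 +
           (1 - fu) * fw * v01 + fu * fw * v11;
  }
};

static GridInterp make_interp(const NumericMatrix &m, const NumericVector &pos,
                              const NumericVector &ang, bool constant,
                              double cval) {
  GridInterp g;
  g.v = constant ? nullptr : &m[0];
  g.n_pos = m.nrow();
  g.n_ang = m.ncol();
  g.p0 = pos.size() ? pos[0] : 0.0;
  g.dp = pos.size() > 1 ? pos[1] - pos[0] : 1.0;
  g.a0 = ang.size() ? ang[0] : 0.0;
  g.da = ang.size() > 1 ? ang[1] - ang[0] : 1.0;
  g.constant = constant;
  g.cval = cval;
  return g;
}

// Euler-Maruyama integration of the wall-bounded planar Langevin model
//   dy   = -Vs(y,phi) sin(phi) dt
//   dphi = [omega_w(y,phi) + omega_g(phi)] dt + sqrt(2 Dr(y,phi) dt) dW
// with specular reflection at y = 0 and y = W (position mirrored, heading
// sign-flipped) and heading wrapped into (-pi, pi]. Coefficients are
// evaluated at the pre-step state (Ito). Uses R's RNG.
//
// After burn_steps, every accum_every-th step the walker states are
// histogrammed on an n_pos x n_ang grid.
// [[Rcpp::export]]
List sim_channel_cpp(NumericVector y0, NumericVector phi0,
                     double W, double dt, int n_steps, int burn_steps,
                     int accum_every,
                     NumericMatrix vs_grid, bool vs_const, double vs_val,
                     NumericMatrix om_grid, bool om_const, double om_val,
                     NumericMatrix dr_grid, bool dr_const, double dr_val,
                     NumericVector grid_pos, NumericVector grid_ang,
                     bool gyro, double B,
                     int n_pos, int n_ang,
                     int dump_n, int dump_every) {
  int n = y0.size();
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> x(n, 0.0);

  GridInterp Vs = make_interp(vs_grid, grid_pos, grid_ang, vs_const, vs_val);
  GridInterp Om = make_interp(om_grid, grid_pos, grid_ang, om_const, om_val);
  GridInterp Dr = make_interp(dr_grid, grid_pos, grid_ang, dr_const, dr_val);

  IntegerMatrix counts(n_pos, n_ang);
  double pos_w = W / n_pos;
  double ang_w = 2.0 * M_PI / n_ang;

  int n_dump_frames = dump_n > 0 ? n_steps / dump_every + 1 : 0;
  NumericMatrix dump_y(n_dump_frames, dump_n > 0 ? dump_n : 1);
  NumericMatrix dump_x(n_dump_frames, dump_n > 0 ? dump_n : 1);
  NumericMatrix dump_phi(n_dump_frames, dump_n > 0 ? dump_n : 1);
  int dump_row = 0;
  if (dump_n > 0) {
    for (int j = 0; j < dump_n; ++j) {
      dump_y(0, j) = y[j]; dump_x(0, j) = x[j]; dump_phi(0, j) = phi[j];
    }
    dump_row = 1;
  }

  RNGScope scope;
  double inv2B = gyro ? 1.0 / (2.0 * B) : 0.0;

  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n; ++i) {
      double yi = y[i], pi_ = phi[i];
      double vs = Vs.at(yi, pi_);
      double om = Om.at(yi, pi_);
      if (gyro) om += -std::cos(pi_) * inv2B;
      double dr = Dr.at(yi, pi_);
      double ny = yi - vs * std::sin(pi_) * dt;
      double nx = x[i] + vs * std::cos(pi_) * dt;
      double nphi = pi_ + om * dt + std::sqrt(2.0 * dr * dt) * norm_rand();
      if (ny < 0.0) {
        if (-ny > W) stop("sim_channel_cpp: walker overshot beyond one reflection; reduce the time step");
        ny = -ny; nphi = -nphi;
      } else if (ny > W) {
        if (ny - W > W) stop("sim_channel_cpp: walker overshot beyond one reflection; reduce the time step");
        ny = 2.0 * W - ny; nphi = -nphi;
      }
      y[i] = ny; x[i] = nx; phi[i] = wrap_ang(nphi);
    }
    if (s > burn_steps && (s - burn_steps) % accum_every == 0) {
      for (int i = 0; i < n; ++i) {
        int pb = (int)(y[i] / pos_w);
        if (pb >= n_pos) pb = n_pos - 1;
        if (pb < 0) pb = 0;
        int ab = (int)((phi[i] + M_PI) / ang_w);
        if (ab >= n_ang) ab = n_ang - 1;
        if (ab < 0) ab = 0;
        counts(pb, ab)++;
      }
    }
    if (dump_n > 0 && s % dump_every == 0) {
      for (int j = 0; j < dump_n; ++j) {
        dump_y(dump_row, j) = y[j];
        dump_x(dump_row, j) = x[j];
        dump_phi(dump_row, j) = phi[j];
      }
      ++dump_row;
    }
  }

  List out = List::create(
    Named("counts") = counts,
    Named("y") = NumericVector(y.begin(), y.end()),
    Named("phi") = NumericVector(phi.begin(), phi.end()));
  if (dump_n > 0) {
    out["dump_y"] = dump_y;
    out["dump_x"] = dump_x;
    out["dump_phi"] = dump_phi;
  }
  return out;
}

// Free-space (unbounded) integration of the gyrotactic orientation/position
// process: dz = -Vs sin(theta) dt, dtheta = -cos(theta)/(2B) dt (optional)
// + sqrt(2 Dr dt) dW. No walls; z grows without bound. Snapshots of all
// walker positions are recorded every snap_every steps (none if 0).
// [[Rcpp::export]]
List sim_free_cpp(NumericVector z0, NumericVector theta0,
                  double Vs, double Dr, bool gyro, double B,
                  double dt, int n_steps, int snap_every) {
  int n = z0.size();
  std::vector<double> z(z0.begin(), z0.end());
  std::vector<double> th(theta0.begin(), theta0.end());
  int n_snap = snap_every > 0 ? n_steps / snap_every : 0;
  NumericMatrix snaps(n_snap > 0 ? n : 1, n_snap > 0 ? n_snap : 1);
  NumericVector snap_t(n_snap > 0 ? n_snap : 0);
  int col = 0;

  RNGScope scope;
  double inv2B = gyro ? 1.0 / (2.0 * B) : 0.0;
  double noise = std::sqrt(2.0 * Dr * dt);

  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n; ++i) {
      double ti = th[i];
      z[i] += -Vs * std::sin(ti) * dt;
      double nt = ti + (gyro ? -std::cos(ti) * inv2B * dt : 0.0) +
                  noise * norm_rand();
      th[i] = wrap_ang(nt);
    }
    if (snap_every > 0 && s % snap_every == 0 && col < n_snap) {
      for (int i = 0; i < n; ++i) snaps(i, col) = z[i];
      snap_t[col] = s * dt;
      ++col;
    }
  }

  List out = List::create(
    Named("z") = NumericVector(z.begin(), z.end()),
    Named("theta") = NumericVector(th.begin(), th.end()));
  if (n_snap > 0) {
    out["snapshots"] = snaps;
    out["snapshot_times"] = snap_t;
  }
  return out;
}
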