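#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Grids are nx x ny matrices in column-major order, values[i + j*nx],
// i indexing x (arena width), j indexing y (arena height).  Pixel centres
// sit at ((i + 0.5) * dx, (j + 0.5) * dy) in arena cm.

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// continuous pixel coordinate for arena position x (0-based index space)
static inline double pixcoord(double x, double d, int n) {
  return clampd(x / d - 0.5, 0.0, (double)(n - 1));
}

static double bilin_raw(const double* V, int nx, int ny,
                        double x, double y, double dx, double dy) {
  double u = pixcoord(x, dx, nx);
  double v = pixcoord(y, dy, ny);
  int i0 = (int)std::floor(u); if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
  int j0 = (int)std::floor(v); if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
  double fx = clampd(u - i0, 0.0, 1.0), fy = clampd(v - j0, 0.0, 1.0);
  if (nx == 1) { i0 = 0; fx = 0.0; }
  if (ny == 1) { j0 = 0; fy = 0.0; }
  int i1 = nx == 1 ? 0 : i0 + 1, j1 = ny == 1 ? 0 : j0 + 1;
  double v00 = V[i0 + j0 * nx], v10 = V[i1 + j0 * nx];
  double v01 = V[i0 + j1 * nx], v11 = V[i1 + j1 * nx];
  return (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
         (1 - fx) * fy * v01 + fx * fy * v11;
}

// central differences in the interior, one-sided on the outermost pixels
static inline double gx_at(const double* V, int nx, int ny, int i, int j, double dx) {
  if (nx == 1) return 0.0;
  if (i == 0)      return (V[1 + j * nx] - V[0 + j * nx]) / dx;
  if (i == nx - 1) return (V[i + j * nx] - V[i - 1 + j * nx]) / dx;
  return (V[i + 1 + j * nx] - V[i - 1 + j * nx]) / (2.0 * dx);
}
static inline double gy_at(const double* V, int nx, int ny, int i, int j, double dy) {
  if (ny == 1) return 0.0;
  if (j == 0)      return (V[i + nx] - V[i]) / dy;
  if (j == ny - 1) return (V[i + j * nx] - V[i + (j - 1) * nx]) / dy;
  return (V[i + (j + 1) * nx] - V[i + (j - 1) * nx]) / (2.0 * dy);
}

static void grad_raw(const double* V, int nx, int ny,
                     double x, double y, double dx, double dy,
                     double* gx, double* gy) {
  double u = pixcoord(x, dx, nx);
  double v = pixcoord(y, dy, ny);
  int i0 = (int)std::floor(u); if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
  int j0 = (int)std::floor(v); if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
  double fx = clampd(u - i0, 0.0, 1.0), fy = clampd(v - j0, 0.0, 1.0);
  if (nx == 1) { i0 = 0; fx = 0.0; }
  if (ny == 1) { j0 = 0; fy = 0.0; }
  int i1 = nx == 1 ? 0 : i0 + 1, j1 = ny == 1 ? 0 : j0 + 1;
  double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
  double w01 = (1 - fx) * fy,       w11 = fx * fy;
  *gx = w00 * gx_at(V, nx, ny, i0, j0, dx) + w10 * gx_at(V, nx, ny, i1, j0, dx) +
        w01 * gx_at(V, nx, ny, i0, j1, dx) + w11 * gx_at(V, nx, ny, i1, j1, dx);
  *gy = w00 * gy_at(V, nx, ny, i0, j0, dy) + w10 * gy_at(V, nx, ny, i1, j0, dy) +
        w01 * gy_at(V, nx, ny, i0, j1, dy) + w11 * gy_at(V, nx, ny, i1, j1, dy);
}

// [[Rcpp::export]]
NumericVector cpp_bilinear(NumericMatrix values, NumericMatrix xy,
                           double dx, double dy) {
  int n = xy.nrow(), nx = values.nrow(), ny = values.ncol();
  NumericVector out(n);
  for (int k = 0; k < n; ++k)
    out[k] = bilin_raw(values.begin(), nx, ny, xy(k, 0), xy(k, 1), dx, dy);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gradient(NumericMatrix values, NumericMatrix xy,
                           double dx, double dy) {
  int n = xy.nrow(), nx = values.nrow(), ny = values.ncol();
  NumericMatrix out(n, 2);
  for (int k = 0; k < n; ++k) {
    double gx, gy;
    grad_raw(values.begin(), nx, ny, xy(k, 0), xy(k, 1), dx, dy, &gx, &gy);
    out(k, 0) = gx; out(k, 1) = gy;
  }
  return out;
}

// Zonal (repulsion / orientation / attraction) desired direction with a
// rear blind zone.  Positions in cm; zone radii already converted to cm.
// Writes the (possibly zero) direction into (ox, oy).
static void social_dir_raw(double px, double py, double hx, double hy,
                           const double* npos, const double* nhead, int nn,
                           double rr, double ro, double ra, double cos_half,
                           double* ox, double* oy, bool warn_coincident) {
  double repx = 0, repy = 0;   int n_rep = 0;
  double orix = 0, oriy = 0;   int n_ori = 0;
  double attx = 0, atty = 0;   int n_att = 0;
  for (int j = 0; j < nn; ++j) {
    double sx = npos[j] - px, sy = npos[j + nn] - py;
    double d = std::sqrt(sx * sx + sy * sy);
    if (d >= ra) continue;
    if (d <= 0.0) {
      if (warn_coincident)
        Rf_warning("coincident agent positions: pair skipped in social direction");
      continue;
    }
    double ux = sx / d, uy = sy / d;
    // blind zone: neighbour visible iff angle to heading <= perception/2
    if (hx * ux + hy * uy < cos_half) continue;
    if (d < rr) { repx -= ux; repy -= uy; ++n_rep; }
    else if (d < ro) { orix += nhead[j]; oriy += nhead[j + nn]; ++n_ori; }
    else { attx += ux; atty += uy; ++n_att; }
  }
  if (n_rep > 0) {
    double n = std::sqrt(repx * repx + repy * repy);
    if (n > 0) { *ox = repx / n; *oy = repy / n; } else { *ox = 0; *oy = 0; }
    return;
  }
  double ddx = 0, ddy = 0;
  if (n_ori > 0) {
    double n = std::sqrt(orix * orix + oriy * oriy);
    if (n > 0) { ddx += orix / n; ddy += oriy / n; }
  }
  if (n_att > 0) {
    double n = std::sqrt(attx * attx + atty * atty);
    if (n > 0) { ddx += attx / n; ddy += atty / n; }
  }
  double n = std::sqrt(ddx * ddx + ddy * ddy);
  if (n > 1e-12) { *ox = ddx / n; *oy = ddy / n; } else { *ox = 0; *oy = 0; }
}

// [[Rcpp::export]]
NumericVector cpp_social_direction(NumericVector focal_pos, NumericVector focal_head,
                                   NumericMatrix nb_pos, NumericMatrix nb_head,
                                   double r_rep, double r_ori, double r_att,
                                   double cos_half_perception,
                                   bool warn_coincident = true) {
  double ox = 0, oy = 0;
  social_dir_raw(focal_pos[0], focal_pos[1], focal_head[0], focal_head[1],
                 nb_pos.begin(), nb_head.begin(), nb_pos.nrow(),
                 r_rep, r_ori, r_att, cos_half_perception, &ox, &oy,
                 warn_coincident);
  return NumericVector::create(ox, oy);
}

static inline void rotate2(double x, double y, double a, double* ox, double* oy) {
  double c = std::cos(a), s = std::sin(a);
  *ox = c * x - s * y;
  *oy = s * x + c * y;
}

// Limit the turn from `current` toward `desired` to max_turn radians.
// Exactly antiparallel desired breaks the tie counter-clockwise.
static void limit_turn_raw(double cx, double cy, double dx_, double dy_,
                           double max_turn, double* ox, double* oy) {
  double dn = std::sqrt(dx_ * dx_ + dy_ * dy_);
  if (dn < 1e-12) { *ox = cx; *oy = cy; return; }
  dx_ /= dn; dy_ /= dn;
  double dot = cx * dx_ + cy * dy_;
  double crs = cx * dy_ - cy * dx_;
  double th = std::atan2(crs, dot);
  if (crs == 0.0 && dot < 0.0) th = M_PI;  // counter-clockwise tie-break
  if (std::fabs(th) <= max_turn) { *ox = dx_; *oy = dy_; return; }
  rotate2(cx, cy, th > 0 ? max_turn : -max_turn, ox, oy);
}

// [[Rcpp::export]]
NumericVector cpp_limit_turn(NumericVector current, NumericVector desired,
                             double max_turn) {
  double ox, oy;
  limit_turn_raw(current[0], current[1], desired[0], desired[1], max_turn,
                 &ox, &oy);
  return NumericVector::create(ox, oy);
}

// Advance N agents through a stack of light-field frames.
//
// pos0/head0: N x 2.  frames: nx*ny*nf vector (frame stacks), frame_of_step:
// 1-based frame index used at each step (length = steps).  Synchronous
// update; reflective walls; all randomness from R's RNG so set.seed()
// controls the run.  Records every record_every-th step plus the initial
// state; returns flat vectors.
// [[Rcpp::export]]
List cpp_run_school(NumericMatrix pos0, NumericMatrix head0,
                    NumericVector frames, IntegerVector grid_dims,
                    IntegerVector frame_of_step,
                    double dx, double dy, double arena_w, double arena_h,
                    double dt, double w, double sigma_w, bool env_enabled,
                    double s_min, double s_max,
                    double r_rep, double r_ori, double r_att,
                    double cos_half_perception, double max_turn,
                    double social_error_sd, double grad_tol,
                    int steps, int record_every) {
  int N = pos0.nrow();
  int nx = grid_dims[0], ny = grid_dims[1], nf = grid_dims[2];
  if ((R_xlen_t)nx * ny * nf != frames.size())
    stop("frame stack size does not match grid dims");
  if (frame_of_step.size() < steps) stop("frame_of_step shorter than steps");
  int nrec = steps / record_every + 1;

  std::vector<double> px(N), py(N), hx(N), hy(N);
  for (int i = 0; i < N; ++i) {
    px[i] = pos0(i, 0); py[i] = pos0(i, 1);
    hx[i] = head0(i, 0); hy[i] = head0(i, 1);
  }
  std::vector<double> npx(N), npy(N), nhx(N), nhy(N), spd(N), lig(N);
  std::vector<double> posbuf(2 * N), headbuf(2 * N);

  NumericVector rt(nrec * N), rx(nrec * N), ry(nrec * N);
  NumericVector rhx(nrec * N), rhy(nrec * N), rs(nrec * N), rl(nrec * N);
  IntegerVector rid(nrec * N);
  int rec = 0;

  const double* fr0 = frames.begin() + (R_xlen_t)(frame_of_step[0] - 1) * nx * ny;
  for (int i = 0; i < N; ++i) {
    double L0 = bilin_raw(fr0, nx, ny, px[i], py[i], dx, dy);
    rt[rec] = 0.0; rid[rec] = i + 1; rx[rec] = px[i]; ry[rec] = py[i];
    rhx[rec] = hx[i]; rhy[rec] = hy[i];
    rl[rec] = L0; rs[rec] = s_min + L0 * (s_max - s_min);
    ++rec;
  }

  for (int step = 1; step <= steps; ++step) {
    const double* fr = frames.begin() +
      (R_xlen_t)(frame_of_step[step - 1] - 1) * nx * ny;
    // snapshot for the synchronous update
    for (int i = 0; i < N; ++i) {
      posbuf[i] = px[i]; posbuf[i + N] = py[i];
      headbuf[i] = hx[i]; headbuf[i + N] = hy[i];
    }
    for (int i = 0; i < N; ++i) {
      // neighbours = all other agents (swap focal out by overwriting with self
      // is avoided: pass full arrays and let distance 0 be the focal itself —
      // instead exclude by index using a copy-free trick below)
      double sxv = 0, syv = 0;
      {
        // social direction over all j != i
        double repx = 0, repy = 0; int n_rep = 0;
        double orix = 0, oriy = 0; int n_ori = 0;
        double attx = 0, atty = 0; int n_att = 0;
        for (int j = 0; j < N; ++j) {
          if (j == i) continue;
          double sx = posbuf[j] - posbuf[i], sy = posbuf[j + N] - posbuf[i + N];
          double d = std::sqrt(sx * sx + sy * sy);
          if (d >= r_att || d <= 0.0) continue;
          double ux = sx / d, uy = sy / d;
          if (headbuf[i] * ux + headbuf[i + N] * uy < cos_half_perception)
            continue;
          if (d < r_rep) { repx -= ux; repy -= uy; ++n_rep; }
          else if (d < r_ori) { orix += headbuf[j]; oriy += headbuf[j + N]; ++n_ori; }
          else { attx += ux; atty += uy; ++n_att; }
        }
        if (n_rep > 0) {
          double n = std::sqrt(repx * repx + repy * repy);
          if (n > 0) { sxv = repx / n; syv = repy / n; }
        } else {
          double ddx = 0, ddy = 0;
          if (n_ori > 0) {
            double n = std::sqrt(orix * orix + oriy * oriy);
            if (n > 0) { ddx += orix / n; ddy += oriy / n; }
          }
          if (n_att > 0) {
            double n = std::sqrt(attx * attx + atty * atty);
            if (n > 0) { ddx += attx / n; ddy += atty / n; }
          }
          double n = std::sqrt(ddx * ddx + ddy * ddy);
          if (n > 1e-12) { sxv = ddx / n; syv = ddy / n; }
        }
      }
      double ex = 0, ey = 0;
      if (env_enabled && w > 0) {
        double gx, gy;
        grad_raw(fr, nx, ny, posbuf[i], posbuf[i + N], dx, dy, &gx, &gy);
        double gn = std::sqrt(gx * gx + gy * gy);
        if (gn >= grad_tol) {
          // descend toward darkness, with per-step angular sensing error;
          // the error draw happens only when the gradient is actually used
          double ang = sigma_w > 0 ? R::rnorm(0.0, sigma_w) : 0.0;
          rotate2(-gx / gn, -gy / gn, ang, &ex, &ey);
        }
      }
      double ddx_ = sxv + w * ex, ddy_ = syv + w * ey;
      double nh_x, nh_y;
      double dn = std::sqrt(ddx_ * ddx_ + ddy_ * ddy_);
      if (dn < 1e-12) {
        nh_x = headbuf[i]; nh_y = headbuf[i + N];
      } else {
        limit_turn_raw(headbuf[i], headbuf[i + N], ddx_ / dn, ddy_ / dn,
                       max_turn, &nh_x, &nh_y);
      }
      if (social_error_sd > 0) {
        double ang = R::rnorm(0.0, social_error_sd);
        rotate2(nh_x, nh_y, ang, &nh_x, &nh_y);
      }
      double L = bilin_raw(fr, nx, ny, posbuf[i], posbuf[i + N], dx, dy);
      double s = s_min + L * (s_max - s_min);
      double x = posbuf[i] + nh_x * s * dt;
      double y = posbuf[i + N] + nh_y * s * dt;
      // reflective walls
      for (int it = 0; it < 4; ++it) {
        bool moved = false;
        if (x < 0)       { x = -x;             nh_x = -nh_x; moved = true; }
        if (x > arena_w) { x = 2 * arena_w - x; nh_x = -nh_x; moved = true; }
        if (y < 0)       { y = -y;             nh_y = -nh_y; moved = true; }
        if (y > arena_h) { y = 2 * arena_h - y; nh_y = -nh_y; moved = true; }
        if (!moved) break;
      }
      npx[i] = x; npy[i] = y; nhx[i] = nh_x; nhy[i] = nh_y;
      spd[i] = s; lig[i] = L;
    }
    for (int i = 0; i < N; ++i) {
      px[i] = npx[i]; py[i] = npy[i]; hx[i] = nhx[i]; hy[i] = nhy[i];
    }
    if (step % record_every == 0) {
      double t = step * dt;
      for (int i = 0; i < N; ++i) {
        rt[rec] = t; rid[rec] = i + 1; rx[rec] = px[i]; ry[rec] = py[i];
        rhx[rec] = hx[i]; rhy[rec] = hy[i]; rs[rec] = spd[i]; rl[rec] = lig[i];
        ++rec;
      }
    }
    if (step % 512 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["t"] = rt, _["id"] = rid, _["x"] = rx, _["y"] = ry,
                      _["hx"] = rhx, _["hy"] = rhy,
                      _["speed"] = rs, _["light"] = rl);
}
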