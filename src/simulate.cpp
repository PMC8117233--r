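#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Velocity-random-walk stimulus path confined to [-bx,bx] x [-by,by] by
// reflection.  Direction performs rotation diffusion, speed relaxes toward
// mean_speed (Ornstein-Uhlenbeck) and is reflected at 0 so it stays positive.
// In the saccadic condition, displacement jumps occur at uniform inter-jump
// intervals; the jump target is uniform in the field rectangle.
// Uses R's RNG so results are governed by set.seed().
// [[Rcpp::export]]
List walk_path_cpp(int n, double dt, double bx, double by,
                   double mean_speed, double dir_sigma,
                   double speed_relax, double speed_sigma,
                   bool saccadic, double jump_min, double jump_max) {
  NumericVector sx(n), sy(n);
  std::vector<int> jumps;
  double x = R::runif(-bx / 2.0, bx / 2.0);
  double y = R::runif(-by / 2.0, by / 2.0);
  double theta = R::runif(0.0, 2.0 * M_PI);
  double v = mean_speed;
  double tnow = 0.0;
  double next_jump = saccadic ? R::runif(jump_min, jump_max) : R_PosInf;
  sx[0] = x; sy[0] = y;
  for (int i = 1; i < n; ++i) {
    tnow += dt;
    if (saccadic && tnow >= next_jump) {
      x = R::runif(-bx, bx);
      y = R::runif(-by, by);
      theta = R::runif(0.0, 2.0 * M_PI);
      jumps.push_back(i + 1);  // 1-based sample index
      next_jump = tnow + R::runif(jump_min, jump_max);
    } else {
      v += speed_relax * (mean_speed - v) * dt +
           speed_sigma * std::sqrt(dt) * R::norm_rand();
      if (v < 0.0) v = -v;
      theta += dir_sigma * std::sqrt(dt) * R::norm_rand();
      x += v * std::cos(theta) * dt;
      y += v * std::sin(theta) * dt;
      if (x > bx)  { x =  2.0 * bx - x; theta = M_PI - theta; }
      if (x < -bx) { x = -2.0 * bx - x; theta = M_PI - theta; }
      if (y > by)  { y =  2.0 * by - y; theta = -theta; }
      if (y < -by) { y = -2.0 * by - y; theta = -theta; }
      // a step larger than the field could double-reflect; clamp as backstop
      if (x > bx) x = bx; if (x < -bx) x = -bx;
      if (y > by) y = by; if (y < -by) y = -by;
    }
    sx[i] = x; sy[i] = y;
  }
  return List::create(_["s_x"] = sx, _["s_y"] = sy,
                      _["jump_times"] = wrap(jumps));
}

static inline bool occluded_at(double rx, double ry, int kind, double radius) {
  switch (kind) {
    case 0: return false;                                     // none
    case 1: return std::sqrt(rx * rx + ry * ry) <= radius;    // central
    case 2: return std::sqrt(rx * rx + ry * ry) >  radius;    // peripheral
    case 3: return rx > 0.0;                                  // hemifield
  }
  return false;
}

// Discrete-time oculomotor control loop.
//   visible:  gaze velocity = gain * delayed stimulus velocity + white noise;
//             a corrective saccade (jump to the delayed target + landing
//             noise) fires once positional error has exceeded `trig` degrees
//             continuously for at least `sacc_lat` seconds.
//   occluded: no visual feedback; gaze extrapolates its last velocity with
//             exponential decay at rate `extrap_decay` 1/s (behavior = 0)
//             or freezes (behavior = 1), noiselessly.  After `search_lat`
//             seconds without feedback the observer makes a memory-guided
//             exploratory saccade: to the last seen stimulus position
//             extrapolated forward with the last seen stimulus velocity,
//             plus isotropic Gaussian scatter of SD `search_scatter`
//             degrees, repeating until the stimulus re-enters the seeing
//             field (the documented compensatory strategy of scotoma
//             patients, who search around the remembered target path).
// The saccade error timer freezes (rather than resets) during occlusion so
// brief glimpses accumulate toward a corrective saccade.
// Gaze is clamped to the screen rectangle [-bx,bx] x [-by,by]: the observer
// cannot fixate beyond the display.
// kind: 0 none, 1 central, 2 peripheral, 3 hemifield; radius in degrees.
// [[Rcpp::export]]
List simulate_gaze_cpp(NumericVector sx, NumericVector sy, double dt,
                       int kind, double radius,
                       double gain, int lat_samp, double noise_sd,
                       double trig, double sacc_lat, double land_sd,
                       int behavior, double extrap_decay,
                       double search_lat, double search_scatter,
                       double bx, double by) {
  int n = sx.size();
  NumericVector px(n), py(n);
  px[0] = sx[0]; py[0] = sy[0];
  double vx = 0.0, vy = 0.0;   // last pursuit velocity, degrees per sample
  double err_timer = 0.0;
  double occl_timer = 0.0;
  double mx = sx[0], my = sy[0];     // remembered stimulus position
  double mvx = 0.0, mvy = 0.0;       // remembered stimulus velocity (deg/sample)
  double lost_for = 0.0;             // seconds since last seen
  double sq = std::sqrt(dt);
  for (int t = 1; t < n; ++t) {
    double rx = sx[t - 1] - px[t - 1];
    double ry = sy[t - 1] - py[t - 1];
    bool occ = occluded_at(rx, ry, kind, radius);
    int i1 = t - lat_samp;           // delayed view of the stimulus
    int i0 = i1 - 1;
    double tx = sx[i1 >= 0 ? i1 : 0];
    double ty = sy[i1 >= 0 ? i1 : 0];
    double dsx = (i0 >= 0) ? sx[i1] - sx[i0] : 0.0;
    double dsy = (i0 >= 0) ? sy[i1] - sy[i0] : 0.0;
    if (!occ) {
      occl_timer = 0.0;
      lost_for = 0.0;
      mx = tx; my = ty; mvx = dsx; mvy = dsy;
      double ex = px[t - 1] - tx, ey = py[t - 1] - ty;
      double err = std::sqrt(ex * ex + ey * ey);
      if (err > trig) err_timer += dt; else err_timer = 0.0;
      if (err_timer >= sacc_lat && sacc_lat >= 0.0) {
        px[t] = tx + land_sd * R::norm_rand();
        py[t] = ty + land_sd * R::norm_rand();
        err_timer = 0.0;
        vx = gain * dsx; vy = gain * dsy;
      } else {
        vx = gain * dsx + noise_sd * sq * R::norm_rand();
        vy = gain * dsy + noise_sd * sq * R::norm_rand();
        px[t] = px[t - 1] + vx;
        py[t] = py[t - 1] + vy;
      }
    } else {
      occl_timer += dt;
      lost_for += dt;
      if (search_lat > 0.0 && occl_timer >= search_lat) {
        // Exploratory saccade.  Mostly memory-guided: aim at the
        // remembered position extrapolated for at most 0.5 s (a stale
        // velocity is useless for a random walk), overshooting past it
        // along the gaze->target direction -- scotoma patients saccade
        // beyond the estimated location so the target lands in the seeing
        // field -- with scatter growing with time lost, like the
        // diffusive uncertainty about the target.  Occasionally (30%) the
        // search is uniform over the screen, which breaks any stale-memory
        // trap and guarantees eventual reacquisition.
        double gx, gy;
        if (R::unif_rand() < 0.3) {
          gx = R::runif(-bx, bx);
          gy = R::runif(-by, by);
        } else {
          double steps = std::min(lost_for, 0.5) / dt;
          double ex = mx + mvx * steps, ey = my + mvy * steps;
          double sd = search_scatter * std::sqrt(1.0 + lost_for / search_lat);
          gx = ex + 0.4 * (ex - px[t - 1]) + sd * R::norm_rand();
          gy = ey + 0.4 * (ey - py[t - 1]) + sd * R::norm_rand();
        }
        px[t] = std::min(std::max(gx, -bx), bx);
        py[t] = std::min(std::max(gy, -by), by);
        occl_timer = 0.0;
        vx = 0.0; vy = 0.0;
      } else if (behavior == 0) {    // extrapolate last velocity, decaying
        double dec = std::exp(-extrap_decay * dt);
        vx *= dec; vy *= dec;
        px[t] = px[t - 1] + vx;
        py[t] = py[t - 1] + vy;
      } else {                       // freeze
        px[t] = px[t - 1];
        py[t] = py[t - 1];
      }
    }
    if (px[t] > bx) px[t] = bx; if (px[t] < -bx) px[t] = -bx;
    if (py[t] > by) py[t] = by; if (py[t] < -by) py[t] = -by;
  }
  return List::create(_["p_x"] = px, _["p_y"] = py);
}
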