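#include <Rcpp.h>
using namespace Rcpp;

// 2-D goal-directed walker with condition-dependent obstacle detection.
//
// Heading relaxes toward the bearing of the current waypoint, with additive
// avoidance steering away from detected obstacles and Gaussian heading noise.
// Detection is referenced either to the body heading (belt-style sector
// coverage) or to the instantaneous head yaw (single forward ray); hesitation
// episodes multiply speed down for a short dwell when an obstacle is
// detected. Collisions are flagged per sample while the walker disc overlaps
// an obstacle disc (the walker passes through, as in VR). Uses R's RNG so
// set.seed() gives byte-identical trials.

static inline double wrapdeg(double a) {
  a -= 360.0 * std::floor((a + 180.0) / 360.0); // [-180, 180)
  if (a == -180.0) a = 180.0;                   // convention: (-180, 180]
  return a;
}

// [[Rcpp::export]]
List walker_trial_cpp(NumericMatrix obstacles, NumericMatrix waypoints,
                      List par) {
  const double dt = as<double>(par["dt"]);
  const int max_steps = as<int>(par["max_steps"]);
  const double v0 = as<double>(par["v0"]);
  const double sigma_speed = as<double>(par["sigma_speed"]);
  const double tau_speed = as<double>(par["tau_speed"]);
  const double sigma_heading = as<double>(par["sigma_heading"]);
  const double k_goal = as<double>(par["k_goal"]);
  const double avoid_gain = as<double>(par["avoid_gain"]);
  const double detect_range = as<double>(par["detect_range"]);
  const double half_cov = as<double>(par["half_cov_deg"]);
  const bool head_ray = as<bool>(par["head_ray"]);
  const double hes_rate = as<double>(par["hesitation_rate"]);
  const int hes_steps = as<int>(par["hesitation_steps"]);
  const double hes_factor = as<double>(par["hesitation_factor"]);
  const double pitch_amp = as<double>(par["pitch_amp"]);
  const double pitch_freq = as<double>(par["pitch_freq"]);
  const double sigma_pitch = as<double>(par["sigma_pitch"]);
  const double scan_amp = as<double>(par["scan_amp"]);
  const double scan_freq = as<double>(par["scan_freq"]);
  const double sigma_yaw = as<double>(par["sigma_yaw"]);
  const double pitch_phase = as<double>(par["pitch_phase"]);
  const double scan_phase = as<double>(par["scan_phase"]);
  const double res_range = as<double>(par["res_range"]);
  const double res_gain = as<double>(par["res_gain"]);
  const double res_half_cov = as<double>(par["res_half_cov"]);
  const double walker_radius = as<double>(par["walker_radius"]);
  const double waypoint_tol = as<double>(par["waypoint_tol"]);

  const int n_obs = obstacles.nrow();
  const int n_wp = waypoints.nrow();
  const double two_pi = 2.0 * M_PI;
  const double deg = M_PI / 180.0;

  NumericMatrix out(max_steps, 11);
  double x = 0.0, y = 0.0;
  double heading = 0.0;
  if (n_wp > 0)
    heading = std::atan2(waypoints(0, 1) - y, waypoints(0, 0) - x) / deg;
  double e_speed = 0.0;
  double steer_mem = 0.0;                       // avoidance follow-through
  const double rho_avoid = std::exp(-dt / 0.7); // ~0.7 s decay after loss
  const double rho = std::exp(-dt / tau_speed);
  const double innov = std::sqrt(1.0 - rho * rho);
  int wp = 0, hes_left = 0, refractory = 0;
  int n = 0;
  bool done = false;

  for (int step = 0; step < max_steps && !done; ++step) {
    double t = step * dt;

    // head kinematics (scanning around the trunk, pitch oscillation)
    double scan = scan_amp * std::sin(two_pi * scan_freq * t + scan_phase);
    double body_yaw = wrapdeg(heading + sigma_yaw * norm_rand());
    double head_yaw = wrapdeg(body_yaw + scan + sigma_yaw * norm_rand());
    double head_pitch = pitch_amp * std::sin(two_pi * pitch_freq * t + pitch_phase) +
      sigma_pitch * norm_rand();

    // waypoint bookkeeping
    double tx = waypoints(wp, 0), ty = waypoints(wp, 1);
    double dxw = tx - x, dyw = ty - y;
    if (std::sqrt(dxw * dxw + dyw * dyw) < waypoint_tol) {
      if (wp + 1 < n_wp) {
        ++wp;
        tx = waypoints(wp, 0); ty = waypoints(wp, 1);
        dxw = tx - x; dyw = ty - y;
      } else {
        done = true;
      }
    }
    double bearing = std::atan2(dyw, dxw) / deg;

    // obstacle detection and avoidance steering
    double steer = 0.0;
    bool detected = false, overlap = false;
    double ref = head_ray ? head_yaw : heading;
    for (int k = 0; k < n_obs; ++k) {
      double dx = obstacles(k, 0) - x, dy = obstacles(k, 1) - y;
      double d = std::sqrt(dx * dx + dy * dy);
      if (d < obstacles(k, 2) + walker_radius) overlap = true;
      double gap = d - obstacles(k, 2);
      double ang = std::atan2(dy, dx) / deg;
      if (gap < detect_range) {
        double rel = wrapdeg(ang - ref);
        if (std::fabs(rel) < half_cov) {
          detected = true;
          double w = avoid_gain * (1.0 - std::max(gap, 0.0) / detect_range);
          steer += (rel >= 0.0) ? -w : w;
        }
      }
      // residual vision persists under every condition; feedback augments it
      if (res_gain > 0.0 && gap < res_range) {
        double rel = wrapdeg(ang - heading);
        if (std::fabs(rel) < res_half_cov) {
          detected = true;
          double w = res_gain * (1.0 - std::max(gap, 0.0) / res_range);
          steer += (rel >= 0.0) ? -w : w;
        }
      }
    }

    // follow-through: keep steering briefly after the obstacle leaves the
    // angular coverage (a walker remembers what it just detected)
    if (detected) steer_mem = steer;
    else { steer_mem *= rho_avoid; steer = steer_mem; }

    // hesitation episodes (haptic caution)
    double hfac = 1.0;
    if (hes_left > 0) {
      hfac = hes_factor;
      --hes_left;
      if (hes_left == 0) refractory = 4 * hes_steps;
    } else if (refractory > 0) {
      --refractory;
    } else if (detected && hes_rate > 0.0 &&
               unif_rand() < 1.0 - std::exp(-hes_rate * dt)) {
      hes_left = hes_steps;
      hfac = hes_factor;
    }

    // log the sample before moving
    out(n, 0) = t;
    out(n, 1) = x;
    out(n, 2) = y;
    out(n, 3) = 1.6;                    // eye height, unused downstream
    out(n, 4) = head_yaw;
    out(n, 5) = head_pitch;
    out(n, 6) = 0.5 * norm_rand();      // head roll: small noise
    out(n, 7) = body_yaw;
    out(n, 8) = 0.5 * norm_rand();      // body pitch
    out(n, 9) = 0.5 * norm_rand();      // body roll
    out(n, 10) = overlap ? 1.0 : 0.0;
    ++n;
    if (done) break;

    // dynamics update
    double err = wrapdeg(bearing - heading);
    heading = wrapdeg(heading + k_goal * err * dt + steer * dt +
                      sigma_heading * std::sqrt(dt) * norm_rand());
    e_speed = rho * e_speed + innov * norm_rand();
    double speed = v0 * std::max(0.0, 1.0 + sigma_speed * e_speed) * hfac;
    x += speed * dt * std::cos(heading * deg);
    y += speed * dt * std::sin(heading * deg);
  }

  return List::create(_["samples"] = out(Range(0, n - 1), _),
                      _["incomplete"] = !done);
}
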