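#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Point-mass flight dynamics in horizontally uniform, vertically sheared wind.
//
// State: position (x, y, z) [m], airspeed V [m/s], flight-path angle gamma
// [rad], heading psi [rad, from +x]. Wind blows toward the unit vector
// (wx, wy) with speed Wz(z). Controls (bank phi, lift coefficient CL, thrust
// per mass T_pm) are recomputed once per step and held over the RK4 stages
// (zero-order hold at the integration rate).
//
// Ground-frame specific energy E = 0.5*|v_ground|^2 + g*z obeys
//   dE/dt = P_thrust - P_drag + P_wind
// exactly, with P_drag = D*V/m, P_thrust = T*V/m and P_wind the total
// non-gravitational force dotted with the wind vector (per unit mass). The
// integrator logs all three so energy closure is testable, not assumed.

struct Polar {
  double mass, S, CD0, k, rho, g;
};

struct Wind {
  int model;        // 0 none, 1 power law, 2 logarithmic, 3 logistic
  double W_ref, z_ref, expnt, z0, z_center, thickness, wx, wy;
  double scale;     // per-segment multiplier
  bool coupling;    // gradient (apparent force) terms active?

  double speed(double z) const {
    if (model == 0) return 0.0;
    if (model == 3) {
      double sig = 1.0 / (1.0 + std::exp(-(z - z_center) / thickness));
      return scale * W_ref * sig;
    }
    double zz = z < 0.5 ? 0.5 : z;
    if (model == 1) return scale * W_ref * std::pow(zz / z_ref, expnt);
    double zl = zz < z0 * 1.01 ? z0 * 1.01 : zz;
    return scale * W_ref * std::log(zl / z0) / std::log(z_ref / z0);
  }
  double gradient(double z) const {
    if (model == 0) return 0.0;
    if (model == 3) {
      double sig = 1.0 / (1.0 + std::exp(-(z - z_center) / thickness));
      return scale * W_ref * sig * (1.0 - sig) / thickness;
    }
    double zz = z < 0.5 ? 0.5 : z;
    if (model == 1)
      return scale * W_ref * expnt * std::pow(zz / z_ref, expnt - 1.0) / z_ref;
    double zl = zz < z0 * 1.01 ? z0 * 1.01 : zz;
    return scale * W_ref / (zl * std::log(z_ref / z0));
  }
};

struct Controls {
  double phi, CL, T_pm;
};

struct State {
  double x, y, z, V, gamma, psi;
};

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}
static inline double wrap_pi(double a) {
  return std::atan2(std::sin(a), std::cos(a));
}
// positive remainder without libm fmod
static inline double mod_pos(double a, double b) {
  return a - std::floor(a / b) * b;
}

// state derivative under fixed controls
static State deriv(const State& s, const Controls& c, const Polar& p,
                   const Wind& w) {
  double q = 0.5 * p.rho * s.V * s.V * p.S;
  double L_pm = q * c.CL / p.mass;
  double CD = p.CD0 + p.k * c.CL * c.CL;
  double D_pm = q * CD / p.mass;
  double sg = std::sin(s.gamma), cg = std::cos(s.gamma);
  double sp = std::sin(s.psi), cp = std::cos(s.psi);
  double Wd = 0.0;
  if (w.coupling) Wd = w.gradient(s.z) * s.V * sg;  // dW/dz * zdot
  double cw = cp * w.wx + sp * w.wy;                // heading . wind dir
  double s2 = -sp * w.wx + cp * w.wy;               // lateral . wind dir

  State d;
  d.x = s.V * cg * cp + w.speed(s.z) * w.wx;
  d.y = s.V * cg * sp + w.speed(s.z) * w.wy;
  d.z = s.V * sg;
  d.V = c.T_pm - D_pm - p.g * sg - Wd * cg * cw;
  double V = s.V < 1.0 ? 1.0 : s.V;
  d.gamma = (L_pm * std::cos(c.phi) - p.g * cg + Wd * sg * cw) / V;
  double cgs = std::fabs(cg) < 0.1 ? (cg < 0 ? -0.1 : 0.1) : cg;
  d.psi = (L_pm * std::sin(c.phi) - Wd * s2) / (V * cgs);
  return d;
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(List par) {
  Polar p;
  p.mass = as<double>(par["mass"]); p.S = as<double>(par["wing_area"]);
  p.CD0 = as<double>(par["CD0"]);  p.k = as<double>(par["k_induced"]);
  p.rho = as<double>(par["rho"]);  p.g = as<double>(par["g"]);

  Wind w;
  w.model = as<int>(par["wind_model"]);
  w.W_ref = as<double>(par["W_ref"]); w.z_ref = as<double>(par["z_ref"]);
  w.expnt = as<double>(par["exponent"]); w.z0 = as<double>(par["z0"]);
  w.z_center = as<double>(par["z_center"]);
  w.thickness = as<double>(par["thickness"]);
  double wdir = as<double>(par["wind_dir"]);
  w.wx = std::cos(wdir); w.wy = std::sin(wdir);
  w.scale = 1.0;
  w.coupling = as<bool>(par["shear_coupling"]);

  const int mode = as<int>(par["mode"]); // 0 soaring, 1 flap_glide, 2 flapping
  const double duration = as<double>(par["duration"]);
  const double dt = as<double>(par["dt"]);
  const double T_c = as<double>(par["cycle_period"]);
  const double psi_amp = as<double>(par["psi_amp"]);
  const double psi_mean = as<double>(par["psi_mean"]);
  const double gamma_amp = as<double>(par["gamma_amp"]);
  const double z_amp = as<double>(par["z_amp"]);
  const double phi_max = as<double>(par["phi_max"]);
  const double k_psi = as<double>(par["k_psi"]);
  const double k_gamma = as<double>(par["k_gamma"]);
  const double CL_min = as<double>(par["CL_min"]);
  const double CL_max = as<double>(par["CL_max"]);
  const double n_cap = as<double>(par["n_cap"]);   // max load factor
  const double z_mid = as<double>(par["z_mid"]);
  const double z_half = as<double>(par["z_half"]);
  const double k_alt = as<double>(par["k_alt"]);
  const double z_floor = as<double>(par["z_floor"]);
  const double z_ceil = as<double>(par["z_ceil"]);

  const double assist_tau = as<double>(par["assist_tau"]);
  const double assist_z_on = as<double>(par["assist_z_on"]);
  const double assist_z_off = as<double>(par["assist_z_off"]);

  const double bout_period = as<double>(par["bout_period"]);
  const double f_flap = as<double>(par["flap_freq"]);
  const double c_flap = as<double>(par["c_flap"]);
  const double k_v = as<double>(par["k_v"]);
  const double V_floor = as<double>(par["V_floor"]);
  const double V_hi = as<double>(par["V_hi"]);
  const double T_max = as<double>(par["thrust_max"]);

  NumericVector seg_start = par["seg_start"];     // segment start times
  NumericVector seg_scale = par["seg_wind_scale"];
  NumericVector seg_Vt = par["seg_target_speed"];
  NumericVector seg_duty = par["seg_duty"];

  const double gps_rate = as<double>(par["gps_rate"]);
  const double accel_rate = as<double>(par["accel_rate"]);
  const double sig_h = as<double>(par["sigma_gps_h"]);
  const double sig_v = as<double>(par["sigma_gps_v"]);
  const double sig_a = as<double>(par["sigma_accel"]);

  State s;
  s.x = 0.0; s.y = 0.0;
  s.z = as<double>(par["z_init"]);
  s.V = as<double>(par["V_init"]);
  s.gamma = 0.0;
  s.psi = as<double>(par["psi_init"]);

  const int n_steps = (int)std::round(duration / dt);
  const int gps_every = (int)std::round(1.0 / (gps_rate * dt));
  const int acc_every = (int)std::round(1.0 / (accel_rate * dt));
  const int n_gps = n_steps / gps_every + 1;
  const int n_acc = n_steps / acc_every + 1;

  NumericMatrix gps(n_gps, 4);    // t, x, y, z (noisy)
  NumericMatrix acc(n_acc, 4);    // t, ax, ay, az (body-frame specific force)
  NumericMatrix truth(n_gps, 18); // t x y z V u E Pw Pt Pd cumW cumT cumD gamma psi phase phi CL

  double zf = s.z;                // slow-filtered altitude for flap assist
  double phi_act = 0.0, CL_act = NA_REAL; // slew-limited control states
  double cumW = 0.0, cumT = 0.0, cumD = 0.0;
  double prevPw = NA_REAL, prevPt = NA_REAL, prevPd = NA_REAL;
  int ig = 0, ia = 0, iseg = 0, status = 0;
  int phase = 0;                  // soaring state machine: 0 climb, 1 dive
  double t_flip = -10.0;          // time of last phase flip (dwell lockout)
  double t = 0.0;

  for (int i = 0; i <= n_steps; ++i) {
    // ---- segment bookkeeping
    while (iseg + 1 < seg_start.size() && t >= seg_start[iseg + 1]) ++iseg;
    w.scale = seg_scale[iseg];
    double V_t = seg_Vt[iseg];
    double duty = seg_duty[iseg];

    // ---- controls from current state
    Controls c;
    double q = 0.5 * p.rho * s.V * s.V * p.S;
    double CD_lvl, D_pm_now;
    bool flap_active = false;
    double cw = std::cos(s.psi) * w.wx + std::sin(s.psi) * w.wy;

    if (mode == 2) { // continuous flapping: level cruise at target speed
      c.phi = 0.0;
      double gamma_d = clampd(k_alt * (z_mid - s.z) / z_half, -0.25, 0.25);
      double CL_lvl = p.mass * p.g * std::cos(s.gamma) / (q > 1e-6 ? q : 1e-6);
      c.CL = clampd(CL_lvl + k_gamma * (gamma_d - s.gamma), CL_min, CL_max);
      CD_lvl = p.CD0 + p.k * c.CL * c.CL;
      D_pm_now = q * CD_lvl / p.mass;
      c.T_pm = clampd(D_pm_now + p.g * std::sin(s.gamma) + k_v * (V_t - s.V),
                      0.0, T_max);
      flap_active = true;
    } else {
      double gamma_d, psi_d;
      if (mode == 0) {
        // Rayleigh cycle as an altitude-triggered state machine: climb into
        // the wind until the top of the band, dive downwind until the
        // bottom; the 180-degree turns happen while the phase flips
        // airspeed is the cycle's state variable: climb into the wind only
        // while fast, dive away downwind whenever slow, so a low-and-slow
        // stall is unreachable; altitude triggers are secondary
        if (t - t_flip >= 1.5) {   // dwell lockout prevents chatter
          if (phase == 0 && (s.V <= V_floor || s.z >= z_mid + z_amp)) {
            phase = 1; t_flip = t;
          } else if (phase == 1 && ((s.V >= V_hi && s.z <= z_mid) ||
                     (s.z <= z_mid - z_amp + 0.5 && s.V > 13.5))) {
            phase = 0; t_flip = t;  // fast enough, or at the bottom with
                                    // enough speed to bank: turn upwind
          }
        }
        psi_d = phase == 0 ? psi_mean + 0.5 * psi_amp
                           : psi_mean - 0.5 * psi_amp;
        if (phase == 0) {
          // climb rate proportional to excess speed, gated by how far the
          // nose has actually come around into the wind
          gamma_d = gamma_amp *
            clampd((s.V - (V_floor - 1.0)) / 4.0, 0.0, 1.0) *
            clampd((-cw - 0.2) / 0.6, 0.02, 1.0);
          gamma_d *= clampd((z_mid + z_amp + 2.0 - s.z) / 3.0, 0.0, 1.0);
        } else {
          // dive steeply while slow, flatten as speed recovers; shallow the
          // dive while the nose is still upwind and near the floor
          double commit = clampd((cw - 0.2) / 0.6, 0.0, 1.0);
          gamma_d = -gamma_amp * commit -
            0.15 * (1.0 - commit);  // keep sinking gently through the turn
          double sink = -s.V * std::sin(s.gamma < 0 ? s.gamma : 0);
          gamma_d *= clampd((s.z - z_floor) / (2.0 + 0.9 * sink), 0.0, 1.0);
        }
      } else {
        // flap_glide: tame sinusoidal cyclic schedule with thrust bouts
        psi_d = psi_mean + psi_amp * std::sin(2.0 * M_PI * t / T_c);
        double th = 2.0 * M_PI * t / T_c;
        double z_d = z_mid - z_amp * std::cos(th);
        double zdot_d = z_amp * (2.0 * M_PI / T_c) * std::sin(th);
        gamma_d = std::asin(clampd(zdot_d / (s.V > 5 ? s.V : 5),
                                   -0.75, 0.75)) +
          clampd(k_alt * (z_d - s.z) / z_half, -0.35, 0.35);
        // track the commanded cruise speed: glide steeper to fly faster
        gamma_d += clampd(0.1 * (s.V - V_t), -0.3, 0.05);
        gamma_d = clampd(gamma_d, -gamma_amp, gamma_amp);
      }
      if (gamma_d < 0.0)
        gamma_d *= clampd((s.z - z_floor) / 6.0, 0.0, 1.0);
      else
        gamma_d *= clampd((z_ceil - s.z) / 8.0, 0.0, 1.0);
      bool emergency = s.z < z_floor + 1.2;
      if (emergency) gamma_d = 0.35;             // emergency pull-up
      else if (s.z > z_ceil + 5.0) gamma_d = -0.3;
      c.phi = clampd(k_psi * wrap_pi(psi_d - s.psi), -phi_max, phi_max);
      if (emergency) c.phi = clampd(c.phi, -0.2, 0.2); // wings level to pull
      // cap the load factor: fast birds do not pull harder, they turn wider
      double CL_cap = CL_max;
      if (n_cap > 0) {
        double CL_n = p.mass * p.g * n_cap / (q > 1e-6 ? q : 1e-6);
        if (CL_n < CL_cap) CL_cap = CL_n;
      }
      // never bank beyond what the lift ceiling supports in level-turn trim
      {
        double qq = q > 1e-6 ? q : 1e-6;
        double cphi_need = p.mass * p.g * std::cos(s.gamma) /
          (qq * 0.95 * CL_cap);
        double phi_avail = cphi_need < 1.0
          ? std::acos(clampd(cphi_need, 0.0, 1.0)) : 0.0;
        // with height to burn, allow wingover-style banking past the
        // coordinated-turn limit (sink during the turn rebuilds speed)
        double phi_floor = (mode == 0 && s.z > z_mid && s.V > 13.0)
          ? 0.9 : 0.25;
        if (phi_avail < phi_floor) phi_avail = phi_floor;
        c.phi = clampd(c.phi, -phi_avail, phi_avail);
      }
      double CL_lvl = p.mass * p.g * std::cos(s.gamma) /
        ((q > 1e-6 ? q : 1e-6) * std::cos(c.phi));
      c.CL = clampd(CL_lvl + k_gamma * (gamma_d - s.gamma), CL_min, CL_cap);
      CD_lvl = p.CD0 + p.k * c.CL * c.CL;
      D_pm_now = q * CD_lvl / p.mass;
      c.T_pm = 0.0;
      if (mode == 0 && assist_tau > 0.0) {
        // weak-wind assist: bouts of corrective flapping when the bird can no
        // longer hold the working band
        zf += (dt / 20.0) * (s.z - zf);
        double frac = clampd((assist_z_on - zf) / (assist_z_on - assist_z_off),
                             0.0, 1.0);
        c.T_pm = assist_tau * frac;
        flap_active = frac > 0.05;
      } else if (mode == 1) {
        bool in_bout = mod_pos(t, bout_period) < duty * bout_period;
        if (s.V < V_floor) {   // emergency flapping near stall
          c.T_pm = clampd(D_pm_now + p.g * std::sin(s.gamma) +
                          k_v * (V_floor + 1.5 - s.V), 0.0, T_max);
          flap_active = true;
        } else if (in_bout) {
          double climb_comp = p.g * (std::sin(s.gamma) > 0 ?
                                     std::sin(s.gamma) : 0.0);
          c.T_pm = clampd(1.1 * D_pm_now + climb_comp + k_v * (V_t - s.V),
                          0.0, T_max);
          flap_active = true;
        }
      }
    }

    // ---- actuator dynamics: banks and lift changes are rate-limited
    {
      const double dphi_max = 1.2 * dt;   // rad per step (1.2 rad/s)
      const double dCL_max = 1.2 * dt;    // CL units per step (1.2 /s)
      phi_act += clampd(c.phi - phi_act, -dphi_max, dphi_max);
      if (!std::isfinite(CL_act)) CL_act = c.CL;
      CL_act += clampd(c.CL - CL_act, -dCL_max, dCL_max);
      c.phi = phi_act; c.CL = CL_act;
    }

    // ---- power bookkeeping (before stepping; trapezoid accumulation)
    double L_pm = q * c.CL / p.mass;
    double CD = p.CD0 + p.k * c.CL * c.CL;
    double D_pm = q * CD / p.mass;
    double sg = std::sin(s.gamma), cg = std::cos(s.gamma);
    double sp = std::sin(s.psi), cp = std::cos(s.psi);
    double Wz = w.speed(s.z);
    double s2 = -sp * w.wx + cp * w.wy;
    double Pd = D_pm * s.V;
    double Pt = c.T_pm * s.V;
    // non-gravitational force . wind vector, per unit mass
    double Pw = Wz * ((c.T_pm - D_pm) * cg * cw +
                      L_pm * (-std::cos(c.phi) * sg * cw +
                               std::sin(c.phi) * s2));
    if (i > 0) {
      cumW += 0.5 * (Pw + prevPw) * dt;
      cumT += 0.5 * (Pt + prevPt) * dt;
      cumD += 0.5 * (Pd + prevPd) * dt;
    }
    prevPw = Pw; prevPt = Pt; prevPd = Pd;

    // ---- logging
    double ux = s.V * cg * cp + Wz * w.wx;
    double uy = s.V * cg * sp + Wz * w.wy;
    double uz = s.V * sg;
    double u = std::sqrt(ux * ux + uy * uy + uz * uz);
    double E = 0.5 * u * u + p.g * s.z;

    if (i % acc_every == 0 && ia < n_acc) {
      double ax = c.T_pm - D_pm;     // body x: along air velocity
      double ay = 0.0;
      double az = L_pm;              // body z: lift axis
      if (flap_active && c_flap > 0.0) {
        double amp = c_flap * c.T_pm * s.V; // amplitude ~ mass-specific power
        double ph = 2.0 * M_PI * f_flap * t;
        az += amp * std::sin(ph);
        ax += 0.25 * amp * std::sin(2.0 * ph);
      }
      acc(ia, 0) = t;
      acc(ia, 1) = ax + R::rnorm(0.0, sig_a);
      acc(ia, 2) = ay + R::rnorm(0.0, sig_a);
      acc(ia, 3) = az + R::rnorm(0.0, sig_a);
      ++ia;
    }
    if (i % gps_every == 0 && ig < n_gps) {
      gps(ig, 0) = t;
      gps(ig, 1) = s.x + R::rnorm(0.0, sig_h);
      gps(ig, 2) = s.y + R::rnorm(0.0, sig_h);
      gps(ig, 3) = s.z + R::rnorm(0.0, sig_v);
      truth(ig, 0) = t;  truth(ig, 1) = s.x; truth(ig, 2) = s.y;
      truth(ig, 3) = s.z; truth(ig, 4) = s.V; truth(ig, 5) = u;
      truth(ig, 6) = E;  truth(ig, 7) = Pw;  truth(ig, 8) = Pt;
      truth(ig, 9) = Pd; truth(ig, 10) = cumW; truth(ig, 11) = cumT;
      truth(ig, 12) = cumD; truth(ig, 13) = s.gamma; truth(ig, 14) = s.psi;
      truth(ig, 15) = phase; truth(ig, 16) = c.phi; truth(ig, 17) = c.CL;
      ++ig;
    }

    if (i == n_steps) break;

    // ---- RK4 step with held controls
    State k1 = deriv(s, c, p, w);
    State s2s = s;
    s2s.x += 0.5 * dt * k1.x; s2s.y += 0.5 * dt * k1.y; s2s.z += 0.5 * dt * k1.z;
    s2s.V += 0.5 * dt * k1.V; s2s.gamma += 0.5 * dt * k1.gamma;
    s2s.psi += 0.5 * dt * k1.psi;
    State k2 = deriv(s2s, c, p, w);
    State s3 = s;
    s3.x += 0.5 * dt * k2.x; s3.y += 0.5 * dt * k2.y; s3.z += 0.5 * dt * k2.z;
    s3.V += 0.5 * dt * k2.V; s3.gamma += 0.5 * dt * k2.gamma;
    s3.psi += 0.5 * dt * k2.psi;
    State k3 = deriv(s3, c, p, w);
    State s4 = s;
    s4.x += dt * k3.x; s4.y += dt * k3.y; s4.z += dt * k3.z;
    s4.V += dt * k3.V; s4.gamma += dt * k3.gamma; s4.psi += dt * k3.psi;
    State k4 = deriv(s4, c, p, w);

    s.x += dt / 6.0 * (k1.x + 2 * k2.x + 2 * k3.x + k4.x);
    s.y += dt / 6.0 * (k1.y + 2 * k2.y + 2 * k3.y + k4.y);
    s.z += dt / 6.0 * (k1.z + 2 * k2.z + 2 * k3.z + k4.z);
    s.V += dt / 6.0 * (k1.V + 2 * k2.V + 2 * k3.V + k4.V);
    s.gamma += dt / 6.0 * (k1.gamma + 2 * k2.gamma + 2 * k3.gamma + k4.gamma);
    s.psi += dt / 6.0 * (k1.psi + 2 * k2.psi + 2 * k3.psi + k4.psi);
    s.psi = wrap_pi(s.psi);
    if (s.V < 1.0) s.V = 1.0;
    t += dt;

    if (s.z < 0.0) { status = 1; break; }
    if (!std::isfinite(s.z) || !std::isfinite(s.V)) { status = 2; break; }
  }

  return List::create(
    _["gps"] = gps, _["accel"] = acc, _["truth"] = truth,
    _["status"] = status, _["n_gps"] = ig, _["n_accel"] = ia);
}
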