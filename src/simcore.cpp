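// Planar 11-DOF forward dynamics of the nine-link macaque model.
//
// Generalized coordinates q (11): hip x, hip y, trunk pitch, then per leg
// (right, left): hip, knee, ankle, MP relative joint angles.  Segment world
// angles follow the chain psi_HAT = pi/2 - pitch, psi_thigh = psi_HAT - pi +
// q_hip, and each more distal segment adds its joint angle.  The equation of
// motion M(q) qdd + bias = Q is assembled from per-body point Jacobians
// (revolute columns J_col = s * perp(p - pivot)) and integrated by
// semi-implicit Euler with an implicit velocity update for joint viscosity
// and the knee-stop stiffness.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Vec2 {
  double x, y;
  Vec2(double x_ = 0, double y_ = 0) : x(x_), y(y_) {}
};
inline Vec2 operator+(Vec2 a, Vec2 b) { return Vec2(a.x + b.x, a.y + b.y); }
inline Vec2 operator-(Vec2 a, Vec2 b) { return Vec2(a.x - b.x, a.y - b.y); }
inline Vec2 operator*(double s, Vec2 a) { return Vec2(s * a.x, s * a.y); }
inline double dot(Vec2 a, Vec2 b) { return a.x * b.x + a.y * b.y; }
inline double cross(Vec2 a, Vec2 b) { return a.x * b.y - a.y * b.x; }
inline Vec2 perp(Vec2 a) { return Vec2(-a.y, a.x); }
inline Vec2 rot(double psi, Vec2 v) {
  double c = std::cos(psi), s = std::sin(psi);
  return Vec2(c * v.x - s * v.y, s * v.x + c * v.y);
}

const double TWOPI = 2.0 * M_PI;

struct PathPoint { int seg; double lx, ly; };  // seg: 0 HAT..4 phalanges

struct Muscle {
  double f_max, rest_length;
  std::vector<PathPoint> path;
  bool span[4];  // hip knee ankle mp
};

struct ContactPoint { int seg; double lx, ly; bool phal; };

struct Model {
  double mass[5], len[5], comf[5], moi[5];
  double visc[4];
  double ks_k1, ks_k2, ks_k3;
  double pe_k1, pe_k2;
  bool pe_clamp;
  std::vector<Muscle> muscles;
  std::vector<ContactPoint> cpts;
  double k_vert, c_vert, k_horz, c_horz, grf_thr, debounce;
  double gravity;
  double fall_height_frac, fall_pitch_max;
};

Model parse_model(List ml) {
  Model M;
  DataFrame segs = as<DataFrame>(ml["segments"]);
  NumericVector mass = segs["mass"], len = segs["length"],
                comf = segs["com_fraction"], moi = segs["moment_of_inertia"];
  for (int i = 0; i < 5; i++) {
    M.mass[i] = mass[i]; M.len[i] = len[i];
    M.comf[i] = comf[i]; M.moi[i] = moi[i];
  }
  DataFrame joints = as<DataFrame>(ml["joints"]);
  NumericVector visc = joints["viscous_coefficient"];
  for (int i = 0; i < 4; i++) M.visc[i] = visc[i];
  List ks = ml["knee_stop"];
  M.ks_k1 = as<double>(ks["k1"]); M.ks_k2 = as<double>(ks["k2"]);
  M.ks_k3 = as<double>(ks["k3"]);
  List pe = ml["pe_params"];
  M.pe_k1 = as<double>(pe["k1_pe"]); M.pe_k2 = as<double>(pe["k2_pe"]);
  M.pe_clamp = pe.containsElementNamed("clamp_nonnegative") ?
               as<bool>(pe["clamp_nonnegative"]) : false;
  List muscles = ml["muscles"];
  const char* segnames[5] = {"HAT", "thigh", "shank", "foot", "phalanges"};
  const char* jnames[4] = {"hip", "knee", "ankle", "mp"};
  for (int m = 0; m < muscles.size(); m++) {
    List mu = muscles[m];
    Muscle mm;
    mm.f_max = as<double>(mu["f_max"]);
    mm.rest_length = as<double>(mu["rest_length"]);
    DataFrame path = as<DataFrame>(mu["path"]);
    CharacterVector pseg = path["segment"];
    NumericVector px = path["x"], py = path["y"];
    for (int i = 0; i < px.size(); i++) {
      PathPoint pp; pp.lx = px[i]; pp.ly = py[i]; pp.seg = -1;
      for (int s = 0; s < 5; s++)
        if (pseg[i] == segnames[s]) pp.seg = s;
      mm.path.push_back(pp);
    }
    CharacterVector span = mu["spanned_joints"];
    for (int j = 0; j < 4; j++) mm.span[j] = false;
    for (int i = 0; i < span.size(); i++)
      for (int j = 0; j < 4; j++)
        if (span[i] == jnames[j]) mm.span[j] = true;
    M.muscles.push_back(mm);
  }
  List contact = ml["contact"];
  DataFrame lay = as<DataFrame>(contact["layout"]);
  CharacterVector cseg = lay["segment"];
  NumericVector cx = lay["x"], cy = lay["y"];
  for (int i = 0; i < cx.size(); i++) {
    ContactPoint cp; cp.lx = cx[i]; cp.ly = cy[i];
    cp.phal = (cseg[i] == "phalanges");
    cp.seg = cp.phal ? 4 : 3;
    M.cpts.push_back(cp);
  }
  List cpar = contact["params"];
  M.k_vert = as<double>(cpar["k_vert"]); M.c_vert = as<double>(cpar["c_vert"]);
  M.k_horz = as<double>(cpar["k_horz"]); M.c_horz = as<double>(cpar["c_horz"]);
  M.grf_thr = cpar.containsElementNamed("grf_threshold") ?
              as<double>(cpar["grf_threshold"]) : 1.0;
  M.debounce = cpar.containsElementNamed("debounce") ?
               as<double>(cpar["debounce"]) : 0.020;
  M.gravity = as<double>(ml["gravity"]);
  List fall = ml["fall"];
  M.fall_height_frac = as<double>(fall["height_frac"]);
  M.fall_pitch_max = as<double>(fall["pitch_max"]);
  return M;
}

// Kinematics of one instant, both legs.
struct Kin {
  double psi[9];       // body world angles: 0 HAT, 1-4 R, 5-8 L
  Vec2 jpos[2][4];     // [leg][hip,knee,ankle,mp]
  Vec2 jvel[2][4];
  Vec2 com[9], comv[9];
};

// body index: 0 HAT; leg bodies 1+4*leg .. 4+4*leg (thigh shank foot phal)
// q columns for leg joints: 3+4*leg .. 6+4*leg

void kinematics(const Model& M, const double* q, const double* qd, Kin& K) {
  K.psi[0] = M_PI / 2 - q[2];
  Vec2 hip(q[0], q[1]);
  Vec2 vhip(qd[0], qd[1]);
  // HAT com
  {
    Vec2 d = rot(K.psi[0], Vec2(M.comf[0] * M.len[0], 0));
    K.com[0] = hip + d;
    K.comv[0] = vhip + (-qd[2]) * perp(d);
  }
  for (int leg = 0; leg < 2; leg++) {
    int qo = 3 + 4 * leg;
    double psi = K.psi[0] - M_PI;
    double omega = -qd[2];
    Vec2 p = hip, v = vhip;
    K.jpos[leg][0] = hip; K.jvel[leg][0] = vhip;
    for (int s = 0; s < 4; s++) {  // thigh shank foot phal
      psi += q[qo + s];
      omega += qd[qo + s];
      int body = 1 + 4 * leg + s;
      int seg = 1 + s;
      K.psi[body] = psi;
      Vec2 axis = rot(psi, Vec2(1, 0));
      Vec2 cd = M.comf[seg] * M.len[seg] * axis;
      K.com[body] = p + cd;
      K.comv[body] = v + omega * perp(cd);
      if (s < 3) {
        Vec2 jd = M.len[seg] * axis;
        p = p + jd;
        v = v + omega * perp(jd);
        K.jpos[leg][s + 1] = p;
        K.jvel[leg][s + 1] = v;
      }
    }
  }
}

// world position & velocity of a local point on a body
inline void point_kin(const Model& M, const Kin& K, int leg, int seg,
                      double lx, double ly, const double* qd,
                      Vec2& p, Vec2& v) {
  if (seg == 0) {
    Vec2 d = rot(K.psi[0], Vec2(lx, ly));
    p = K.jpos[0][0] + d;
    v = K.jvel[0][0] + (-qd[2]) * perp(d);
    return;
  }
  int body = 1 + 4 * leg + (seg - 1);
  double omega = -qd[2];
  int qo = 3 + 4 * leg;
  for (int s = 0; s <= seg - 1; s++) omega += qd[qo + s];
  Vec2 d = rot(K.psi[body], Vec2(lx, ly));
  p = K.jpos[leg][seg - 1] + d;
  v = K.jvel[leg][seg - 1] + omega * perp(d);
}

// accumulate generalized force of a world force F applied at point p on
// (leg, seg); seg as in point_kin (0 = HAT)
inline void add_point_force(const Kin& K, int leg, int seg, Vec2 p, Vec2 F,
                            double* Q) {
  Q[0] += F.x;
  Q[1] += F.y;
  Q[2] -= cross(p - K.jpos[0][0], F);
  if (seg >= 1) {
    int qo = 3 + 4 * leg;
    for (int j = 0; j < seg && j < 4; j++)
      Q[qo + j] += cross(p - K.jpos[leg][j], F);
  }
}

struct Genome {  // per muscle: gamma, delta, mu1, mu2, s1, s2 + grid max
  int n;
  std::vector<double> g, d, m1, m2, s1, s2, amax;
};

inline double gauss2(const Genome& G, int m, double phi) {
  double a = 0;
  for (int im = -1; im <= 1; im++) {
    double ph = phi + im * TWOPI;
    double d1 = ph - G.m1[m], d2 = ph - G.m2[m];
    a += G.g[m] / (std::sqrt(TWOPI) * G.s1[m]) *
           std::exp(-d1 * d1 / (2.0 * G.s1[m])) +
         (1.0 - G.g[m]) / (std::sqrt(TWOPI) * G.s2[m]) *
           std::exp(-d2 * d2 / (2.0 * G.s2[m]));
  }
  return a;
}

Genome parse_genome(NumericMatrix gm, bool periodic) {
  Genome G;
  G.n = gm.nrow();
  for (int m = 0; m < G.n; m++) {
    G.g.push_back(gm(m, 0)); G.d.push_back(gm(m, 1));
    G.m1.push_back(gm(m, 2)); G.m2.push_back(gm(m, 3));
    G.s1.push_back(gm(m, 4)); G.s2.push_back(gm(m, 5));
    if (G.s1[m] <= 0 || G.s2[m] <= 0)
      stop("pattern width parameters must be > 0");
  }
  // normalization max on the fixed 2048-point phase grid
  for (int m = 0; m < G.n; m++) {
    double mx = 0;
    for (int k = 0; k < 2048; k++) {
      double phi = TWOPI * k / 2048.0;
      double a;
      if (periodic) a = gauss2(G, m, phi);
      else {
        double d1 = phi - G.m1[m], d2 = phi - G.m2[m];
        a = G.g[m] / (std::sqrt(TWOPI) * G.s1[m]) *
              std::exp(-d1 * d1 / (2.0 * G.s1[m])) +
            (1.0 - G.g[m]) / (std::sqrt(TWOPI) * G.s2[m]) *
              std::exp(-d2 * d2 / (2.0 * G.s2[m]));
      }
      if (a > mx) mx = a;
    }
    G.amax.push_back(mx > 0 ? mx : 1.0);
  }
  return G;
}

inline double pattern_act(const Genome& G, int m, double phi, bool periodic) {
  double a;
  if (periodic) a = gauss2(G, m, phi);
  else {
    double d1 = phi - G.m1[m], d2 = phi - G.m2[m];
    a = G.g[m] / (std::sqrt(TWOPI) * G.s1[m]) *
          std::exp(-d1 * d1 / (2.0 * G.s1[m])) +
        (1.0 - G.g[m]) / (std::sqrt(TWOPI) * G.s2[m]) *
          std::exp(-d2 * d2 / (2.0 * G.s2[m]));
  }
  return G.d[m] * a / G.amax[m];
}

}  // namespace

// [[Rcpp::export(name = ".sim_run")]]
List sim_run(List model, List control, NumericVector q0, NumericVector qd0,
             NumericVector phases0, double duration, double dt,
             int record_every, List options) {
  Model M = parse_model(model);
  const int NQ = 11;
  double q[NQ], qd[NQ];
  for (int i = 0; i < NQ; i++) { q[i] = q0[i]; qd[i] = qd0[i]; }
  double phi[2] = {phases0[0], phases0[1]};

  bool contact_on = as<bool>(options["contact_on"]);
  bool muscles_on = as<bool>(options["muscles_on"]);
  bool passive_on = as<bool>(options["passive_on"]);
  bool gravity_on = as<bool>(options["gravity_on"]);
  bool stop_on_fall = as<bool>(options["stop_on_fall"]);

  std::string ctrl_type = as<std::string>(control["type"]);
  bool use_cpg = (ctrl_type == "cpg");
  Genome G;
  double cpg_T = 0.747, cpg_K = 1.0, kappa = 5.0, theta_ref = 0.0;
  double ramp_time = 0.0;
  double reset_window = M_PI;
  bool periodic = true;
  NumericVector fixed_act(20);
  if (use_cpg) {
    G = parse_genome(as<NumericMatrix>(control["genome"]), true);
    List cpg = control["cpg"];
    cpg_T = as<double>(cpg["T"]); cpg_K = as<double>(cpg["K"]);
    List pf = control["posture"];
    kappa = as<double>(pf["kappa"]); theta_ref = as<double>(pf["theta_ref"]);
    if (control.containsElementNamed("periodic"))
      periodic = as<bool>(control["periodic"]);
    if (periodic != true) G = parse_genome(as<NumericMatrix>(control["genome"]), false);
    if (control.containsElementNamed("ramp_time"))
      ramp_time = as<double>(control["ramp_time"]);
    if (control.containsElementNamed("reset_window"))
      reset_window = as<double>(control["reset_window"]);
  } else {
    fixed_act = as<NumericVector>(control["activations"]);
    for (int i = 0; i < 20; i++)
      if (!(fixed_act[i] >= 0 && fixed_act[i] <= 1))
        stop("activations must be within [0, 1]");
  }
  double omega = TWOPI / cpg_T;

  int n_steps = (int)std::floor(duration / dt + 0.5);
  int n_rec = n_steps / record_every + 1;
  int ncp = M.cpts.size();

  // per-leg contact bookkeeping
  std::vector<double> anchor(2 * ncp, 0.0);
  std::vector<bool> incontact(2 * ncp, false);
  bool phal_enabled[2] = {true, true};
  bool stance[2] = {false, false};
  double last_trans[2] = {0.0, 0.0};

  std::vector<double> ev_time; std::vector<int> ev_leg, ev_type;

  // recorders
  NumericVector r_time(n_rec);
  NumericMatrix r_q(n_rec, NQ), r_qd(n_rec, NQ), r_phi(n_rec, 2),
      r_act(n_rec, 20), r_ftot(n_rec, 20), r_fact(n_rec, 20),
      r_fpe(n_rec, 20), r_len(n_rec, 20), r_grf(n_rec, 4), r_cop(n_rec, 2),
      r_com(n_rec, 2), r_vcom(n_rec, 2), r_stance(n_rec, 2);
  double Wpos[20] = {0}, Wneg[20] = {0};
  double jgrf_brake = 0.0;

  double total_mass = M.mass[0] + 2 * (M.mass[1] + M.mass[2] + M.mass[3] + M.mass[4]);

  Kin K;
  kinematics(M, q, qd, K);
  double standing_hat_com = K.com[0].y;
  double x_start = q[0];

  bool fell = false, nonfinite = false;
  double fall_time = NA_REAL;
  int rec_i = 0, step_count = 0;

  for (int istep = 0; istep <= n_steps; istep++) {
    kinematics(M, q, qd, K);

    // ---- contact forces ----
    double grf[2][2] = {{0, 0}, {0, 0}};  // [leg][vert, horz]
    double cop_num[2] = {0, 0};
    std::vector<Vec2> cforce(2 * ncp, Vec2());
    std::vector<Vec2> cpos(2 * ncp, Vec2());
    std::vector<int> cseg(2 * ncp, 3);
    double phal_brake[2] = {0, 0};
    if (contact_on) {
      for (int leg = 0; leg < 2; leg++) {
        for (int i = 0; i < ncp; i++) {
          const ContactPoint& cp = M.cpts[i];
          int idx = leg * ncp + i;
          Vec2 p, v;
          point_kin(M, K, leg, cp.seg, cp.lx, cp.ly, qd, p, v);
          cpos[idx] = p; cseg[idx] = cp.seg;
          bool enabled = !cp.phal || phal_enabled[leg];
          if (enabled && p.y < 0) {
            if (!incontact[idx]) { incontact[idx] = true; anchor[idx] = p.x; }
            double fy = M.k_vert * (-p.y) + M.c_vert * (-v.y);
            if (fy < 0) fy = 0;
            double fx = -M.k_horz * (p.x - anchor[idx]) - M.c_horz * v.x;
            cforce[idx] = Vec2(fx, fy);
            grf[leg][0] += fy; grf[leg][1] += fx;
            cop_num[leg] += fy * p.x;
            if (cp.phal && fx < 0) phal_brake[leg] += -fx;
          } else {
            incontact[idx] = false;
          }
        }
      }
    }

    // ---- contact events, swing policy, phase resetting ----
    double tnow = istep * dt;
    for (int leg = 0; leg < 2; leg++) {
      bool loaded = grf[leg][0] > M.grf_thr;
      if (istep == 0) { stance[leg] = loaded; continue; }
      if (loaded != stance[leg] && tnow - last_trans[leg] >= M.debounce) {
        stance[leg] = loaded;
        last_trans[leg] = tnow;
        ev_time.push_back(tnow);
        ev_leg.push_back(leg);
        ev_type.push_back(loaded ? 1 : 2);  // 1 touchdown, 2 toe-off
        if (loaded) {
          // touchdown: reset this leg's oscillator phase.  The reset is
          // accepted only in the late half of the cycle (phi >= pi), i.e.
          // for genuine post-swing contacts; penalty-contact chatter around
          // mid-stance must not resynchronize the two oscillators.
          if (use_cpg && phi[leg] >= reset_window) phi[leg] = 0.0;
          phal_enabled[leg] = true;
        } else {       // toe-off: allow phalangeal penetration during swing
          phal_enabled[leg] = false;
        }
      }
    }

    // ---- controller ----
    double act[20];
    if (use_cpg) {
      // soft start: pattern drive ramps in over ramp_time so the standing
      // model eases into the gait instead of firing a full stance burst
      double ramp = (ramp_time > 0 && tnow < ramp_time) ? tnow / ramp_time
                                                        : 1.0;
      for (int leg = 0; leg < 2; leg++)
        for (int m = 0; m < 10; m++)
          act[10 * leg + m] = ramp * pattern_act(G, m, phi[leg], periodic);
      // trunk posture feedback through hip uniarticular muscles of support legs
      double pitch = q[2];
      if (!std::isfinite(pitch)) { nonfinite = true; }
      double a_il = kappa * std::max(theta_ref - pitch, 0.0);
      double a_gl = kappa * std::max(pitch - theta_ref, 0.0);
      for (int leg = 0; leg < 2; leg++) {
        if (grf[leg][0] > M.grf_thr) {
          act[10 * leg + 0] += a_il;  // IL
          act[10 * leg + 1] += a_gl;  // GMED
        }
      }
      for (int i = 0; i < 20; i++)
        act[i] = std::min(1.0, std::max(0.0, act[i]));
    } else {
      for (int i = 0; i < 20; i++) act[i] = fixed_act[i];
    }
    if (!muscles_on) for (int i = 0; i < 20; i++) act[i] = 0;

    // ---- muscle lengths, forces, joint torques ----
    double tau[8] = {0};  // R hip knee ankle mp, L ...
    double flen[20], ftot[20], fact[20], fpe[20], ldot[20];
    int nm = M.muscles.size();
    for (int leg = 0; leg < 2; leg++) {
      for (int m = 0; m < nm; m++) {
        const Muscle& mu = M.muscles[m];
        int k = 10 * leg + m;
        int np = mu.path.size();
        std::vector<Vec2> pts(np), vts(np);
        for (int i = 0; i < np; i++)
          point_kin(M, K, leg, mu.path[i].seg, mu.path[i].lx, mu.path[i].ly,
                    qd, pts[i], vts[i]);
        double L = 0, Ld = 0;
        double dLdq[4] = {0, 0, 0, 0};
        for (int i = 0; i + 1 < np; i++) {
          Vec2 seg = pts[i + 1] - pts[i];
          double sl = std::sqrt(dot(seg, seg));
          L += sl;
          Vec2 u = (1.0 / sl) * seg;
          Ld += dot(u, vts[i + 1] - vts[i]);
          for (int j = 0; j < 4; j++) {
            if (!mu.span[j]) continue;
            Vec2 piv = K.jpos[leg][j];
            Vec2 da = (mu.path[i].seg - 1 >= j) ? perp(pts[i] - piv) : Vec2();
            Vec2 db = (mu.path[i + 1].seg - 1 >= j) ? perp(pts[i + 1] - piv) : Vec2();
            dLdq[j] += dot(u, db - da);
          }
        }
        flen[k] = L; ldot[k] = Ld;
        double pe = M.pe_k1 * (std::exp(M.pe_k2 * (L - mu.rest_length)) - 1.0);
        if (M.pe_clamp && pe < 0) pe = 0;
        double fa = muscles_on ? mu.f_max * act[k] : 0.0;
        if (!muscles_on) pe = 0;
        fpe[k] = pe; fact[k] = fa; ftot[k] = fa + pe;
        if (muscles_on)
          for (int j = 0; j < 4; j++)
            if (mu.span[j]) tau[4 * leg + j] -= ftot[k] * dLdq[j];
        // mechanical work of the contractile element
        double pwr = fa * (-Ld);
        if (pwr > 0) Wpos[k] += pwr * dt; else Wneg[k] += pwr * dt;
      }
    }

    // ---- passive joint moments ----
    double kstop_stiff[2] = {0, 0};
    if (passive_on) {
      for (int leg = 0; leg < 2; leg++) {
        for (int j = 0; j < 4; j++)
          tau[4 * leg + j] -= M.visc[j] * qd[3 + 4 * leg + j];
        double th = q[3 + 4 * leg + 1];
        double ex = -M.ks_k2 * (M.ks_k3 - th);
        if (ex > 25.0) ex = 25.0;  // cap the stop torque (~7e10 scaled by k1)
        double Tknee = -M.ks_k1 * std::exp(ex);
        tau[4 * leg + 1] += Tknee;
        kstop_stiff[leg] = M.ks_k2 * M.ks_k1 * std::exp(ex);
      }
    }

    // ---- record ----
    if (istep % record_every == 0 && rec_i < n_rec) {
      Vec2 com(0, 0), vcom(0, 0);
      double msum = 0;
      for (int b = 0; b < 9; b++) {
        int seg = (b == 0) ? 0 : 1 + (b - 1) % 4;
        com = com + M.mass[seg] * K.com[b];
        vcom = vcom + M.mass[seg] * K.comv[b];
        msum += M.mass[seg];
      }
      com = (1.0 / msum) * com; vcom = (1.0 / msum) * vcom;
      r_time[rec_i] = tnow;
      for (int i = 0; i < NQ; i++) { r_q(rec_i, i) = q[i]; r_qd(rec_i, i) = qd[i]; }
      r_phi(rec_i, 0) = phi[0]; r_phi(rec_i, 1) = phi[1];
      for (int i = 0; i < 20; i++) {
        r_act(rec_i, i) = act[i]; r_ftot(rec_i, i) = ftot[i];
        r_fact(rec_i, i) = fact[i]; r_fpe(rec_i, i) = fpe[i];
        r_len(rec_i, i) = flen[i];
      }
      for (int leg = 0; leg < 2; leg++) {
        r_grf(rec_i, 2 * leg) = grf[leg][0];
        r_grf(rec_i, 2 * leg + 1) = grf[leg][1];
        r_cop(rec_i, leg) = grf[leg][0] > 0 ? cop_num[leg] / grf[leg][0]
                                            : NA_REAL;
        r_stance(rec_i, leg) = stance[leg] ? 1.0 : 0.0;
      }
      r_com(rec_i, 0) = com.x; r_com(rec_i, 1) = com.y;
      r_vcom(rec_i, 0) = vcom.x; r_vcom(rec_i, 1) = vcom.y;
      rec_i++;
    }
    step_count = istep;

    // ---- fall / termination checks ----
    double hat_y = K.com[0].y;
    if (stop_on_fall &&
        (hat_y <= M.fall_height_frac * standing_hat_com ||
         std::fabs(q[2]) >= M.fall_pitch_max)) {
      fell = true; fall_time = tnow; break;
    }
    for (int i = 0; i < NQ; i++)
      if (!std::isfinite(q[i]) || !std::isfinite(qd[i])) nonfinite = true;
    if (nonfinite) { fell = true; fall_time = tnow; break; }
    if (istep == n_steps) break;

    // ---- GRF objective accumulator (braking on phalanges, pi<=phi<=2pi) ----
    for (int leg = 0; leg < 2; leg++)
      if (phi[leg] >= M_PI) jgrf_brake += phal_brake[leg] * dt;

    // ---- assemble M(q), bias, Q; integrate ----
    arma::mat Mm(NQ, NQ, arma::fill::zeros);
    double Q[NQ] = {0};

    for (int b = 0; b < 9; b++) {
      int seg = (b == 0) ? 0 : 1 + (b - 1) % 4;
      int leg = (b == 0) ? 0 : (b - 1) / 4;
      double mass = M.mass[seg], moi = M.moi[seg];
      // Jacobian columns of the COM point: (col index, 2-vector)
      int cols[6]; Vec2 Jc[6]; double asign[6];
      int nc = 0;
      cols[nc] = 0; Jc[nc] = Vec2(1, 0); asign[nc] = 0; nc++;
      cols[nc] = 1; Jc[nc] = Vec2(0, 1); asign[nc] = 0; nc++;
      cols[nc] = 2; Jc[nc] = -1.0 * perp(K.com[b] - K.jpos[0][0]);
      asign[nc] = -1; nc++;
      if (b > 0) {
        int qo = 3 + 4 * leg;
        int depth = (b - 1) % 4;  // 0 thigh .. 3 phal
        for (int j = 0; j <= depth; j++) {
          cols[nc] = qo + j;
          Jc[nc] = perp(K.com[b] - K.jpos[leg][j]);
          asign[nc] = 1; nc++;
        }
      }
      // mass matrix contribution
      for (int a = 0; a < nc; a++)
        for (int c = 0; c < nc; c++)
          Mm(cols[a], cols[c]) += mass * dot(Jc[a], Jc[c]) +
                                  moi * asign[a] * asign[c];
      // bias: Jdot * qd for translational part (angular Jacobian constant)
      Vec2 u(0, 0);
      for (int a = 0; a < nc; a++) {
        if (cols[a] < 2) continue;
        Vec2 vpiv = (cols[a] == 2) ? K.jvel[0][0]
                                   : K.jvel[leg][cols[a] - (3 + 4 * leg)];
        double s = (cols[a] == 2) ? -1.0 : 1.0;
        u = u + (s * qd[cols[a]]) * perp(K.comv[b] - vpiv);
      }
      for (int a = 0; a < nc; a++) Q[cols[a]] -= mass * dot(Jc[a], u);
      // gravity
      if (gravity_on) {
        Vec2 Fg(0, -mass * M.gravity);
        for (int a = 0; a < nc; a++) Q[cols[a]] += dot(Jc[a], Fg);
      }
    }
    // joint torques
    for (int leg = 0; leg < 2; leg++)
      for (int j = 0; j < 4; j++)
        Q[3 + 4 * leg + j] += tau[4 * leg + j];
    // contact forces
    if (contact_on)
      for (int leg = 0; leg < 2; leg++)
        for (int i = 0; i < ncp; i++) {
          int idx = leg * ncp + i;
          if (cforce[idx].x != 0 || cforce[idx].y != 0)
            add_point_force(K, leg, cseg[idx], cpos[idx], cforce[idx], Q);
        }

    // implicit treatment of joint viscosity + knee stop stiffness
    arma::mat LHS = Mm;
    arma::vec rhs(NQ);
    for (int i = 0; i < NQ; i++) rhs(i) = 0;
    if (passive_on) {
      for (int leg = 0; leg < 2; leg++) {
        for (int j = 0; j < 4; j++) {
          int col = 3 + 4 * leg + j;
          LHS(col, col) += dt * M.visc[j];
        }
        int kc = 3 + 4 * leg + 1;
        LHS(kc, kc) += dt * dt * kstop_stiff[leg];
      }
    }
    arma::vec v(NQ);
    for (int i = 0; i < NQ; i++) v(i) = qd[i];
    arma::vec extra = (LHS - Mm) * v;  // (hD + h^2 K) v
    arma::vec qv(NQ);
    for (int i = 0; i < NQ; i++) rhs(i) = dt * Q[i] + extra(i);
    rhs += Mm * v;
    bool ok = arma::solve(qv, LHS, rhs, arma::solve_opts::fast);
    if (!ok) { nonfinite = true; fell = true; fall_time = tnow; break; }
    for (int i = 0; i < NQ; i++) { qd[i] = qv(i); q[i] += dt * qd[i]; }

    // ---- oscillator phases (Euler on Eq. of the rhythm generator) ----
    if (use_cpg) {
      double dR = omega - cpg_K * std::sin(phi[0] - phi[1] - M_PI);
      double dL = omega - cpg_K * std::sin(phi[1] - phi[0] - M_PI);
      phi[0] += dt * dR;
      phi[1] += dt * dL;
      // wrap into [0, 2pi) without fmod (keeps the binary portable across
      // glibc versions)
      phi[0] -= TWOPI * std::floor(phi[0] / TWOPI);
      phi[1] -= TWOPI * std::floor(phi[1] / TWOPI);
    }
  }

  // trim recorders
  int nr = rec_i;
  NumericVector state_q(NQ), state_qd(NQ);
  for (int i = 0; i < NQ; i++) { state_q[i] = q[i]; state_qd[i] = qd[i]; }

  List out = List::create(
      _["time"] = r_time, _["q"] = r_q, _["qd"] = r_qd, _["phases"] = r_phi,
      _["act"] = r_act, _["f_total"] = r_ftot, _["f_active"] = r_fact,
      _["f_pe"] = r_fpe, _["muscle_len"] = r_len, _["grf"] = r_grf,
      _["cop"] = r_cop, _["stance"] = r_stance, _["com"] = r_com,
      _["vcom"] = r_vcom,
      _["n_rec"] = nr,
      _["events"] = List::create(_["time"] = wrap(ev_time),
                                 _["leg"] = wrap(ev_leg),
                                 _["type"] = wrap(ev_type)),
      _["Wpos"] = NumericVector(Wpos, Wpos + 20),
      _["Wneg"] = NumericVector(Wneg, Wneg + 20),
      _["distance"] = q[0] - x_start,
      _["fell"] = fell, _["fall_time"] = fall_time,
      _["nonfinite"] = nonfinite,
      _["t_end"] = step_count * dt,
      _["jgrf_brake"] = jgrf_brake,
      _["final_q"] = state_q, _["final_qd"] = state_qd,
      _["final_phases"] = NumericVector::create(phi[0], phi[1]),
      _["total_mass"] = total_mass,
      _["standing_hat_com"] = standing_hat_com);
  return out;
}
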