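#include <Rcpp.h>
using namespace Rcpp;

// Deterministic 60 Hz game engine with built-in potential-field steering
// agents. The R-level step_physics()/run_trial() implement the identical
// update rule for arbitrary R controllers; equivalence is asserted in the
// test suite.

static inline void clamp_mag(double &x, double &y, double m) {
  double n = std::sqrt(x * x + y * y);
  if (n > m && n > 0) { x *= m / n; y *= m / n; }
}

// distance from point to border of rotated rectangle (0 inside)
static inline double rect_dist(double px, double py, const double *r) {
  double ca = std::cos(r[2]), sa = std::sin(r[2]);
  double dx = px - r[0], dy = py - r[1];
  double lx = std::fabs(ca * dx + sa * dy) - r[3];
  double ly = std::fabs(-sa * dx + ca * dy) - r[4];
  lx = lx > 0 ? lx : 0; ly = ly > 0 ? ly : 0;
  return std::sqrt(lx * lx + ly * ly);
}

// closest point on rectangle border/interior to p, in world coords
static inline void rect_closest(double px, double py, const double *r,
                                double &qx, double &qy) {
  double ca = std::cos(r[2]), sa = std::sin(r[2]);
  double dx = px - r[0], dy = py - r[1];
  double lx = ca * dx + sa * dy, ly = -sa * dx + ca * dy;
  double cx = std::max(-r[3], std::min(r[3], lx));
  double cy = std::max(-r[4], std::min(r[4], ly));
  qx = r[0] + ca * cx - sa * cy;
  qy = r[1] + sa * cx + ca * cy;
}

struct Agent {
  double goal_gain, partner_gain, skill, exploration, p_learn;
  double avoid_gain, avoid_radius, cap, noise_phi;
  int delay;
  std::vector<bool> known;
  int goal;        // 0-based index into targets
  double noise_th; // AR(1) steering-wobble state (radians)
};

static Agent make_agent(List a) {
  Agent ag;
  ag.goal_gain = as<double>(a["goal_gain"]);
  ag.partner_gain = as<double>(a["partner_gain"]);
  ag.skill = as<double>(a["skill"]);
  ag.exploration = as<double>(a["exploration"]);
  ag.p_learn = as<double>(a["p_learn"]);
  ag.avoid_gain = as<double>(a["avoid_gain"]);
  ag.avoid_radius = as<double>(a["avoid_radius"]);
  ag.cap = as<double>(a["cap"]);
  ag.delay = as<int>(a["delay"]);
  ag.noise_phi = as<double>(a["noise_phi"]);
  LogicalVector vis = a["visible"];
  ag.known.assign(vis.begin(), vis.end());
  ag.goal = -1;
  ag.noise_th = 0;
  return ag;
}

// pick a goal among active targets: nearest, or (with prob exploration)
// a uniformly random other active target
static void pick_goal(Agent &ag, const std::vector<int> &active,
                      const NumericMatrix &targets, double bx, double by) {
  int best = active[0];
  double bd = R_PosInf;
  for (size_t k = 0; k < active.size(); ++k) {
    double dx = targets(active[k], 0) - bx, dy = targets(active[k], 1) - by;
    double d = dx * dx + dy * dy;
    if (d < bd) { bd = d; best = active[k]; }
  }
  ag.goal = best;
  if (ag.exploration > 0 && unif_rand() < ag.exploration) {
    std::vector<int> others;
    for (size_t k = 0; k < active.size(); ++k)
      if (active[k] != best) others.push_back(active[k]);
    if (!others.empty())
      ag.goal = others[(int)(unif_rand() * others.size()) % others.size()];
  }
}

static void agent_input(Agent &ag, const NumericMatrix &targets,
                        const NumericMatrix &obst, int n_obst,
                        double bx, double by,
                        double pfx, double pfy, bool have_partner,
                        double &ix, double &iy) {
  double gx = targets(ag.goal, 0) - bx, gy = targets(ag.goal, 1) - by;
  double gn = std::sqrt(gx * gx + gy * gy);
  if (gn > 1e-12) { gx /= gn; gy /= gn; } else { gx = gy = 0; }
  double ax = 0, ay = 0;
  std::vector<double> row(5);
  for (int k = 0; k < n_obst; ++k) {
    if (!ag.known[k]) continue;
    for (int j = 0; j < 5; ++j) row[j] = obst(k, j);
    double d = rect_dist(bx, by, row.data());
    if (d < ag.avoid_radius) {
      double qx, qy;
      rect_closest(bx, by, row.data(), qx, qy);
      double rx = bx - qx, ry = by - qy;
      double rn = std::sqrt(rx * rx + ry * ry);
      if (rn < 1e-12) { rx = bx - row[0]; ry = by - row[1];
                        rn = std::sqrt(rx * rx + ry * ry); }
      if (rn > 1e-12) {
        double w = ag.avoid_gain * (1.0 - d / ag.avoid_radius);
        rx /= rn; ry /= rn;
        // tangential slide along the obstacle, on the side of the goal
        double tx = -ry, ty = rx;
        if (tx * gx + ty * gy < 0) { tx = -tx; ty = -ty; }
        ax += w * (0.6 * rx + 0.8 * tx);
        ay += w * (0.6 * ry + 0.8 * ty);
      }
    }
  }
  double px = 0, py = 0;
  if (have_partner && ag.partner_gain > 0) {
    double pn = std::sqrt(pfx * pfx + pfy * pfy);
    if (pn > 1e-12) { px = pfx / pn; py = pfy / pn; }
  }
  double rx = ag.goal_gain * gx + ag.partner_gain * px + ax;
  double ry = ag.goal_gain * gy + ag.partner_gain * py + ay;
  if (ag.skill > 0) {
    // smooth AR(1) steering wobble with stationary SD = skill
    ag.noise_th = ag.noise_phi * ag.noise_th +
      norm_rand() * ag.skill * std::sqrt(1 - ag.noise_phi * ag.noise_phi);
    double th = ag.noise_th;
    double ca = std::cos(th), sa = std::sin(th);
    double tx = ca * rx - sa * ry, ty = sa * rx + ca * ry;
    rx = tx; ry = ty;
  }
  double rn = std::sqrt(rx * rx + ry * ry);
  if (rn > 1e-12) { ix = ag.cap * rx / rn; iy = ag.cap * ry / rn; }
  else { ix = iy = 0; }
}

// [[Rcpp::export]]
List cpp_run_trial(NumericMatrix targets, IntegerVector initial_active,
                   int inactive, NumericMatrix obstacles, List phys,
                   bool joint, List agent1, List agent2, int n_frames) {
  const double dt = as<double>(phys["dt"]);
  const double drag = as<double>(phys["drag"]);
  const double gain = as<double>(phys["gain"]);
  const double vmax = as<double>(phys["vmax"]);
  const double cap_player = as<double>(phys["cap_player"]);
  const double cap_force = as<double>(phys["cap_force"]);
  const double obf = as<double>(phys["obstacle_factor"]);
  const double lim = as<double>(phys["arena_half"]) -
    as<double>(phys["ball_radius"]);
  const double ball_r = as<double>(phys["ball_radius"]);
  const double collect_r = as<double>(phys["target_radius"]) + ball_r;
  const int n_obst = obstacles.nrow();

  Agent ag1 = make_agent(agent1);
  Agent ag2 = make_agent(agent2);

  std::vector<int> active;
  for (int k = 0; k < initial_active.size(); ++k)
    active.push_back(initial_active[k] - 1);
  int inact = inactive - 1;

  double bx = 0, by = 0, vx = 0, vy = 0;
  pick_goal(ag1, active, targets, bx, by);
  if (joint) pick_goal(ag2, active, targets, bx, by);

  NumericMatrix frames(n_frames, 13);
  std::vector<int> ev_frame, ev_target;
  std::vector<double> h1x(n_frames), h1y(n_frames), h2x(n_frames),
      h2y(n_frames);
  std::vector<double> row(5);

  for (int t = 0; t < n_frames; ++t) {
    // nearest obstacle at frame start
    double nd = R_PosInf; int nk = 0;
    for (int k = 0; k < n_obst; ++k) {
      for (int j = 0; j < 5; ++j) row[j] = obstacles(k, j);
      double d = rect_dist(bx, by, row.data());
      if (d < nd) { nd = d; nk = k; }
    }
    bool on_obs = nd <= ball_r;

    double i1x, i1y, i2x = 0, i2y = 0;
    double p2fx = 0, p2fy = 0, p1fx = 0, p1fy = 0;
    bool hp1 = false, hp2 = false;
    // partner term: the partner's input `delay` frames back (>= 1 frame,
    // since the current frame's inputs are not yet known)
    int s1 = t - std::max(ag1.delay, 1);
    if (joint && s1 >= 0) { p2fx = h2x[s1]; p2fy = h2y[s1]; hp1 = true; }
    int s2 = t - std::max(ag2.delay, 1);
    if (joint && s2 >= 0) { p1fx = h1x[s2]; p1fy = h1y[s2]; hp2 = true; }
    agent_input(ag1, targets, obstacles, n_obst, bx, by, p2fx, p2fy, hp1,
                i1x, i1y);
    if (joint)
      agent_input(ag2, targets, obstacles, n_obst, bx, by, p1fx, p1fy, hp2,
                  i2x, i2y);

    // within-trial learning: unexplained slowdown reveals a hidden obstacle
    if (on_obs) {
      if (!ag1.known[nk] && ag1.p_learn > 0 && unif_rand() < ag1.p_learn)
        ag1.known[nk] = true;
      if (joint && !ag2.known[nk] && ag2.p_learn > 0 &&
          unif_rand() < ag2.p_learn)
        ag2.known[nk] = true;
    }

    clamp_mag(i1x, i1y, cap_player);
    if (joint) clamp_mag(i2x, i2y, cap_player);
    double fx = i1x + (joint ? i2x : 0.0);
    double fy = i1y + (joint ? i2y : 0.0);
    clamp_mag(fx, fy, cap_force);

    frames(t, 0) = bx; frames(t, 1) = by;
    frames(t, 2) = vx; frames(t, 3) = vy;
    frames(t, 4) = i1x; frames(t, 5) = i1y;
    frames(t, 6) = i2x; frames(t, 7) = i2y;
    frames(t, 8) = fx; frames(t, 9) = fy;
    frames(t, 10) = on_obs ? 1.0 : 0.0;
    frames(t, 11) = nk + 1;  // index into active-obstacle rows
    frames(t, 12) = nd;
    h1x[t] = i1x; h1y[t] = i1y; h2x[t] = i2x; h2y[t] = i2y;

    vx += (gain * fx - drag * vx) * dt;
    vy += (gain * fy - drag * vy) * dt;
    clamp_mag(vx, vy, vmax);
    double fac = on_obs ? obf : 1.0;
    bx += vx * dt * fac;
    by += vy * dt * fac;
    if (bx > lim) { bx = lim; vx = 0; }
    if (bx < -lim) { bx = -lim; vx = 0; }
    if (by > lim) { by = lim; vy = 0; }
    if (by < -lim) { by = -lim; vy = 0; }

    // collection: nearest active target within reach
    int hit = -1; double hd = R_PosInf;
    for (size_t k = 0; k < active.size(); ++k) {
      double dx = targets(active[k], 0) - bx;
      double dy = targets(active[k], 1) - by;
      double d = std::sqrt(dx * dx + dy * dy);
      if (d < collect_r && d < hd) { hd = d; hit = (int)k; }
    }
    if (hit >= 0) {
      int collected = active[hit];
      active[hit] = inact;
      inact = collected;
      ev_frame.push_back(t);
      ev_target.push_back(collected + 1);
      pick_goal(ag1, active, targets, bx, by);
      if (joint) pick_goal(ag2, active, targets, bx, by);
    }
  }

  return List::create(
      _["frames"] = frames,
      _["event_frame"] = wrap(ev_frame),
      _["event_target"] = wrap(ev_target));
}

// column-wise average ranks (ties share the mean rank), for the WLCC
// [[Rcpp::export]]
NumericMatrix cpp_colranks(NumericMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  NumericMatrix out(nr, nc);
  std::vector<int> idx(nr);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) idx[i] = i;
    NumericMatrix::Column col = m(_, j);
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return col[a] < col[b]; });
    int i = 0;
    while (i < nr) {
      int k = i;
      while (k + 1 < nr && col[idx[k + 1]] == col[idx[i]]) ++k;
      double r = (i + k) / 2.0 + 1.0;
      for (int t = i; t <= k; ++t) out(idx[t], j) = r;
      i = k + 1;
    }
  }
  return out;
}
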