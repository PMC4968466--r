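#include <Rcpp.h>
using namespace Rcpp;

// Von Mises(0, c) draw by the Best-Fisher rejection scheme; uses R's RNG so
// results are reproducible under set.seed(). c = 0 falls back to uniform.
static double vm_draw(double c) {
  if (c < 1e-8) return R::unif_rand() * 2.0 * M_PI - M_PI;
  const double tau = 1.0 + std::sqrt(1.0 + 4.0 * c * c);
  const double rho = (tau - std::sqrt(2.0 * tau)) / (2.0 * c);
  const double r = (1.0 + rho * rho) / (2.0 * rho);
  double f = 0.0;
  for (;;) {
    double u1 = R::unif_rand();
    double z = std::cos(M_PI * u1);
    f = (1.0 + r * z) / (r + z);
    double cc = c * (r - f);
    double u2 = R::unif_rand();
    if (cc * (2.0 - cc) - u2 > 0.0) break;
    if (std::log(cc / u2) + 1.0 - cc >= 0.0) break;
  }
  double u3 = R::unif_rand();
  double th = std::acos(f);
  return (u3 > 0.5) ? th : -th;
}

static inline double wrap_angle(double a) {
  // reduce to (-pi, pi] without fmod (keeps the binary portable across
  // older C libraries); floor-based reduction is exact enough at these
  // magnitudes since |a| never exceeds a few multiples of pi per step
  a -= 2.0 * M_PI * std::floor((a + M_PI) / (2.0 * M_PI));
  if (a <= -M_PI) a = M_PI;
  return a;
}

// [[Rcpp::export]]
NumericVector cpp_vonmises(int n, double concentration) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = vm_draw(concentration);
  return out;
}

// Force of one well at (x, y): Keplerian outside the core, harmonic inside.
static inline void well_force_at(double x, double y, double wx, double wy,
                                 double V0, double sigma,
                                 double &fx, double &fy) {
  double dx = wx - x, dy = wy - y;
  double d = std::sqrt(dx * dx + dy * dy);
  if (d == 0.0) { fx = 0.0; fy = 0.0; return; }
  double mag = (d >= sigma) ? V0 * sigma / (d * d) : V0 * d / (sigma * sigma);
  fx = mag * dx / d;
  fy = mag * dy / d;
}

// One walker of the overdamped Langevin stop-and-run model.
//  wells: matrix with columns x, y, V0, sigma. skip: wells this walker ignores
//  (treated as visited from the start). use_wells = false disables the whole
//  reactive machinery (RW / CRW presets).
// [[Rcpp::export]]
List cpp_run_walker(double x0, double y0, double theta0,
                    NumericMatrix wells, LogicalVector skip, bool use_wells,
                    double dt, double sample_every, double gamma_,
                    double beta, double kappa, double lifetime,
                    double arena_w, double arena_h, bool record_raw) {
  const int nw = wells.nrow();
  std::vector<bool> visited(nw, false);
  int n_skipped = 0;
  for (int j = 0; j < nw; ++j) if (skip[j]) { visited[j] = true; ++n_skipped; }
  int trapped = -1;               // 0-based well index, -1 = free
  int n_visited = 0;              // genuinely visited (excludes skipped)

  const int nsteps = (int)std::floor(lifetime / dt + 1e-9);
  const int k = std::max(1, (int)std::lround(sample_every / dt));
  const double conc = (kappa > 0.0) ? kappa / dt : 0.0;
  const double noise_v = std::sqrt(2.0 * beta / dt);  // |F_A| scale per rho

  double x = x0, y = y0, theta = theta0;
  double wR = 0.0, wA = 0.0, power_total = 0.0;
  std::string term = "lifetime";

  std::vector<double> st, sx, sy;                  // sampled fixes
  st.reserve(nsteps / k + 2);
  sx.reserve(nsteps / k + 2); sy.reserve(nsteps / k + 2);
  st.push_back(0.0); sx.push_back(x); sy.push_back(y);

  std::vector<double> rt, rx, ry, rfrx, rfry, rfax, rfay, rvx, rvy;
  if (record_raw) {
    rt.reserve(nsteps); rx.reserve(nsteps); ry.reserve(nsteps);
    rfrx.reserve(nsteps); rfry.reserve(nsteps);
    rfax.reserve(nsteps); rfay.reserve(nsteps);
    rvx.reserve(nsteps); rvy.reserve(nsteps);
  }

  int step = 0;
  double age = 0.0;
  for (step = 1; step <= nsteps; ++step) {
    // reactive force at the current position
    double frx = 0.0, fry = 0.0;
    if (use_wells) {
      if (trapped >= 0) {
        well_force_at(x, y, wells(trapped, 0), wells(trapped, 1),
                      wells(trapped, 2), wells(trapped, 3), frx, fry);
      } else {
        for (int j = 0; j < nw; ++j) {
          if (visited[j]) continue;
          double fx, fy;
          well_force_at(x, y, wells(j, 0), wells(j, 1), wells(j, 2),
                        wells(j, 3), fx, fy);
          frx += fx; fry += fy;
        }
      }
    }
    // active force: Rayleigh modulus, Von Mises heading increment (heading
    // keeps updating while trapped, enabling Kramers escape)
    theta = wrap_angle(theta + vm_draw(conc));
    double rho = (beta > 0.0) ? std::sqrt(-2.0 * std::log(R::unif_rand())) : 0.0;
    double fax = noise_v * rho * std::cos(theta);
    double fay = noise_v * rho * std::sin(theta);

    double vx = (frx + fax) / gamma_;
    double vy = (fry + fay) / gamma_;
    x += vx * dt;
    y += vy * dt;
    age = step * dt;

    wR += (frx * vx + fry * vy) * dt;
    wA += (fax * vx + fay * vy) * dt;
    power_total += gamma_ * (vx * vx + vy * vy) * dt;

    if (record_raw) {
      rt.push_back(age); rx.push_back(x); ry.push_back(y);
      rfrx.push_back(frx); rfry.push_back(fry);
      rfax.push_back(fax); rfay.push_back(fay);
      rvx.push_back(vx); rvy.push_back(vy);
    }

    // border crossing: detected, not clamped; the outside fix is not sampled
    if (x < 0.0 || x > arena_w || y < 0.0 || y > arena_h) {
      term = "border";
      break;
    }

    // trapping / memory update at the new position
    if (use_wells) {
      if (trapped >= 0) {
        double dxw = wells(trapped, 0) - x, dyw = wells(trapped, 1) - y;
        double d = std::sqrt(dxw * dxw + dyw * dyw);
        if (d > wells(trapped, 3)) {
          visited[trapped] = true;
          ++n_visited;
          trapped = -1;
        }
      } else {
        int pick = -1; double best = R_PosInf;
        for (int j = 0; j < nw; ++j) {
          if (visited[j]) continue;
          double dxw = wells(j, 0) - x, dyw = wells(j, 1) - y;
          double d = std::sqrt(dxw * dxw + dyw * dyw);
          if (d < wells(j, 3) && d < best) { best = d; pick = j; }
        }
        if (pick >= 0) trapped = pick;
      }
      if (n_visited + n_skipped == nw && nw > 0) {
        term = "all_visited";
      }
    }

    if (step % k == 0) { st.push_back(age); sx.push_back(x); sy.push_back(y); }

    if (term != "lifetime") break;
  }

  List raw = R_NilValue;
  if (record_raw) {
    raw = DataFrame::create(_["t"] = rt, _["x"] = rx, _["y"] = ry,
                            _["F_Rx"] = rfrx, _["F_Ry"] = rfry,
                            _["F_Ax"] = rfax, _["F_Ay"] = rfay,
                            _["vx"] = rvx, _["vy"] = rvy);
  }
  return List::create(
    _["t"] = st, _["x"] = sx, _["y"] = sy,
    _["age"] = age, _["termination"] = term,
    _["work_R"] = wR, _["work_A"] = wA, _["power_total"] = power_total,
    _["n_visited"] = n_visited, _["raw"] = raw);
}

// Residence times (entry to exit of the sigma-core) of a particle diffusing
// in a single well with no visit memory: the two-dimensional Kramers set-up.
// The episode in progress at t = 0 (the particle starts at the centre) is
// discarded; only full entry-to-exit episodes are returned.
// [[Rcpp::export]]
NumericVector cpp_trapping_times(double V0, double sigma, double beta,
                                 double dt, int n_events, double max_steps) {
  std::vector<double> times;
  times.reserve(n_events);
  double x = 0.0, y = 0.0;          // well at the origin, start at the centre
  const double noise_v = std::sqrt(2.0 * beta / dt);
  bool inside = true;               // starts inside: first episode discarded
  bool armed = false;               // becomes true at the first fresh entry
  double entry_t = 0.0;
  double t = 0.0;
  for (double step = 0; step < max_steps && (int)times.size() < n_events;
       ++step) {
    double frx, fry;
    well_force_at(x, y, 0.0, 0.0, V0, sigma, frx, fry);
    double th = R::unif_rand() * 2.0 * M_PI - M_PI;
    double rho = std::sqrt(-2.0 * std::log(R::unif_rand()));
    double vx = frx + noise_v * rho * std::cos(th);
    double vy = fry + noise_v * rho * std::sin(th);
    x += vx * dt;
    y += vy * dt;
    t += dt;
    double d = std::sqrt(x * x + y * y);
    if (inside && d > sigma) {
      if (armed) times.push_back(t - entry_t);
      inside = false;
    } else if (!inside && d < sigma) {
      inside = true;
      armed = true;
      entry_t = t;
    }
    if ((long)step % 1048576 == 0) Rcpp::checkUserInterrupt();
  }
  return wrap(times);
}
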