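// Agent-based model of cognate T-cells searching a spherical lymph-node
// paracortex for antigen-carrying dendritic cells.
//
// T-cells run-and-tumble (exponential free path, uniform new direction) at
// speed v inside a reflective sphere of radius R; DCs appear at their arrival
// times, are active for dc_lifetime, and are stationary unless w > 0.  A
// contact starts when centre separation first drops below b and cannot
// restart for the same pair until separation exceeds b again.  Each contact
// at time t succeeds with P(Binom(N, A(t)) >= T), where A(t) is the cognate
// bound fraction decayed from the DC's own dermal departure.  Because antigen
// only decays, a cell's activation probability by time t is accumulated
// analytically as 1 - prod(1 - q_i) over its contacts (the maximum-probability
// rule), rather than by Bernoulli retirement.
//
// All randomness comes from a std::mt19937_64 seeded per replicate, so runs
// are bit-identical for a given seed.

#include <Rcpp.h>
#include <random>
using namespace Rcpp;

namespace {

struct Vec3 { double x, y, z; };

inline double norm2(const Vec3& a) { return a.x * a.x + a.y * a.y + a.z * a.z; }

inline Vec3 rand_dir(std::mt19937_64& rng,
                     std::uniform_real_distribution<double>& unif) {
  // Marsaglia: uniform direction on the unit sphere.
  double u = 2.0 * unif(rng) - 1.0, phi = 2.0 * M_PI * unif(rng);
  double s = std::sqrt(std::max(0.0, 1.0 - u * u));
  return {s * std::cos(phi), s * std::sin(phi), u};
}

inline Vec3 rand_in_sphere(double R, std::mt19937_64& rng,
                           std::uniform_real_distribution<double>& unif) {
  while (true) {
    Vec3 p{R * (2 * unif(rng) - 1), R * (2 * unif(rng) - 1),
           R * (2 * unif(rng) - 1)};
    if (norm2(p) <= R * R) return p;
  }
}

// Reflect a position back inside the sphere of radius R (radial reflection
// about the surface); also reverses the radial component of the direction.
inline void reflect(Vec3& p, Vec3& d, double R) {
  double r = std::sqrt(norm2(p));
  if (r <= R || r == 0.0) return;
  double rnew = 2.0 * R - r;
  if (rnew < 0) rnew = 0;  // pathological overshoot; clamp to centre
  double ux = p.x / r, uy = p.y / r, uz = p.z / r;
  p.x = ux * rnew; p.y = uy * rnew; p.z = uz * rnew;
  double dr = d.x * ux + d.y * uy + d.z * uz;
  d.x -= 2 * dr * ux; d.y -= 2 * dr * uy; d.z -= 2 * dr * uz;
}

inline double run_length(double F, double levy_alpha, std::mt19937_64& rng,
                         std::uniform_real_distribution<double>& unif) {
  double u = unif(rng);
  if (u <= 0) u = std::numeric_limits<double>::min();
  if (levy_alpha <= 0) return -F * std::log(u);  // exponential, mean F
  // Pareto with shape alpha > 1 and scale chosen so the mean is F.
  double xm = F * (levy_alpha - 1.0) / levy_alpha;
  return xm * std::pow(u, -1.0 / levy_alpha);
}

}  // namespace

// [[Rcpp::export(name = ".ln_abm_cpp")]]
List ln_abm_cpp(NumericVector arrival_h, double transit_h, double dc_lifetime_h,
                double A_depart, double koff_per_h,
                double R, double v_um_min, double F_um, double b_um,
                int N, int T, double w_um_min, double F_dc_um,
                int n_cells, double horizon_h, int replicates,
                double dt_min, NumericVector out_times_h,
                double levy_alpha, int seed) {
  const int D = arrival_h.size();
  const int n_out = out_times_h.size();
  const double b2 = b_um * b_um;

  NumericVector p_cell(n_out), p_any(n_out);
  double total_contacts = 0.0;
  double max_radius = 0.0;

  // Per-DC dermal departure times: arrival minus lymphatic transit.
  std::vector<double> depart(D);
  for (int j = 0; j < D; ++j) depart[j] = arrival_h[j] - transit_h;

  // Per-contact success probability q(A) = P(Binom(N, A) >= T), cached on the
  // fly via R's pbinom (contacts are sparse, so per-call cost is negligible).
  auto contact_q = [&](double A) -> double {
    if (A <= 0.0) return (T <= 0) ? 1.0 : 0.0;
    if (T <= 0) return 1.0;
    if (A >= 1.0) return (T <= N) ? 1.0 : 0.0;
    return R::pbinom(T - 1, N, A, 0, 0);
  };

  for (int rep = 0; rep < replicates; ++rep) {
    std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2654435761ULL + rep);
    std::uniform_real_distribution<double> unif(0.0, 1.0);

    std::vector<Vec3> tc_pos(n_cells), tc_dir(n_cells);
    std::vector<double> tc_run(n_cells);           // remaining run length, µm
    std::vector<double> log_surv(n_cells, 0.0);    // log prod(1 - q_i)
    for (int i = 0; i < n_cells; ++i) {
      tc_pos[i] = rand_in_sphere(R, rng, unif);
      tc_dir[i] = rand_dir(rng, unif);
      tc_run[i] = run_length(F_um, levy_alpha, rng, unif);
    }
    std::vector<Vec3> dc_pos(D), dc_dir(D);
    std::vector<double> dc_run(D);
    for (int j = 0; j < D; ++j) {
      dc_pos[j] = rand_in_sphere(R, rng, unif);
      if (w_um_min > 0) {
        dc_dir[j] = rand_dir(rng, unif);
        dc_run[j] = run_length(F_dc_um, levy_alpha, rng, unif);
      }
    }
    // Pair contact state (refractory until separation exceeds b).
    std::vector<char> in_contact(static_cast<size_t>(n_cells) * D, 0);

    const double dt_h = dt_min / 60.0;
    const int n_steps = static_cast<int>(std::ceil(horizon_h / dt_h));
    int out_idx = 0;
    int rep_contacts = 0;

    for (int step = 0; step <= n_steps; ++step) {
      double t = step * dt_h;

      // Record output points passed since the last step.
      while (out_idx < n_out && out_times_h[out_idx] <= t + 1e-12) {
        double sum_log = 0.0, sum_p = 0.0;
        for (int i = 0; i < n_cells; ++i) {
          sum_log += log_surv[i];
          sum_p += 1.0 - std::exp(log_surv[i]);
        }
        p_cell[out_idx] += (n_cells > 0) ? sum_p / n_cells : 0.0;
        p_any[out_idx] += 1.0 - std::exp(sum_log);
        ++out_idx;
      }
      if (step == n_steps) break;

      // Move T-cells.
      double step_len = v_um_min * dt_min;
      for (int i = 0; i < n_cells; ++i) {
        double remain = step_len;
        while (remain > 0) {
          double seg = std::min(remain, tc_run[i]);
          tc_pos[i].x += seg * tc_dir[i].x;
          tc_pos[i].y += seg * tc_dir[i].y;
          tc_pos[i].z += seg * tc_dir[i].z;
          reflect(tc_pos[i], tc_dir[i], R);
          tc_run[i] -= seg;
          remain -= seg;
          if (tc_run[i] <= 0) {
            tc_dir[i] = rand_dir(rng, unif);
            tc_run[i] = run_length(F_um, levy_alpha, rng, unif);
          }
        }
        double r2 = norm2(tc_pos[i]);
        if (r2 > max_radius) max_radius = r2;
      }
      // Move DCs (stationary unless w > 0).
      if (w_um_min > 0) {
        double dstep = w_um_min * dt_min;
        for (int j = 0; j < D; ++j) {
          if (arrival_h[j] > t) continue;
          double remain = dstep;
          while (remain > 0) {
            double seg = std::min(remain, dc_run[j]);
            dc_pos[j].x += seg * dc_dir[j].x;
            dc_pos[j].y += seg * dc_dir[j].y;
            dc_pos[j].z += seg * dc_dir[j].z;
            reflect(dc_pos[j], dc_dir[j], R);
            dc_run[j] -= seg;
            remain -= seg;
            if (dc_run[j] <= 0) {
              dc_dir[j] = rand_dir(rng, unif);
              dc_run[j] = run_length(F_dc_um, levy_alpha, rng, unif);
            }
          }
        }
      }

      // Contact detection against active DCs.
      double t_next = t + dt_h;
      for (int j = 0; j < D; ++j) {
        if (arrival_h[j] > t_next || t_next > arrival_h[j] + dc_lifetime_h) {
          // Inactive: clear any lingering contact flags.
          for (int i = 0; i < n_cells; ++i)
            in_contact[static_cast<size_t>(i) * D + j] = 0;
          continue;
        }
        const Vec3& dj = dc_pos[j];
        for (int i = 0; i < n_cells; ++i) {
          double dx = tc_pos[i].x - dj.x, dy = tc_pos[i].y - dj.y,
                 dz = tc_pos[i].z - dj.z;
          double d2 = dx * dx + dy * dy + dz * dz;
          size_t key = static_cast<size_t>(i) * D + j;
          if (d2 <= b2) {
            if (!in_contact[key]) {
              in_contact[key] = 1;
              ++rep_contacts;
              double A = A_depart * std::exp(-koff_per_h * (t_next - depart[j]));
              double q = contact_q(A);
              if (q >= 1.0) log_surv[i] = -std::numeric_limits<double>::infinity();
              else if (q > 0.0) log_surv[i] += std::log1p(-q);
            }
          } else {
            in_contact[key] = 0;
          }
        }
      }
    }
    // Any output times beyond the final step (horizon not on the grid).
    while (out_idx < n_out) {
      double sum_log = 0.0, sum_p = 0.0;
      for (int i = 0; i < n_cells; ++i) {
        sum_log += log_surv[i];
        sum_p += 1.0 - std::exp(log_surv[i]);
      }
      p_cell[out_idx] += (n_cells > 0) ? sum_p / n_cells : 0.0;
      p_any[out_idx] += 1.0 - std::exp(sum_log);
      ++out_idx;
    }
    total_contacts += rep_contacts;
  }

  for (int k = 0; k < n_out; ++k) {
    p_cell[k] /= replicates;
    p_any[k] /= replicates;
  }
  return List::create(_["p_per_cell"] = p_cell,
                      _["p_any"] = p_any,
                      _["n_contacts"] = total_contacts,
                      _["max_tcell_radius"] = std::sqrt(max_radius));
}
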