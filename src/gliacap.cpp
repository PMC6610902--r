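// Compiled cores: Euler-Maruyama integration of the 10-state glioma
// differentiation SDEs, and class-wise k-th nearest neighbour distances for
// the kNN density estimator. Each cell integrates from its own
// counter-derived RNG stream, so ensembles are bit-reproducible and
// independent of cell ordering.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

// splitmix64: seeds the per-cell xoshiro256+ streams.
inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97f4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256 {
  uint64_t s[4];
  explicit Xoshiro256(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  // Box-Muller with caching.
  bool have_spare = false;
  double spare = 0.0;
  inline double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u));
    double a = 6.283185307179586476925286766559 * v;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

inline double hill(double x, double K, double n) {
  if (x <= 0.0) return 0.0;
  double xn = std::pow(x, n);
  return xn / (std::pow(K, n) + xn);
}

// x^n with fast exponentiation when n is a small non-negative integer
// (the state-dependent Hill exponents are integers in practice).
inline double powfast(double x, double n) {
  int ni = (int)n;
  if (n == (double)ni && ni >= 0 && ni <= 64) {
    double r = 1.0, b = x;
    int e = ni;
    while (e > 0) {
      if (e & 1) r *= b;
      b *= b;
      e >>= 1;
    }
    return r;
  }
  return std::pow(x, n);
}

// Parameter order must match the packaged YAML / R-side vector.
enum Par {
  b_pka, k_pka, K_ct1, n_ct1, d_pka,
  k_creb, K_creb, d_creb,
  b_il6, k_il6, d_il6,
  k_jak, K_jak, d_jak,
  k_stat, K_stat, d_stat,
  b_pi3k, d_pi3k, k_ipi, K_ct2, n_ct2,
  k_akt, K_akt, d_akt,
  k_gsk, K_gsk, d_gsk,
  b_cyc, k_fb, n_fb, K_fb, d_cyc, k_deg, K_deg,
  b_g, k_g1, k_g2, K_r, n_r, d_g,
  N_PAR
};

// Dose- and parameter-dependent constants, hoisted out of the step loop
// (recomputed per cell because extrinsic noise perturbs the parameters).
struct CellConsts {
  double act_pka;   // b_pka + k_pka * H(u; K_ct1, n_ct1)
  double deact_pi3k; // d_pi3k + k_ipi * H(u; K_ct2, n_ct2)
  double Kfbn;      // K_fb ^ n_fb
  double Krn;       // K_r ^ n_r
};

inline CellConsts make_consts(const double *p, double u) {
  CellConsts c;
  c.act_pka = p[b_pka] + p[k_pka] * hill(u, p[K_ct1], p[n_ct1]);
  c.deact_pi3k = p[d_pi3k] + p[k_ipi] * hill(u, p[K_ct2], p[n_ct2]);
  c.Kfbn = std::pow(p[K_fb], p[n_fb]);
  c.Krn = std::pow(p[K_r], p[n_r]);
  return c;
}

inline void propensities(const double *x, const double *p,
                         const CellConsts &cc, double fs,
                         double *prod, double *deg) {
  const double PKA = x[0], CREB = x[1], IL6 = x[2], JAK2 = x[3], STAT3 = x[4],
               PI3K = x[5], AKT = x[6], GSK = x[7], CYC = x[8], GFAP = x[9];
  double A = 1.0 - GSK;
  if (A < 0.0) A = 0.0; else if (A > 1.0) A = 1.0;
  const double cyc_nr = powfast(CYC, p[n_r]);
  const double gate = cc.Krn / (cc.Krn + cyc_nr);
  const double cyc_nfb = powfast(CYC, p[n_fb]);
  prod[0] = cc.act_pka * (1.0 - PKA);
  prod[1] = p[k_creb] * PKA / (p[K_creb] + PKA) * (1.0 - CREB);
  prod[2] = p[b_il6] + p[k_il6] * CREB;
  prod[3] = p[k_jak] * IL6 / (p[K_jak] + IL6) * (1.0 - JAK2);
  prod[4] = p[k_stat] * JAK2 / (p[K_stat] + JAK2) * (1.0 - STAT3);
  prod[5] = p[b_pi3k] * (1.0 - PI3K);
  prod[6] = p[k_akt] * PI3K / (p[K_akt] + PI3K) * (1.0 - AKT);
  prod[7] = p[k_gsk] * AKT / (p[K_gsk] + AKT) * (1.0 - GSK);
  prod[8] = p[b_cyc] + fs * p[k_fb] * (CYC > 0.0 ?
            cyc_nfb / (cc.Kfbn + cyc_nfb) : 0.0);
  prod[9] = (p[b_g] + (p[k_g1] * STAT3 + p[k_g2] * CREB) * gate) * (1.0 - GFAP);
  deg[0] = p[d_pka] * PKA;
  deg[1] = p[d_creb] * CREB;
  deg[2] = p[d_il6] * IL6;
  deg[3] = p[d_jak] * JAK2;
  deg[4] = p[d_stat] * STAT3;
  deg[5] = cc.deact_pi3k * PI3K;
  deg[6] = p[d_akt] * AKT;
  deg[7] = p[d_gsk] * GSK;
  deg[8] = (p[d_cyc] + p[k_deg] * A / (p[K_deg] + A)) * CYC;
  deg[9] = p[d_g] * GFAP;
}

// Untreated (dose 0) deterministic steady state for one cell's parameters,
// with the cyclin D1 feedback intact: the cascade is feed-forward at u = 0,
// so all states solve in sequence; cyclin D1 needs a scalar fixed-point
// iteration started from the proliferative (high) branch.
inline void untreated_state(const double *p, double cyc_start, double *x) {
  x[0] = p[b_pka] / (p[b_pka] + p[d_pka]);
  double r = p[k_creb] * x[0] / (p[K_creb] + x[0]);
  x[1] = r / (r + p[d_creb]);
  x[2] = (p[b_il6] + p[k_il6] * x[1]) / p[d_il6];
  r = p[k_jak] * x[2] / (p[K_jak] + x[2]);
  x[3] = r / (r + p[d_jak]);
  r = p[k_stat] * x[3] / (p[K_stat] + x[3]);
  x[4] = r / (r + p[d_stat]);
  x[5] = p[b_pi3k] / (p[b_pi3k] + p[d_pi3k]);
  r = p[k_akt] * x[5] / (p[K_akt] + x[5]);
  x[6] = r / (r + p[d_akt]);
  r = p[k_gsk] * x[6] / (p[K_gsk] + x[6]);
  x[7] = r / (r + p[d_gsk]);
  double A = 1.0 - x[7];
  if (A < 0.0) A = 0.0; else if (A > 1.0) A = 1.0;
  const double rate = p[d_cyc] + p[k_deg] * A / (p[K_deg] + A);
  const double Kfbn = std::pow(p[K_fb], p[n_fb]);
  double C = cyc_start;
  for (int i = 0; i < 200; ++i) {
    double cn = powfast(C, p[n_fb]);
    double Cn = (p[b_cyc] + p[k_fb] * cn / (Kfbn + cn)) / rate;
    if (std::fabs(Cn - C) < 1e-13) { C = Cn; break; }
    C = Cn;
  }
  x[8] = C;
  const double Krn = std::pow(p[K_r], p[n_r]);
  const double gate = Krn / (Krn + powfast(C, p[n_r]));
  const double P = p[b_g] + (p[k_g1] * x[4] + p[k_g2] * x[1]) * gate;
  x[9] = P / (P + p[d_g]);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_simulate_ensemble")]]
List cpp_simulate_ensemble(NumericVector params, NumericVector init,
                           double ct_dose, double feedback_scale,
                           int noise_kind,  // 0 none, 1 AN, 2 CLE
                           double sigma_int, double sigma_ext, double sigma_an,
                           NumericVector cle_weights, NumericVector an_scales,
                           int n_cells, double t_end, double dt,
                           int save_stride, double seed_lo, double seed_hi,
                           bool save_full_state, double burn_in) {
  if (params.size() != N_PAR) stop("expected %d drift parameters", (int)N_PAR);
  const int n_steps = (int)std::lround(t_end / dt);
  const int n_save = n_steps / save_stride + 1;
  const double sqdt = std::sqrt(dt);

  NumericMatrix gfap(n_cells, n_save);
  NumericVector time_grid(n_save);
  for (int j = 0; j < n_save; ++j) time_grid[j] = j * save_stride * dt;
  NumericVector full;
  if (save_full_state) {
    full = NumericVector(Dimension(n_cells, 10, n_save));
  }

  const uint64_t base_seed =
      ((uint64_t)(uint32_t)seed_hi << 32) ^ (uint64_t)(uint32_t)seed_lo;

  std::vector<double> p(params.begin(), params.end());
  double x[10], prod[10], deg[10];
  int blow_cell = -1, blow_state = -1;
  double blow_time = 0.0;

  for (int c = 0; c < n_cells; ++c) {
    uint64_t h = base_seed;
    // one extra mix per cell index gives independent streams
    uint64_t cs = h ^ (0x9E3779B97f4A7C15ULL * (uint64_t)(c + 1));
    Xoshiro256 rng(splitmix64(cs));

    std::vector<double> pc(p);
    if (noise_kind == 2 && sigma_ext > 0.0) {
      const double half = 0.5 * sigma_ext * sigma_ext;
      for (int j = 0; j < N_PAR; ++j)
        pc[j] = p[j] * std::exp(sigma_ext * rng.norm() - half);
    }
    // rest state under this cell's parameters (feedback intact), then a
    // stochastic settling period at dose 0 so each cell carries its own
    // fluctuating baseline when treatment starts at t = 0
    untreated_state(pc.data(), init[8], x);
    const int n_burn = (int)std::lround(burn_in / dt);
    const CellConsts cc0 = make_consts(pc.data(), 0.0);
    const CellConsts cc = make_consts(pc.data(), ct_dose);
    for (int it = -n_burn; it <= n_steps; ++it) {
      const bool burn = it <= 0;
      if (it == 0) {
        gfap(c, 0) = x[9];
        if (save_full_state)
          for (int s = 0; s < 10; ++s) full[c + n_cells * s] = x[s];
        continue;
      }
      propensities(x, pc.data(), burn ? cc0 : cc,
                   burn ? 1.0 : feedback_scale, prod, deg);
      for (int s = 0; s < 10; ++s) {
        double amp = 0.0;
        if (noise_kind == 1) {
          amp = sigma_an * an_scales[s];
        } else if (noise_kind == 2 && sigma_int > 0.0) {
          double pp = prod[s] > 0.0 ? prod[s] : 0.0;
          double dd = deg[s] > 0.0 ? deg[s] : 0.0;
          amp = sigma_int * cle_weights[s] * std::sqrt(pp + dd);
        }
        double xi = (amp > 0.0) ? rng.norm() : 0.0;
        x[s] += (prod[s] - deg[s]) * dt + amp * xi * sqdt;
        if (x[s] < 0.0) x[s] = 0.0;
        if (!std::isfinite(x[s])) {
          blow_cell = c; blow_state = s; blow_time = it * dt;
          goto done;
        }
      }
      if (!burn && it % save_stride == 0) {
        int j = it / save_stride;
        gfap(c, j) = x[9];
        if (save_full_state)
          for (int s = 0; s < 10; ++s)
            full[c + n_cells * (s + 10 * (size_t)j)] = x[s];
      }
    }
  }
done:
  if (blow_cell >= 0) {
    stop("numerical blow-up: non-finite state %d (1-based) in cell %d at t = %.3f h",
         blow_state + 1, blow_cell + 1, blow_time);
  }
  List out = List::create(_["gfap"] = gfap, _["time"] = time_grid);
  if (save_full_state) out["full_state"] = full;
  return out;
}

// For every sample i and class s: Euclidean distance to the k-th nearest
// neighbour of i among the class-s samples, excluding i itself when i
// belongs to s. Returns the S x N distance matrix and per-class counts.
// [[Rcpp::export(name = ".cpp_knn_class_dist")]]
List cpp_knn_class_dist(NumericMatrix X, IntegerVector labels, int n_class,
                        int k) {
  const int N = X.nrow(), d = X.ncol();
  std::vector<std::vector<int>> members(n_class);
  for (int i = 0; i < N; ++i) {
    int s = labels[i] - 1;
    if (s < 0 || s >= n_class) stop("label out of range");
    members[s].push_back(i);
  }
  IntegerVector counts(n_class);
  for (int s = 0; s < n_class; ++s) counts[s] = (int)members[s].size();

  // row-major copy: sample vectors contiguous in memory
  std::vector<double> Xr((size_t)N * d);
  for (int i = 0; i < N; ++i)
    for (int t = 0; t < d; ++t) Xr[(size_t)i * d + t] = X(i, t);

  NumericMatrix R(n_class, N);
  std::vector<double> d2;
  for (int s = 0; s < n_class; ++s) {
    const std::vector<int> &mem = members[s];
    const int m = (int)mem.size();
    if (m <= k) stop("class %d has %d members; needs more than k = %d",
                     s + 1, m, k);
    // class block, contiguous
    std::vector<double> B((size_t)m * d);
    for (int jj = 0; jj < m; ++jj)
      for (int t = 0; t < d; ++t) B[(size_t)jj * d + t] = Xr[(size_t)mem[jj] * d + t];
    for (int i = 0; i < N; ++i) {
      const double *xi = &Xr[(size_t)i * d];
      d2.clear();
      d2.reserve(m);
      for (int jj = 0; jj < m; ++jj) {
        if (mem[jj] == i) continue;  // leave-one-out within own class
        const double *xj = &B[(size_t)jj * d];
        double acc = 0.0;
        for (int t = 0; t < d; ++t) {
          double diff = xi[t] - xj[t];
          acc += diff * diff;
        }
        d2.push_back(acc);
      }
      std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.end());
      R(s, i) = std::sqrt(d2[k - 1]);
    }
  }
  return List::create(_["kth_dist"] = R, _["counts"] = counts);
}
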