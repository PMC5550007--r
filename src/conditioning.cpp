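// Monte-Carlo conditioning engine. All replicates advance in lockstep:
// activity states are voxels x replicates matrices and one TR is a handful
// of matrix operations. Spontaneous activity is generated inside the engine
// from an explicit 64-bit seed (xoshiro256++ with Box-Muller normals), so a
// full experiment is a single call; a "supplied" noise mode accepts
// pre-drawn activity for exact equivalence tests against the stepwise
// reference implementation.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    // splitmix64 expansion of the seed into the state
    for (int i = 0; i < 4; ++i) {
      seed += 0x9E3779B97F4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0,1)
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  bool has_spare = false;
  double spare = 0.0;
  double gauss() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// Spontaneous-activity generator writing one TR of activity (voxels x reps).
struct NoiseGen {
  int type;  // 0 iid, 1 grf, 2 orientation mixture, 3 supplied
  double sigma = 0, g_sd = 0, c_mix = 0;
  mat K1, K2kron, K3;  // separable smoothing pieces (grf)
  vec mult;            // per-voxel re-standardization (grf)
  uvec tuned;          // 0-based tuned voxel indices (mixture)
  vec pref;            // preferred orientations of tuned voxels (mixture)
  int nx = 0, ny = 0, nz = 0;
  const double* supplied = nullptr;  // column-major voxels x (reps * n_steps)
  Xoshiro256pp rng{0};

  void fill(mat& N, uword step) {
    const uword V = N.n_rows, R = N.n_cols;
    switch (type) {
    case 0:
      for (uword i = 0; i < V * R; ++i) N(i) = sigma * rng.gauss();
      break;
    case 1: {
      for (uword i = 0; i < V * R; ++i) N(i) = rng.gauss();
      // axis 1 (fastest): one GEMM over the unfolded grid
      {
        mat M(N.memptr(), (uword)nx, V / nx * R, false, true);
        M = K1 * M;
      }
      // axis 2: kron(K2, I_nx) over the (nx*ny) x (nz*R) unfolding
      {
        mat M(N.memptr(), (uword)(nx * ny), (uword)nz * R, false, true);
        M = K2kron * M;
      }
      // axis 3: per replicate, right-multiply the (nx*ny) x nz view
      if (nz > 1) {
        for (uword r = 0; r < R; ++r) {
          mat M(N.colptr(r), (uword)(nx * ny), (uword)nz, false, true);
          M = M * K3;
        }
      }
      N.each_col() %= mult;
      break;
    }
    case 2: {
      for (uword i = 0; i < V * R; ++i) N(i) = g_sd * rng.gauss();
      const double k = std::log(1.0 / 16.0) / 90.0;
      for (uword r = 0; r < R; ++r) {
        double theta = 180.0 * rng.unif();
        for (uword t = 0; t < tuned.n_elem; ++t) {
          // pref and theta both lie in [0, 180), so |diff| < 180 already
          double d = std::fabs(pref(t) - theta);
          if (d > 90.0) d = 180.0 - d;
          N(tuned(t), r) += c_mix * std::exp(k * d);
        }
      }
      break;
    }
    default:
      std::memcpy(N.memptr(), supplied + (size_t)step * V * R,
                  sizeof(double) * V * R);
    }
  }
};

NoiseGen make_noise_gen(const Rcpp::List& spec, const Rcpp::NumericMatrix& sup) {
  NoiseGen g;
  g.type = Rcpp::as<int>(spec["type"]);
  g.rng = Xoshiro256pp((uint64_t)Rcpp::as<double>(spec["seed"]));
  if (g.type == 0) g.sigma = Rcpp::as<double>(spec["sigma"]);
  if (g.type == 1) {
    g.K1 = Rcpp::as<mat>(spec["K1"]);
    g.K2kron = Rcpp::as<mat>(spec["K2kron"]);
    g.K3 = Rcpp::as<mat>(spec["K3"]);
    g.mult = Rcpp::as<vec>(spec["mult"]);
    g.nx = g.K1.n_rows;
    g.ny = g.K2kron.n_rows / g.nx;
    g.nz = g.K3.n_rows;
  }
  if (g.type == 2) {
    g.g_sd = Rcpp::as<double>(spec["g_sd"]);
    g.c_mix = Rcpp::as<double>(spec["c_mix"]);
    g.tuned = Rcpp::as<uvec>(spec["tuned"]);
    g.pref = Rcpp::as<vec>(spec["pref"]);
  }
  if (g.type == 3) g.supplied = sup.begin();
  return g;
}

// target-class softmax probability of the affine decision function, per column
rowvec softmax_target(const mat& W, const vec& b, const mat& P, uword target) {
  mat S = W.t() * P;
  S.each_col() += b;
  S.each_row() -= max(S, 0);
  mat E = exp(S);
  return E.row(target) / sum(E, 0);
}

}  // namespace

// Draw n_tr TRs of spontaneous activity from an engine noise spec (testing
// hook: lets the R suite check the engine's noise distribution directly).
// [[Rcpp::export]]
arma::mat cc_noise_sample(Rcpp::List noise_spec, int n_voxels, int reps,
                          int n_tr) {
  Rcpp::NumericMatrix empty(0, 0);
  NoiseGen gen = make_noise_gen(noise_spec, empty);
  mat out((uword)n_voxels, (uword)reps * n_tr);
  mat N((uword)n_voxels, (uword)reps);
  for (int t = 0; t < n_tr; ++t) {
    gen.fill(N, t);
    out.cols((uword)t * reps, (uword)(t + 1) * reps - 1) = N;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cc_run(const arma::mat& W, const arma::vec& b, int target1,
                  const arma::vec& h, const arma::vec& m_w, int schedule,
                  int n_steps, int reps, double alpha, int cue_tr, int wait_tr,
                  Rcpp::List noise_spec, Rcpp::NumericMatrix supplied_noise,
                  bool keep_patterns) {
  const uword V = W.n_rows, R = (uword)reps;
  const uword target = (uword)(target1 - 1);
  NoiseGen gen = make_noise_gen(noise_spec, supplied_noise);
  mat Ac(V, R, fill::zeros);
  rowvec fprev(R);
  fprev.fill(1.0 / W.n_cols);
  mat fout((uword)n_steps, R);
  mat N(V, R);

  if (schedule == 0) {  // continuous
    const uword Lp1 = std::max(h.n_elem, m_w.n_elem);
    cube buf(V, R, Lp1, fill::zeros);
    for (uword n = 1; n <= (uword)n_steps; ++n) {
      gen.fill(N, n - 1);
      buf.slice((n - 1) % Lp1) = N + Ac;
      mat P(V, R, fill::zeros);
      for (uword j = 0; j < h.n_elem && j < n; ++j)
        P += h(j) * buf.slice((n - 1 - j) % Lp1);
      rowvec f = softmax_target(W, b, P, target);
      rowvec l = f - fprev;
      mat Cr(V, R, fill::zeros);
      for (uword j = 0; j < m_w.n_elem && j < n; ++j)
        Cr += m_w(j) * buf.slice((n - 1 - j) % Lp1);
      Cr.each_row() %= l;
      Ac += alpha * Cr;
      fprev = f;
      fout.row(n - 1) = f;
    }
  } else {  // intermittent: carryover resets between trials, cue gates a_c
    const uword n_tr = (uword)(cue_tr + wait_tr);
    std::vector<mat> A(n_tr);
    for (uword k = 0; k < (uword)n_steps; ++k) {
      mat Abar(V, R, fill::zeros);
      rowvec fsum(R, fill::zeros);
      for (uword t = 0; t < n_tr; ++t) {
        gen.fill(N, k * n_tr + t);
        A[t] = N;
        if (t < (uword)cue_tr) {
          A[t] += Ac;
          Abar += A[t];
        } else {
          mat P(V, R, fill::zeros);
          for (uword j = 0; j < h.n_elem && j <= t; ++j)
            P += h(j) * A[t - j];
          fsum += softmax_target(W, b, P, target);
        }
      }
      rowvec fk = fsum / wait_tr;
      rowvec l = fk - fprev;
      Abar /= cue_tr;
      Abar.each_row() %= l;
      Ac += alpha * Abar;
      fprev = fk;
      fout.row(k) = fk;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("f") = fout,
      Rcpp::Named("final_patterns") =
          keep_patterns ? Rcpp::wrap(Ac) : R_NilValue);
}
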