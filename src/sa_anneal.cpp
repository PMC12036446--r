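#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Best-of-reads single-flip Metropolis annealing for a QUBO
//   value(y) = y'Qy + q'y   (Q symmetric, zero diagonal; constant added in R)
// With local field h = Qy: value = sum_i y_i (q_i + h_i), and the energy
// change of flipping bit i is (1 - 2 y_i) (q_i + 2 h_i).
// Deterministic for a fixed seed: each read runs its own mt19937 stream.
// [[Rcpp::export(name = ".sa_anneal_cpp")]]
List sa_anneal_cpp(NumericMatrix Q, NumericVector q, NumericVector betas,
                   int n_reads, double seed) {
  const int B = q.size();
  const int sweeps = betas.size();
  std::vector<double> best_y(B, 0.0);
  double best_val = R_PosInf;

  for (int read = 0; read < n_reads; ++read) {
    std::mt19937 rng(static_cast<std::uint32_t>(seed) +
                     0x9e3779b9u * static_cast<std::uint32_t>(read + 1));
    std::uniform_real_distribution<double> unif(0.0, 1.0);

    std::vector<int> y(B);
    for (int i = 0; i < B; ++i) y[i] = (unif(rng) < 0.5) ? 1 : 0;

    std::vector<double> h(B, 0.0);
    double val = 0.0;
    for (int i = 0; i < B; ++i) {
      double hi = 0.0;
      for (int j = 0; j < B; ++j) if (y[j]) hi += Q(i, j);
      h[i] = hi;
      if (y[i]) val += q[i] + hi;
    }

    double run_best = val;
    std::vector<int> run_best_y = y;

    for (int s = 0; s < sweeps; ++s) {
      const double beta = betas[s];
      for (int i = 0; i < B; ++i) {
        const double delta = (1 - 2 * y[i]) * (q[i] + 2.0 * h[i]);
        if (delta <= 0.0 || unif(rng) < std::exp(-beta * delta)) {
          const double sgn = y[i] ? -1.0 : 1.0;
          y[i] = 1 - y[i];
          val += delta;
          for (int j = 0; j < B; ++j) h[j] += sgn * Q(j, i);
          if (val < run_best) { run_best = val; run_best_y = y; }
        }
      }
    }
    if (run_best < best_val) {
      best_val = run_best;
      for (int i = 0; i < B; ++i) best_y[i] = run_best_y[i];
    }
  }
  return List::create(Named("y") = NumericVector(best_y.begin(), best_y.end()),
                      Named("value") = best_val);
}
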