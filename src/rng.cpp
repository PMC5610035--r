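#include <Rcpp.h>
#include <cstdint>
#include <cmath>

// Counter-based per-site random streams. Each (site stream, step, draw index)
// triple maps to an independent standard normal through a splitmix64-style
// finalizer + Box-Muller, so a site's stream does not depend on how many other
// sites exist in the lattice and a fixed master seed gives bit-identical
// trajectories on any platform with IEEE doubles.

static inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t stream_seed(uint64_t master, uint64_t stream) {
  // counter-based split: independent of the number of streams in use
  return mix64(master ^ (0xA0761D6478BD642FULL * (stream + 1)));
}

static inline double u01(uint64_t z) {
  // top 53 bits -> (0, 1]; never exactly 0 so log() is safe
  return (double)((z >> 11) + 1) * (1.0 / 9007199254740993.0);
}

static inline double std_normal(uint64_t seed, uint64_t counter) {
  uint64_t a = mix64(seed ^ (0x8BB84B93962EACC9ULL * (counter + 1)));
  uint64_t b = mix64(a ^ 0x2545F4914F6CDD1DULL);
  double u1 = u01(a), u2 = u01(b);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
}

// [[Rcpp::export(name = ".ct_normals")]]
Rcpp::NumericMatrix ct_normals(double master, Rcpp::IntegerVector streams,
                               double step, int nrow, double draw_offset) {
  // nrow draws per stream at integration step `step`; draw_offset separates
  // different consumers (e.g. the two pathways) within one step.
  uint64_t ms = (uint64_t)master;
  uint64_t st = (uint64_t)step;
  uint64_t off = (uint64_t)draw_offset;
  int ns = streams.size();
  Rcpp::NumericMatrix out(nrow, ns);
  for (int s = 0; s < ns; ++s) {
    uint64_t seed = stream_seed(ms, (uint64_t)streams[s]);
    uint64_t base = st * 0x100000ULL + off; // up to 2^20 draws per step
    for (int i = 0; i < nrow; ++i)
      out(i, s) = std_normal(seed, base + (uint64_t)i);
  }
  return out;
}
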