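#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Ancestry-sampling Monte-Carlo oracle for pool-level MIDs.
// Each molecule's labeling pattern is sampled by recursing through the
// source decomposition: pick a source by its fraction; injections return
// the tracer pattern (at purity) or unlabeled; reaction sources sample each
// substrate independently (one level deeper) and combine bits through the
// atom map; symmetric pools are scrambled with probability 1/2. Ancestries
// deeper than max_depth return unlabeled, consistent with fixed-point
// iteration started from the unlabeled state.

namespace {

struct Source {
  double frac;
  int kind;          // 0 unlabeled, 1 inject, 2 reaction
  int pattern;       // inject: bitmask of labeled carbons
  double purity;     // inject
  std::vector<int> subs;  // reaction: pool ids, -1 for CO2
  std::vector<int> msub;  // per output carbon: substrate index
  std::vector<int> mcar;  // per output carbon: substrate carbon bit
};

struct Pool {
  int n;
  std::vector<int> symlut;  // pattern permutation LUT, empty if asymmetric
  std::vector<Source> srcs;
};

struct Sampler {
  std::vector<Pool> pools;
  double co2_frac;

  int sample(int pid, int depth) {
    if (depth <= 0) return 0;
    const Pool& P = pools[pid];
    double u = unif_rand();
    size_t si = 0;
    double acc = 0.0;
    for (; si < P.srcs.size(); ++si) {
      acc += P.srcs[si].frac;
      if (u < acc) break;
    }
    if (si >= P.srcs.size()) si = P.srcs.size() - 1;
    const Source& S = P.srcs[si];
    int pat = 0;
    if (S.kind == 1) {
      pat = (unif_rand() < S.purity) ? S.pattern : 0;
    } else if (S.kind == 2) {
      int sp[2] = {0, 0};
      for (size_t j = 0; j < S.subs.size(); ++j) {
        if (S.subs[j] < 0)
          sp[j] = (unif_rand() < co2_frac) ? 1 : 0;
        else
          sp[j] = sample(S.subs[j], depth - 1);
      }
      for (int k = 0; k < P.n; ++k)
        if ((sp[S.msub[k]] >> S.mcar[k]) & 1) pat |= (1 << k);
    }
    if (!P.symlut.empty() && unif_rand() < 0.5) pat = P.symlut[pat];
    return pat;
  }
};

}  // namespace

// [[Rcpp::export(name = ".mc_oracle_cpp")]]
List mc_oracle_cpp(List pool_spec, double co2_frac, int n_molecules,
                   int max_depth) {
  Sampler sampler;
  sampler.co2_frac = co2_frac;
  int P = pool_spec.size();
  sampler.pools.resize(P);
  for (int i = 0; i < P; ++i) {
    List pl = pool_spec[i];
    Pool& pool = sampler.pools[i];
    pool.n = as<int>(pl["n"]);
    IntegerVector lut = pl["sym_lut"];
    pool.symlut.assign(lut.begin(), lut.end());
    List srcs = pl["sources"];
    for (int j = 0; j < srcs.size(); ++j) {
      List sl = srcs[j];
      Source s;
      s.frac = as<double>(sl["frac"]);
      s.kind = as<int>(sl["kind"]);
      s.pattern = as<int>(sl["pattern"]);
      s.purity = as<double>(sl["purity"]);
      IntegerVector subs = sl["subs"], msub = sl["msub"], mcar = sl["mcar"];
      s.subs.assign(subs.begin(), subs.end());
      s.msub.assign(msub.begin(), msub.end());
      s.mcar.assign(mcar.begin(), mcar.end());
      if (s.subs.size() > 2) stop("at most two substrates are supported");
      sampler.pools[i].srcs.push_back(s);
    }
  }
  List out(P);
  for (int i = 0; i < P; ++i) {
    int n = sampler.pools[i].n;
    IntegerVector counts(n + 1);
    for (int m = 0; m < n_molecules; ++m) {
      int pat = sampler.sample(i, max_depth);
      int w = 0;
      while (pat) { w += pat & 1; pat >>= 1; }
      counts[w] += 1;
    }
    out[i] = counts;
  }
  return out;
}
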