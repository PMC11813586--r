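#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Sequential preference-based mate assignment (the serial core of
// select_mates()): for each female in the given order, the eligible males
// are those with |tau_f - tau_m| < p; one is drawn with probability
// proportional to 1 - |tau_f - tau_m| and removed from the pool.  Uses
// R's RNG stream.  Returns one row per mated pair: (female position,
// male position), 1-based into the supplied vectors.
//' @noRd
// [[Rcpp::export(name = ".select_mates_pref_cpp")]]
IntegerMatrix select_mates_pref_cpp(NumericVector tau_f, NumericVector tau_m,
                                    double p) {
  const int nf = tau_f.size();
  const int nm = tau_m.size();
  std::vector<int> pool(nm);
  for (int j = 0; j < nm; ++j) pool[j] = j;
  int npool = nm;
  std::vector<int> dam, sire;
  dam.reserve(nf); sire.reserve(nf);
  for (int i = 0; i < nf && npool > 0; ++i) {
    const double tf = tau_f[i];
    double tot = 0.0;
    for (int j = 0; j < npool; ++j) {
      double d = std::fabs(tf - tau_m[pool[j]]);
      if (d < p) tot += 1.0 - d;
    }
    if (tot <= 0.0) continue;   // no eligible male: she skips this year
    double u = unif_rand() * tot;
    double acc = 0.0;
    int pick = -1;
    for (int j = 0; j < npool; ++j) {
      double d = std::fabs(tf - tau_m[pool[j]]);
      if (d < p) {
        acc += 1.0 - d;
        if (acc >= u) { pick = j; break; }
      }
    }
    if (pick < 0) {             // numeric tie at the upper edge
      for (int j = npool - 1; j >= 0; --j)
        if (std::fabs(tf - tau_m[pool[j]]) < p) { pick = j; break; }
    }
    dam.push_back(i + 1);
    sire.push_back(pool[pick] + 1);
    pool[pick] = pool[npool - 1];   // annual monogamy: male leaves the pool
    --npool;
  }
  IntegerMatrix out(dam.size(), 2);
  for (size_t r = 0; r < dam.size(); ++r) {
    out(r, 0) = dam[r];
    out(r, 1) = sire[r];
  }
  return out;
}
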