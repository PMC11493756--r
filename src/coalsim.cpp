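// Monte-Carlo structured coalescent for two demes with piecewise-constant
// deme sizes and asymmetric migration.  Returns, for each folded SFS cell,
// the mean and Monte-Carlo variance (of the mean) of the branch length
// subtending (i, j) sampled lineages from population 1 and 2, accumulated
// over n_reps independent genealogies.  Each genealogy gets its own RNG
// stream derived from (seed, rep): under common random numbers a parameter
// change can only desynchronise draws within a replicate, keeping the
// likelihood surface near-continuous.  Waiting times enter the estimate
// through their conditional expectation given the lineage configuration
// (Rao-Blackwellisation), which removes the exponential holding-time noise.
//
// Time is measured in units of 2 N_ref generations; the coalescence rate in
// a deme of relative size nu is C(k,2)/nu and each lineage in deme d
// migrates (backward) to the other deme at the per-lineage rate mig[d].

#include <Rcpp.h>
#include <random>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".coalBranchLengths")]]
List coalBranchLengths(int n1, int n2,
                       NumericVector epochStart,
                       NumericVector size1, NumericVector size2,
                       NumericVector mig12, NumericVector mig21,
                       LogicalVector merged,
                       IntegerMatrix foldMap,
                       int nReps, int seed) {
  const int K = epochStart.size();
  if (size1.size() != K || size2.size() != K || mig12.size() != K ||
      mig21.size() != K || merged.size() != K)
    stop("epoch vectors must share length");
  for (int k = 0; k < K; ++k)
    if (size1[k] <= 0 || size2[k] <= 0) stop("deme sizes must be positive");
  const int nc = (n1 + 1) * (n2 + 1);
  if (foldMap.nrow() != n1 + 1 || foldMap.ncol() != n2 + 1)
    stop("foldMap shape mismatch");

  std::vector<double> acc(nc, 0.0), acc2(nc, 0.0), raw(nc), fold(nc);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  const int n = n1 + n2;
  std::vector<int> deme(n), d1(n), d2(n);

  for (int rep = 0; rep < nReps; ++rep) {
    std::mt19937_64 rng(static_cast<unsigned long long>(seed) * 2654435761ULL
                        + static_cast<unsigned long long>(rep) * 40503ULL + 1ULL);
    std::fill(raw.begin(), raw.end(), 0.0);
    int k = n;
    for (int i = 0; i < n; ++i) {
      deme[i] = (i < n1) ? 0 : 1;
      d1[i] = (i < n1) ? 1 : 0;
      d2[i] = (i < n1) ? 0 : 1;
    }
    double t = 0.0;
    int ep = 0;
    bool isMerged = merged[0];
    if (isMerged) for (int i = 0; i < n; ++i) deme[i] = 0;
    while (k > 1) {
      while (ep + 1 < K && t >= epochStart[ep + 1]) {
        ++ep;
        if (merged[ep] && !isMerged) {
          for (int i = 0; i < k; ++i) deme[i] = 0;
          isMerged = true;
        }
      }
      int k1 = 0;
      for (int i = 0; i < k; ++i) if (deme[i] == 0) ++k1;
      int k2 = k - k1;
      double rc1 = 0.5 * k1 * (k1 - 1) / size1[ep];
      double rc2 = isMerged ? 0.0 : 0.5 * k2 * (k2 - 1) / size2[ep];
      double rm1 = isMerged ? 0.0 : k1 * mig12[ep];
      double rm2 = isMerged ? 0.0 : k2 * mig21[ep];
      double R = rc1 + rc2 + rm1 + rm2;
      double tNext = (ep + 1 < K) ? epochStart[ep + 1] : R_PosInf;
      double dt;
      if (R <= 0.0) {
        if (!R_finite(tNext)) stop("zero event rate in the final epoch");
        dt = tNext - t;
      } else {
        double u = unif(rng);
        if (u <= 0.0) u = 1e-300;
        dt = -std::log(u) / R;
      }
      bool crossed = (t + dt >= tNext);
      double step = crossed ? (tNext - t) : dt;
      double estep;           // E[elapsed | configuration]
      if (R <= 0.0) {
        estep = step;
      } else if (R_finite(tNext)) {
        estep = (1.0 - std::exp(-R * (tNext - t))) / R;
      } else {
        estep = 1.0 / R;
      }
      for (int i = 0; i < k; ++i) raw[d1[i] + d2[i] * (n1 + 1)] += estep;
      t += step;
      if (crossed || R <= 0.0) continue;
      double u = unif(rng) * R;
      if (u < rc1 + rc2) {
        int target = (u < rc1) ? 0 : 1;
        int kt = (target == 0) ? k1 : k2;
        int a = (int)(unif(rng) * kt); if (a >= kt) a = kt - 1;
        int b = (int)(unif(rng) * (kt - 1)); if (b >= kt - 1) b = kt - 2;
        if (b >= a) ++b;
        int ia = -1, ib = -1, seen = 0;
        for (int i = 0; i < k; ++i) {
          if (deme[i] == target) {
            if (seen == a) ia = i;
            if (seen == b) ib = i;
            ++seen;
          }
        }
        d1[ia] += d1[ib]; d2[ia] += d2[ib];
        d1[ib] = d1[k - 1]; d2[ib] = d2[k - 1]; deme[ib] = deme[k - 1];
        --k;
      } else {
        int from = (u < rc1 + rc2 + rm1) ? 0 : 1;
        int kt = (from == 0) ? k1 : k2;
        int a = (int)(unif(rng) * kt); if (a >= kt) a = kt - 1;
        int seen = 0;
        for (int i = 0; i < k; ++i) {
          if (deme[i] == from) {
            if (seen == a) { deme[i] = 1 - from; break; }
            ++seen;
          }
        }
      }
    }
    // fold this replicate's contribution, then accumulate mean and square
    std::fill(fold.begin(), fold.end(), 0.0);
    for (int c = 0; c < nc; ++c) fold[foldMap[c]] += raw[c];
    for (int c = 0; c < nc; ++c) {
      acc[c] += fold[c];
      acc2[c] += fold[c] * fold[c];
    }
  }
  NumericMatrix mean(n1 + 1, n2 + 1), var(n1 + 1, n2 + 1);
  for (int c = 0; c < nc; ++c) {
    double mu = acc[c] / nReps;
    mean[c] = mu;
    double v = acc2[c] / nReps - mu * mu;
    if (v < 0) v = 0;
    var[c] = v / nReps;      // variance of the mean
  }
  return List::create(Named("mean") = mean, Named("var") = var);
}
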