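#include <Rcpp.h>
using namespace Rcpp;

// Nearest-taxon distances under a tip-label permutation.
//
// M(i, s) = min over taxa j present in sample s of D(perm[i], perm[j]).
// D(i, i) = 0, so a taxon present in s has M = 0 against s.
static void nearest_taxon(const NumericMatrix& D,
                          const std::vector< std::vector<int> >& present,
                          const std::vector<int>& perm,
                          std::vector<double>& M) {
  const int n = D.nrow();
  const int S = (int) present.size();
  for (int s = 0; s < S; ++s) {
    const std::vector<int>& pres = present[s];
    for (int i = 0; i < n; ++i) {
      const double* col = &D(0, perm[i]);   // column-major: D(., perm[i])
      double best = R_PosInf;
      for (size_t k = 0; k < pres.size(); ++k) {
        double d = col[perm[pres[k]]];
        if (d < best) best = d;
      }
      M[(size_t) s * n + i] = best;
    }
  }
}

// beta-MNTD for all sample pairs given nearest-taxon matrix M and weights W.
// bmntd(k, m) = 0.5 * (sum_i W(i,k) M(i,m) + sum_j W(j,m) M(j,k))
static void bmntd_from_M(const NumericMatrix& W,
                         const std::vector<double>& M,
                         std::vector<double>& out) {
  const int n = W.nrow();
  const int S = W.ncol();
  // A(k, s) = sum_i W(i,k) * M(i,s)
  std::vector<double> A((size_t) S * S, 0.0);
  for (int s = 0; s < S; ++s) {
    const double* Ms = &M[(size_t) s * n];
    for (int k = 0; k < S; ++k) {
      const double* Wk = &W(0, k);
      double acc = 0.0;
      for (int i = 0; i < n; ++i) acc += Wk[i] * Ms[i];
      A[(size_t) s * S + k] = acc;
    }
  }
  for (int k = 0; k < S; ++k)
    for (int m = 0; m < S; ++m)
      out[(size_t) m * S + k] =
        0.5 * (A[(size_t) m * S + k] + A[(size_t) k * S + m]);
}

static std::vector< std::vector<int> > presence_lists(const NumericMatrix& W) {
  const int n = W.nrow(), S = W.ncol();
  std::vector< std::vector<int> > present(S);
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < n; ++i)
      if (W(i, s) > 0) present[s].push_back(i);
  return present;
}

// [[Rcpp::export]]
NumericMatrix cpp_beta_mntd(NumericMatrix D, NumericMatrix W) {
  const int n = D.nrow(), S = W.ncol();
  if (W.nrow() != n) stop("weight matrix rows must match distance matrix");
  std::vector< std::vector<int> > present = presence_lists(W);
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  std::vector<double> M((size_t) S * n), out((size_t) S * S);
  nearest_taxon(D, present, perm, M);
  bmntd_from_M(W, M, out);
  NumericMatrix res(S, S);
  std::copy(out.begin(), out.end(), res.begin());
  return res;
}

// Observed beta-MNTD plus null mean/sd over tip-label permutations.
// perms: n_null x n_taxa matrix of 0-based permutations (generated in R so
// that the null is reproducible from R's RNG state).
// [[Rcpp::export]]
List cpp_bnti_null(NumericMatrix D, NumericMatrix W, IntegerMatrix perms) {
  const int n = D.nrow(), S = W.ncol();
  if (W.nrow() != n) stop("weight matrix rows must match distance matrix");
  if (perms.ncol() != n) stop("permutation matrix columns must match taxa");
  const int n_null = perms.nrow();

  std::vector< std::vector<int> > present = presence_lists(W);
  std::vector<int> perm(n);
  std::vector<double> M((size_t) S * n), val((size_t) S * S);

  for (int i = 0; i < n; ++i) perm[i] = i;
  nearest_taxon(D, present, perm, M);
  std::vector<double> obs((size_t) S * S);
  bmntd_from_M(W, M, obs);

  std::vector<double> sum((size_t) S * S, 0.0), sumsq((size_t) S * S, 0.0);
  for (int r = 0; r < n_null; ++r) {
    for (int i = 0; i < n; ++i) perm[i] = perms(r, i);
    nearest_taxon(D, present, perm, M);
    bmntd_from_M(W, M, val);
    for (size_t k = 0; k < val.size(); ++k) {
      sum[k] += val[k];
      sumsq[k] += val[k] * val[k];
    }
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix obs_m(S, S), mean_m(S, S), sd_m(S, S);
  for (size_t k = 0; k < obs.size(); ++k) {
    obs_m[k] = obs[k];
    double mu = sum[k] / n_null;
    mean_m[k] = mu;
    double var = (sumsq[k] - n_null * mu * mu) / (n_null - 1.0);
    sd_m[k] = var > 0 ? std::sqrt(var) : 0.0;
  }
  return List::create(_["obs"] = obs_m, _["null_mean"] = mean_m,
                      _["null_sd"] = sd_m);
}

static int draw_cum(const std::vector<double>& cum) {
  // binary search for first cum[i] >= u
  double u = unif_rand() * cum.back();
  int lo = 0, hi = (int) cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] >= u) hi = mid; else lo = mid + 1;
  }
  return lo;
}

// Sloan death-replacement chain for one local community.
// A vector of N individual labels is evolved for burn_in events: a uniformly
// chosen individual dies and is replaced by a metacommunity immigrant with
// probability m_event, otherwise by a copy of a uniformly chosen local
// individual. Uses R's RNG (seed-reproducible from R).
// [[Rcpp::export]]
IntegerVector cpp_neutral_community(NumericVector meta_p, int N,
                                    double m_event, int burn_in) {
  const int n = meta_p.size();
  std::vector<double> cum(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) { acc += meta_p[i]; cum[i] = acc; }

  std::vector<int> ind(N);
  for (int k = 0; k < N; ++k) ind[k] = draw_cum(cum);

  for (int t = 0; t < burn_in; ++t) {
    int dead = (int) (unif_rand() * N);
    if (dead == N) dead = N - 1;
    if (unif_rand() < m_event) {
      ind[dead] = draw_cum(cum);
    } else {
      int parent = (int) (unif_rand() * N);
      if (parent == N) parent = N - 1;
      ind[dead] = ind[parent];
    }
  }

  IntegerVector counts(n);
  for (int k = 0; k < N; ++k) counts[ind[k]] += 1;
  return counts;
}
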