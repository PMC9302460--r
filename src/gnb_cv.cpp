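// Gaussian naive Bayes repeated stratified cross-validation engine.
//
// This loop runs once per searchlight cell and per label randomization, so
// the hot path lives here. Semantics match the exported R reference
// implementation (fitGnb / predictGnb):
//   - per-class feature means and maximum-likelihood variances (divisor n),
//   - variance floor eps = 1e-9 * mean(class-feature variances)
//     (absolute fallback 1e-12 when everything is constant),
//   - priors = training class frequencies,
//   - argmax of log prior + sum of log univariate normal densities,
//     ties broken toward the lowest class index (canonical class order).
//
// Fold assignments and undersampling are decided in R (seeded there) and
// passed in as plans. Per fold, training statistics are the repeat totals
// minus the fold's own sufficient statistics; the per-fold class
// parameters are stacked so each repeat needs only two GEMMs for all test
// log-likelihoods. Data are held transposed (features x trials) so trial
// access is contiguous.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// One repeat for one labeling; appends per-fold accuracies to foldAcc.
static void evalRepeat(const arma::mat& Xt, const arma::mat& X2t,
                       const arma::ivec& y, // labels per trial (1..K)
                       const arma::uvec& idx, const arma::ivec& fold,
                       int K, std::vector<double>& foldAcc) {
  const arma::uword p = Xt.n_rows;
  const arma::uword m = idx.n_elem;
  int F = 0;
  for (arma::uword i = 0; i < m; ++i) F = std::max(F, (int)fold[i]);
  if (F < 2) return;

  // sufficient statistics per (class, fold)
  arma::cube sum1(p, K, F, arma::fill::zeros);
  arma::cube sum2(p, K, F, arma::fill::zeros);
  arma::imat cnt(K, F, arma::fill::zeros);
  for (arma::uword i = 0; i < m; ++i) {
    const int k = y[idx[i]] - 1;
    const int f = fold[i] - 1;
    sum1.slice(f).unsafe_col(k) += Xt.unsafe_col(idx[i]);
    sum2.slice(f).unsafe_col(k) += X2t.unsafe_col(idx[i]);
    cnt(k, f) += 1;
  }
  arma::mat tot1(p, K, arma::fill::zeros), tot2(p, K, arma::fill::zeros);
  arma::ivec totn(K, arma::fill::zeros);
  for (int f = 0; f < F; ++f) {
    tot1 += sum1.slice(f);
    tot2 += sum2.slice(f);
    totn += cnt.col(f);
  }

  // per-fold class parameters, stacked: columns f*K + k
  arma::mat Wall(p, (arma::uword)K * F);
  arma::mat MWall(p, (arma::uword)K * F);
  arma::rowvec base((arma::uword)K * F);
  std::vector<bool> foldOk(F, true);
  for (int f = 0; f < F; ++f) {
    arma::ivec ntr = totn - cnt.col(f);
    if (arma::any(ntr < 2)) { foldOk[f] = false; continue; }
    arma::mat mu(p, K), vr(p, K);
    double ntrain = 0;
    for (int k = 0; k < K; ++k) {
      const double nk = (double)ntr[k];
      mu.col(k) = (tot1.col(k) - sum1.slice(f).col(k)) / nk;
      vr.col(k) = (tot2.col(k) - sum2.slice(f).col(k)) / nk -
                  arma::square(mu.col(k));
      ntrain += nk;
    }
    vr.elem(arma::find(vr < 0)).zeros(); // numerical guard
    double eps = 1e-9 * arma::mean(arma::vectorise(vr));
    if (eps <= 0) eps = 1e-12;
    vr.elem(arma::find(vr < eps)).fill(eps);
    for (int k = 0; k < K; ++k) {
      const arma::uword c = (arma::uword)f * K + k;
      Wall.col(c) = 1.0 / vr.col(k);
      MWall.col(c) = mu.col(k) % Wall.col(c);
      base[c] = std::log((double)ntr[k] / ntrain) -
                0.5 * arma::accu(arma::log(vr.col(k))) -
                0.5 * arma::dot(mu.col(k), MWall.col(c));
    }
  }

  // two GEMMs cover every kept trial's log-likelihood under every fold's
  // parameters; each trial is then scored under its own fold only
  arma::mat A = Wall.t() * X2t.cols(idx);   // (K*F) x m
  arma::mat B = MWall.t() * Xt.cols(idx);   // (K*F) x m
  std::vector<int> correct(F, 0), total(F, 0);
  for (arma::uword i = 0; i < m; ++i) {
    const int f = fold[i] - 1;
    if (!foldOk[f]) continue;
    const arma::uword c0 = (arma::uword)f * K;
    int best = 0;
    double bestLL = -0.5 * A(c0, i) + B(c0, i) + base[c0];
    for (int k = 1; k < K; ++k) {
      const double ll = -0.5 * A(c0 + k, i) + B(c0 + k, i) + base[c0 + k];
      if (ll > bestLL) { bestLL = ll; best = k; }
    }
    total[f] += 1;
    if (best + 1 == y[idx[i]]) correct[f] += 1;
  }
  for (int f = 0; f < F; ++f)
    if (foldOk[f] && total[f] > 0)
      foldAcc.push_back((double)correct[f] / (double)total[f]);
}

// ---- deterministic in-engine randomization -------------------------------
// Fold assignment and undersampling are re-randomized per (cell, labeling,
// repeat). A self-contained SplitMix64 stream plus explicit
// rejection-bounded draws keeps the assignment bit-identical across
// platforms (nothing here depends on implementation-defined library
// distributions).

static inline uint64_t splitmix64(uint64_t& x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t boundedDraw(uint64_t& state, uint64_t n) {
  const uint64_t lim = UINT64_MAX - UINT64_MAX % n;
  uint64_t v;
  do { v = splitmix64(state); } while (v >= lim);
  return v % n;
}

// Stratified undersampled fold plan for one labeling/repeat: every class
// keeps the minority count via a Fisher-Yates shuffle, and fold ids cycle
// within each class so per-fold class counts differ by at most one.
static bool makePlan(const arma::ivec& y, int K, int F, bool undersample,
                     uint64_t state, arma::uvec& idx, arma::ivec& fold) {
  const int n = y.n_elem;
  std::vector<std::vector<int> > byClass(K);
  for (int i = 0; i < n; ++i) byClass[y[i] - 1].push_back(i);
  int m = n;
  for (int k = 0; k < K; ++k) m = std::min(m, (int)byClass[k].size());
  if (m < F) return false;
  std::vector<int> outIdx, outFold;
  for (int k = 0; k < K; ++k) {
    std::vector<int>& cls = byClass[k];
    for (int i = (int)cls.size() - 1; i > 0; --i)
      std::swap(cls[i], cls[boundedDraw(state, (uint64_t)(i + 1))]);
    const int keepK = undersample ? m : (int)cls.size();
    for (int i = 0; i < keepK; ++i) {
      outIdx.push_back(cls[i]);
      outFold.push_back(i % F + 1);
    }
  }
  idx.set_size(outIdx.size());
  fold.set_size(outFold.size());
  for (size_t i = 0; i < outIdx.size(); ++i) {
    idx[i] = (arma::uword)outIdx[i];
    fold[i] = outFold[i];
  }
  return true;
}

// [[Rcpp::export(name = ".gnbCvManyGen")]]
NumericVector gnbCvManyGen(const arma::mat& Xt, const IntegerMatrix& labels,
                           int nClasses, int nFolds, int nRepeats,
                           bool undersample, double cellSeed) {
  const int L = labels.ncol();
  if ((int)Xt.n_cols != labels.nrow())
    stop("Xt must be features x trials with one column per labeled trial");
  arma::mat X2t = arma::square(Xt);
  NumericVector out(L);
  for (int l = 0; l < L; ++l) {
    arma::ivec y(labels.nrow());
    for (int i = 0; i < labels.nrow(); ++i) y[i] = labels(i, l);
    std::vector<double> foldAcc;
    for (int r = 0; r < nRepeats; ++r) {
      uint64_t state = (uint64_t)cellSeed;
      state ^= splitmix64(state) + (uint64_t)(l + 1) * 0x9E3779B97F4A7C15ULL;
      state ^= splitmix64(state) + (uint64_t)(r + 1) * 0xC2B2AE3D27D4EB4FULL;
      arma::uvec idx;
      arma::ivec fold;
      if (!makePlan(y, nClasses, nFolds, undersample, state, idx, fold))
        continue;
      evalRepeat(Xt, X2t, y, idx, fold, nClasses, foldAcc);
    }
    out[l] = foldAcc.empty()
      ? NA_REAL
      : std::accumulate(foldAcc.begin(), foldAcc.end(), 0.0) / foldAcc.size();
  }
  return out;
}

// [[Rcpp::export(name = ".gnbCvMany")]]
NumericVector gnbCvMany(const arma::mat& Xt, const IntegerMatrix& labels,
                        const List& plans, int nClasses) {
  const int L = labels.ncol();
  if (plans.size() != L) stop("plans must have one element per labeling");
  if ((int)Xt.n_cols != labels.nrow())
    stop("Xt must be features x trials with one column per labeled trial");
  arma::mat X2t = arma::square(Xt);
  NumericVector out(L);
  for (int l = 0; l < L; ++l) {
    arma::ivec y(labels.nrow());
    for (int i = 0; i < labels.nrow(); ++i) y[i] = labels(i, l);
    List reps = plans[l];
    std::vector<double> foldAcc;
    for (int r = 0; r < reps.size(); ++r) {
      List plan = reps[r];
      IntegerVector idxR = plan["idx"];   // 0-based kept trials
      IntegerVector foldR = plan["fold"]; // 1..F per kept trial
      arma::uvec idx(idxR.size());
      arma::ivec fold(foldR.size());
      for (int i = 0; i < idxR.size(); ++i) {
        idx[i] = (arma::uword)idxR[i];
        fold[i] = foldR[i];
      }
      evalRepeat(Xt, X2t, y, idx, fold, nClasses, foldAcc);
    }
    out[l] = foldAcc.empty()
      ? NA_REAL
      : std::accumulate(foldAcc.begin(), foldAcc.end(), 0.0) / foldAcc.size();
  }
  return out;
}
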