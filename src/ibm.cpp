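// Individual-based Wright-Fisher engine.
//
// The community is stored as classes of identical cells (focal allele,
// background genotype, niche, count) rather than per-cell arrays, so
// N = 1e5..1e6 communities with thousands of distinct immigrant lineages
// stay tractable. All randomness is drawn from R's RNG stream (unif_rand /
// rbinom), so set.seed() in R makes runs bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>

#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Binomial(n, p) draw. For modest means uses the BINV inversion series
// (one log1p/exp plus ~mean iterations); otherwise defers to R::rbinom
// (BTPE). Both consume R's RNG stream.
static inline int fast_binom(double n, double p) {
  if (n <= 0 || p <= 0) return 0;
  if (p >= 1) return (int)n;
  double np = n * p;
  if (np < 100.0 && p < 0.4) {
    double sp = p / (1.0 - p);
    double f = std::exp(n * std::log1p(-p));
    if (f <= 0) return (int)R::rbinom(n, p);
    double u = unif_rand();
    int k = 0;
    while (u > f) {
      u -= f;
      f *= sp * (n - k) / (k + 1.0);
      ++k;
      if (k >= (int)n || f <= 0 || k > 1200) break;
    }
    return k;
  }
  return (int)R::rbinom(n, p);
}

struct Community {
  std::vector<double> focal, bg; // genotype ids, integral values (exact < 2^53)
  std::vector<int> niche;        // 0-based
  std::vector<int> cnt;
  size_t size() const { return cnt.size(); }
};

// [[Rcpp::export]]
DataFrame ibm_run_cpp(NumericVector focal0, NumericVector bg0,
                      IntegerVector niche0, IntegerVector cnt0,
                      int N, int n, double z, double s, double r, double m,
                      int t_end, double next_id, int record_every) {
  Community cm;
  size_t K0 = focal0.size();
  cm.focal.assign(focal0.begin(), focal0.end());
  cm.bg.assign(bg0.begin(), bg0.end());
  cm.niche.resize(K0);
  for (size_t i = 0; i < K0; ++i) cm.niche[i] = niche0[i] - 1;
  cm.cnt.assign(cnt0.begin(), cnt0.end());

  const double fsel = 1.0 + s;
  const double off = (n > 1) ? (1.0 - z) / (n - 1) : 0.0;
  std::vector<double> W(n), A(n), G(n);
  std::vector<double> wgt;
  std::vector<int> positions;
  std::vector<uint64_t> bitmap;

  std::vector<int> out_gen;
  std::vector<double> out_C, out_flux, out_cum, out_Df, out_Dbg, out_DR;
  std::unordered_map<long long, double> bgsum;
  double total_conv = 0;

  // order-2 Hill diversities; non-carrier focal ids are unique per class,
  // background ids may span several classes (original + converted copies)
  auto record = [&](int gen, double flux) {
    double ncar = 0, sum2f = 0;
    for (size_t i = 0; i < cm.size(); ++i) {
      if (cm.focal[i] == 1.0) ncar += cm.cnt[i];
      else sum2f += (double)cm.cnt[i] * cm.cnt[i];
    }
    sum2f = (sum2f + ncar * ncar) / ((double)N * N);
    bgsum.clear();
    for (size_t i = 0; i < cm.size(); ++i)
      bgsum[(long long)cm.bg[i]] += cm.cnt[i];
    double sum2b = 0;
    for (auto &kv : bgsum) sum2b += kv.second * kv.second;
    sum2b /= (double)N * N;
    double Df = 1.0 / sum2f, Dbg = 1.0 / sum2b;
    out_gen.push_back(gen);
    out_C.push_back(ncar / N);
    out_flux.push_back(flux);
    out_cum.push_back(total_conv);
    out_Df.push_back(Df);
    out_Dbg.push_back(Dbg);
    out_DR.push_back(Dbg / Df);
  };

  record(0, 0.0);

  for (int gen = 1; gen <= t_end; ++gen) {
    size_t K = cm.size();

    // --- resource allocation -------------------------------------------
    // Omega_j = z W_j + off (W_tot - W_j); per-cell resources of a class
    // in niche a: R = f * (z A_a + off (S_A - A_a)), A_j = (N/n)/Omega_j
    std::fill(W.begin(), W.end(), 0.0);
    double Wtot = 0;
    for (size_t i = 0; i < K; ++i) {
      double w = cm.cnt[i] * (cm.focal[i] == 1.0 ? fsel : 1.0);
      W[cm.niche[i]] += w;
      Wtot += w;
    }
    double SA = 0;
    for (int j = 0; j < n; ++j) {
      double Om = (n > 1) ? z * W[j] + off * (Wtot - W[j]) : Wtot;
      A[j] = (Om > 0) ? ((double)N / n) / Om : 0.0;
      SA += A[j];
    }
    for (int j = 0; j < n; ++j)
      G[j] = (n > 1) ? z * A[j] + off * (SA - A[j]) : A[j];

    wgt.resize(K);
    double Wrem = 0;
    for (size_t i = 0; i < K; ++i) {
      wgt[i] = cm.cnt[i] * (cm.focal[i] == 1.0 ? fsel : 1.0) * G[cm.niche[i]];
      Wrem += wgt[i];
    }
    if (Wrem <= 0) stop("all classes received zero resources");

    // --- Wright-Fisher reproduction ------------------------------------
    // sequential conditional binomials == exact multinomial(N, w)
    int Trem = N;
    size_t wr = 0;
    for (size_t i = 0; i < K; ++i) {
      int k;
      if (i + 1 == K || Wrem <= wgt[i]) {
        k = Trem;
      } else {
        double pp = wgt[i] / Wrem;
        if (pp > 1) pp = 1;
        k = fast_binom(Trem, pp);
        if (k > Trem) k = Trem;
      }
      Wrem -= wgt[i];
      if (k > 0) {
        Trem -= k;
        cm.focal[wr] = cm.focal[i];
        cm.bg[wr] = cm.bg[i];
        cm.niche[wr] = cm.niche[i];
        cm.cnt[wr] = k;
        ++wr;
      }
      if (Trem == 0) break;
    }
    cm.focal.resize(wr); cm.bg.resize(wr);
    cm.niche.resize(wr); cm.cnt.resize(wr);
    K = wr;

    double ncar = 0;
    for (size_t i = 0; i < K; ++i)
      if (cm.focal[i] == 1.0) ncar += cm.cnt[i];
    double C = ncar / N;

    // --- horizontal transfer -------------------------------------------
    // each non-carrier converts independently w.p. C*r; successes located
    // by geometric skips over the concatenated non-carrier cells
    double pr = C * r;
    int conversions = 0;
    long long noncar = N - (long long)ncar;
    if (pr > 0 && noncar > 0) {
      positions.clear();
      double lq = std::log1p(-pr);
      double pos = std::floor(std::log(unif_rand()) / lq);
      while (pos < (double)noncar) {
        positions.push_back((int)pos);
        pos += 1.0 + std::floor(std::log(unif_rand()) / lq);
      }
      if (!positions.empty()) {
        size_t pi = 0;
        long long cum = 0;
        for (size_t i = 0; i < K && pi < positions.size(); ++i) {
          if (cm.focal[i] == 1.0) continue;
          cum += cm.cnt[i];
          int here = 0;
          while (pi < positions.size() && positions[pi] < cum) { ++here; ++pi; }
          if (here > 0) {
            cm.cnt[i] -= here;
            cm.focal.push_back(1.0);
            cm.bg.push_back(cm.bg[i]);
            cm.niche.push_back(cm.niche[i]);
            cm.cnt.push_back(here);
          }
        }
        conversions = (int)positions.size();
        total_conv += conversions;
        ncar += conversions;
        K = cm.size();
      }
    }

    // --- migration ------------------------------------------------------
    // Binomial(N, m) distinct cells replaced by unique immigrants; the
    // victim cell indices are marked in a bitmap (rejection sampling of
    // distinct uniforms) and mapped to classes by range popcounts
    int M = fast_binom(N, m);
    if (M > 0) {
      size_t words = (size_t)(N + 63) / 64;
      if (bitmap.size() < words) bitmap.resize(words);
      if (M <= N / 2) {
        std::fill(bitmap.begin(), bitmap.begin() + words, 0ULL);
        for (int drawn = 0; drawn < M; ) {
          int x = (int)(unif_rand() * N);
          if (x >= N) x = N - 1;
          uint64_t mask = 1ULL << (x & 63);
          if (!(bitmap[x >> 6] & mask)) { bitmap[x >> 6] |= mask; ++drawn; }
        }
      } else { // dense case: mark all, then clear N - M survivors
        std::fill(bitmap.begin(), bitmap.begin() + words, ~0ULL);
        if (N & 63) bitmap[words - 1] = (1ULL << (N & 63)) - 1;
        for (int cleared = 0; cleared < N - M; ) {
          int x = (int)(unif_rand() * N);
          if (x >= N) x = N - 1;
          uint64_t mask = 1ULL << (x & 63);
          if (bitmap[x >> 6] & mask) { bitmap[x >> 6] &= ~mask; ++cleared; }
        }
      }
      long long cum = 0;
      int left = M;
      for (size_t i = 0; i < K && left > 0; ++i) {
        if (cm.cnt[i] == 0) continue;
        long long lo = cum, hi = cum + cm.cnt[i];
        cum = hi;
        // popcount of bitmap bits in [lo, hi)
        int here = 0;
        size_t wlo = (size_t)(lo >> 6), whi = (size_t)((hi - 1) >> 6);
        if (wlo == whi) {
          uint64_t w = bitmap[wlo] >> (lo & 63);
          int span = (int)(hi - lo);
          if (span < 64) w &= (1ULL << span) - 1;
          here = __builtin_popcountll(w);
        } else {
          here = __builtin_popcountll(bitmap[wlo] >> (lo & 63));
          for (size_t w = wlo + 1; w < whi; ++w)
            here += __builtin_popcountll(bitmap[w]);
          int rem = (int)(hi & 63);
          uint64_t wl = bitmap[whi];
          if (rem > 0) wl &= (1ULL << rem) - 1;
          here += __builtin_popcountll(wl);
        }
        if (here > 0) {
          left -= here;
          cm.cnt[i] -= here;
          if (cm.focal[i] == 1.0) ncar -= here;
        }
      }
      for (int j = 0; j < M; ++j) {
        cm.focal.push_back(next_id);
        cm.bg.push_back(next_id);
        int nj = (int)(unif_rand() * n);
        cm.niche.push_back(nj >= n ? n - 1 : nj);
        cm.cnt.push_back(1);
        next_id += 1.0;
      }
      K = cm.size();
    }

    // --- compaction and periodic carrier-class merge --------------------
    size_t w2 = 0;
    for (size_t i = 0; i < K; ++i) {
      if (cm.cnt[i] > 0) {
        if (w2 != i) {
          cm.focal[w2] = cm.focal[i]; cm.bg[w2] = cm.bg[i];
          cm.niche[w2] = cm.niche[i]; cm.cnt[w2] = cm.cnt[i];
        }
        ++w2;
      }
    }
    cm.focal.resize(w2); cm.bg.resize(w2);
    cm.niche.resize(w2); cm.cnt.resize(w2);
    K = w2;

    if (gen % 64 == 0) {
      // transfer can duplicate (1, bg, niche) rows; fold them together
      std::unordered_map<long long, size_t> first;
      size_t w3 = 0;
      for (size_t i = 0; i < K; ++i) {
        if (cm.focal[i] == 1.0) {
          long long key = (long long)cm.bg[i] * (n + 1) + cm.niche[i];
          auto it = first.find(key);
          if (it != first.end()) { cm.cnt[it->second] += cm.cnt[i]; continue; }
          first[key] = w3;
        }
        cm.focal[w3] = cm.focal[i]; cm.bg[w3] = cm.bg[i];
        cm.niche[w3] = cm.niche[i]; cm.cnt[w3] = cm.cnt[i];
        ++w3;
      }
      cm.focal.resize(w3); cm.bg.resize(w3);
      cm.niche.resize(w3); cm.cnt.resize(w3);
      K = w3;
    }

    long long tot = 0;
    for (size_t i = 0; i < K; ++i) tot += cm.cnt[i];
    if (tot != N) stop("internal error: community size drifted");

    if (gen % record_every == 0 || gen == t_end)
      record(gen, (double)conversions);

    if (gen % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return DataFrame::create(
    _["generation"] = out_gen, _["C"] = out_C,
    _["flux_realized"] = out_flux, _["cumulative_flux"] = out_cum,
    _["D_f"] = out_Df, _["D_bg"] = out_Dbg, _["DR"] = out_DR);
}
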