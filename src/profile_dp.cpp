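// Profile-HMM dynamic programming for single-sequence path resampling.
//
// States: Begin (= M_0), M_1..M_w, I_0..I_w, D_1..D_w, End.  Insert and
// delete states may not interleave (no I->D or D->I transitions), so a
// sequence's path is uniquely determined by its match-column map.
//
// Modes: 0 = stochastic traceback (posterior path sample under the given
// emission/transition weights, with its proposal log-probability),
// 1 = Viterbi, 2 = evaluate the proposal log-probability of a given path.

#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

static const double NEG_INF = -DBL_MAX / 4;

static inline double lse2(double a, double b) {
  if (a < b) std::swap(a, b);
  if (a <= NEG_INF) return NEG_INF;
  if (b <= NEG_INF) return a;
  return a + std::log1p(std::exp(b - a));
}
static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

// Column order in logTrans: mm, mi, md, im, ii, dm, dd (rows = blocks 0..w).
enum { MM = 0, MI, MD, IM, II, DM, DD };

struct DP {
  int w, L;
  std::vector<double> M, I, D;
  double& m(int j, int i) { return M[(size_t)j * (L + 1) + i]; }
  double& ins(int j, int i) { return I[(size_t)j * (L + 1) + i]; }
  double& d(int j, int i) { return D[(size_t)j * (L + 1) + i]; }
};

// Pick among up to three weighted options; returns index, adds conditional
// log-probability to logq.
static int pick3(double w0, double w1, double w2, bool sample, double& logq) {
  double tot = lse3(w0, w1, w2);
  double lw[3] = { w0, w1, w2 };
  int choice = 0;
  if (sample) {
    double u = unif_rand(), acc = 0;
    for (int t = 0; t < 3; ++t) {
      acc += std::exp(lw[t] - tot);
      if (u <= acc || t == 2) { choice = t; break; }
    }
    while (lw[choice] <= NEG_INF) --choice; // numeric guard
  } else {
    choice = 0;
    for (int t = 1; t < 3; ++t) if (lw[t] > lw[choice]) choice = t;
  }
  logq += lw[choice] - tot;
  return choice;
}

// [[Rcpp::export(name = ".dpAlign")]]
List dpAlign(NumericMatrix logEmis, NumericVector logIns,
             NumericMatrix logTrans, IntegerVector seqCodes,
             int mode, IntegerVector givenPath) {
  const int w = logEmis.nrow();
  const int L = seqCodes.size();
  if (logTrans.nrow() != w + 1) stop("logTrans must have w+1 rows");

  DP dp;
  dp.w = w; dp.L = L;
  dp.M.assign((size_t)(w + 1) * (L + 1), NEG_INF);
  dp.I.assign((size_t)(w + 1) * (L + 1), NEG_INF);
  dp.D.assign((size_t)(w + 1) * (L + 1), NEG_INF);
  dp.m(0, 0) = 0.0; // Begin

  std::vector<double> em(L + 1), insEm(L + 1);
  for (int i = 1; i <= L; ++i) {
    int r = seqCodes[i - 1]; // 1..20, 0 = X
    insEm[i] = (r > 0) ? logIns[r - 1] : 0.0;
  }

  for (int j = 0; j <= w; ++j) {
    if (j >= 1) {
      for (int i = 0; i <= L; ++i) {
        if (i >= 1) {
          int r = seqCodes[i - 1];
          double e = (r > 0) ? logEmis(j - 1, r - 1) : 0.0;
          double a = dp.m(j - 1, i - 1) + logTrans(j - 1, MM);
          double b = dp.ins(j - 1, i - 1) + logTrans(j - 1, IM);
          double c = (j >= 2) ? dp.d(j - 1, i - 1) + logTrans(j - 1, DM) : NEG_INF;
          dp.m(j, i) = e + lse3(a, b, c);
        }
        double a = dp.m(j - 1, i) + logTrans(j - 1, MD);
        double c = (j >= 2) ? dp.d(j - 1, i) + logTrans(j - 1, DD) : NEG_INF;
        dp.d(j, i) = lse2(a, c);
      }
    }
    for (int i = 1; i <= L; ++i) {
      double a = dp.m(j, i - 1) + logTrans(j, MI);
      double b = dp.ins(j, i - 1) + logTrans(j, II);
      dp.ins(j, i) = insEm[i] + lse2(a, b);
    }
  }

  double endM = dp.m(w, L) + logTrans(w, MM);
  double endI = dp.ins(w, L) + logTrans(w, IM);
  double endD = (w >= 1) ? dp.d(w, L) + logTrans(w, DM) : NEG_INF;
  double logZ = lse3(endM, endI, endD);

  IntegerVector path(w, 0); // 0 = deletion
  double logq = 0.0;

  if (mode == 2) {
    // Evaluate the proposal probability of a given path by replaying the
    // (unique) state chain backward through the traceback conditionals.
    // Reconstruct states: list of (type 0=M,1=I,2=D, j, i) from Begin..End.
    std::vector<std::array<int, 3>> chain;
    chain.push_back({0, 0, 0});
    int pos = 0;
    int lastMatchedJ = 0;
    for (int j = 1; j <= w; ++j) {
      int a = givenPath[j - 1];
      if (a > 0) {
        // inserts between pos and a sit at I_{j-1}: requires previous block
        // reachable (legality checked implicitly by weights)
        for (int q = pos + 1; q < a; ++q)
          chain.push_back({1, j - 1, q});
        chain.push_back({0, j, a});
        pos = a;
        lastMatchedJ = j;
      } else {
        chain.push_back({2, j, pos});
      }
    }
    for (int q = pos + 1; q <= L; ++q) chain.push_back({1, w, q});
    (void)lastMatchedJ;
    // Backward replay: End choice first.
    auto last = chain.back();
    double lw0 = endM, lw1 = endI, lw2 = endD;
    double tot = lse3(lw0, lw1, lw2);
    double chosen = (last[0] == 0 && last[1] == w && last[2] == L) ? lw0 :
                    (last[0] == 1 && last[1] == w) ? lw1 : lw2;
    if (!(last[1] == w) || chosen <= NEG_INF || tot <= NEG_INF)
      return List::create(_["path"] = givenPath, _["logq"] = R_NegInf,
                          _["logZ"] = logZ);
    logq += chosen - tot;
    for (size_t t = chain.size() - 1; t >= 1; --t) {
      auto cur = chain[t];
      auto prev = chain[t - 1];
      int type = cur[0], j = cur[1], i = cur[2];
      double wM = NEG_INF, wI = NEG_INF, wD = NEG_INF;
      if (type == 0) {
        wM = dp.m(j - 1, i - 1) + logTrans(j - 1, MM);
        wI = dp.ins(j - 1, i - 1) + logTrans(j - 1, IM);
        if (j >= 2) wD = dp.d(j - 1, i - 1) + logTrans(j - 1, DM);
      } else if (type == 1) {
        wM = dp.m(j, i - 1) + logTrans(j, MI);
        wI = dp.ins(j, i - 1) + logTrans(j, II);
      } else {
        wM = dp.m(j - 1, i) + logTrans(j - 1, MD);
        if (j >= 2) wD = dp.d(j - 1, i) + logTrans(j - 1, DD);
      }
      double total = lse3(wM, wI, wD);
      double pick = (prev[0] == 0) ? wM : (prev[0] == 1) ? wI : wD;
      if (pick <= NEG_INF || total <= NEG_INF)
        return List::create(_["path"] = givenPath, _["logq"] = R_NegInf,
                            _["logZ"] = logZ);
      logq += pick - total;
      if (t == 1) break;
    }
    return List::create(_["path"] = givenPath, _["logq"] = logq,
                        _["logZ"] = logZ);
  }

  bool sample = (mode == 0);
  // Traceback from End.
  int choice = pick3(endM, endI, endD, sample, logq);
  int type = (choice == 0) ? 0 : (choice == 1) ? 1 : 2;
  int j = w, i = L;
  while (!(type == 0 && j == 0 && i == 0)) {
    if (type == 0) {
      path[j - 1] = i;
      double wM = dp.m(j - 1, i - 1) + logTrans(j - 1, MM);
      double wI = dp.ins(j - 1, i - 1) + logTrans(j - 1, IM);
      double wD = (j >= 2) ? dp.d(j - 1, i - 1) + logTrans(j - 1, DM) : NEG_INF;
      int c = pick3(wM, wI, wD, sample, logq);
      --j; --i;
      type = (c == 0) ? 0 : (c == 1) ? 1 : 2;
    } else if (type == 1) {
      double wM = dp.m(j, i - 1) + logTrans(j, MI);
      double wI = dp.ins(j, i - 1) + logTrans(j, II);
      int c = pick3(wM, wI, NEG_INF, sample, logq);
      --i;
      type = (c == 0) ? 0 : 1;
    } else {
      double wM = dp.m(j - 1, i) + logTrans(j - 1, MD);
      double wD = (j >= 2) ? dp.d(j - 1, i) + logTrans(j - 1, DD) : NEG_INF;
      int c = pick3(wM, wD, NEG_INF, sample, logq);
      --j;
      type = (c == 0) ? 0 : 2;
    }
  }
  return List::create(_["path"] = path, _["logq"] = logq, _["logZ"] = logZ);
}
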