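#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Profile-HMM local scoring in log2-odds space.
//
// States at position j = 0..m: M_j (M_0 = Begin), I_j, D_j (j >= 1).
// Begin is available before every sequence offset at score 0 and exit from
// position m is allowed after any offset, so residues flanking the aligned
// window are free (log-odds 0 against the background). Transitions follow
// the plan7 core (no I->D, no D->I). Insert emissions equal the background,
// hence contribute log-odds 0.

static const double NEG = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  // log2(2^a + 2^b)
  if (a == NEG) return b;
  if (b == NEG) return a;
  double hi = a > b ? a : b, lo = a > b ? b : a;
  return hi + std::log1p(std::exp2(lo - hi)) / M_LN2;
}

static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

// dedicated Viterbi path: plain max/plus, no function-object indirection
static double viterbi_one(const int* seq, int L,
                          const double* em, int m,   // em: column-major m x 20
                          const double* mm, const double* mi,
                          const double* md, const double* im,
                          const double* ii, const double* dm,
                          const double* dd) {
  std::vector<double> VMp(m + 1, NEG), VIp(m + 1, NEG), VDp(m + 1, NEG);
  std::vector<double> VM(m + 1, NEG), VI(m + 1, NEG), VD(m + 1, NEG);
  VMp[0] = 0.0;
  VDp[1] = md[0];
  for (int j = 2; j <= m; ++j) VDp[j] = VDp[j - 1] + dd[j - 1];
  double best = VDp[m] + dm[m];
  for (int i = 1; i <= L; ++i) {
    const int a = seq[i - 1];
    VM[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      double e = (a >= 0) ? em[(j - 1) + m * a] : 0.0;
      double v = VMp[j - 1] + mm[j - 1];
      double w = VIp[j - 1] + im[j - 1];
      if (w > v) v = w;
      if (j >= 2) { w = VDp[j - 1] + dm[j - 1]; if (w > v) v = w; }
      VM[j] = e + v;
    }
    for (int j = 0; j <= m; ++j) {
      double v = VMp[j] + mi[j];
      double w = VIp[j] + ii[j];
      VI[j] = v > w ? v : w;
    }
    VD[1] = VM[0] + md[0];
    for (int j = 2; j <= m; ++j) {
      double v = VM[j - 1] + md[j - 1];
      double w = VD[j - 1] + dd[j - 1];
      VD[j] = v > w ? v : w;
    }
    double ex = VM[m] + mm[m];
    double w = VI[m] + im[m]; if (w > ex) ex = w;
    w = VD[m] + dm[m]; if (w > ex) ex = w;
    if (ex > best) best = ex;
    std::swap(VM, VMp); std::swap(VI, VIp); std::swap(VD, VDp);
  }
  return best;
}

static double score_one(const IntegerVector& seq,
                        const NumericMatrix& em,    // m x 20 log2-odds
                        const NumericVector& mm, const NumericVector& mi,
                        const NumericVector& md, const NumericVector& im,
                        const NumericVector& ii, const NumericVector& dm,
                        const NumericVector& dd, bool viterbi) {
  const int L = seq.size(), m = em.nrow();
  std::vector<double> VMp(m + 1, NEG), VIp(m + 1, NEG), VDp(m + 1, NEG);
  std::vector<double> VM(m + 1, NEG), VI(m + 1, NEG), VD(m + 1, NEG);

  auto comb3 = [viterbi](double a, double b, double c) {
    if (viterbi) return std::max(a, std::max(b, c));
    return lse3(a, b, c);
  };
  auto comb2 = [viterbi](double a, double b) {
    if (viterbi) return std::max(a, b);
    return lse2(a, b);
  };

  double best = NEG;

  // row i = 0: nothing consumed; Begin = 0; delete chain from Begin
  VMp[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    double fromM = (j == 1 ? 0.0 : NEG) + md[j - 1];
    double fromD = (j >= 2 ? VDp[j - 1] + dd[j - 1] : NEG);
    VDp[j] = comb2(fromM, fromD);
  }
  best = comb2(best, VDp[m] + dm[m]);

  for (int i = 1; i <= L; ++i) {
    int a = seq[i - 1];
    std::fill(VM.begin(), VM.end(), NEG);
    std::fill(VI.begin(), VI.end(), NEG);
    std::fill(VD.begin(), VD.end(), NEG);
    VM[0] = 0.0;  // Begin available before offset i

    for (int j = 1; j <= m; ++j) {
      double e = (a >= 0) ? em(j - 1, a) : 0.0;
      double fM = VMp[j - 1] + mm[j - 1];               // VMp[0] = Begin
      double fI = VIp[j - 1] + im[j - 1];
      double fD = (j >= 2) ? VDp[j - 1] + dm[j - 1] : NEG;
      VM[j] = e + comb3(fM, fI, fD);
    }
    for (int j = 0; j <= m; ++j) {
      double fM = VMp[j] + mi[j];
      double fI = VIp[j] + ii[j];
      VI[j] = comb2(fM, fI);  // insert log-odds emission = 0
    }
    for (int j = 1; j <= m; ++j) {
      double fM = VM[j - 1] + md[j - 1];
      double fD = (j >= 2) ? VD[j - 1] + dd[j - 1] : NEG;
      VD[j] = comb2(fM, fD);
    }
    double exit_i = comb3(VM[m] + mm[m], VI[m] + im[m], VD[m] + dm[m]);
    best = comb2(best, exit_i);
    std::swap(VM, VMp); std::swap(VI, VIp); std::swap(VD, VDp);
  }
  return best;
}

// [[Rcpp::export]]
double hmm_score_cpp(IntegerVector seq, NumericMatrix em_lo,
                     NumericVector mm, NumericVector mi, NumericVector md,
                     NumericVector im, NumericVector ii, NumericVector dm,
                     NumericVector dd, bool viterbi) {
  if (viterbi) {
    return viterbi_one(INTEGER(seq), seq.size(), REAL(em_lo), em_lo.nrow(),
                       REAL(mm), REAL(mi), REAL(md), REAL(im), REAL(ii),
                       REAL(dm), REAL(dd));
  }
  return score_one(seq, em_lo, mm, mi, md, im, ii, dm, dd, viterbi);
}

// [[Rcpp::export]]
NumericVector hmm_score_batch_cpp(List seqs, NumericMatrix em_lo,
                                  NumericVector mm, NumericVector mi,
                                  NumericVector md, NumericVector im,
                                  NumericVector ii, NumericVector dm,
                                  NumericVector dd, bool viterbi) {
  int n = seqs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector s = seqs[i];
    if (viterbi) {
      out[i] = viterbi_one(INTEGER(s), s.size(), REAL(em_lo), em_lo.nrow(),
                           REAL(mm), REAL(mi), REAL(md), REAL(im), REAL(ii),
                           REAL(dm), REAL(dd));
    } else {
      out[i] = score_one(s, em_lo, mm, mi, md, im, ii, dm, dd, viterbi);
    }
  }
  return out;
}

// Smith-Waterman local alignment with affine gaps, for the orthology
// prefilter-free path when a plain score (no traceback) suffices.
// [[Rcpp::export]]
double sw_score_cpp(IntegerVector a, IntegerVector b, NumericMatrix subst,
                    double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double Hdiag = 0.0, F = NEG;
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(E[j] - gap_extend, H[j] - gap_open - gap_extend);
      F = std::max(F - gap_extend, H[j - 1] - gap_open - gap_extend);
      double s = Hdiag + subst(a[i - 1], b[j - 1]);
      double h = std::max(0.0, std::max(s, std::max(E[j], F)));
      Hdiag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}
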