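#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh). Gap of length L costs gap_open + L * gap_ext
// (NCBI convention). N is scored as a mismatch against everything, including N.
// Masked positions are unalignable (large negative substitution score), which is
// what drives HSP chaining by query/subject masking at the R level.

static const int BIGNEG = -100000000;

static inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4; // N / anything else
  }
}

static inline int subscore(int a, int b, int match, int mismatch) {
  return (a < 4 && a == b) ? match : mismatch;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string q, std::string s,
                  int match, int mismatch, int gap_open, int gap_ext,
                  IntegerVector q_mask, IntegerVector s_mask) {
  const int n = (int) q.size(), m = (int) s.size();
  std::vector<int> qe(n), se(m);
  for (int i = 0; i < n; ++i) qe[i] = enc(q[i]);
  for (int j = 0; j < m; ++j) se[j] = enc(s[j]);
  const bool has_qm = q_mask.size() == n, has_sm = s_mask.size() == m;

  const size_t W = (size_t) m + 1;
  std::vector<int> H((size_t)(n + 1) * W, 0), E((size_t)(n + 1) * W, BIGNEG),
      F((size_t)(n + 1) * W, BIGNEG);
  const int go = gap_open + gap_ext;

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const size_t ro = (size_t) i * W, rp = (size_t)(i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      int sub = subscore(qe[i - 1], se[j - 1], match, mismatch);
      if ((has_qm && q_mask[i - 1]) || (has_sm && s_mask[j - 1])) sub = BIGNEG;
      int e = std::max(H[ro + j - 1] - go, E[ro + j - 1] - gap_ext);
      int f = std::max(H[rp + j] - go, F[rp + j] - gap_ext);
      int h = H[rp + j - 1] + sub;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      E[ro + j] = e; F[ro + j] = f; H[ro + j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  int n_ident = 0, aln_len = 0, n_gap = 0;
  int i = bi, j = bj;
  if (best > 0) {
    int state = 0; // 0 = H, 1 = F (up, gap in subject), 2 = E (left, gap in query)
    while (i > 0 && j > 0) {
      const size_t ro = (size_t) i * W, rp = (size_t)(i - 1) * W;
      if (state == 0) {
        int h = H[ro + j];
        if (h == 0) break;
        int sub = subscore(qe[i - 1], se[j - 1], match, mismatch);
        if ((has_qm && q_mask[i - 1]) || (has_sm && s_mask[j - 1])) sub = BIGNEG;
        if (H[rp + j - 1] + sub == h) { // diagonal preferred
          ++aln_len;
          if (qe[i - 1] < 4 && qe[i - 1] == se[j - 1]) ++n_ident;
          --i; --j;
        } else if (F[ro + j] == h) {
          state = 1;
        } else {
          state = 2;
        }
      } else if (state == 1) { // gap in subject, consume query char
        const size_t ro2 = (size_t) i * W;
        ++aln_len; ++n_gap;
        if (F[ro2 + j] == H[(size_t)(i - 1) * W + j] - go) state = 0;
        --i;
      } else { // gap in query, consume subject char
        const size_t ro2 = (size_t) i * W;
        ++aln_len; ++n_gap;
        if (E[ro2 + j] == H[ro2 + j - 1] - go) state = 0;
        --j;
      }
    }
    // trailing gap-state columns at matrix edge cannot occur in an optimal local
    // alignment (they would lower the score), so i/j now sit just before the start
  }

  return List::create(
    _["score"] = best, _["n_ident"] = n_ident, _["aln_len"] = aln_len,
    _["n_gap_cols"] = n_gap,
    _["q_start"] = best > 0 ? i + 1 : 0, _["q_end"] = best > 0 ? bi : 0,
    _["s_start"] = best > 0 ? j + 1 : 0, _["s_end"] = best > 0 ? bj : 0);
}

// Score-only rolling-row DP: best local score of q against each subject.
// [[Rcpp::export(name = ".sw_score_batch_cpp")]]
IntegerVector sw_score_batch_cpp(std::string q, CharacterVector subjects,
                                 int match, int mismatch, int gap_open, int gap_ext) {
  const int n = (int) q.size();
  std::vector<int> qe(n);
  for (int i = 0; i < n; ++i) qe[i] = enc(q[i]);
  const int go = gap_open + gap_ext;
  IntegerVector out(subjects.size());

  for (R_xlen_t k = 0; k < subjects.size(); ++k) {
    std::string s = as<std::string>(subjects[k]);
    const int m = (int) s.size();
    std::vector<int> se(m);
    for (int j = 0; j < m; ++j) se[j] = enc(s[j]);
    std::vector<int> Hp(m + 1, 0), Hc(m + 1, 0), Ec(m + 1, BIGNEG), Fp(m + 1, BIGNEG),
        Fc(m + 1, BIGNEG);
    int best = 0;
    for (int i = 1; i <= n; ++i) {
      Hc[0] = 0; Ec[0] = BIGNEG; Fc[0] = BIGNEG;
      const int qi = qe[i - 1];
      for (int j = 1; j <= m; ++j) {
        int e = std::max(Hc[j - 1] - go, Ec[j - 1] - gap_ext);
        int f = std::max(Hp[j] - go, Fp[j] - gap_ext);
        int h = Hp[j - 1] + subscore(qi, se[j - 1], match, mismatch);
        if (e > h) h = e;
        if (f > h) h = f;
        if (h < 0) h = 0;
        Ec[j] = e; Fc[j] = f; Hc[j] = h;
        if (h > best) best = h;
      }
      std::swap(Hp, Hc); std::swap(Fp, Fc);
    }
    out[k] = best;
  }
  return out;
}
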