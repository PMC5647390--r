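#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh). A gap of
// length L costs open + L * ext (BLAST "existence/extension" convention).
// Sequences arrive as integer codes 1..20 indexing the substitution
// matrix; profiles as a (length x 20) score matrix. Identity and
// similarity are counted over aligned columns only; gap columns count
// toward alignment length but never toward identity/similarity.

namespace {

struct AlnStats {
  double score;
  int aln_len, n_id, n_pos;
  int qstart, qend, sstart, send; // 1-based inclusive, 0 if empty
};

const unsigned char PTR_NONE = 0, PTR_DIAG = 1, PTR_LEFT = 2, PTR_UP = 3;

// scorer(i, j) gives the score of pairing query position i with subject
// position j (0-based).
template <class Scorer>
AlnStats sw_core(int m, int n, const Scorer& scorer, double open, double ext,
                 std::vector<int>* qcols, std::vector<int>* scols) {
  const double NEG = -1e30;
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Eprev(n + 1, NEG), Ecur(n + 1, NEG);
  std::vector<double> Fcur(n + 1, NEG);
  // pointer matrices for H, E (gap in query, horizontal) and F (vertical)
  std::vector<unsigned char> ptrH((size_t)(m + 1) * (n + 1), PTR_NONE);
  std::vector<unsigned char> extE((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> extF((size_t)(m + 1) * (n + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0.0;
    Ecur[0] = NEG;
    double Fdiag = NEG; // F[i][j] depends on row i-1 at same j
    (void)Fdiag;
    for (int j = 1; j <= n; ++j) {
      // E: gap in query (consume subject), from the left
      double e_open = Hcur[j - 1] - open - ext;
      double e_ext = Ecur[j - 1] - ext;
      if (e_ext > e_open) {
        Ecur[j] = e_ext;
        extE[(size_t)i * (n + 1) + j] = 1;
      } else {
        Ecur[j] = e_open;
      }
      // F: gap in subject (consume query), from above
      double f_open = Hprev[j] - open - ext;
      double f_ext = Fcur[j] - ext; // Fcur[j] currently holds F[i-1][j]
      if (f_ext > f_open) {
        Fcur[j] = f_ext;
        extF[(size_t)i * (n + 1) + j] = 1;
      } else {
        Fcur[j] = f_open;
      }
      double diag = Hprev[j - 1] + scorer(i - 1, j - 1);
      double h = 0.0;
      unsigned char p = PTR_NONE;
      if (diag > h) { h = diag; p = PTR_DIAG; }
      if (Ecur[j] > h) { h = Ecur[j]; p = PTR_LEFT; }
      if (Fcur[j] > h) { h = Fcur[j]; p = PTR_UP; }
      Hcur[j] = h;
      ptrH[(size_t)i * (n + 1) + j] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }

  AlnStats st;
  st.score = best;
  st.aln_len = st.n_id = st.n_pos = 0;
  st.qstart = st.qend = st.sstart = st.send = 0;
  if (best <= 0.0) return st;

  // traceback
  int i = bi, j = bj;
  st.qend = bi; st.send = bj;
  int state = 0; // 0 = H, 1 = E, 2 = F
  std::vector<int> qc, sc; // aligned columns, 0 = gap
  while (i > 0 && j > 0) {
    if (state == 0) {
      unsigned char p = ptrH[(size_t)i * (n + 1) + j];
      if (p == PTR_NONE) break;
      if (p == PTR_DIAG) {
        qc.push_back(i); sc.push_back(j);
        double s = scorer(i - 1, j - 1);
        ++st.aln_len;
        if (s > 0) ++st.n_pos;
        --i; --j;
      } else if (p == PTR_LEFT) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      qc.push_back(0); sc.push_back(j);
      ++st.aln_len;
      if (!extE[(size_t)i * (n + 1) + j]) state = 0;
      --j;
    } else {
      qc.push_back(i); sc.push_back(0);
      ++st.aln_len;
      if (!extF[(size_t)i * (n + 1) + j]) state = 0;
      --i;
    }
  }
  st.qstart = i + 1;
  st.sstart = j + 1;
  std::reverse(qc.begin(), qc.end());
  std::reverse(sc.begin(), sc.end());
  if (qcols) *qcols = qc;
  if (scols) *scols = sc;
  return st;
}

struct PairScorer {
  const int* q; const int* s; const double* sub; int nrow;
  double operator()(int i, int j) const {
    return sub[(q[i] - 1) + (size_t)nrow * (s[j] - 1)];
  }
};

struct IdCounter {
  // identities counted where residues are equal
};

struct ProfScorer {
  const double* w; int L; const int* s;
  double operator()(int i, int j) const {
    return w[i + (size_t)L * (s[j] - 1)];
  }
};

AlnStats sw_pair(const IntegerVector& q, const IntegerVector& s,
                 const NumericMatrix& sub, double open, double ext,
                 std::vector<int>* qc, std::vector<int>* sc) {
  PairScorer sco{q.begin(), s.begin(), sub.begin(), (int)sub.nrow()};
  AlnStats st = sw_core(q.size(), s.size(), sco, open, ext, qc, sc);
  // identity needs residue comparison over diagonal columns
  if (qc && sc) {
    int nid = 0;
    for (size_t k = 0; k < qc->size(); ++k)
      if ((*qc)[k] > 0 && (*sc)[k] > 0 && q[(*qc)[k] - 1] == s[(*sc)[k] - 1])
        ++nid;
    st.n_id = nid;
  }
  return st;
}

} // namespace

// [[Rcpp::export(name = ".C_sw_align")]]
List C_sw_align(IntegerVector q, IntegerVector s, NumericMatrix sub,
                double open, double ext) {
  std::vector<int> qc, sc;
  AlnStats st = sw_pair(q, s, sub, open, ext, &qc, &sc);
  return List::create(
      _["score"] = st.score, _["aln_len"] = st.aln_len,
      _["n_id"] = st.n_id, _["n_pos"] = st.n_pos,
      _["qstart"] = st.qstart, _["qend"] = st.qend,
      _["sstart"] = st.sstart, _["send"] = st.send,
      _["qcols"] = wrap(qc), _["scols"] = wrap(sc));
}

// [[Rcpp::export(name = ".C_sw_batch")]]
NumericMatrix C_sw_batch(IntegerVector q, List subjects, NumericMatrix sub,
                         double open, double ext) {
  int n = subjects.size();
  NumericMatrix out(n, 8);
  colnames(out) = CharacterVector::create("score", "aln_len", "n_id",
                                          "n_pos", "qstart", "qend",
                                          "sstart", "send");
  for (int k = 0; k < n; ++k) {
    IntegerVector s = subjects[k];
    std::vector<int> qc, sc;
    AlnStats st = sw_pair(q, s, sub, open, ext, &qc, &sc);
    out(k, 0) = st.score; out(k, 1) = st.aln_len; out(k, 2) = st.n_id;
    out(k, 3) = st.n_pos; out(k, 4) = st.qstart; out(k, 5) = st.qend;
    out(k, 6) = st.sstart; out(k, 7) = st.send;
  }
  return out;
}

// [[Rcpp::export(name = ".C_profile_batch")]]
NumericMatrix C_profile_batch(NumericMatrix weights, List subjects,
                              double open, double ext) {
  int n = subjects.size();
  int L = weights.nrow();
  NumericMatrix out(n, 9);
  colnames(out) = CharacterVector::create("score", "aln_len", "n_pos",
                                          "n_prof", "n_best", "pstart",
                                          "pend", "sstart", "send");
  for (int k = 0; k < n; ++k) {
    IntegerVector s = subjects[k];
    ProfScorer sco{weights.begin(), L, s.begin()};
    std::vector<int> pc, sc;
    AlnStats st = sw_core(L, s.size(), sco, open, ext, &pc, &sc);
    int nprof = 0, nbest = 0;
    for (size_t t = 0; t < pc.size(); ++t) {
      if (pc[t] > 0) ++nprof;
      if (pc[t] > 0 && sc[t] > 0) {
        // column where the subject residue is the profile's top choice
        int i = pc[t] - 1, a = s[sc[t] - 1] - 1;
        double w = weights(i, a), best = weights(i, 0);
        for (int b = 1; b < 20; ++b)
          if (weights(i, b) > best) best = weights(i, b);
        if (w >= best) ++nbest;
      }
    }
    out(k, 0) = st.score; out(k, 1) = st.aln_len; out(k, 2) = st.n_pos;
    out(k, 3) = nprof; out(k, 4) = nbest; out(k, 5) = st.qstart;
    out(k, 6) = st.qend; out(k, 7) = st.sstart; out(k, 8) = st.send;
  }
  return out;
}
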