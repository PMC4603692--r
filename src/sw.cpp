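#include <Rcpp.h>
#include <climits>
#include <vector>
using namespace Rcpp;

// Affine-gap Smith-Waterman (Gotoh) over integer-encoded residues.
// A gap of length L costs gap_open + L * gap_extend (NCBI BLAST convention).
// Traceback tie-break: diagonal > up (gap in subject) > left (gap in query).
// Best cell = first maximum in row-major order.

static const int NEG = INT_MIN / 4;

struct AlnStats {
  int score, qstart, qend, sstart, send, nident, alnlen;
  std::vector<int> path_a, path_b; // 1-based positions, 0 = gap (only if want_path)
};

static void sw_core(const std::vector<int> &a, const std::vector<int> &b,
                    const int *S, int nS, int go, int ge, bool want_path,
                    AlnStats &out) {
  const int m = (int)a.size(), n = (int)b.size();
  out.score = 0;
  out.qstart = out.qend = out.sstart = out.send = 0;
  out.nident = out.alnlen = 0;
  out.path_a.clear();
  out.path_b.clear();
  if (m == 0 || n == 0) return;

  // tbH: 0 stop, 1 diag, 2 up(F), 3 left(E); tbE/tbF: 1 = extend, 0 = open
  std::vector<unsigned char> tbH((size_t)(m + 1) * (n + 1), 0),
      tbE((size_t)(m + 1) * (n + 1), 0), tbF((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Fv(n + 1, NEG);

  int best = 0, bi = 0, bj = 0;
  const int open_cost = go + ge;

  for (int i = 1; i <= m; ++i) {
    int E = NEG;
    Hcur[0] = 0;
    const int ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      const size_t idx = (size_t)i * (n + 1) + j;
      // E: gap in query a (consume b[j])
      int e_open = Hcur[j - 1] - open_cost, e_ext = E - ge;
      if (e_ext > e_open) { E = e_ext; tbE[idx] = 1; }
      else { E = e_open; tbE[idx] = 0; }
      // F: gap in subject b (consume a[i])
      int f_open = Hprev[j] - open_cost, f_ext = Fv[j] - ge;
      if (f_ext > f_open) { Fv[j] = f_ext; tbF[idx] = 1; }
      else { Fv[j] = f_open; tbF[idx] = 0; }
      const int diag = Hprev[j - 1] + S[ai * nS + b[j - 1]];
      int h = 0; unsigned char dir = 0;
      if (diag >= h) { h = diag; dir = 1; }
      if (Fv[j] > h) { h = Fv[j]; dir = 2; }
      if (E > h) { h = E; dir = 3; }
      if (h <= 0) { h = 0; dir = 0; }
      Hcur[j] = h;
      tbH[idx] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }

  out.score = best;
  if (best <= 0) return;

  // traceback
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  out.qend = bi; out.send = bj;
  std::vector<int> pa, pb;
  while (i > 0 && j > 0) {
    const size_t idx = (size_t)i * (n + 1) + j;
    if (state == 0) {
      const unsigned char d = tbH[idx];
      if (d == 0) break;
      if (d == 1) {
        pa.push_back(i); pb.push_back(j);
        if (a[i - 1] == b[j - 1]) out.nident++;
        --i; --j;
      } else if (d == 2) state = 2;
      else state = 1;
    } else if (state == 1) { // E consumes b[j]
      pa.push_back(0); pb.push_back(j);
      const unsigned char e = tbE[idx];
      --j;
      if (!e) state = 0;
    } else { // F consumes a[i]
      pa.push_back(i); pb.push_back(0);
      const unsigned char f = tbF[idx];
      --i;
      if (!f) state = 0;
    }
  }
  out.qstart = i + 1;
  out.sstart = j + 1;
  out.alnlen = (int)pa.size();
  if (want_path) {
    out.path_a.assign(pa.rbegin(), pa.rend());
    out.path_b.assign(pb.rbegin(), pb.rend());
  }
}

// score-only DP (no traceback bookkeeping): used as a fast first pass
static int sw_score_only(const std::vector<int> &a, const std::vector<int> &b,
                         const int *S, int nS, int open_cost, int ge) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) return 0;
  std::vector<int> H(n + 1, 0), F(n + 1, NEG);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int E = NEG, Hdiag = 0;
    const int *Srow = S + (size_t)a[i - 1] * nS;
    for (int j = 1; j <= n; ++j) {
      const int tmp = H[j]; // H[i-1][j]
      int f = F[j] - ge, fo = tmp - open_cost;
      F[j] = f > fo ? f : fo;
      int e = E - ge, eo = H[j - 1] - open_cost;
      E = e > eo ? e : eo;
      int h = Hdiag + Srow[b[j - 1]];
      if (h < E) h = E;
      if (h < F[j]) h = F[j];
      if (h < 0) h = 0;
      Hdiag = tmp;
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

static std::vector<int> as_vec(SEXP x) {
  IntegerVector v(x);
  return std::vector<int>(v.begin(), v.end());
}

// [[Rcpp::export(name = ".sw_pair_cpp")]]
List sw_pair_cpp(IntegerVector a, IntegerVector b, IntegerMatrix S,
                 int gap_open, int gap_extend) {
  std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());
  AlnStats st;
  sw_core(av, bv, S.begin(), S.nrow(), gap_open, gap_extend, true, st);
  return List::create(
      _["score"] = st.score, _["qstart"] = st.qstart, _["qend"] = st.qend,
      _["sstart"] = st.sstart, _["send"] = st.send, _["nident"] = st.nident,
      _["alnlen"] = st.alnlen, _["path_a"] = wrap(st.path_a),
      _["path_b"] = wrap(st.path_b));
}

// Batch pairwise stats. If self = TRUE, B is ignored and all unordered pairs
// i < j within A are computed; otherwise the full A x B cross is computed.
// Alignment detail (identity, span) is computed only for pairs whose raw
// score reaches min_score_detail; below it the detail columns are zero.
// [[Rcpp::export(name = ".sw_batch_cpp")]]
DataFrame sw_batch_cpp(List A, List B, IntegerMatrix S, int gap_open,
                       int gap_extend, bool self,
                       int min_score_detail = 0) {
  const int nS = S.nrow();
  const int *Sm = S.begin();
  std::vector<std::vector<int> > av(A.size());
  for (int i = 0; i < A.size(); ++i) av[i] = as_vec(A[i]);
  std::vector<std::vector<int> > bv;
  if (!self) {
    bv.resize(B.size());
    for (int i = 0; i < B.size(); ++i) bv[i] = as_vec(B[i]);
  }
  const R_xlen_t npair = self
      ? (R_xlen_t)A.size() * (A.size() - 1) / 2
      : (R_xlen_t)A.size() * (R_xlen_t)B.size();
  IntegerVector ri(npair), rj(npair), sc(npair), nid(npair), al(npair),
      qs(npair), qe(npair), ss(npair), se(npair);
  AlnStats st;
  const int open_cost = gap_open + gap_extend;
  R_xlen_t k = 0;
  if (self) {
    for (int i = 0; i < (int)av.size(); ++i) {
      for (int j = i + 1; j < (int)av.size(); ++j, ++k) {
        const int score = sw_score_only(av[i], av[j], Sm, nS, open_cost,
                                        gap_extend);
        ri[k] = i + 1; rj[k] = j + 1; sc[k] = score;
        if (score >= min_score_detail && score > 0) {
          sw_core(av[i], av[j], Sm, nS, gap_open, gap_extend, false, st);
          nid[k] = st.nident; al[k] = st.alnlen; qs[k] = st.qstart;
          qe[k] = st.qend; ss[k] = st.sstart; se[k] = st.send;
        } else {
          nid[k] = 0; al[k] = 0; qs[k] = 0; qe[k] = 0; ss[k] = 0; se[k] = 0;
        }
      }
      Rcpp::checkUserInterrupt();
    }
  } else {
    for (int i = 0; i < (int)av.size(); ++i) {
      for (int j = 0; j < (int)bv.size(); ++j, ++k) {
        const int score = sw_score_only(av[i], bv[j], Sm, nS, open_cost,
                                        gap_extend);
        ri[k] = i + 1; rj[k] = j + 1; sc[k] = score;
        if (score >= min_score_detail && score > 0) {
          sw_core(av[i], bv[j], Sm, nS, gap_open, gap_extend, false, st);
          nid[k] = st.nident; al[k] = st.alnlen; qs[k] = st.qstart;
          qe[k] = st.qend; ss[k] = st.sstart; se[k] = st.send;
        } else {
          nid[k] = 0; al[k] = 0; qs[k] = 0; qe[k] = 0; ss[k] = 0; se[k] = 0;
        }
      }
      Rcpp::checkUserInterrupt();
    }
  }
  return DataFrame::create(
      _["i"] = ri, _["j"] = rj, _["raw_score"] = sc, _["n_ident"] = nid,
      _["aln_len"] = al, _["q_start"] = qs, _["q_end"] = qe,
      _["s_start"] = ss, _["s_end"] = se);
}
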