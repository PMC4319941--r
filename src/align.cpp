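#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh) with full traceback.
//
// Sequences arrive as 0-based integer codes into the rows/columns of `sub`.
// Gap convention: a gap of length L costs gap_open + (L-1) * gap_extend,
// i.e. gap_open is charged for the first gap column (EMBOSS convention;
// both penalties are negative numbers).
//
// ident_ok[code] says whether a code may count as an identical column
// (ambiguity codes such as N/X never do, even when equal).
//
// Returns NULL when the best local score is <= 0.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
SEXP sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_extend, LogicalVector ident_ok) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0) stop("empty sequence");
  const double cells = (double)(m + 1) * (double)(n + 1);
  if (cells > 6.5e7)
    stop("dynamic-programming matrix too large (%d x %d); use the seeded path", m, n);

  // traceback codes: H: 0 stop, 1 diag, 2 from E (gap in a), 3 from F (gap in b)
  //                  E: 0 opened from H, 1 extended ; F likewise
  std::vector<uint8_t> tbH((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> tbE((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> tbF((size_t)(m + 1) * (n + 1), 0);

  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Ecur(n + 1, NEG_INF);
  std::vector<double> Fcol(n + 1, NEG_INF);

  double best = 0.0;
  int bi = 0, bj = 0;

  const int* pa = INTEGER(a);
  const int* pb = INTEGER(b);
  const double* psub = REAL(sub);
  const int nsub = sub.nrow();

  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0.0;
    Ecur[0] = NEG_INF;
    const double* subrow = psub + (size_t)pa[i - 1];  // column-major: + code*nsub later
    const size_t row = (size_t)i * (n + 1);
    double* hp = Hprev.data();
    double* hc = Hcur.data();
    double* ec = Ecur.data();
    double* fc = Fcol.data();
    uint8_t* th = tbH.data() + row;
    uint8_t* te = tbE.data() + row;
    uint8_t* tf = tbF.data() + row;
    for (int j = 1; j <= n; ++j) {
      // E: gap in a (consumes b[j])
      double e_open = hc[j - 1] + gap_open;
      double e_ext = ec[j - 1] + gap_extend;
      double E = (e_open >= e_ext) ? e_open : e_ext;
      te[j] = (e_open >= e_ext) ? 0 : 1;
      ec[j] = E;
      // F: gap in b (consumes a[i])
      double f_open = hp[j] + gap_open;
      double f_ext = fc[j] + gap_extend;
      double F = (f_open >= f_ext) ? f_open : f_ext;
      tf[j] = (f_open >= f_ext) ? 0 : 1;
      fc[j] = F;
      // H
      double diag = hp[j - 1] + subrow[(size_t)pb[j - 1] * nsub];
      double H = 0.0;
      uint8_t t = 0;
      if (diag > H) { H = diag; t = 1; }
      if (E > H) { H = E; t = 2; }
      if (F > H) { H = F; t = 3; }
      hc[j] = H;
      th[j] = t;
      if (H > best) { best = H; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }

  if (best <= 0.0) return R_NilValue;

  // traceback
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  int alen = 0, nid = 0, ngap = 0;
  int qend = bi, send = bj, qstart = bi, sstart = bj;
  while (true) {
    const size_t idx = (size_t)i * (n + 1) + j;
    if (state == 0) {
      uint8_t t = tbH[idx];
      if (t == 0) break;
      if (t == 1) {
        ++alen;
        if (a[i - 1] == b[j - 1] && ident_ok[a[i - 1]]) ++nid;
        --i; --j;
        qstart = i + 1; sstart = j + 1;
      } else if (t == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {  // gap in a, consume b[j]
      ++alen; ++ngap;
      uint8_t t = tbE[idx];
      --j;
      sstart = j + 1; qstart = i + 1;
      state = (t == 0) ? 0 : 1;
    } else {  // gap in b, consume a[i]
      ++alen; ++ngap;
      uint8_t t = tbF[idx];
      --i;
      qstart = i + 1; sstart = j + 1;
      state = (t == 0) ? 0 : 2;
    }
  }

  return List::create(
      _["score"] = best,
      _["qstart"] = qstart - 1,  // 0-based half-open
      _["qend"] = qend,
      _["sstart"] = sstart - 1,
      _["send"] = send,
      _["align_len"] = alen,
      _["n_ident"] = nid,
      _["n_gap_cols"] = ngap);
}

// Exact k-mer seed matches between a (query) and b (subject).
// Returns a two-column matrix of 0-based positions (qpos, spos).
// Positions whose k-mer contains an ambiguous code (>= ambig_code) are skipped.
// [[Rcpp::export]]
IntegerMatrix seed_matches_cpp(IntegerVector a, IntegerVector b, int k,
                               int ambig_code) {
  const int m = a.size(), n = b.size();
  std::vector<int> qpos, spos;
  if (m < k || n < k) return IntegerMatrix(0, 2);

  std::unordered_map<uint64_t, std::vector<int> > index;
  index.reserve(m * 2);
  const uint64_t base = (uint64_t)(ambig_code + 1);

  // index query k-mers
  for (int i = 0; i + k <= m; ++i) {
    uint64_t h = 0;
    bool ok = true;
    for (int t = 0; t < k; ++t) {
      int c = a[i + t];
      if (c >= ambig_code) { ok = false; break; }
      h = h * base + (uint64_t)c;
    }
    if (ok) index[h].push_back(i);
  }
  // scan subject
  for (int j = 0; j + k <= n; ++j) {
    uint64_t h = 0;
    bool ok = true;
    for (int t = 0; t < k; ++t) {
      int c = b[j + t];
      if (c >= ambig_code) { ok = false; break; }
      h = h * base + (uint64_t)c;
    }
    if (!ok) continue;
    auto it = index.find(h);
    if (it == index.end()) continue;
    for (int q : it->second) {
      qpos.push_back(q);
      spos.push_back(j);
    }
  }
  IntegerMatrix out(qpos.size(), 2);
  for (size_t r = 0; r < qpos.size(); ++r) {
    out(r, 0) = qpos[r];
    out(r, 1) = spos[r];
  }
  colnames(out) = CharacterVector::create("qpos", "spos");
  return out;
}

// Candidate pairs sharing at least min_shared distinct k-mers, over a list of
// integer-coded sequences. Used as an all-vs-all prefilter before alignment.
// Returns a 3-column matrix (i, j, shared), 1-based, i < j.
// [[Rcpp::export]]
IntegerMatrix shared_kmer_pairs_cpp(List seqs, int k, int ambig_code,
                                    int min_shared) {
  const int ns = seqs.size();
  std::unordered_map<uint64_t, std::vector<int> > postings;
  const uint64_t base = (uint64_t)(ambig_code + 1);

  for (int s = 0; s < ns; ++s) {
    IntegerVector v = seqs[s];
    const int L = v.size();
    std::unordered_map<uint64_t, bool> seen;
    for (int i = 0; i + k <= L; ++i) {
      uint64_t h = 0;
      bool ok = true;
      for (int t = 0; t < k; ++t) {
        int c = v[i + t];
        if (c >= ambig_code) { ok = false; break; }
        h = h * base + (uint64_t)c;
      }
      if (!ok) continue;
      if (seen.find(h) != seen.end()) continue;
      seen[h] = true;
      postings[h].push_back(s);
    }
  }

  std::unordered_map<uint64_t, int> counts;
  for (auto const& kv : postings) {
    const std::vector<int>& p = kv.second;
    const size_t L = p.size();
    if (L < 2) continue;
    for (size_t x = 0; x + 1 < L; ++x)
      for (size_t y = x + 1; y < L; ++y) {
        uint64_t key = (uint64_t)p[x] * (uint64_t)ns + (uint64_t)p[y];
        ++counts[key];
      }
  }

  std::vector<int> ii, jj, cc;
  for (auto const& kv : counts) {
    if (kv.second >= min_shared) {
      ii.push_back((int)(kv.first / ns) + 1);
      jj.push_back((int)(kv.first % ns) + 1);
      cc.push_back(kv.second);
    }
  }
  IntegerMatrix out(ii.size(), 3);
  for (size_t r = 0; r < ii.size(); ++r) {
    out(r, 0) = ii[r];
    out(r, 1) = jj[r];
    out(r, 2) = cc[r];
  }
  colnames(out) = CharacterVector::create("i", "j", "shared");
  return out;
}
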