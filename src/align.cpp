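#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with Gotoh affine gaps.
// A gap of length k costs gap_open + (k - 1) * gap_extend, i.e. gap_open is
// the cost of the first gapped base.

struct AlnResult {
  double score = 0.0;
  int ref_start = 0, ref_end = -1, read_start = 0, read_end = -1;
  std::vector<int> ref_pos, read_pos;  // 0-based, diagonal columns only
  int n_match = 0, n_mismatch = 0, n_gap_cols = 0;
};

static AlnResult sw_align(const std::string &read, const std::string &ref,
                          double match, double mismatch, double gap_open,
                          double gap_extend) {
  const int m = (int)read.size(), n = (int)ref.size();
  AlnResult res;
  if (m == 0 || n == 0) return res;

  const double NEG = -1e18;
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Eprev(n + 1, NEG), Ecur(n + 1, NEG);
  std::vector<double> Fcur(n + 1, NEG), Fprev(n + 1, NEG);
  // traceback: tbH 0=stop 1=diag 2=E 3=F; tbE/tbF 0=from H, 1=extend
  std::vector<int8_t> tbH((size_t)(m + 1) * (n + 1), 0);
  std::vector<int8_t> tbE((size_t)(m + 1) * (n + 1), 0);
  std::vector<int8_t> tbF((size_t)(m + 1) * (n + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0.0; Ecur[0] = NEG;
    size_t row = (size_t)i * (n + 1);
    size_t rowp = (size_t)(i - 1) * (n + 1);
    for (int j = 1; j <= n; ++j) {
      double e_open = Hcur[j - 1] + gap_open;
      double e_ext = Ecur[j - 1] + gap_extend;
      Ecur[j] = e_open >= e_ext ? e_open : e_ext;
      tbE[row + j] = e_open >= e_ext ? 0 : 1;

      double f_open = Hprev[j] + gap_open;
      double f_ext = Fprev[j] + gap_extend;
      Fcur[j] = f_open >= f_ext ? f_open : f_ext;
      tbF[row + j] = f_open >= f_ext ? 0 : 1;

      double diag = Hprev[j - 1] +
        (read[i - 1] == ref[j - 1] ? match : mismatch);
      double h = 0.0; int8_t tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (Ecur[j] > h) { h = Ecur[j]; tb = 2; }
      if (Fcur[j] > h) { h = Fcur[j]; tb = 3; }
      Hcur[j] = h; tbH[row + j] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
    std::swap(Fprev, Fcur);
    std::fill(Ecur.begin(), Ecur.end(), NEG);
    std::fill(Fcur.begin(), Fcur.end(), NEG);
  }

  res.score = best;
  if (best <= 0.0) return res;
  res.ref_end = bj - 1; res.read_end = bi - 1;

  int i = bi, j = bj;
  int state = 0;  // 0=H 1=E 2=F
  std::vector<int> rp, qp;
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (n + 1) + j;
    if (state == 0) {
      int8_t tb = tbH[idx];
      if (tb == 0) break;
      if (tb == 1) {
        rp.push_back(j - 1); qp.push_back(i - 1);
        if (read[i - 1] == ref[j - 1]) res.n_match++; else res.n_mismatch++;
        --i; --j;
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      res.n_gap_cols++;
      state = tbE[idx] == 0 ? 0 : 1;
      --j;
    } else {
      res.n_gap_cols++;
      state = tbF[idx] == 0 ? 0 : 2;
      --i;
    }
  }
  res.ref_start = j; res.read_start = i;
  res.ref_pos.assign(rp.rbegin(), rp.rend());
  res.read_pos.assign(qp.rbegin(), qp.rend());
  return res;
}

// [[Rcpp::export]]
List cpp_sw_align(std::string read, std::string ref, double match,
                  double mismatch, double gap_open, double gap_extend) {
  AlnResult r = sw_align(read, ref, match, mismatch, gap_open, gap_extend);
  return List::create(
    _["score"] = r.score,
    _["ref_start"] = r.ref_start, _["ref_end"] = r.ref_end,
    _["read_start"] = r.read_start, _["read_end"] = r.read_end,
    _["ref_pos"] = IntegerVector(r.ref_pos.begin(), r.ref_pos.end()),
    _["read_pos"] = IntegerVector(r.read_pos.begin(), r.read_pos.end()),
    _["n_match"] = r.n_match, _["n_mismatch"] = r.n_mismatch,
    _["n_gap_cols"] = r.n_gap_cols);
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// k-mer index per reference: 2-bit packed k-mer -> first occurrence
// position (k <= 15)
static std::vector<std::unordered_map<uint32_t, int>> build_kmer_maps(
    const std::vector<std::string> &refs, int k) {
  std::vector<std::unordered_map<uint32_t, int>> maps(refs.size());
  const uint32_t mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  for (size_t r = 0; r < refs.size(); ++r) {
    const std::string &s = refs[r];
    uint32_t km = 0; int run = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int c = base_code(s[p]);
      if (c < 0) { run = 0; km = 0; continue; }
      km = ((km << 2) | (uint32_t)c) & mask;
      if (++run >= k)
        maps[r].emplace(km, (int)p - k + 1);  // keeps first occurrence
    }
  }
  return maps;
}

// best-scoring ungapped segment on a fixed diagonal (Kadane): the exact
// Smith-Waterman solution restricted to gap-free alignments on that diagonal
static AlnResult diag_align(const std::string &read, const std::string &ref,
                            int diag, double match, double mismatch) {
  const int m = (int)read.size(), n = (int)ref.size();
  AlnResult res;
  int i_lo = diag < 0 ? -diag : 0;
  int i_hi = std::min(m, n - diag);
  double run = 0.0, best = 0.0;
  int run_start = i_lo, best_i1 = 0, best_i2 = -1;
  for (int i = i_lo; i < i_hi; ++i) {
    double s = (read[i] == ref[i + diag]) ? match : mismatch;
    if (run <= 0.0) { run = s; run_start = i; }
    else run += s;
    if (run > best) { best = run; best_i1 = run_start; best_i2 = i; }
  }
  if (best <= 0.0) return res;
  res.score = best;
  res.read_start = best_i1; res.read_end = best_i2;
  res.ref_start = best_i1 + diag; res.ref_end = best_i2 + diag;
  res.ref_pos.reserve(best_i2 - best_i1 + 1);
  res.read_pos.reserve(best_i2 - best_i1 + 1);
  for (int i = best_i1; i <= best_i2; ++i) {
    res.ref_pos.push_back(i + diag);
    res.read_pos.push_back(i);
    if (read[i] == ref[i + diag]) res.n_match++; else res.n_mismatch++;
  }
  return res;
}

// Batch aligner: seeds each read against the references by shared k-mers,
// aligns along the best-supported diagonal of the best reference, and falls
// back to full Smith-Waterman when the seeded alignment is too weak. For
// each read it reports the base contributed at every requested reference
// offset ('.' when the alignment does not cover the offset or gaps there).
// [[Rcpp::export]]
List cpp_align_batch(CharacterVector reads, CharacterVector refs,
                     List site_offsets, double match, double mismatch,
                     double gap_open, double gap_extend, int kmer,
                     double min_identity) {
  const int nref = refs.size(), nread = reads.size();
  std::vector<std::string> R(nref);
  for (int r = 0; r < nref; ++r) R[r] = as<std::string>(refs[r]);
  std::vector<std::vector<int>> offs(nref);
  for (int r = 0; r < nref; ++r) {
    IntegerVector o = site_offsets[r];
    offs[r].assign(o.begin(), o.end());
  }
  std::vector<std::unordered_map<uint32_t, int>> kmaps =
    build_kmer_maps(R, kmer);
  const uint32_t mask = (1u << (2 * kmer)) - 1u;

  IntegerVector ref_index(nread, NA_INTEGER);
  NumericVector score(nread, 0.0);
  IntegerVector ref_start(nread, NA_INTEGER), span(nread, 0),
    n_match(nread, 0), n_mismatch(nread, 0), n_gap(nread, 0),
    align_len(nread, 0);
  CharacterVector site_bases(nread);

  for (int q = 0; q < nread; ++q) {
    std::string rd = as<std::string>(reads[q]);
    site_bases[q] = "";
    if (rd.empty()) continue;

    // seed: count k-mer hits per ref and vote for a diagonal on each
    std::vector<int> hits(nref, 0);
    std::vector<std::unordered_map<int, int>> diag_votes(nref);
    if ((int)rd.size() >= kmer) {
      uint32_t km = 0; int run = 0;
      for (size_t p = 0; p < rd.size(); ++p) {
        int c = base_code(rd[p]);
        if (c < 0) { run = 0; km = 0; continue; }
        km = ((km << 2) | (uint32_t)c) & mask;
        if (++run >= kmer) {
          int rpos = (int)p - kmer + 1;
          for (int r = 0; r < nref; ++r) {
            auto it = kmaps[r].find(km);
            if (it != kmaps[r].end()) {
              hits[r]++;
              diag_votes[r][it->second - rpos]++;
            }
          }
        }
      }
    }
    int mx = 0;
    for (int r = 0; r < nref; ++r) if (hits[r] > mx) mx = hits[r];

    AlnResult best; int best_r = -1;
    if (mx > 0) {
      for (int r = 0; r < nref; ++r) {
        if (hits[r] != mx) continue;
        int bdiag = 0, bv = -1;
        for (auto &kv : diag_votes[r])
          if (kv.second > bv || (kv.second == bv && kv.first < bdiag)) {
            bv = kv.second; bdiag = kv.first;
          }
        AlnResult a = diag_align(rd, R[r], bdiag, match, mismatch);
        if (best_r < 0 || a.score > best.score) { best = a; best_r = r; }
      }
      // weak seeded alignment (possible indel): redo with full SW
      int alen = best.n_match + best.n_mismatch;
      if (best_r >= 0 &&
          (best.score <= 0.0 ||
           (alen > 0 && (double)best.n_match / alen < min_identity))) {
        AlnResult a = sw_align(rd, R[best_r], match, mismatch, gap_open,
                               gap_extend);
        if (a.score > best.score) best = a;
      }
    } else {
      for (int r = 0; r < nref; ++r) {
        AlnResult a = sw_align(rd, R[r], match, mismatch, gap_open,
                               gap_extend);
        if (best_r < 0 || a.score > best.score) { best = a; best_r = r; }
      }
    }
    if (best_r < 0 || best.score <= 0.0) continue;

    ref_index[q] = best_r + 1;
    score[q] = best.score;
    ref_start[q] = best.ref_start;
    span[q] = best.ref_end - best.ref_start + 1;
    n_match[q] = best.n_match;
    n_mismatch[q] = best.n_mismatch;
    n_gap[q] = best.n_gap_cols;
    align_len[q] = best.n_match + best.n_mismatch + best.n_gap_cols;

    const std::vector<int> &so = offs[best_r];
    std::string bases(so.size(), '.');
    size_t k2 = 0;
    for (size_t s = 0; s < so.size(); ++s) {
      // ref_pos is sorted ascending; advance a cursor per site (sites sorted)
      while (k2 < best.ref_pos.size() && best.ref_pos[k2] < so[s]) ++k2;
      if (k2 < best.ref_pos.size() && best.ref_pos[k2] == so[s])
        bases[s] = rd[best.read_pos[k2]];
    }
    site_bases[q] = bases;
  }

  return List::create(
    _["ref_index"] = ref_index, _["score"] = score,
    _["ref_start"] = ref_start, _["span"] = span,
    _["n_match"] = n_match, _["n_mismatch"] = n_mismatch,
    _["n_gap_cols"] = n_gap, _["align_len"] = align_len,
    _["site_bases"] = site_bases);
}
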