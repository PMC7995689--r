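#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// unit is a repetition of a proper divisor-length prefix?
static bool unit_periodic(const std::string& s, size_t off, int u) {
  for (int d = 1; d < u; ++d) {
    if (u % d != 0) continue;
    bool rep = true;
    for (int i = d; i < u && rep; ++i)
      if (s[off + i] != s[off + i % d]) rep = false;
    if (rep) return true;
  }
  return false;
}

// Maximal perfect tandem arrays of primitive 2-4 bp units. The reported
// span is the full maximal run including any trailing partial unit, so the
// same physical array gets mirror-image coordinates on the two strands;
// unit_count counts whole units only. Overlaps resolved longest-first,
// then leftmost, then shortest unit.
// [[Rcpp::export]]
DataFrame cpp_scan_seq(std::string seq, int min_units) {
  int n = (int) seq.size();
  std::vector<int> c_start, c_end, c_ulen, c_count;

  for (int u = 2; u <= 4; ++u) {
    int i = 0;
    while (i + u < n) {
      if (!is_acgt(seq[i]) || !is_acgt(seq[i + u]) || seq[i] != seq[i + u]) {
        ++i;
        continue;
      }
      // run of consecutive positions j with seq[j] == seq[j+u]
      int j = i;
      while (j + u < n && is_acgt(seq[j]) && is_acgt(seq[j + u]) &&
             seq[j] == seq[j + u])
        ++j;
      int span = (j - i) + u;          // maximal array span incl. partial unit
      int count = span / u;            // whole units
      if (count >= min_units && !unit_periodic(seq, i, u)) {
        c_start.push_back(i);
        c_end.push_back(i + span);
        c_ulen.push_back(u);
        c_count.push_back(count);
      }
      i = j + 1;
    }
  }

  // order: length desc, start asc, unit length asc
  std::vector<int> ord(c_start.size());
  for (size_t k = 0; k < ord.size(); ++k) ord[k] = (int) k;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    int la = c_end[a] - c_start[a], lb = c_end[b] - c_start[b];
    if (la != lb) return la > lb;
    if (c_start[a] != c_start[b]) return c_start[a] < c_start[b];
    return c_ulen[a] < c_ulen[b];
  });

  std::vector<bool> covered(n, false);
  std::vector<int> keep;
  for (int k : ord) {
    bool free_ = true;
    for (int p = c_start[k]; p < c_end[k] && free_; ++p)
      if (covered[p]) free_ = false;
    if (!free_) continue;
    for (int p = c_start[k]; p < c_end[k]; ++p) covered[p] = true;
    keep.push_back(k);
  }
  std::sort(keep.begin(), keep.end(), [&](int a, int b) {
    return c_start[a] < c_start[b];
  });

  int m = (int) keep.size();
  IntegerVector start(m), end(m), unit_count(m);
  CharacterVector unit(m);
  for (int k = 0; k < m; ++k) {
    int idx = keep[k];
    start[k] = c_start[idx];
    end[k] = c_end[idx];
    unit_count[k] = c_count[idx];
    unit[k] = seq.substr(c_start[idx], c_ulen[idx]);
  }
  return DataFrame::create(_["start"] = start, _["end"] = end,
                           _["unit"] = unit, _["unit_count"] = unit_count,
                           _["stringsAsFactors"] = false);
}

// All positions (0-based) on the given strand of `templ` where `primer`
// binds with Hamming distance <= max_mismatch and its 3'-most
// `three_prime_exact` bases matching exactly. N never matches.
// [[Rcpp::export]]
DataFrame cpp_find_sites(std::string primer, std::string templ,
                         int max_mismatch, int three_prime_exact,
                         bool anchor_at_end) {
  int m = (int) primer.size(), n = (int) templ.size();
  std::vector<int> pos, mm;
  if (m > n) {
    return DataFrame::create(_["start"] = IntegerVector(0),
                             _["mismatches"] = IntegerVector(0));
  }
  // the primer 3' anchor sits at the pattern end on the forward strand,
  // at the pattern start for a reverse-complemented pattern
  for (int p = 0; p + m <= n; ++p) {
    int d = 0;
    bool ok = true;
    for (int i = m - 1; i >= 0; --i) {
      char a = primer[i], b = templ[p + i];
      bool match = is_acgt(a) && a == b;
      if (!match) {
        bool in_anchor = anchor_at_end ? (i >= m - three_prime_exact)
                                       : (i < three_prime_exact);
        if (in_anchor) { ok = false; break; }
        if (++d > max_mismatch) { ok = false; break; }
      }
    }
    if (ok) { pos.push_back(p); mm.push_back(d); }
  }
  return DataFrame::create(_["start"] = wrap(pos), _["mismatches"] = wrap(mm));
}

// Best ungapped local identity of `query` against `subject`, seeded by exact
// k-mer matches. On each seeded diagonal a 1-D Smith-Waterman (match +1,
// mismatch -2) finds the best segment; segments shorter than min_span are
// ignored. Returns c(identity, span). Strand handling is done by the caller.
// [[Rcpp::export]]
NumericVector cpp_best_identity(std::string query, std::string subject,
                                int seed_k, int min_span) {
  int nq = (int) query.size(), ns = (int) subject.size();
  double best_id = 0.0;
  int best_span = 0;
  if (nq < seed_k || ns < seed_k)
    return NumericVector::create(best_id, best_span);

  std::unordered_map<std::string, std::vector<int>> index;
  for (int i = 0; i + seed_k <= ns; ++i)
    index[subject.substr(i, seed_k)].push_back(i);

  std::vector<bool> diag_done(nq + ns, false);
  for (int i = 0; i + seed_k <= nq; ++i) {
    auto it = index.find(query.substr(i, seed_k));
    if (it == index.end()) continue;
    for (int j : it->second) {
      int d = (j - i) + nq;  // shift to non-negative
      if (diag_done[d]) continue;
      diag_done[d] = true;
      int off = j - i;
      int qs = std::max(0, -off), qe = std::min(nq, ns - off);
      double sc = 0.0;
      int seg_start = qs, seg_mm = 0, cur_mm = 0;
      double best_sc = 0.0;
      int b0 = qs, b1 = qs, bmm = 0;
      for (int q = qs; q < qe; ++q) {
        bool match = is_acgt(query[q]) && query[q] == subject[q + off];
        double add = match ? 1.0 : -2.0;
        if (sc + add <= 0) {
          sc = 0.0; seg_start = q + 1; cur_mm = 0;
        } else {
          sc += add;
          if (!match) ++cur_mm;
          if (sc > best_sc) {
            best_sc = sc; b0 = seg_start; b1 = q + 1; bmm = cur_mm;
          }
        }
      }
      int span = b1 - b0;
      if (span >= min_span) {
        double ident = (double)(span - bmm) / (double) span;
        if (ident > best_id || (ident == best_id && span > best_span)) {
          best_id = ident; best_span = span;
        }
      }
    }
  }
  return NumericVector::create(best_id, best_span);
}
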