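#include <Rcpp.h>
using namespace Rcpp;

// Elementwise Hamming distance between two equal-length string vectors.
// `b` of length 1 is recycled against `a`.
// [[Rcpp::export(name = ".hamming_cpp")]]
IntegerVector hamming_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  bool recycle = (b.size() == 1);
  if (!recycle && b.size() != n)
    stop("'a' and 'b' must have the same length (or 'b' length 1)");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i] == NA_STRING || b[recycle ? 0 : i] == NA_STRING) {
      out[i] = NA_INTEGER;
      continue;
    }
    const char *x = CHAR(a[i]);
    const char *y = CHAR(b[recycle ? 0 : i]);
    R_xlen_t lx = LENGTH(a[i]), ly = LENGTH(b[recycle ? 0 : i]);
    if (lx != ly) stop("sequences must have equal length");
    int d = 0;
    for (R_xlen_t j = 0; j < lx; ++j) if (x[j] != y[j]) ++d;
    out[i] = d;
  }
  return out;
}

// Minimum pairwise Hamming distance over a set of equal-length sequences.
// [[Rcpp::export(name = ".min_pairwise_hamming_cpp")]]
int min_pairwise_hamming_cpp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  if (n < 2) stop("need at least two sequences");
  R_xlen_t L = LENGTH(seqs[0]);
  int best = (int) L + 1;
  for (R_xlen_t i = 0; i < n - 1; ++i) {
    const char *x = CHAR(seqs[i]);
    if (LENGTH(seqs[i]) != L) stop("sequences must have equal length");
    for (R_xlen_t j = i + 1; j < n; ++j) {
      const char *y = CHAR(seqs[j]);
      int d = 0;
      for (R_xlen_t k = 0; k < L && d < best; ++k) if (x[k] != y[k]) ++d;
      if (d < best) {
        best = d;
        if (best == 0) return 0;
      }
    }
  }
  return best;
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// Inject i.i.d. per-base substitution errors at `rate`, using R's RNG so
// results are reproducible under set.seed(). Non-ACGT characters untouched.
// [[Rcpp::export(name = ".mutate_bases_cpp")]]
CharacterVector mutate_bases_cpp(CharacterVector seqs, double rate) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(seqs[i]);
    R_xlen_t L = LENGTH(seqs[i]);
    buf.assign(s, L);
    bool changed = false;
    for (R_xlen_t j = 0; j < L; ++j) {
      if (unif_rand() < rate) {
        char c = buf[j];
        int b = (int) (unif_rand() * 3.0);
        if (b > 2) b = 2;
        // pick among the three bases differing from c
        int k = 0;
        for (int m = 0; m < 4; ++m) {
          if (BASES[m] == c) continue;
          if (k == b) { buf[j] = BASES[m]; break; }
          ++k;
        }
        changed = changed || (buf[j] != c);
      }
    }
    out[i] = changed ? String(buf) : seqs[i];
  }
  return out;
}

// Mismatch count of each read against `subject` starting at 1-based `starts`.
// NA where the window would run off the subject.
// [[Rcpp::export(name = ".mismatch_at_cpp")]]
IntegerVector mismatch_at_cpp(std::string subject, CharacterVector reads,
                              IntegerVector starts) {
  R_xlen_t n = reads.size();
  if (starts.size() != n) stop("'starts' must match 'reads' length");
  R_xlen_t S = subject.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (reads[i] == NA_STRING || starts[i] == NA_INTEGER) {
      out[i] = NA_INTEGER;
      continue;
    }
    const char *r = CHAR(reads[i]);
    R_xlen_t L = LENGTH(reads[i]);
    R_xlen_t s0 = starts[i] - 1;
    if (s0 < 0 || s0 + L > S) { out[i] = NA_INTEGER; continue; }
    int d = 0;
    for (R_xlen_t j = 0; j < L; ++j) if (r[j] != subject[s0 + j]) ++d;
    out[i] = d;
  }
  return out;
}

static inline int mm_count_capped(const char *a, const char *b, int L, int cap) {
  int d = 0;
  for (int j = 0; j < L && d <= cap; ++j) if (a[j] != b[j]) ++d;
  return d;
}

// Locate `left` anchor (<= max_mm mismatches) in each read, check the
// `right` anchor immediately after the barcode, and return the intervening
// barcode. NA where either anchor is not found.
// [[Rcpp::export(name = ".scan_anchor_cpp")]]
CharacterVector scan_anchor_cpp(CharacterVector reads, std::string left,
                                std::string right, int bc_len, int max_mm) {
  R_xlen_t n = reads.size();
  int ll = left.size(), lr = right.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = NA_STRING;
    if (reads[i] == NA_STRING) continue;
    const char *r = CHAR(reads[i]);
    int L = LENGTH(reads[i]);
    int last = L - ll - bc_len - lr;
    for (int p = 0; p <= last; ++p) {
      if (mm_count_capped(r + p, left.c_str(), ll, max_mm) <= max_mm &&
          mm_count_capped(r + p + ll + bc_len, right.c_str(), lr, max_mm) <= max_mm) {
        out[i] = String(std::string(r + p + ll, bc_len));
        break;
      }
    }
  }
  return out;
}

// Merge read pairs. s2 / q2 must already be reverse-complemented /
// reversed so both mates read 5'->3' on the same strand. The overlap is
// the suffix of read 1 against the prefix of read 2; among overlaps of
// length >= min_overlap with mismatch fraction <= max_mm_frac the one
// maximising matches - 4*mismatches is kept (ties -> longer overlap).
// Disagreements resolve to the higher-quality base (tie -> read 1).
// [[Rcpp::export(name = ".merge_pairs_cpp")]]
List merge_pairs_cpp(CharacterVector s1, CharacterVector q1,
                     CharacterVector s2, CharacterVector q2,
                     int min_overlap, double max_mm_frac) {
  R_xlen_t n = s1.size();
  CharacterVector mseq(n), mqual(n);
  IntegerVector olen(n), omm(n);
  std::string sb, qb;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *a = CHAR(s1[i]); int la = LENGTH(s1[i]);
    const char *b = CHAR(s2[i]); int lb = LENGTH(s2[i]);
    const char *qa = CHAR(q1[i]);
    const char *qb_ = CHAR(q2[i]);
    int best_o = -1, best_mm = 0;
    double best_score = -1e18;
    int omax = la < lb ? la : lb;
    for (int o = min_overlap; o <= omax; ++o) {
      const char *ta = a + la - o;
      int cap = (int) (max_mm_frac * o);
      int mm = 0;
      for (int j = 0; j < o; ++j) {
        if (ta[j] != b[j] && ++mm > cap) break;
      }
      if (mm > cap) continue;
      double score = (o - mm) - 4.0 * mm;
      if (score > best_score || (score == best_score && o > best_o)) {
        best_score = score; best_o = o; best_mm = mm;
      }
    }
    if (best_o < 0) {
      mseq[i] = NA_STRING; mqual[i] = NA_STRING;
      olen[i] = NA_INTEGER; omm[i] = NA_INTEGER;
      continue;
    }
    int o = best_o;
    sb.assign(a, la - o);
    qb.assign(qa, la - o);
    for (int j = 0; j < o; ++j) {
      char ca = a[la - o + j], cb = b[j];
      char pa = qa[la - o + j], pb = qb_[j];
      if (ca == cb) {
        sb.push_back(ca);
        qb.push_back(pa >= pb ? pa : pb);
      } else if (pb > pa) {
        sb.push_back(cb); qb.push_back(pb);
      } else {
        sb.push_back(ca); qb.push_back(pa);
      }
    }
    sb.append(b + o, lb - o);
    qb.append(qb_ + o, lb - o);
    mseq[i] = String(sb); mqual[i] = String(qb);
    olen[i] = o; omm[i] = best_mm;
  }
  return List::create(_["sequence"] = mseq, _["quality"] = mqual,
                      _["overlap"] = olen, _["mismatches"] = omm);
}

// Reverse each string (for reversing per-base quality strings).
// [[Rcpp::export(name = ".reverse_strings")]]
CharacterVector reverse_strings(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    buf.assign(CHAR(x[i]), LENGTH(x[i]));
    std::reverse(buf.begin(), buf.end());
    out[i] = String(buf);
  }
  return out;
}

// Substitution calls for reads whose length equals the reference length
// (the gap-free fast path of the mutation caller). Returns flat parallel
// vectors: read index (1-based), 0-based position, ref base, alt base.
// [[Rcpp::export(name = ".call_substitutions_cpp")]]
List call_substitutions_cpp(CharacterVector reads, std::string ref) {
  R_xlen_t n = reads.size();
  int L = ref.size();
  std::vector<int> rid, pos;
  std::vector<char> rb, ab;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *r = CHAR(reads[i]);
    if (LENGTH(reads[i]) != L) stop("read length must equal reference length");
    for (int j = 0; j < L; ++j) {
      if (r[j] != ref[j]) {
        rid.push_back((int) i + 1);
        pos.push_back(j);
        rb.push_back(ref[j]);
        ab.push_back(r[j]);
      }
    }
  }
  R_xlen_t m = rid.size();
  CharacterVector refv(m), altv(m);
  for (R_xlen_t k = 0; k < m; ++k) {
    refv[k] = String(std::string(1, rb[k]));
    altv[k] = String(std::string(1, ab[k]));
  }
  return List::create(_["read"] = IntegerVector(rid.begin(), rid.end()),
                      _["position"] = IntegerVector(pos.begin(), pos.end()),
                      _["ref"] = refv, _["alt"] = altv);
}
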