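#include <Rcpp.h>
using namespace Rcpp;

// Best ungapped overlap merge of read pairs.
//
// r1 is the forward mate as sequenced; r2rc the reverse-complemented reverse
// mate (so both are on the fragment's sense strand); q1/q2rc the matching
// Phred+33 quality strings (q2rc reversed along with the sequence).
//
// The candidate overlap of length L aligns the last L bases of r1 with the
// first L bases of r2rc; the merged fragment is
//   r1[0 .. n1-L-1] + consensus(overlap) + r2rc[L .. n2-1].
// The best overlap maximises the match count; ties go to the longer overlap.
// Scanning runs from the longest candidate down and stops once no shorter
// overlap can beat the current best (matches(L') <= L' <= best_matches).
//
// Consensus at a disagreeing column keeps the base with the higher quality
// when the qualities differ by at least delta_q, else emits 'N' (quality '#').
// At agreeing columns the higher of the two qualities is kept. 'N' never
// counts as a match.
// [[Rcpp::export(name = ".overlap_merge_cpp")]]
List overlap_merge_cpp(CharacterVector r1, CharacterVector q1,
                       CharacterVector r2rc, CharacterVector q2rc,
                       int min_overlap, double max_mismatch_frac,
                       int delta_q) {
  const int n = r1.size();
  CharacterVector out_seq(n), out_qual(n), reason(n);
  IntegerVector overlap_len(n), n_mismatch(n);
  LogicalVector merged(n);
  std::string buf_s, buf_q;

  for (int i = 0; i < n; ++i) {
    const char *s1 = CHAR(STRING_ELT(r1, i));
    const char *u1 = CHAR(STRING_ELT(q1, i));
    const char *s2 = CHAR(STRING_ELT(r2rc, i));
    const char *u2 = CHAR(STRING_ELT(q2rc, i));
    const int n1 = LENGTH(STRING_ELT(r1, i));
    const int n2 = LENGTH(STRING_ELT(r2rc, i));
    const int lmax = n1 < n2 ? n1 : n2;

    merged[i] = false;
    overlap_len[i] = NA_INTEGER;
    n_mismatch[i] = NA_INTEGER;
    out_seq[i] = NA_STRING;
    out_qual[i] = NA_STRING;

    if (lmax < min_overlap) {
      reason[i] = "too_short_for_overlap";
      continue;
    }

    int best_matches = -1, best_L = -1;
    for (int L = lmax; L >= min_overlap && L > best_matches; --L) {
      const char *a = s1 + (n1 - L);
      int m = 0;
      for (int k = 0; k < L; ++k) {
        const char c = a[k];
        if (c == s2[k] && c != 'N') ++m;
      }
      if (m > best_matches) {
        best_matches = m;
        best_L = L;
      }
    }

    const int mm = best_L - best_matches;
    if (best_matches <= 0 ||
        (double)mm / (double)best_L > max_mismatch_frac) {
      reason[i] = best_matches <= 0 ? "no_overlap" : "overlap_mismatch";
      continue;
    }

    buf_s.assign(s1, s1 + (n1 - best_L));
    buf_q.assign(u1, u1 + (n1 - best_L));
    const char *a = s1 + (n1 - best_L);
    const char *qa = u1 + (n1 - best_L);
    for (int k = 0; k < best_L; ++k) {
      const char c1 = a[k], c2 = s2[k];
      const int v1 = qa[k], v2 = u2[k];
      if (c1 == c2) {
        buf_s.push_back(c1);
        buf_q.push_back((char)(v1 > v2 ? v1 : v2));
      } else if (v1 - v2 >= delta_q) {
        buf_s.push_back(c1);
        buf_q.push_back((char)v1);
      } else if (v2 - v1 >= delta_q) {
        buf_s.push_back(c2);
        buf_q.push_back((char)v2);
      } else {
        buf_s.push_back('N');
        buf_q.push_back('#');
      }
    }
    buf_s.append(s2 + best_L, s2 + n2);
    buf_q.append(u2 + best_L, u2 + n2);

    out_seq[i] = buf_s;
    out_qual[i] = buf_q;
    overlap_len[i] = best_L;
    n_mismatch[i] = mm;
    merged[i] = true;
    reason[i] = NA_STRING;
  }

  return List::create(_["seq"] = out_seq, _["qual"] = out_qual,
                      _["overlap_len"] = overlap_len,
                      _["n_mismatch"] = n_mismatch,
                      _["merged"] = merged, _["reason"] = reason);
}
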