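#include <Rcpp.h>
using namespace Rcpp;

// Ungapped best-placement scan over a reference tier.
//
// For each read, every offset of every reference is scored by Hamming
// distance (substitutions only; hydrolysis fragments carry no indel signal).
// All placements achieving the minimum mismatch count are returned, provided
// that minimum is <= max_mm. 'N' in a read matches nothing and is never
// counted as a mismatch. Output rows are ordered (read, ref index, offset),
// which downstream code relies on for deterministic reporting.
//
// [[Rcpp::export]]
DataFrame align_scan(CharacterVector reads, CharacterVector refs, int max_mm) {
  const int nref = refs.size();
  std::vector<std::string> subj(nref);
  for (int j = 0; j < nref; ++j) subj[j] = as<std::string>(refs[j]);

  std::vector<int> out_read, out_ref, out_off, out_mm;
  for (int i = 0; i < reads.size(); ++i) {
    const std::string q = as<std::string>(reads[i]);
    const int L = (int)q.size();
    int best = max_mm + 1;           // current bound; placements must beat it
    std::vector<std::array<int, 3>> hits;
    for (int j = 0; j < nref; ++j) {
      const std::string &s = subj[j];
      const int maxoff = (int)s.size() - L;
      for (int off = 0; off <= maxoff; ++off) {
        int mm = 0;
        for (int k = 0; k < L; ++k) {
          const char c = q[k];
          if (c == 'N') continue;
          if (c != s[off + k] && ++mm > best) break;
        }
        if (mm > max_mm || mm > best) continue;
        if (mm < best) { best = mm; hits.clear(); }
        hits.push_back({j, off, mm});
      }
    }
    for (const auto &h : hits) {
      out_read.push_back(i + 1);
      out_ref.push_back(h[0] + 1);
      out_off.push_back(h[1]);
      out_mm.push_back(h[2]);
    }
  }
  return DataFrame::create(_["read"] = out_read, _["ref"] = out_ref,
                           _["offset"] = out_off, _["n_mm"] = out_mm);
}
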