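#include <Rcpp.h>
#include <string>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

static inline char complement_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

// canonical form = lexicographic min of a k-mer and its reverse complement;
// returns false when the window contains a non-ACGT character
static inline bool canonical_kmer(const std::string& s, size_t pos, int k,
                                  std::string& out) {
  for (int i = 0; i < k; ++i) {
    char c = s[pos + i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return false;
  }
  std::string fwd = s.substr(pos, k);
  std::string rc(k, 'N');
  for (int i = 0; i < k; ++i) rc[k - 1 - i] = complement_base(fwd[i]);
  out = (rc < fwd) ? rc : fwd;
  return true;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical_kmers(CharacterVector seqs, int k) {
  std::unordered_set<std::string> seen;
  std::vector<std::string> ordered;
  std::string km;
  for (R_xlen_t j = 0; j < seqs.size(); ++j) {
    std::string s = as<std::string>(seqs[j]);
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + k <= s.size(); ++p) {
      if (!canonical_kmer(s, p, k, km)) continue;
      if (seen.insert(km).second) ordered.push_back(km);
    }
  }
  return wrap(ordered);
}

// per read: number of k-mer windows whose canonical form is in `kmers`
// [[Rcpp::export]]
IntegerVector cpp_shared_kmer_counts(CharacterVector seqs, CharacterVector kmers,
                                     int k) {
  std::unordered_set<std::string> idx;
  for (R_xlen_t j = 0; j < kmers.size(); ++j)
    idx.insert(as<std::string>(kmers[j]));
  IntegerVector out(seqs.size());
  std::string km;
  for (R_xlen_t j = 0; j < seqs.size(); ++j) {
    std::string s = as<std::string>(seqs[j]);
    int n = 0;
    if (!idx.empty() && (int)s.size() >= k) {
      for (size_t p = 0; p + k <= s.size(); ++p) {
        if (!canonical_kmer(s, p, k, km)) continue;
        if (idx.count(km)) ++n;
      }
    }
    out[j] = n;
  }
  return out;
}

// Leftmost position where a prefix of the adapter matches the read suffix
// (or a full internal occurrence), overlap >= min_overlap and mismatch
// fraction <= max_mismatch_rate; returns the new read length (bases kept).
// 'N' never matches.
// [[Rcpp::export]]
IntegerVector cpp_clip_lengths(CharacterVector seqs, std::string adapter,
                               int min_overlap, double max_mismatch_rate) {
  int m = (int)adapter.size();
  IntegerVector out(seqs.size());
  for (R_xlen_t j = 0; j < seqs.size(); ++j) {
    std::string s = as<std::string>(seqs[j]);
    int n = (int)s.size();
    int keep = n;
    for (int p = 0; p < n; ++p) {
      int L = std::min(n - p, m);
      if (L < min_overlap) break;  // overlaps only shrink from here on
      double budget = max_mismatch_rate * L + 1e-9;
      int mism = 0;
      bool ok = true;
      for (int i = 0; i < L; ++i) {
        char a = adapter[i], b = s[p + i];
        if (a != b || a == 'N' || b == 'N') {
          if (++mism > budget) { ok = false; break; }
        }
      }
      if (ok) { keep = p; break; }
    }
    out[j] = keep;
  }
  return out;
}

// Adaptive 3' trimming: slide a `window`-base window from the read end toward
// the start, dropping the final base while the window mean quality is below
// `threshold`; when fewer than `window` bases remain the mean test is applied
// once to all remaining bases. Qualities are Phred+33 encoded strings.
// Returns the number of bases kept (a prefix length).
// [[Rcpp::export]]
IntegerVector cpp_trim_lengths(CharacterVector quals, int window,
                               double threshold) {
  IntegerVector out(quals.size());
  for (R_xlen_t j = 0; j < quals.size(); ++j) {
    std::string q = as<std::string>(quals[j]);
    int n = (int)q.size();
    std::vector<double> pre(n + 1, 0.0);
    for (int i = 0; i < n; ++i) pre[i + 1] = pre[i] + (double)(q[i] - 33);
    int keep = -1;
    double need = threshold * window - 1e-9;
    for (int L = n; L >= window; --L) {
      if (pre[L] - pre[L - window] >= need) { keep = L; break; }
    }
    if (keep < 0) {
      int rem = (n >= window) ? window - 1 : n;
      if (rem == 0) keep = 0;
      else keep = (pre[rem] / rem >= threshold - 1e-9) ? rem : 0;
    }
    out[j] = keep;
  }
  return out;
}

// distinct bases among {A,C,G,T} per sequence; N (and anything else) ignored
// [[Rcpp::export]]
IntegerVector cpp_unique_base_count(CharacterVector seqs) {
  IntegerVector out(seqs.size());
  for (R_xlen_t j = 0; j < seqs.size(); ++j) {
    std::string s = as<std::string>(seqs[j]);
    bool seen[4] = {false, false, false, false};
    for (size_t i = 0; i < s.size(); ++i) {
      switch (s[i]) {
      case 'A': seen[0] = true; break;
      case 'C': seen[1] = true; break;
      case 'G': seen[2] = true; break;
      case 'T': seen[3] = true; break;
      default: break;
      }
    }
    out[j] = (int)seen[0] + seen[1] + seen[2] + seen[3];
  }
  return out;
}
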