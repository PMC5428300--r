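#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// All maximal exact reverse-complement repeats of length >= min_len.
// Seed-and-extend on 2-bit packed k-mers: hash every clean k-mer of s,
// scan the k-mers of revcomp(s), keep only left-maximal seed pairs
// (O(1) test) and extend those to full maximal matches. Returns a matrix
// with one row per repeat: start1, start2 (1-based, on s) and length,
// where [start2, start2+len) on s is the reverse complement of
// [start1, start1+len).
// [[Rcpp::export]]
IntegerMatrix revcomp_repeats_cpp(std::string s, int min_len) {
  const int n = s.size();
  int k = std::min(31, min_len);
  if (k < 4) k = 4;
  if (n < 2 * k) return IntegerMatrix(0, 3);

  std::string rc(n, 'N');
  for (int i = 0; i < n; ++i) {
    char c = s[n - 1 - i];
    rc[i] = (c == 'A') ? 'T' : (c == 'C') ? 'G' : (c == 'G') ? 'C'
            : (c == 'T') ? 'A' : 'N';
  }

  // rolling 2-bit hash of s k-mers
  std::unordered_map<uint64_t, std::vector<int>> pos;
  pos.reserve(n);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t h = 0; int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = code(s[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run >= k) pos[h].push_back(i - k + 1);
  }

  std::vector<int> out1, out2, outl;
  h = 0; run = 0;
  for (int j = 0; j < n; ++j) {
    int c = code(rc[j]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (run + 1 < k) { ++run; continue; }
    ++run;
    int jj = j - k + 1; // k-mer start in rc
    auto it = pos.find(h);
    if (it == pos.end()) continue;
    for (int i : it->second) {
      // left-maximality in (s, rc) coordinates
      if (i > 0 && jj > 0 && s[i - 1] == rc[jj - 1] && code(s[i - 1]) >= 0)
        continue;
      // extend right
      int len = k;
      while (i + len < n && jj + len < n && s[i + len] == rc[jj + len] &&
             code(s[i + len]) >= 0)
        ++len;
      if (len < min_len) continue;
      // map rc interval back to s: rc[jj, jj+len) <-> s[n-jj-len, n-jj)
      int i2 = n - jj - len;
      if (i2 <= i) continue; // keep each pair once, first copy leftmost
      out1.push_back(i + 1);
      out2.push_back(i2 + 1);
      outl.push_back(len);
    }
  }
  IntegerMatrix res(out1.size(), 3);
  for (size_t r = 0; r < out1.size(); ++r) {
    res(r, 0) = out1[r]; res(r, 1) = out2[r]; res(r, 2) = outl[r];
  }
  colnames(res) = CharacterVector::create("start1", "start2", "length");
  return res;
}
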