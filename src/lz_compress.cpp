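#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

// Size (in bits) of a greedy LZ77 parse of `s`, counting only tokens emitted
// at positions >= dict_len.  Positions [0, dict_len) are indexed as match
// sources but never emitted, which yields the conditional size C(x|y) when
// s = y + x and dict_len = |y|.
//
// Bit-accounting model (fixed; no bitstream is produced):
//   ACGT literal      : 1 flag + 2 payload            =  3 bits
//   non-ACGT literal  : 1 flag + 1 escape + 8 payload = 10 bits
//   match             : 1 flag + gamma(offset) + gamma(length)
// At each position the longest *beneficial* match is taken: a candidate is
// beneficial when its token is strictly cheaper than coding the covered
// span as literals, so a short match at a huge offset never beats literal
// coding.  Minimum match length 4, ties broken by smallest offset, matches
// may overlap the current position (self-referential copy).

static inline int elias_gamma_bits(long v) {
  // v >= 1
  int b = 0;
  while (v >> b) ++b;        // b = floor(log2 v) + 1
  return 2 * b - 1;
}

static inline bool is_acgt(unsigned char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// [[Rcpp::export]]
double lz_parse_bits(std::string s, int dict_len) {
  const int n = (int) s.size();
  if (n == 0) Rcpp::stop("empty input");
  if (dict_len < 0 || dict_len >= n) Rcpp::stop("invalid dictionary length");
  const unsigned char *p = (const unsigned char *) s.data();

  // prefix sums of per-symbol literal cost, for pricing a covered span
  std::vector<long> litcum(n + 1, 0);
  for (int i = 0; i < n; ++i) litcum[i + 1] = litcum[i] + (is_acgt(p[i]) ? 3 : 10);

  std::unordered_map<uint32_t, std::vector<int> > tab;
  tab.reserve((size_t) n * 2);
  auto key_at = [&](int i) -> uint32_t {
    return ((uint32_t) p[i] << 24) | ((uint32_t) p[i + 1] << 16) |
           ((uint32_t) p[i + 2] << 8) | (uint32_t) p[i + 3];
  };

  long bits = 0;
  int indexed = 0;  // next position to insert into the table
  int i = 0;
  while (i < n) {
    // index all positions strictly before i whose 4-mer fits in s
    while (indexed < i && indexed + 3 < n) {
      tab[key_at(indexed)].push_back(indexed);
      ++indexed;
    }
    int best_len = 0, best_j = -1, best_cost = 0;
    if (i + 3 < n) {
      auto it = tab.find(key_at(i));
      if (it != tab.end()) {
        const std::vector<int> &cand = it->second;
        // scan most-recent first; strict improvement keeps smallest offset
        for (int c = (int) cand.size() - 1; c >= 0; --c) {
          int j = cand[c];
          int len = 0;
          while (i + len < n && p[j + len] == p[i + len]) ++len;
          if (len < 4 || len <= best_len) continue;
          int cost = 1 + elias_gamma_bits(i - j) + elias_gamma_bits(len);
          if (cost < litcum[i + len] - litcum[i]) {
            best_len = len; best_j = j; best_cost = cost;
          }
        }
      }
    }
    if (best_len >= 4) {
      if (i >= dict_len) bits += best_cost;
      i += best_len;
    } else {
      if (i >= dict_len) bits += is_acgt(p[i]) ? 3 : 10;
      ++i;
    }
  }
  return (double) bits;
}
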