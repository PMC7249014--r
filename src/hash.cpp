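#include <Rcpp.h>
#include <cstdint>
#include <string>
using namespace Rcpp;

// 64-bit FNV-1a over UTF-8 bytes, salted by folding the seed's 8 bytes in
// first.  Used for the hashed n-gram encoder and the circular fingerprint so
// that embeddings are bit-identical across platforms (R's own hashing makes
// no such promise).
static inline uint64_t fnv1a64(const std::string &s, uint64_t seed) {
  uint64_t h = 14695981039346656037ULL;
  const uint64_t prime = 1099511628211ULL;
  for (int i = 0; i < 8; ++i) {
    h ^= (seed >> (8 * i)) & 0xffULL;
    h *= prime;
  }
  for (unsigned char c : s) {
    h ^= (uint64_t)c;
    h *= prime;
  }
  return h;
}

// [[Rcpp::export]]
IntegerVector fnv_index(CharacterVector units, int dimension, int seed) {
  const uint64_t s = (uint64_t)(int64_t)seed;
  IntegerVector out(units.size());
  for (R_xlen_t i = 0; i < units.size(); ++i) {
    uint64_t h = fnv1a64(std::string(units[i]), s);
    out[i] = (int)(h % (uint64_t)dimension) + 1;  // 1-based for R
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector fnv_sign(CharacterVector units, int seed) {
  const uint64_t s = (uint64_t)(int64_t)seed;
  IntegerVector out(units.size());
  for (R_xlen_t i = 0; i < units.size(); ++i) {
    uint64_t h = fnv1a64(std::string(units[i]), s);
    out[i] = (h >> 63) ? -1 : 1;  // sign from bit 63
  }
  return out;
}

// Raw 64-bit hash reduced into [0, 2^31): used as a portable identifier for
// fingerprint environments before folding into n_bits.
// [[Rcpp::export]]
IntegerVector fnv_id31(CharacterVector units, int seed) {
  const uint64_t s = (uint64_t)(int64_t)seed;
  IntegerVector out(units.size());
  for (R_xlen_t i = 0; i < units.size(); ++i) {
    uint64_t h = fnv1a64(std::string(units[i]), s);
    out[i] = (int)(h & 0x7fffffffULL);
  }
  return out;
}
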