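#ifndef GAPCLOSR_KBLOOM_H
#define GAPCLOSR_KBLOOM_H

#include <cstdint>
#include <string>
#include <vector>
#include <stdexcept>

namespace gapclosr {

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

inline uint64_t fnv1a(const std::string& s, uint64_t seed) {
  uint64_t h = 1469598103934665603ULL ^ splitmix64(seed);
  for (size_t i = 0; i < s.size(); ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 1099511628211ULL;
  }
  return h;
}

inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

inline char comp_acgt(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
  }
  return '\0';
}

// Writes the reverse complement of s into buf and returns whichever of the
// two strands is lexicographically smaller (byte-wise, strand-neutral id).
inline const std::string& canonical_of(const std::string& s, std::string& buf) {
  const size_t n = s.size();
  buf.resize(n);
  for (size_t i = 0; i < n; ++i) buf[n - 1 - i] = comp_acgt(s[i]);
  return (buf < s) ? buf : s;
}

// Multiplicity-thresholded (cascading) Bloom filter over canonical k-mers.
// One bit array per level; an occurrence advances a k-mer by one level, and
// a k-mer is "solid" once present in all levels. Double hashing
// h_i = h1 + i*h2 with a fixed seed keeps runs reproducible.
struct CascadeBloom {
  int k;
  int n_levels;          // multiplicity threshold
  uint64_t size_bits;    // bits per level
  int num_hashes;
  uint64_t seed;
  std::vector<std::vector<uint64_t> > bits;
  uint64_t n_occ;        // k-mer occurrences processed
  uint64_t n_solid;      // k-mers that crossed the threshold (approximate distinct solid)

  CascadeBloom(int k_, int n_levels_, uint64_t size_bits_, int num_hashes_,
               uint64_t seed_)
      : k(k_), n_levels(n_levels_), size_bits(size_bits_),
        num_hashes(num_hashes_), seed(seed_), n_occ(0), n_solid(0) {
    if (k < 1) throw std::invalid_argument("k must be >= 1");
    if (n_levels < 1) throw std::invalid_argument("threshold must be >= 1");
    if (num_hashes < 1) throw std::invalid_argument("num_hashes must be >= 1");
    if (size_bits < (uint64_t)(8 * num_hashes))
      throw std::invalid_argument("size_bits too small (< 8 * num_hashes)");
    bits.assign(n_levels, std::vector<uint64_t>((size_bits + 63) / 64, 0ULL));
  }

  // Each level hashes with its own derived seed; with a shared seed a hit
  // in the top level would imply hits in all lower levels (same bit
  // positions, superset content), collapsing the cascade's false positive
  // rate to that of a single level.
  inline void hash_pair(const std::string& ck, int lev, uint64_t& h1,
                        uint64_t& h2) const {
    const uint64_t s = seed + 0x9e3779b97f4a7c15ULL * (uint64_t)lev;
    h1 = splitmix64(fnv1a(ck, s));
    h2 = splitmix64(fnv1a(ck, s ^ 0x5deece66dULL)) | 1ULL;
  }

  inline bool level_has(int lev, uint64_t h1, uint64_t h2) const {
    for (int i = 0; i < num_hashes; ++i) {
      uint64_t b = (h1 + (uint64_t)i * h2) % size_bits;
      if (!((bits[lev][b >> 6] >> (b & 63)) & 1ULL)) return false;
    }
    return true;
  }

  inline void level_set(int lev, uint64_t h1, uint64_t h2) {
    for (int i = 0; i < num_hashes; ++i) {
      uint64_t b = (h1 + (uint64_t)i * h2) % size_bits;
      bits[lev][b >> 6] |= (1ULL << (b & 63));
    }
  }

  // One occurrence of a canonical k-mer: inserted into level i+1 only if
  // already present in levels 1..i.
  inline void insert_occ(const std::string& ck) {
    uint64_t h1, h2;
    ++n_occ;
    for (int lev = 0; lev < n_levels; ++lev) {
      hash_pair(ck, lev, h1, h2);
      if (!level_has(lev, h1, h2)) {
        level_set(lev, h1, h2);
        if (lev == n_levels - 1) ++n_solid;
        return;
      }
    }
  }

  inline bool solid_canonical(const std::string& ck) const {
    uint64_t h1, h2;
    for (int lev = 0; lev < n_levels; ++lev) {
      hash_pair(ck, lev, h1, h2);
      if (!level_has(lev, h1, h2)) return false;
    }
    return true;
  }

  // Canonicalizes (buf is scratch) then queries.
  inline bool solid_kmer(const std::string& x, std::string& buf) const {
    return solid_canonical(canonical_of(x, buf));
  }
};

}  // namespace gapclosr

#endif
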