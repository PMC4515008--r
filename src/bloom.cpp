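#include <Rcpp.h>
#include <cctype>
#include <cstdio>
#include <cstring>
#include "kbloom.h"

using namespace Rcpp;
using gapclosr::CascadeBloom;
using gapclosr::canonical_of;
using gapclosr::is_acgt;

static void check_kmers(const CharacterVector& x, int k) {
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const char* p = CHAR(STRING_ELT(x, i));
    int n = 0;
    for (; p[n]; ++n) {
      if (!is_acgt(p[n]))
        stop("k-mer %d contains non-ACGT character '%c'", (int)(i + 1), p[n]);
    }
    if (n != k)
      stop("k-mer %d has length %d; filter k is %d", (int)(i + 1), n, k);
  }
}

// [[Rcpp::export]]
SEXP bloom_new_cpp(int k, int threshold, double size_bits, int num_hashes,
                   double seed) {
  XPtr<CascadeBloom> p(new CascadeBloom(k, threshold, (uint64_t)size_bits,
                                        num_hashes, (uint64_t)seed),
                       true);
  return p;
}

// [[Rcpp::export]]
void bloom_insert_reads_cpp(SEXP bp, CharacterVector reads) {
  XPtr<CascadeBloom> B(bp);
  const int k = B->k;
  std::string s, win, rcbuf;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    s.assign(CHAR(STRING_ELT(reads, r)));
    for (size_t i = 0; i < s.size(); ++i)
      s[i] = (char)std::toupper((unsigned char)s[i]);
    int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      run = is_acgt(s[i]) ? run + 1 : 0;
      if (run >= k) {
        win.assign(s, i - (size_t)k + 1, (size_t)k);
        B->insert_occ(canonical_of(win, rcbuf));
      }
    }
  }
}

// [[Rcpp::export]]
LogicalVector bloom_solid_cpp(SEXP bp, CharacterVector kmers) {
  XPtr<CascadeBloom> B(bp);
  check_kmers(kmers, B->k);
  LogicalVector out(kmers.size());
  std::string x, rcbuf;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    x.assign(CHAR(STRING_ELT(kmers, i)));
    out[i] = B->solid_kmer(x, rcbuf);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector bloom_neighbors_cpp(SEXP bp, std::string x, bool right) {
  XPtr<CascadeBloom> B(bp);
  const int k = B->k;
  if ((int)x.size() != k) stop("k-mer has length %d; filter k is %d",
                               (int)x.size(), k);
  for (size_t i = 0; i < x.size(); ++i)
    if (!is_acgt(x[i])) stop("k-mer contains non-ACGT character '%c'", x[i]);
  static const char EXT[4] = {'A', 'C', 'G', 'T'};
  std::vector<std::string> kept;
  std::vector<std::string> base;
  std::string cand, rcbuf;
  for (int ci = 0; ci < 4; ++ci) {
    if (right)
      cand = x.substr(1) + EXT[ci];
    else
      cand = std::string(1, EXT[ci]) + x.substr(0, (size_t)k - 1);
    if (B->solid_kmer(cand, rcbuf)) {
      kept.push_back(cand);
      base.push_back(std::string(1, EXT[ci]));
    }
  }
  CharacterVector out(kept.size());
  CharacterVector nm(kept.size());
  for (size_t i = 0; i < kept.size(); ++i) {
    out[i] = kept[i];
    nm[i] = base[i];
  }
  out.attr("names") = nm;
  return out;
}

// [[Rcpp::export]]
NumericVector bloom_fill_cpp(SEXP bp) {
  XPtr<CascadeBloom> B(bp);
  NumericVector out(B->n_levels);
  for (int lev = 0; lev < B->n_levels; ++lev) {
    uint64_t set = 0;
    const std::vector<uint64_t>& w = B->bits[lev];
    for (size_t i = 0; i < w.size(); ++i) {
      uint64_t v = w[i];
      // Kernighan popcount; portable across compilers
      while (v) { v &= v - 1; ++set; }
    }
    out[lev] = (double)set / (double)B->size_bits;
  }
  return out;
}

// [[Rcpp::export]]
List bloom_info_cpp(SEXP bp) {
  XPtr<CascadeBloom> B(bp);
  return List::create(
      _["k"] = B->k, _["threshold"] = B->n_levels,
      _["size_bits"] = (double)B->size_bits, _["num_hashes"] = B->num_hashes,
      _["hash_seed"] = (double)B->seed, _["n_occurrences"] = (double)B->n_occ,
      _["n_solid"] = (double)B->n_solid);
}

static const char BLOOM_MAGIC[8] = {'G', 'C', 'K', 'B', 'L', 'M', '0', '1'};

// [[Rcpp::export]]
void bloom_save_cpp(SEXP bp, std::string path) {
  XPtr<CascadeBloom> B(bp);
  std::FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  uint64_t hdr[7] = {(uint64_t)B->k,          (uint64_t)B->n_levels,
                     B->size_bits,            (uint64_t)B->num_hashes,
                     B->seed,                 B->n_occ,
                     B->n_solid};
  bool ok = std::fwrite(BLOOM_MAGIC, 1, 8, f) == 8 &&
            std::fwrite(hdr, sizeof(uint64_t), 7, f) == 7;
  for (int lev = 0; ok && lev < B->n_levels; ++lev) {
    const std::vector<uint64_t>& w = B->bits[lev];
    ok = std::fwrite(&w[0], sizeof(uint64_t), w.size(), f) == w.size();
  }
  std::fclose(f);
  if (!ok) stop("write failed for '%s'", path.c_str());
}

// [[Rcpp::export]]
SEXP bloom_load_cpp(std::string path) {
  std::FILE* f = std::fopen(path.c_str(), "rb");
  if (!f) stop("cannot open '%s' for reading", path.c_str());
  char magic[8];
  uint64_t hdr[7];
  if (std::fread(magic, 1, 8, f) != 8 ||
      std::memcmp(magic, BLOOM_MAGIC, 8) != 0 ||
      std::fread(hdr, sizeof(uint64_t), 7, f) != 7) {
    std::fclose(f);
    stop("'%s' is not a k-mer Bloom filter file", path.c_str());
  }
  CascadeBloom* B;
  try {
    B = new CascadeBloom((int)hdr[0], (int)hdr[1], hdr[2], (int)hdr[3], hdr[4]);
  } catch (...) {
    std::fclose(f);
    throw;
  }
  B->n_occ = hdr[5];
  B->n_solid = hdr[6];
  bool ok = true;
  for (int lev = 0; ok && lev < B->n_levels; ++lev) {
    std::vector<uint64_t>& w = B->bits[lev];
    ok = std::fread(&w[0], sizeof(uint64_t), w.size(), f) == w.size();
  }
  std::fclose(f);
  if (!ok) {
    delete B;
    stop("'%s' is truncated", path.c_str());
  }
  return XPtr<CascadeBloom>(B, true);
}

// [[Rcpp::export]]
CharacterVector canonical_cpp(CharacterVector kmers) {
  CharacterVector out(kmers.size());
  std::string x, rcbuf;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    x.assign(CHAR(STRING_ELT(kmers, i)));
    for (size_t j = 0; j < x.size(); ++j)
      if (!is_acgt(x[j]))
        stop("k-mer %d contains non-ACGT character '%c'", (int)(i + 1), x[j]);
    out[i] = canonical_of(x, rcbuf);
  }
  return out;
}

// Substitution errors for the read simulator; uses R's RNG stream so results
// are reproducible under set.seed(). Each hit base is replaced by one of the
// three other bases, uniformly.
// [[Rcpp::export]]
CharacterVector mutate_seqs_cpp(CharacterVector seqs, double rate) {
  if (rate <= 0) return seqs;
  static const char* B = "ACGT";
  CharacterVector out(seqs.size());
  std::string s;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    s.assign(CHAR(STRING_ELT(seqs, r)));
    for (size_t i = 0; i < s.size(); ++i) {
      if (!is_acgt(s[i])) continue;
      if (R::unif_rand() < rate) {
        int cur = (s[i] == 'A') ? 0 : (s[i] == 'C') ? 1 : (s[i] == 'G') ? 2 : 3;
        int j = (int)(R::unif_rand() * 3.0);
        if (j > 2) j = 2;
        if (j >= cur) ++j;
        s[i] = B[j];
      }
    }
    out[r] = s;
  }
  return out;
}
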