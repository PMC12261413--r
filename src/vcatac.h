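#ifndef VCATAC_H
#define VCATAC_H

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <unordered_map>
#include <unordered_set>

// 2-bit encoding A=0 C=1 G=2 T=3; complement is b ^ 3.
static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

static inline char bits2base(uint64_t b) { return "ACGT"[b & 3ULL]; }

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
  }
  return 'N';
}

static inline uint64_t revcomp_bits(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) { r = (r << 2) | ((x & 3ULL) ^ 3ULL); x >>= 2; }
  return r;
}

static inline std::string decode_bits(uint64_t x, int k) {
  std::string s(k, 'N');
  for (int i = k - 1; i >= 0; --i) { s[i] = bits2base(x); x >>= 2; }
  return s;
}

// K->U value: unitig id (1-based), 0-based offset of the k-mer start within
// the unitig, and whether the canonical form matches the unitig forward strand.
struct Entry {
  int32_t uid;
  int32_t off;
  uint8_t fwd;
};

// Write-once terminal k-mer cache shared across mapping calls.
struct KmerCache {
  size_t cap;
  std::unordered_map<uint64_t, Entry> m;
  explicit KmerCache(size_t c) : cap(c) { }
};

// Light view over the R-side dbg_index list; no copies.
struct IndexView {
  int k;
  R_xlen_t nk;
  const int *hi, *lo, *uid, *off, *fwd;
  const int *ulen;
  Rcpp::CharacterVector unitigs;
  const int *occ_ptr, *occ_ref, *occ_pos, *occ_fwd;
  int n_unitigs;

  uint64_t key(R_xlen_t i) const {
    return ((uint64_t)(uint32_t)hi[i] << 32) | (uint64_t)(uint32_t)lo[i];
  }
  // binary search over the uint64-sorted canonical k-mer table
  bool find(uint64_t canon, Entry &e) const {
    R_xlen_t a = 0, b = nk;
    while (a < b) {
      R_xlen_t mid = a + (b - a) / 2;
      if (key(mid) < canon) a = mid + 1; else b = mid;
    }
    if (a < nk && key(a) == canon) {
      e.uid = uid[a]; e.off = off[a]; e.fwd = (uint8_t)fwd[a];
      return true;
    }
    return false;
  }
  int unitig_len(int uid1) const { return ulen[uid1 - 1]; }
  const char *unitig_seq(int uid1) const {
    return CHAR(STRING_ELT(unitigs, uid1 - 1));
  }
};

inline IndexView make_view(Rcpp::List index) {
  IndexView v;
  v.k = Rcpp::as<int>(index["k"]);
  Rcpp::IntegerVector hi = index["kmer_hi"], lo = index["kmer_lo"],
    uid = index["kmer_uid"], off = index["kmer_off"], fwd = index["kmer_fwd"],
    ulen = index["unitig_len"], optr = index["occ_ptr"], oref = index["occ_ref"],
    opos = index["occ_pos"], ofwd = index["occ_fwd"];
  v.nk = hi.size();
  v.hi = INTEGER(hi); v.lo = INTEGER(lo); v.uid = INTEGER(uid);
  v.off = INTEGER(off); v.fwd = INTEGER(fwd); v.ulen = INTEGER(ulen);
  v.unitigs = Rcpp::CharacterVector(index["unitigs"]);
  v.n_unitigs = (int)v.unitigs.size();
  v.occ_ptr = INTEGER(optr); v.occ_ref = INTEGER(oref);
  v.occ_pos = INTEGER(opos); v.occ_fwd = INTEGER(ofwd);
  return v;
}

#endif
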