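#ifndef HAPCORRECT_SEQCORE_H
#define HAPCORRECT_SEQCORE_H

#include <cstdint>
#include <string>
#include <vector>

// 2-bit encoding; anything non-ACGT has been normalised upstream (R side).
inline uint8_t enc_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    default:            return 3; // T
  }
}

inline char dec_base(uint8_t b) {
  static const char tab[4] = {'A', 'C', 'G', 'T'};
  return tab[b & 3];
}

inline std::vector<uint8_t> enc_seq(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc_base(s[i]);
  return v;
}

// invertible 64-bit mix (splitmix64 finaliser), deterministic across runs
inline uint64_t hash64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

#endif
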