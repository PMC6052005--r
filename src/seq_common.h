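#ifndef GAPFILLR_SEQ_COMMON_H
#define GAPFILLR_SEQ_COMMON_H

#include <string>
#include <cstdint>

inline char comp_base(char c) {
    switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
    }
}

inline std::string revcomp(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (auto &c : r) c = comp_base(c);
    return r;
}

// 2-bit encoding; -1 for anything that is not an unambiguous base
inline int base2bit(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

inline bool bases_match(char a, char b) {
    int x = base2bit(a), y = base2bit(b);
    return x >= 0 && x == y;   // N never matches, not even itself
}

#endif
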