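#ifndef NANOAMPLIKIT_IUPAC_H
#define NANOAMPLIKIT_IUPAC_H

// IUPAC nucleotide codes as 4-bit sets over {A=1, C=2, G=4, T=8}.
// Two codes are compatible when their sets intersect.
static inline int iupac_mask(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': case 'U': case 'u': return 8;
    case 'R': case 'r': return 5;   // A/G
    case 'Y': case 'y': return 10;  // C/T
    case 'S': case 's': return 6;   // C/G
    case 'W': case 'w': return 9;   // A/T
    case 'K': case 'k': return 12;  // G/T
    case 'M': case 'm': return 3;   // A/C
    case 'B': case 'b': return 14;  // C/G/T
    case 'D': case 'd': return 13;  // A/G/T
    case 'H': case 'h': return 11;  // A/C/T
    case 'V': case 'v': return 7;   // A/C/G
    case 'N': case 'n': return 15;
    default: return 0;
  }
}

static inline bool iupac_compatible(char a, char b, bool degenerate) {
  if (degenerate) return (iupac_mask(a) & iupac_mask(b)) != 0;
  return a == b && iupac_mask(a) != 0;
}

#endif
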