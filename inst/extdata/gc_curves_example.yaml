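# Example curve-model override for the one_two_exon strategy.
# Layout: codon box -> third-position nucleotide -> {floor, ceiling, tau}
# p(i) = floor + (ceiling - floor) * exp(-i / tau), i = 0-based codon index.
# Boxes not listed keep the package default curve. Probabilities are
# renormalized over each box's nucleotides at every index.
GGN:
  C: {floor: 0.30, ceiling: 0.45, tau: 50}
  G: {floor: 0.25, ceiling: 0.40, tau: 50}
  A: {floor: 0.25, ceiling: 0.08, tau: 50}
  T: {floor: 0.20, ceiling: 0.07, tau: 50}
GAR:
  G: {floor: 0.55, ceiling: 0.80, tau: 50}
  A: {floor: 0.45, ceiling: 0.20, tau: 50}
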