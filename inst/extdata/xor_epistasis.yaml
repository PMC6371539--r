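residual_sd: 0.3
loci:
- ref_allele: A
  alt_allele: G
  alt_freq: 0.5
- ref_allele: T
  alt_allele: C
  alt_freq: 0.5
components:
- kind: xor
  loci:
  - 1
  - 2
  low_mean: 10.0
  high_mean: 11.0
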