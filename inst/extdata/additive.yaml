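residual_sd: 0.3
loci:
- ref_allele: A
  alt_allele: G
  alt_freq: 0.5
components:
- kind: additive
  loci: 1
  base_mean: 10.0
  per_allele_effect: 0.5
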