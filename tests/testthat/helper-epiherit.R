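# Shared fixtures and assertion helpers.

expect_within <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol)
}

one_locus <- locus_spec("A", "G", 0.5)
two_loci <- dplyr::bind_rows(locus_spec("A", "G", 0.5),
                             locus_spec("T", "C", 0.5))

# Deterministic het/hom parents for transmission tests: start from fixed-dose
# founders and overwrite alleles explicitly.
fixed_parent <- function(a1, a2, loci = one_locus) {
  ind <- simulate_founders(1, loci, seed = 1)
  ind$a1[1, ] <- as.integer(a1)
  ind$a2[1, ] <- as.integer(a2)
  ind
}
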