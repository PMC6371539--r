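test_that("founder genotypes follow Hardy-Weinberg frequencies", {
  f <- simulate_founders(5000, one_locus, seed = 101)
  d <- dose_matrix(f)[, 1]
  freq <- tabulate(d + 1L, 3L) / 5000
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / 5000)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se))

  expect_true(all(dose_matrix(simulate_founders(200, locus_spec("A", "G", 0),
                                                seed = 1)) == 0))
  expect_true(all(dose_matrix(simulate_founders(200, locus_spec("A", "G", 1),
                                                seed = 1)) == 2))
  expect_error(simulate_founders(0, one_locus), ">= 1")
})

test_that("transmission draws each parental allele with probability 0.5", {
  hom_alt <- fixed_parent(1, 1)
  expect_equal(transmit(hom_alt, 1), 1L)
  het <- fixed_parent(0, 1)
  set.seed(202)
  draws <- replicate(10000, transmit(het, 1))
  expect_within(mean(draws), 0.5, 3 * sqrt(0.25 / 10000))
})

test_that("children follow Mendelian segregation", {
  aa <- fixed_parent(0, 0)
  gg <- fixed_parent(1, 1)
  kid <- make_child(aa, gg)
  expect_equal(unname(dose_matrix(kid)[1, 1]), 1L)  # forced heterozygote
  # two homozygous-ref parents -> dose 0 always
  expect_equal(unname(dose_matrix(make_child(aa, aa))[1, 1]), 0L)
  # AG x AG -> dose distribution 0.25 / 0.5 / 0.25 (Punnett)
  het <- fixed_parent(0, 1)
  set.seed(303)
  doses <- replicate(10000, unname(dose_matrix(make_child(het, het))[1, 1]))
  freq <- tabulate(doses + 1L, 3L) / 10000
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / 10000)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se))
  expect_true(all(doses >= 0 & doses <= 2))
  expect_error(make_child(fixed_parent(0, 1, two_loci), aa), "different loci")
})

test_that("sib cohorts have the expected structure and genotype concordance", {
  co <- simulate_sib_pairs(2, one_locus, seed = 1)
  expect_equal(nrow(co$pairs), 2)
  expect_equal(nrow(cohort_founders(co)), 4)
  expect_equal(co$expected_relatedness, 0.5)

  big <- simulate_sib_pairs(10000, one_locus, seed = 404)
  pt <- pair_table(big)
  both_het <- mean(pt$member1_dose_1 == 1 & pt$member2_dose_1 == 1)
  # enumeration over the six parental mating types gives P(both sibs het) = 0.3125
  expect_within(both_het, 0.3125, 3 * sqrt(0.3125 * (1 - 0.3125) / 10000))
  # Mendelian conservation of allele frequency among children
  kids <- dplyr::filter(big$individuals, role == "child")
  expect_within(mean(kids$a1 + kids$a2) / 2, 0.5, 3 * sqrt(0.25 / 20000) / 2)
  expect_error(simulate_sib_pairs(1, one_locus), ">= 2")
})

test_that("half-sib cohorts have relatedness 0.25 and het concordance 0.25", {
  co <- simulate_half_sib_pairs(3, one_locus, seed = 1)
  expect_equal(nrow(co$pairs), 3)
  expect_equal(co$expected_relatedness, 0.25)

  big <- simulate_half_sib_pairs(10000, one_locus, seed = 505)
  pt <- pair_table(big)
  both_het <- mean(pt$member1_dose_1 == 1 & pt$member2_dose_1 == 1)
  # at p = 0.5 half-sib het indicators are uncorrelated: P(both het) = 0.25
  expect_within(both_het, 0.25, 3 * sqrt(0.25 * 0.75 / 10000))
  expect_within(mean(ibd_sharing(big)$ibd_sharing), 0.25, 0.01)
})

test_that("cousin cohorts realise identity-by-descent sharing of 0.125", {
  co <- simulate_cousin_pairs(5, one_locus, seed = 1)
  expect_equal(nrow(co$pairs), 5)
  expect_equal(co$expected_relatedness, 0.125)

  big <- simulate_cousin_pairs(10000, one_locus, seed = 606)
  sharing <- ibd_sharing(big)$ibd_sharing
  # cousins share 0 or 1 allele IBD per locus: sharing in {0, 0.5}, mean 0.125
  se <- sqrt(stats::var(sharing) / length(sharing))
  expect_within(mean(sharing), 0.125, 3 * se)
})

test_that("pair dose covariance decreases sib > half-sib > cousin as r * Va", {
  covs <- vapply(
    list(simulate_sib_pairs(10000, one_locus, seed = 707),
         simulate_half_sib_pairs(10000, one_locus, seed = 708),
         simulate_cousin_pairs(10000, one_locus, seed = 709)),
    function(co) {
      pt <- pair_table(co)
      stats::cov(pt$member1_dose_1, pt$member2_dose_1)
    }, numeric(1))
  expect_true(covs[1] > covs[2] && covs[2] > covs[3])
  # dose variance at p = 0.5 is 0.5, so covariances target r * 0.5
  expect_true(all(abs(covs - c(0.5, 0.25, 0.125) * 0.5) < 0.025))
})

test_that("phenotypes are genotypic means plus per-component residuals", {
  noiseless <- trait_preset("additive", residual_sd = 0)
  f <- simulate_founders(100, noiseless$loci, seed = 9)
  f <- sample_phenotypes(f, noiseless)
  expect_equal(f$phenotype, 10 + 0.5 * dose_matrix(f)[, 1])

  arch <- trait_preset("additive")
  f <- sample_phenotypes(simulate_founders(5000, arch$loci, seed = 10), arch)
  # population variance 2pq a^2 + residual = 0.125 + 0.09
  expect_within(stats::var(f$phenotype), 0.215, 0.012)

  xor_arch <- trait_preset("xor_epistasis")
  fx <- sample_phenotypes(simulate_founders(5000, xor_arch$loci, seed = 11),
                          xor_arch)
  expect_within(stats::var(fx$phenotype), 0.34, 0.013)

  expect_error(sample_phenotypes(f, xor_arch), "loci")
})

test_that("identical seeds reproduce cohorts bit for bit", {
  a <- simulate_sib_pairs(50, two_loci, seed = 42)
  b <- simulate_sib_pairs(50, two_loci, seed = 42)
  expect_identical(a, b)
  expect_identical(sample_phenotypes(a, trait_preset("xor_epistasis"), seed = 7),
                   sample_phenotypes(b, trait_preset("xor_epistasis"), seed = 7))
})

test_that("pair members are exchangeable", {
  co <- sample_phenotypes(simulate_sib_pairs(500, one_locus, seed = 13),
                          trait_preset("additive"))
  pt <- pair_table(co)
  swapped <- pt
  swapped$member1_phenotype <- pt$member2_phenotype
  swapped$member2_phenotype <- pt$member1_phenotype
  expect_equal(pair_correlation(swapped)$correlation,
               pair_correlation(pt)$correlation)
})

test_that("child genotype counts stay at HWE across 100 seeded runs", {
  # chi-square goodness of fit at alpha = 0.001; with a fixed master seed the
  # outcome is deterministic, and the false-positive budget is <= 2 runs
  set.seed(808)
  pvals <- replicate(100, {
    co <- simulate_sib_pairs(200, one_locus)
    kids <- dplyr::filter(co$individuals, role == "child")
    counts <- tabulate(kids$a1[, 1] + kids$a2[, 1] + 1L, 3L)
    stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value
  })
  expect_lte(sum(pvals < 0.001), 2)
})
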