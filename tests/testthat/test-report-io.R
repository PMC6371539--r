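test_that("run_experiment produces a complete, seeded estimates table", {
  cfg <- run_config("additive", n_sib_families = 300,
                    n_half_sib_families = 300, n_cousin_families = 300,
                    seed = 11)
  run <- run_experiment(cfg)
  est <- run$estimates
  expect_equal(est$relationship, c("sib", "half_sib", "cousin"))
  expect_equal(est$preset, rep("additive", 3))
  expect_equal(est$seed, rep(11L, 3))
  expect_true(all(c("pair_correlation", "nsh_pair", "nsh_vc", "bsh",
                    "expected_correlation", "expected_nsh_pair")
                  %in% names(est)))
  # oracle expectations ride along with every estimate row
  expect_equal(est$expected_correlation[1], 0.0625 / 0.215, tolerance = 1e-12)
  expect_error(run_config("nonexistent"), "arg")
  warns <- capture_warnings(
    run_experiment(run_config("additive", n_sib_families = 2,
                              n_half_sib_families = 2,
                              n_cousin_families = 2, seed = 1)))
  expect_true(any(grepl("wide tolerance", warns)))
})

test_that("experiment CSVs are stamped and byte-reproducible under a seed", {
  cfg <- run_config("xor_epistasis", n_sib_families = 200,
                    n_half_sib_families = 200, n_cousin_families = 200,
                    seed = 5)
  dir1 <- tempfile(); dir2 <- tempfile()
  run1 <- run_experiment(cfg, out_dir = dir1)
  run2 <- run_experiment(cfg, out_dir = dir2)
  for (nm in names(run1$paths)) {
    f1 <- run1$paths[[nm]]; f2 <- run2$paths[[nm]]
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
  }
  header <- readLines(run1$paths[["estimates"]], n = 2)
  expect_match(header[1], "^# seed: 5$")
  expect_match(header[2], "^# config: ")
  back <- read_stamped_csv(run1$paths[["pairs_sib"]])
  expect_equal(nrow(back), 200)
  expect_true(all(c("member1_phenotype", "member2_phenotype",
                    "member1_dose_2") %in% names(back)))
  # a different seed must change the data
  run3 <- run_experiment(run_config("xor_epistasis", n_sib_families = 200,
                                    n_half_sib_families = 200,
                                    n_cousin_families = 200, seed = 6),
                         out_dir = tempfile())
  expect_false(identical(readLines(run1$paths[["estimates"]])[-(1:2)],
                         readLines(run3$paths[["estimates"]])[-(1:2)]))
})

test_that("YAML run configs mirror the constructor and allow overrides", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(preset = "combined", n_sib_families = 50,
                        n_half_sib_families = 50, n_cousin_families = 50,
                        seed = 3), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$preset, "combined")
  expect_equal(cfg$n_sib_families, 50L)
  cfg2 <- read_run_config(path, seed = 9, n_sib_families = 60)
  expect_equal(cfg2$seed, 9L)
  expect_equal(cfg2$n_sib_families, 60L)
  yaml::write_yaml(list(preset = "additive", bogus = 1), path)
  expect_error(read_run_config(path), "unknown config keys")
})

test_that("figure data has six panels with scatter tables and triples", {
  panels <- reproduce_figure1(seed = 2, n_families = 200)
  expect_named(panels, c("a", "b", "c", "d", "e", "f"))
  expect_equal(nrow(panels$a), 200)
  expect_true(all(c("member1_phenotype", "member2_phenotype") %in%
                  names(panels$b)))
  for (nm in c("d", "e", "f")) {
    expect_equal(panels[[nm]]$relatedness, c(0.5, 0.25, 0.125))
    expect_equal(nrow(panels[[nm]]), 3)
  }
  out <- tempfile()
  panels2 <- reproduce_figure1(seed = 2, out_dir = out, n_families = 200)
  expect_equal(sort(list.files(out)),
               sort(paste0("figure1_", letters[1:6], ".csv")))
  expect_equal(panels2$d$correlation, panels$d$correlation)
})

test_that("XOR sib phenotypes are multimodal where additive ones are not", {
  # Sarle's bimodality coefficient (skew^2 + 1) / kurtosis: ~1/3 for a normal,
  # 0.555 for a uniform. The XOR marginal is an equal mixture of N(10, 0.3)
  # and N(11, 0.3) with exact kurtosis 1.918, hence coefficient ~0.52; the
  # test threshold 0.45 separates it cleanly from the unimodal additive case.
  bimodality <- function(x) {
    z <- (x - mean(x)) / stats::sd(x)
    (mean(z^3)^2 + 1) / mean(z^4)
  }
  xor_arch <- trait_preset("xor_epistasis")
  fx <- sample_phenotypes(simulate_founders(5000, xor_arch$loci, seed = 8),
                          xor_arch)
  expect_gt(bimodality(fx$phenotype), 0.45)
  add <- trait_preset("additive")
  fa <- sample_phenotypes(simulate_founders(5000, add$loci, seed = 8), add)
  expect_lt(bimodality(fa$phenotype), 0.45)
})

test_that("PED/MAP export is PLINK-shaped with unlinked chromosome codes", {
  arch <- trait_preset("xor_epistasis")
  co <- sample_phenotypes(simulate_sib_pairs(10, arch$loci, seed = 4), arch)
  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  write_ped(co, ped, map)
  ped_rows <- strsplit(readLines(ped), "\t")
  expect_equal(length(ped_rows), 40)  # 20 founders + 20 children
  expect_true(all(lengths(ped_rows) == 6 + 2 * 2))
  alleles <- unlist(lapply(ped_rows, `[`, 7:10))
  expect_true(all(alleles %in% c("A", "G", "T", "C")))
  map_rows <- strsplit(readLines(map), "\t")
  expect_equal(sapply(map_rows, `[`, 1), c("1", "2"))  # distinct chromosomes
  expect_equal(sapply(map_rows, `[`, 2), c("locus_1", "locus_2"))
  # founders have parent codes 0; children point at their parents
  founder_rows <- ped_rows[vapply(ped_rows, function(r) r[3] == "0", TRUE)]
  expect_equal(length(founder_rows), 20)
})

test_that("plot builders return ggplot objects", {
  arch <- trait_preset("additive")
  co <- sample_phenotypes(simulate_sib_pairs(50, arch$loci, seed = 12), arch)
  expect_s3_class(plot_pair_scatter(co), "ggplot")
  expect_s3_class(autoplot(co), "ggplot")
  triples <- tibble::tibble(relatedness = c(0.5, 0.25, 0.125),
                            correlation = c(0.29, 0.15, 0.07),
                            preset = "additive")
  expect_s3_class(plot_correlation_vs_relatedness(triples), "ggplot")
})
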