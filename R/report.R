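# Full-study driver: configuration, seeded experiment runs, figure-data
# reproduction, and CSV / PLINK PED export.

#' Experiment configuration
#'
#' Collects everything a reproducible run needs: the architecture (by preset
#' name or as an object), cohort sizes, residual SD, and the seed. Defaults
#' mirror the study conditions: 2500 families per relationship (5000 founder
#' parents in the sib cohort) and residual SD 0.3.
#'
#' @param preset Preset name passed to [trait_preset()]; ignored when
#'   `architecture` is supplied.
#' @param architecture Optional `trait_architecture` overriding the preset.
#' @param n_sib_families,n_half_sib_families,n_cousin_families Family counts
#'   (>= 2 each).
#' @param residual_sd Residual SD per architecture component.
#' @param seed Integer RNG seed; recorded in every output artifact.
#' @return A `run_config` list.
#' @export
run_config <- function(preset = c("additive", "xor_epistasis", "combined"),
                       architecture = NULL,
                       n_sib_families = 2500, n_half_sib_families = 2500,
                       n_cousin_families = 2500,
                       residual_sd = 0.3, seed = 1L) {
  if (is.null(architecture)) {
    preset <- match.arg(preset)
    architecture <- trait_preset(preset, residual_sd = residual_sd)
  } else {
    stopifnot(inherits(architecture, "trait_architecture"))
    preset <- "custom"
  }
  stopifnot(n_sib_families >= 2, n_half_sib_families >= 2,
            n_cousin_families >= 2, residual_sd >= 0)
  structure(
    list(preset = preset, architecture = architecture,
         n_sib_families = as.integer(n_sib_families),
         n_half_sib_families = as.integer(n_half_sib_families),
         n_cousin_families = as.integer(n_cousin_families),
         residual_sd = residual_sd, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read an experiment configuration from YAML
#'
#' Keys mirror the [run_config()] arguments; an inline `architecture` block
#' uses the [write_architecture()] schema. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @param ... Overrides applied on top of the file's values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  known <- c("preset", "architecture", "n_sib_families", "n_half_sib_families",
             "n_cousin_families", "residual_sd", "seed")
  if (length(setdiff(names(vals), known))) {
    stop("unknown config keys: ",
         paste(setdiff(names(vals), known), collapse = ", "), call. = FALSE)
  }
  if (!is.null(vals$architecture)) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(vals$architecture, tmp)
    vals$architecture <- read_architecture(tmp)
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

config_hash <- function(config) {
  rlang::hash(list(config$preset,
                   lapply(config$architecture$components, unclass),
                   as.list(config$architecture$loci),
                   config$architecture$residual_sd,
                   config$n_sib_families, config$n_half_sib_families,
                   config$n_cousin_families, config$residual_sd, config$seed))
}

# CSV with a provenance header: "# seed: ..." / "# config: <hash>". Floats at
# 6 significant digits.
write_csv_stamped <- function(df, path, seed, hash) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.double),
                                        ~ signif(.x, 6)))
  writeLines(c(sprintf("# seed: %s", seed), sprintf("# config: %s", hash)),
             path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a stamped CSV back
#' @param path File written by the package's exporters.
#' @return A tibble (provenance comment lines skipped).
#' @export
read_stamped_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Run the full heritability experiment
#'
#' Simulates sib, half-sib, and cousin cohorts under the configured
#' architecture, phenotypes everyone, runs the complete analysis
#' ([heritability_report()]) per relationship using the sib cohort's founder
#' parents for the variance-components regression, and tabulates each
#' estimate next to its exact-oracle expectation. Deterministic given the
#' seed.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; if given, writes `estimates.csv` and
#'   one `pairs_<relationship>.csv` per cohort, each stamped with the seed
#'   and a config hash.
#' @param verbose Log progress to stderr.
#' @return A list: `estimates` (tibble, one row per relationship with every
#'   report field plus oracle expectations), `reports`, `cohorts`, `config`,
#'   and `paths` when `out_dir` was given.
#' @export
run_experiment <- function(config = run_config(), out_dir = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  arch <- config$architecture
  set.seed(config$seed)
  say("simulating cohorts under preset '%s' (seed %d)", config$preset,
      config$seed)
  cohorts <- list(
    sib = simulate_sib_pairs(config$n_sib_families, arch$loci),
    half_sib = simulate_half_sib_pairs(config$n_half_sib_families, arch$loci),
    cousin = simulate_cousin_pairs(config$n_cousin_families, arch$loci)
  )
  cohorts <- lapply(cohorts, sample_phenotypes, arch = arch)
  for (nm in names(cohorts)) cohorts[[nm]]$seed <- config$seed
  founders <- cohort_founders(cohorts$sib)
  small <- min(config$n_sib_families, config$n_half_sib_families,
               config$n_cousin_families)
  if (small < 30) {
    warning("cohort sizes below 30 families: estimates carry very wide tolerances",
            call. = FALSE)
  }
  reports <- lapply(cohorts, heritability_report, founders = founders,
                    arch = arch)
  oracle <- expected_estimates(arch)
  estimates <- dplyr::left_join(
    dplyr::bind_rows(lapply(reports, glance)),
    oracle[, c("relationship", "expected_correlation", "expected_nsh_pair",
               "expected_nsh_vc", "expected_bsh")],
    by = "relationship"
  )
  estimates <- dplyr::mutate(estimates, preset = config$preset,
                             .before = 1L)
  for (i in seq_len(nrow(estimates))) {
    say("%s: correlation %.4f (oracle %.4f), NSH %.4f (oracle %.4f)",
        estimates$relationship[i], estimates$pair_correlation[i],
        estimates$expected_correlation[i], estimates$nsh_pair[i],
        estimates$expected_nsh_pair[i])
  }
  out <- list(estimates = estimates, reports = reports, cohorts = cohorts,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hash <- config_hash(config)
    paths <- c(estimates = file.path(out_dir, "estimates.csv"))
    write_csv_stamped(estimates, paths[["estimates"]], config$seed, hash)
    for (nm in names(cohorts)) {
      paths[[paste0("pairs_", nm)]] <- file.path(out_dir,
                                                 paste0("pairs_", nm, ".csv"))
      write_csv_stamped(pair_table(cohorts[[nm]]),
                        paths[[paste0("pairs_", nm)]], config$seed, hash)
    }
    out$paths <- paths
    say("wrote %d files to %s", length(paths), out_dir)
  }
  out
}

#' Reproduce the six-panel figure data
#'
#' Panels a-c are the sib-pair scatter tables for the additive, XOR, and
#' combined architectures; panels d-f are the corresponding (relatedness,
#' correlation) triples from sib, half-sib, and cousin cohorts. Under the
#' additive and combined models the triples fall close to a line through the
#' origin; under the pure XOR model the sib point is positive while the
#' half-sib and cousin correlations are zero in expectation.
#'
#' @param seed Integer seed.
#' @param out_dir Optional directory; if given, writes `figure1_a.csv` ...
#'   `figure1_f.csv`.
#' @param n_families Families per relationship (default 2500).
#' @return A named list of tibbles `a` ... `f` (invisible `paths` attribute
#'   when files were written).
#' @export
reproduce_figure1 <- function(seed = 1L, out_dir = NULL, n_families = 2500) {
  presets <- c(a = "additive", b = "xor_epistasis", c = "combined")
  panels <- list()
  for (i in seq_along(presets)) {
    cfg <- run_config(presets[[i]], n_sib_families = n_families,
                      n_half_sib_families = n_families,
                      n_cousin_families = n_families, seed = seed)
    run <- run_experiment(cfg)
    panels[[names(presets)[i]]] <- pair_table(run$cohorts$sib)
    panels[[c("d", "e", "f")[i]]] <- tibble::tibble(
      preset = presets[[i]],
      relationship = run$estimates$relationship,
      relatedness = run$estimates$expected_relatedness,
      correlation = run$estimates$pair_correlation
    )
  }
  panels <- panels[c("a", "b", "c", "d", "e", "f")]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character()
    for (nm in names(panels)) {
      path <- file.path(out_dir, paste0("figure1_", nm, ".csv"))
      write_csv_stamped(panels[[nm]], path, seed,
                        rlang::hash(list(seed, n_families)))
      paths[nm] <- path
    }
    attr(panels, "paths") <- paths
  }
  panels
}

#' Export genotypes as PLINK PED/MAP text files
#'
#' PED columns: family, individual, father, mother, sex, phenotype (`-9` when
#' missing), then two allele-letter columns per locus. The MAP file places
#' each locus on its own chromosome code (the loci are unlinked) at position
#' equal to its index.
#'
#' @param x A `pair_cohort` or individuals tibble.
#' @param loci Locus table (taken from the cohort when omitted).
#' @param ped_path,map_path Output paths.
#' @return Invisibly, `c(ped_path, map_path)`.
#' @export
write_ped <- function(x, ped_path, map_path, loci = NULL) {
  if (inherits(x, "pair_cohort")) {
    if (is.null(loci)) loci <- x$loci
    x <- x$individuals
  }
  stopifnot(!is.null(loci), nrow(loci) == ncol(x$a1))
  letters1 <- letters2 <- matrix("", nrow(x), nrow(loci))
  for (l in seq_len(nrow(loci))) {
    alleles <- c(loci$ref_allele[l], loci$alt_allele[l])
    letters1[, l] <- alleles[x$a1[, l] + 1L]
    letters2[, l] <- alleles[x$a2[, l] + 1L]
  }
  geno <- matrix("", nrow(x), 2L * nrow(loci))
  geno[, seq(1L, by = 2L, length.out = nrow(loci))] <- letters1
  geno[, seq(2L, by = 2L, length.out = nrow(loci))] <- letters2
  ped <- cbind(x$family_id, x$id, x$father_id, x$mother_id, x$sex,
               ifelse(is.na(x$phenotype), "-9", sprintf("%.6g", x$phenotype)),
               geno)
  utils::write.table(ped, ped_path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  map <- cbind(seq_len(nrow(loci)), paste0("locus_", seq_len(nrow(loci))),
               0L, seq_len(nrow(loci)))
  utils::write.table(map, map_path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(c(ped_path, map_path))
}
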