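# Pedigree simulation: HWE founders, Mendelian transmission, sib / half-sib /
# cousin pair cohorts, and phenotype sampling under a trait architecture.
#
# Individuals are rows of a tibble with matrix columns `a1`/`a2` (0 = reference
# allele, 1 = alternate; one column per locus; a1 = maternally inherited copy
# for non-founders) and `t1`/`t2` (founder-allele tags used to track identity
# by descent). Keeping alleles as ordered pairs, not doses, is what makes
# Mendelian transmission well-defined.

new_individuals <- function(id, family_id, father_id, mother_id, sex, role,
                            a1, a2, t1, t2, phenotype = NA_real_) {
  n <- length(id)
  tibble::tibble(
    id = as.integer(id),
    family_id = as.integer(rep_len(family_id, n)),
    father_id = as.integer(rep_len(father_id, n)),
    mother_id = as.integer(rep_len(mother_id, n)),
    sex = as.integer(rep_len(sex, n)),
    role = rep_len(role, n),
    phenotype = rep_len(phenotype, n),
    a1 = a1, a2 = a2, t1 = t1, t2 = t2
  )
}

#' Simulate unrelated founder individuals under Hardy-Weinberg equilibrium
#'
#' Each founder's two alleles at each locus are drawn independently with
#' alternate-allele probability `alt_freq`, which induces HWE genotype
#' frequencies; at frequency 0.5 these are 0.25 / 0.5 / 0.25. Every founder
#' allele receives a unique identity-by-descent tag so that allele sharing can
#' be traced through any pedigree built on top.
#'
#' @param n Number of founders (>= 1).
#' @param loci Locus table ([locus_spec()] rows).
#' @param seed Optional integer; if given, `set.seed()` is called first.
#' @param family_id,sex,id_start Bookkeeping for pedigree assembly: family
#'   labels, PED sex codes (1 male / 2 female), and the first individual id.
#' @return An individuals tibble (see package overview) with `role =
#'   "founder"` and phenotypes unset.
#' @export
simulate_founders <- function(n, loci, seed = NULL, family_id = seq_len(n),
                              sex = rep_len(c(1L, 2L), n), id_start = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a count >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  L <- nrow(loci)
  a1 <- matrix(0L, n, L)
  a2 <- matrix(0L, n, L)
  for (l in seq_len(L)) {
    a1[, l] <- stats::rbinom(n, 1L, loci$alt_freq[l])
    a2[, l] <- stats::rbinom(n, 1L, loci$alt_freq[l])
  }
  ids <- seq.int(from = id_start, length.out = n)
  t1 <- matrix(rep(2L * ids - 1L, L), n, L)
  t2 <- matrix(rep(2L * ids, L), n, L)
  new_individuals(ids, family_id, 0L, 0L, sex, "founder", a1, a2, t1, t2)
}

# One gamete per individual: at each locus pick one of the two alleles with
# probability 0.5, carrying its IBD tag along. Independent across loci
# (unlinked) and across calls.
gametes <- function(ind) {
  a1 <- ind$a1
  pick_first <- matrix(stats::runif(length(a1)) < 0.5, nrow(a1))
  list(a = ifelse(pick_first, a1, ind$a2),
       t = ifelse(pick_first, ind$t1, ind$t2))
}

#' Transmit one parental allele at one locus
#'
#' Draws one of the parent's two alleles at `locus_index`, each with
#' probability 0.5 — a single meiosis at a single locus.
#'
#' @param parent A one-row individuals tibble.
#' @param locus_index Locus column to transmit.
#' @return The transmitted allele as 0 (reference) or 1 (alternate).
#' @export
transmit <- function(parent, locus_index) {
  stopifnot(nrow(parent) == 1L, locus_index >= 1L,
            locus_index <= ncol(parent$a1))
  if (stats::runif(1) < 0.5) parent$a1[1L, locus_index] else parent$a2[1L, locus_index]
}

# Vectorised child generation: row i of the result is the child of mothers[i]
# x fathers[i]. Child a1/t1 = maternal gamete, a2/t2 = paternal gamete.
make_children <- function(mothers, fathers, ids, family_id, sex, role = "child") {
  stopifnot(nrow(mothers) == nrow(fathers),
            ncol(mothers$a1) == ncol(fathers$a1))
  gm <- gametes(mothers)
  gf <- gametes(fathers)
  new_individuals(ids, family_id, fathers$id, mothers$id, sex, role,
                  a1 = gm$a, a2 = gf$a, t1 = gm$t, t2 = gf$t)
}

#' Simulate one child of two parents
#'
#' The child receives one independently transmitted allele from each parent at
#' every locus ([transmit()] semantics, vectorised over loci).
#'
#' @param mother,father One-row individuals tibbles genotyped at the same loci.
#' @param id,family_id,sex Bookkeeping for the child row.
#' @return A one-row individuals tibble.
#' @export
make_child <- function(mother, father, id = mother$id * 1000L,
                       family_id = mother$family_id, sex = 1L) {
  stopifnot(nrow(mother) == 1L, nrow(father) == 1L)
  if (ncol(mother$a1) != ncol(father$a1)) {
    stop("parents are genotyped at different loci", call. = FALSE)
  }
  make_children(mother, father, id, family_id, sex)
}

relatedness_of <- c(sib = 0.5, half_sib = 0.25, cousin = 0.125)

new_pair_cohort <- function(relationship, individuals, pairs, loci, seed) {
  structure(
    list(relationship = relationship,
         expected_relatedness = relatedness_of[[relationship]],
         individuals = individuals, pairs = pairs, loci = loci,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "pair_cohort"
  )
}

#' @export
print.pair_cohort <- function(x, ...) {
  cat(sprintf("<pair_cohort: %d %s pairs (r = %g), %d individuals, %d locus/loci, seed = %s>\n",
              nrow(x$pairs), x$relationship, x$expected_relatedness,
              nrow(x$individuals), nrow(x$loci),
              ifelse(is.na(x$seed), "unset", x$seed)))
  invisible(x)
}

check_n_families <- function(n_families) {
  if (!is.numeric(n_families) || length(n_families) != 1L || n_families < 2) {
    stop("`n_families` must be a count >= 2", call. = FALSE)
  }
  as.integer(n_families)
}

#' Simulate a cohort of full-sibling pairs
#'
#' Each family is a fresh founder couple drawn under HWE; the couple's two
#' children (one Mendelian transmission from each parent per locus) form one
#' sib pair. Expected relatedness 0.5. The two children are generated
#' exchangeably, so the member-1/member-2 axis assignment is uniform.
#'
#' @param n_families Number of families (one pair each), >= 2.
#' @param loci Locus table.
#' @param seed Optional integer seed.
#' @return A `pair_cohort` with `2 * n_families` founders and one pair per
#'   family. Phenotypes are unset until [sample_phenotypes()].
#' @export
simulate_sib_pairs <- function(n_families, loci, seed = NULL) {
  n <- check_n_families(n_families)
  if (!is.null(seed)) set.seed(seed)
  fam <- seq_len(n)
  mothers <- simulate_founders(n, loci, family_id = fam, sex = 2L, id_start = 1L)
  fathers <- simulate_founders(n, loci, family_id = fam, sex = 1L, id_start = n + 1L)
  c1 <- make_children(mothers, fathers, ids = 2L * n + fam, family_id = fam, sex = 1L)
  c2 <- make_children(mothers, fathers, ids = 3L * n + fam, family_id = fam, sex = 2L)
  new_pair_cohort("sib", rbind(mothers, fathers, c1, c2),
                  tibble::tibble(family_id = fam, id1 = c1$id, id2 = c2$id),
                  loci, seed)
}

#' Simulate a cohort of half-sibling pairs
#'
#' Each family has one shared mother and two unrelated fathers; one child per
#' father. The children share the maternal genome only: expected relatedness
#' 0.25.
#'
#' @inheritParams simulate_sib_pairs
#' @return A `pair_cohort` with three founders and one pair per family.
#' @export
simulate_half_sib_pairs <- function(n_families, loci, seed = NULL) {
  n <- check_n_families(n_families)
  if (!is.null(seed)) set.seed(seed)
  fam <- seq_len(n)
  mothers  <- simulate_founders(n, loci, family_id = fam, sex = 2L, id_start = 1L)
  fathers1 <- simulate_founders(n, loci, family_id = fam, sex = 1L, id_start = n + 1L)
  fathers2 <- simulate_founders(n, loci, family_id = fam, sex = 1L, id_start = 2L * n + 1L)
  c1 <- make_children(mothers, fathers1, ids = 3L * n + fam, family_id = fam, sex = 1L)
  c2 <- make_children(mothers, fathers2, ids = 4L * n + fam, family_id = fam, sex = 2L)
  new_pair_cohort("half_sib", rbind(mothers, fathers1, fathers2, c1, c2),
                  tibble::tibble(family_id = fam, id1 = c1$id, id2 = c2$id),
                  loci, seed)
}

#' Simulate a cohort of first-cousin pairs
#'
#' Each family starts from one founder grandparental couple whose two
#' daughters each marry an unrelated founder; one child per couple. The two
#' grandchildren share one pair of grandparents: expected relatedness 0.125.
#'
#' @inheritParams simulate_sib_pairs
#' @return A `pair_cohort`; the intermediate sib generation carries
#'   `role = "parent"`.
#' @export
simulate_cousin_pairs <- function(n_families, loci, seed = NULL) {
  n <- check_n_families(n_families)
  if (!is.null(seed)) set.seed(seed)
  fam <- seq_len(n)
  grandma <- simulate_founders(n, loci, family_id = fam, sex = 2L, id_start = 1L)
  grandpa <- simulate_founders(n, loci, family_id = fam, sex = 1L, id_start = n + 1L)
  sib1 <- make_children(grandma, grandpa, ids = 2L * n + fam, family_id = fam,
                        sex = 2L, role = "parent")
  sib2 <- make_children(grandma, grandpa, ids = 3L * n + fam, family_id = fam,
                        sex = 2L, role = "parent")
  spouse1 <- simulate_founders(n, loci, family_id = fam, sex = 1L, id_start = 4L * n + 1L)
  spouse2 <- simulate_founders(n, loci, family_id = fam, sex = 1L, id_start = 5L * n + 1L)
  c1 <- make_children(sib1, spouse1, ids = 6L * n + fam, family_id = fam, sex = 1L)
  c2 <- make_children(sib2, spouse2, ids = 7L * n + fam, family_id = fam, sex = 2L)
  new_pair_cohort(
    "cousin", rbind(grandma, grandpa, sib1, sib2, spouse1, spouse2, c1, c2),
    tibble::tibble(family_id = fam, id1 = c1$id, id2 = c2$id),
    loci, seed)
}

#' Allele-dose matrix of an individuals table or cohort
#'
#' @param x An individuals tibble or `pair_cohort`.
#' @return Integer matrix (individuals x loci) of alternate-allele counts,
#'   columns named `dose_1 ... dose_L`.
#' @export
dose_matrix <- function(x) {
  if (inherits(x, "pair_cohort")) x <- x$individuals
  d <- x$a1 + x$a2
  colnames(d) <- paste0("dose_", seq_len(ncol(d)))
  d
}

#' Draw phenotypes under a trait architecture
#'
#' Each individual's phenotype is the sum, over architecture components, of
#' the component's genotypic mean plus an independent Normal(0, `residual_sd`)
#' residual. Residuals are independent across individuals and components, so a
#' composed (e.g. additive + XOR) trait is the sum of two independently noised
#' component traits.
#'
#' @param x A `pair_cohort` (all members and founders are phenotyped) or an
#'   individuals tibble.
#' @param arch A `trait_architecture`; individuals must be genotyped at
#'   exactly its loci.
#' @param seed Optional integer seed.
#' @return `x` with the `phenotype` column filled.
#' @export
sample_phenotypes <- function(x, arch, seed = NULL) {
  stopifnot(inherits(arch, "trait_architecture"))
  if (!is.null(seed)) set.seed(seed)
  ind <- if (inherits(x, "pair_cohort")) x$individuals else x
  if (ncol(ind$a1) != n_loci(arch)) {
    stop("individuals are not genotyped at the architecture's loci", call. = FALSE)
  }
  d <- ind$a1 + ind$a2
  n <- nrow(ind)
  phen <- numeric(n)
  for (comp in arch$components) {
    phen <- phen + component_values(comp, d) +
      stats::rnorm(n, 0, arch$residual_sd)
  }
  ind$phenotype <- phen
  if (inherits(x, "pair_cohort")) {
    x$individuals <- ind
    x
  } else {
    ind
  }
}

#' Founders of a cohort
#'
#' @param cohort A `pair_cohort`.
#' @return The individuals tibble restricted to `role == "founder"` — for sib
#'   cohorts these are the unrelated parents used for the variance-components
#'   analysis.
#' @export
cohort_founders <- function(cohort) {
  stopifnot(inherits(cohort, "pair_cohort"))
  dplyr::filter(cohort$individuals, .data$role == "founder")
}

#' Tidy per-pair table of a cohort
#'
#' One row per relative pair with both members' phenotypes and per-locus
#' allele doses — the data behind a pair scatterplot.
#'
#' @param cohort A `pair_cohort`.
#' @return A tibble with columns `family_id`, `relationship`,
#'   `member1_phenotype`, `member2_phenotype`, and `member{1,2}_dose_{l}` per
#'   locus.
#' @export
pair_table <- function(cohort) {
  stopifnot(inherits(cohort, "pair_cohort"))
  ind <- cohort$individuals
  i1 <- match(cohort$pairs$id1, ind$id)
  i2 <- match(cohort$pairs$id2, ind$id)
  d <- ind$a1 + ind$a2
  out <- tibble::tibble(
    family_id = cohort$pairs$family_id,
    relationship = cohort$relationship,
    member1_phenotype = ind$phenotype[i1],
    member2_phenotype = ind$phenotype[i2]
  )
  for (l in seq_len(ncol(d))) {
    out[[paste0("member1_dose_", l)]] <- d[i1, l]
    out[[paste0("member2_dose_", l)]] <- d[i2, l]
  }
  out
}

#' Realised identity-by-descent sharing within pairs
#'
#' Uses the founder-allele tags carried through transmission to compute, for
#' each pair, the fraction of alleles shared identical by descent (averaged
#' over loci). Its expectation is the relationship's relatedness coefficient:
#' 0.5 for sibs, 0.25 for half-sibs, 0.125 for cousins.
#'
#' @param cohort A `pair_cohort`.
#' @return A tibble with `family_id` and `ibd_sharing` per pair.
#' @export
ibd_sharing <- function(cohort) {
  stopifnot(inherits(cohort, "pair_cohort"))
  ind <- cohort$individuals
  i1 <- match(cohort$pairs$id1, ind$id)
  i2 <- match(cohort$pairs$id2, ind$id)
  x1 <- ind$t1[i1, , drop = FALSE]; x2 <- ind$t2[i1, , drop = FALSE]
  y1 <- ind$t1[i2, , drop = FALSE]; y2 <- ind$t2[i2, , drop = FALSE]
  # no inbreeding in the supported pedigrees, so tags within an individual are
  # distinct and shared-allele count = |{x1,x2} intersect {y1,y2}|
  shared <- (x1 == y1 | x1 == y2) + (x2 == y1 | x2 == y2)
  tibble::tibble(family_id = cohort$pairs$family_id,
                 ibd_sharing = rowMeans(shared / 2))
}
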