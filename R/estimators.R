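# Heritability estimation: relative-pair correlations, genotype-coded
# variance components, narrow- and broad-sense heritability.

#' Pearson correlation and regression slope of a pair cohort
#'
#' Computes the Pearson correlation between member-1 and member-2 phenotypes
#' and the slope of the member-2-on-member-1 least-squares line (for pairs of
#' exchangeable relatives the two coincide in expectation).
#'
#' @param pairs A `pair_cohort` with phenotypes, or a data frame with columns
#'   `member1_phenotype` and `member2_phenotype`.
#' @return A one-row tibble: `n_pairs`, `correlation`, `slope`.
#' @export
pair_correlation <- function(pairs) {
  if (inherits(pairs, "pair_cohort")) pairs <- pair_table(pairs)
  x <- pairs$member1_phenotype
  y <- pairs$member2_phenotype
  if (anyNA(x) || anyNA(y)) {
    stop("pair phenotypes contain missing values; run sample_phenotypes() first",
         call. = FALSE)
  }
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (n < 30L) {
    warning("fewer than 30 pairs: correlation estimate has very wide tolerance",
            call. = FALSE)
  }
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    stop("degenerate cohort: zero phenotype variance in a member column",
         call. = FALSE)
  }
  r <- stats::cor(x, y)
  tibble::tibble(n_pairs = n, correlation = r, slope = r * sy / sx)
}

#' Narrow-sense heritability from a relative-pair correlation
#'
#' Scales a relative-pair phenotype correlation by the inverse of the pair's
#' expected relatedness: twice the sib correlation, four times the half-sib
#' correlation, eight times the cousin correlation. The estimator is
#' unbounded; values outside \[0, 1\] are returned as-is with a warning, since
#' correlation-vs-relatedness linearity plots need the raw values.
#'
#' @param correlation Pair phenotype correlation(s).
#' @param expected_relatedness Relatedness coefficient(s) in (0, 1\]: 0.5 sib,
#'   0.25 half-sib, 0.125 cousin.
#' @return Numeric NSH estimate(s): `correlation / expected_relatedness`.
#' @export
nsh_from_correlation <- function(correlation, expected_relatedness) {
  if (any(expected_relatedness <= 0 | expected_relatedness > 1)) {
    stop("`expected_relatedness` must lie in (0, 1]", call. = FALSE)
  }
  est <- correlation / expected_relatedness
  if (any(est < 0 | est > 1)) {
    warning("NSH estimate outside [0, 1]; reported unclipped", call. = FALSE)
  }
  est
}

#' Additive variance components from dose-coded regression
#'
#' Ordinary least squares of the phenotype on all 0/1/2 allele-dose columns
#' jointly. The per-locus additive variance component is `slope^2 *
#' var(dose)` (the variance of that locus's fitted contribution; valid as a
#' sum because unlinked loci are independent). Sample variances use the n-1
#' convention.
#'
#' @param phenotypes Numeric phenotype vector.
#' @param doses Matrix or data frame of dose codings, one column per locus.
#' @return A tibble with one row per locus: `locus`, `slope`,
#'   `dose_variance`, `vc`. The total additive component is `sum(vc)`.
#' @export
additive_vc <- function(phenotypes, doses) {
  doses <- as.matrix(doses)
  stopifnot(length(phenotypes) == nrow(doses))
  if (length(phenotypes) <= ncol(doses) + 1L) {
    stop("sample size must exceed number of loci + 1", call. = FALSE)
  }
  fit <- stats::lm(phenotypes ~ doses)
  slopes <- stats::coef(fit)[-1L]
  if (anyNA(slopes)) {
    stop("collinear dose codings: additive components not identifiable",
         call. = FALSE)
  }
  v <- apply(doses, 2L, stats::var)
  tibble::tibble(
    locus = seq_len(ncol(doses)),
    slope = unname(slopes),
    dose_variance = unname(v),
    vc = unname(slopes^2 * v)
  )
}

#' Epistatic variance component from a mean-class indicator
#'
#' Least squares of the phenotype on a 0/1 indicator of the two-locus mean
#' class (0 = low-mean genotype combinations, 1 = high-mean). The component is
#' `slope^2 * var(indicator)`.
#'
#' @param phenotypes Numeric phenotype vector.
#' @param indicator Binary 0/1 vector, non-constant.
#' @return A one-row tibble: `slope`, `indicator_variance`, `vc`.
#' @export
epistasis_vc <- function(phenotypes, indicator) {
  stopifnot(length(phenotypes) == length(indicator))
  if (!all(indicator %in% c(0, 1))) {
    stop("`indicator` must be coded 0/1", call. = FALSE)
  }
  v <- stats::var(indicator)
  if (v == 0) stop("constant indicator: epistatic component not identifiable",
                   call. = FALSE)
  slope <- stats::cov(phenotypes, indicator) / v
  tibble::tibble(slope = slope, indicator_variance = v, vc = slope^2 * v)
}

#' Mean-class indicator of an XOR component
#'
#' Codes each multilocus genotype 0 if the XOR component assigns it the low
#' mean (exactly one interacting locus heterozygous) and 1 if the high mean —
#' the coding under which a single regression captures the full epistatic
#' variance.
#'
#' @param component A `trait_component` of kind `"xor"`.
#' @param doses Dose matrix over the architecture's loci.
#' @return Integer 0/1 vector.
#' @export
mean_class_indicator <- function(component, doses) {
  if (!inherits(component, "trait_component") || component$kind != "xor") {
    stop("`component` must be an xor trait_component", call. = FALSE)
  }
  d1 <- doses[, component$loci[1]]
  d2 <- doses[, component$loci[2]]
  as.integer(!xor(d1 == 1L, d2 == 1L))
}

#' Broad-sense heritability
#'
#' Ratio of total genetic variance (additive + epistatic components) to total
#' phenotypic variance, clipped to \[0, 1\] with a warning if clipping occurs.
#'
#' @param genetic_vc_total Total genetic variance component.
#' @param total_variance Total phenotypic variance (> 0).
#' @return BSH estimate in \[0, 1\].
#' @export
bsh <- function(genetic_vc_total, total_variance) {
  if (any(total_variance <= 0)) {
    stop("`total_variance` must be positive", call. = FALSE)
  }
  ratio <- genetic_vc_total / total_variance
  if (any(ratio < 0 | ratio > 1)) {
    warning("heritability ratio clipped to [0, 1]", call. = FALSE)
  }
  pmin(1, pmax(0, ratio))
}

#' Full heritability analysis of a cohort
#'
#' Bundles the complete analysis sequence: pair correlation and regression
#' slope, pair-based NSH (correlation / relatedness), variance components in
#' the unrelated founders (additive from joint dose regression over all loci,
#' epistatic from the mean-class indicator of each XOR component), total
#' phenotypic variance, VC-based NSH, and BSH.
#'
#' @param cohort A phenotyped `pair_cohort`.
#' @param founders Phenotyped unrelated individuals (typically the sib
#'   cohort's parents, via [cohort_founders()]) used for the
#'   variance-components analysis.
#' @param arch The `trait_architecture` both were simulated under; supplies
#'   the codings.
#' @return A `heritability_report` object; see [tidy.heritability_report()]
#'   and [glance.heritability_report()].
#' @export
heritability_report <- function(cohort, founders, arch) {
  stopifnot(inherits(cohort, "pair_cohort"),
            inherits(arch, "trait_architecture"))
  if (anyNA(founders$phenotype)) {
    stop("founders must be phenotyped", call. = FALSE)
  }
  pc <- pair_correlation(cohort)
  nsh_pair <- suppressWarnings(
    nsh_from_correlation(pc$correlation, cohort$expected_relatedness)
  )
  fd <- dose_matrix(founders)
  fp <- founders$phenotype
  avc <- additive_vc(fp, fd)
  additive_total <- sum(avc$vc)
  xor_comps <- Filter(function(comp) comp$kind == "xor", arch$components)
  epistatic_total <- sum(vapply(
    xor_comps,
    function(comp) epistasis_vc(fp, mean_class_indicator(comp, fd))$vc,
    numeric(1)
  ))
  total_variance <- stats::var(fp)
  structure(
    list(
      relationship = cohort$relationship,
      expected_relatedness = cohort$expected_relatedness,
      n_pairs = pc$n_pairs,
      n_founders = length(fp),
      pair_correlation = pc$correlation,
      regression_slope = pc$slope,
      nsh_pair = nsh_pair,
      additive_vc = additive_total,
      additive_vc_by_locus = avc,
      epistatic_vc = epistatic_total,
      total_variance = total_variance,
      nsh_vc = suppressWarnings(bsh(additive_total, total_variance)),
      bsh = suppressWarnings(bsh(additive_total + epistatic_total,
                                 total_variance)),
      seed = cohort$seed
    ),
    class = "heritability_report"
  )
}

#' @export
print.heritability_report <- function(x, ...) {
  cat(sprintf("<heritability_report: %d %s pairs>\n", x$n_pairs, x$relationship))
  cat(sprintf("  pair correlation %.4f (slope %.4f) -> NSH %.4f (x%g)\n",
              x$pair_correlation, x$regression_slope, x$nsh_pair,
              1 / x$expected_relatedness))
  cat(sprintf("  variance components (n = %d founders): additive %.4f, epistatic %.4f, total %.4f\n",
              x$n_founders, x$additive_vc, x$epistatic_vc, x$total_variance))
  cat(sprintf("  VC-based NSH %.4f, BSH %.4f\n", x$nsh_vc, x$bsh))
  invisible(x)
}

#' Tidy a heritability report
#'
#' @param x A `heritability_report`.
#' @param ... Unused.
#' @return One row per estimated quantity with columns `term`, `estimate`.
#' @method tidy heritability_report
#' @export
tidy.heritability_report <- function(x, ...) {
  tibble::tibble(
    term = c("pair_correlation", "regression_slope", "nsh_pair",
             "additive_vc", "epistatic_vc", "total_variance", "nsh_vc", "bsh"),
    estimate = c(x$pair_correlation, x$regression_slope, x$nsh_pair,
                 x$additive_vc, x$epistatic_vc, x$total_variance,
                 x$nsh_vc, x$bsh)
  )
}

#' Glance at a heritability report
#'
#' @param x A `heritability_report`.
#' @param ... Unused.
#' @return A one-row wide tibble with all report fields.
#' @method glance heritability_report
#' @export
glance.heritability_report <- function(x, ...) {
  tibble::tibble(
    relationship = x$relationship,
    expected_relatedness = x$expected_relatedness,
    n_pairs = x$n_pairs,
    n_founders = x$n_founders,
    pair_correlation = x$pair_correlation,
    regression_slope = x$regression_slope,
    nsh_pair = x$nsh_pair,
    additive_vc = x$additive_vc,
    epistatic_vc = x$epistatic_vc,
    total_variance = x$total_variance,
    nsh_vc = x$nsh_vc,
    bsh = x$bsh,
    seed = x$seed
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
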