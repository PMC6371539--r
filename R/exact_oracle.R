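# Exact enumeration oracle: population moments and relative-pair covariances
# for any trait architecture, computed by brute force over founder alleles and
# Mendelian transmission outcomes. Ground truth for every stochastic estimate.

#' Exact joint genotype distribution of a relative pair at one locus
#'
#' Enumerates every founder-allele configuration and every meiosis outcome of
#' the pedigree that generates the relationship, and accumulates the joint
#' probability of the two members' allele doses. Relationships: `sib` (two
#' children of one couple), `half_sib` (shared mother, two fathers), `cousin`
#' (one grandparental couple, two sib parents married to unrelated founders),
#' plus the degenerate checks `mz` (a pair sharing the full genotype) and
#' `unrelated` (independent HWE draws).
#'
#' @param relationship One of `"sib"`, `"half_sib"`, `"cousin"`, `"mz"`,
#'   `"unrelated"`.
#' @param alt_freq Alternate-allele frequency at the locus.
#' @return A 3 x 3 matrix `J` with `J[i, j] = P(dose_A = i - 1, dose_B = j -
#'   1)`; entries sum to 1 and both margins are the HWE distribution.
#' @export
pair_dose_joint <- function(relationship, alt_freq = 0.5) {
  p <- alt_freq
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  hw <- unname(hwe_probs(p))
  if (relationship == "mz") return(diag(hw))
  if (relationship == "unrelated") return(outer(hw, hw))
  ap <- function(a) ifelse(a == 1L, p, 1 - p)
  pick <- function(choice, first, second) ifelse(choice == 1L, first, second)
  if (relationship == "sib") {
    g <- expand.grid(m1 = 0:1, m2 = 0:1, f1 = 0:1, f2 = 0:1,
                     c1m = 1:2, c1f = 1:2, c2m = 1:2, c2f = 1:2)
    w <- ap(g$m1) * ap(g$m2) * ap(g$f1) * ap(g$f2) * 0.5^4
    dA <- pick(g$c1m, g$m1, g$m2) + pick(g$c1f, g$f1, g$f2)
    dB <- pick(g$c2m, g$m1, g$m2) + pick(g$c2f, g$f1, g$f2)
  } else if (relationship == "half_sib") {
    g <- expand.grid(m1 = 0:1, m2 = 0:1, fa1 = 0:1, fa2 = 0:1,
                     fb1 = 0:1, fb2 = 0:1,
                     c1m = 1:2, c1f = 1:2, c2m = 1:2, c2f = 1:2)
    w <- ap(g$m1) * ap(g$m2) * ap(g$fa1) * ap(g$fa2) * ap(g$fb1) * ap(g$fb2) *
      0.5^4
    dA <- pick(g$c1m, g$m1, g$m2) + pick(g$c1f, g$fa1, g$fa2)
    dB <- pick(g$c2m, g$m1, g$m2) + pick(g$c2f, g$fb1, g$fb2)
  } else if (relationship == "cousin") {
    g <- expand.grid(gm1 = 0:1, gm2 = 0:1, gf1 = 0:1, gf2 = 0:1,
                     p1a = 0:1, p1b = 0:1, p2a = 0:1, p2b = 0:1,
                     s1m = 1:2, s1f = 1:2, s2m = 1:2, s2f = 1:2,
                     c1s = 1:2, c1p = 1:2, c2s = 1:2, c2p = 1:2)
    w <- ap(g$gm1) * ap(g$gm2) * ap(g$gf1) * ap(g$gf2) *
      ap(g$p1a) * ap(g$p1b) * ap(g$p2a) * ap(g$p2b) * 0.5^8
    s1a <- pick(g$s1m, g$gm1, g$gm2); s1b <- pick(g$s1f, g$gf1, g$gf2)
    s2a <- pick(g$s2m, g$gm1, g$gm2); s2b <- pick(g$s2f, g$gf1, g$gf2)
    dA <- pick(g$c1s, s1a, s1b) + pick(g$c1p, g$p1a, g$p1b)
    dB <- pick(g$c2s, s2a, s2b) + pick(g$c2p, g$p2a, g$p2b)
  } else {
    stop("unsupported relationship: ", relationship, call. = FALSE)
  }
  J <- matrix(0, 3L, 3L)
  for (i in 0:2) for (j in 0:2) J[i + 1L, j + 1L] <- sum(w[dA == i & dB == j])
  J
}

# Exact covariance of one component's values between the two members of a
# pair, enumerating the joint genotype distribution over the component's loci
# (factorised across loci, which are unlinked and transmitted independently).
component_pair_cov <- function(component, loci, relationship) {
  idx <- component$loci
  k <- length(idx)
  Js <- lapply(loci$alt_freq[idx], function(p) pair_dose_joint(relationship, p))
  grid <- as.matrix(do.call(expand.grid, rep(list(0:2), 2L * k)))
  dA <- grid[, seq_len(k), drop = FALSE]
  dB <- grid[, k + seq_len(k), drop = FALSE]
  w <- rep(1, nrow(grid))
  for (j in seq_len(k)) {
    w <- w * Js[[j]][cbind(dA[, j] + 1L, dB[, j] + 1L)]
  }
  local <- component
  local$loci <- seq_len(k)
  mA <- component_values(local, dA)
  mB <- component_values(local, dB)
  sum(w * mA * mB) - sum(w * mA) * sum(w * mB)
}

# Independent closed-form route for the XOR component, combining per-locus
# joint moments: with het indicators h1, h2 at the two loci, the
# exactly-one-het indicator is X = h1 + h2 - 2 h1 h2 and
# Cov(value_A, value_B) = (high - low)^2 * Cov(X_A, X_B), where the cross
# moments factorise across unlinked loci.
xor_cov_moments <- function(component, loci, relationship) {
  stopifnot(component$kind == "xor")
  Js <- lapply(loci$alt_freq[component$loci],
               function(p) pair_dose_joint(relationship, p))
  m <- vapply(loci$alt_freq[component$loci], function(p) hwe_probs(p)[2], 0)
  e <- vapply(Js, function(J) J[2L, 2L], 0)  # P(both members het)
  exx <- e[1] + e[2] + 2 * m[1] * m[2] - 4 * e[1] * m[2] - 4 * m[1] * e[2] +
    4 * e[1] * e[2]
  ex <- m[1] + m[2] - 2 * m[1] * m[2]
  (component$high_mean - component$low_mean)^2 * (exx - ex^2)
}

# Non-factorised cross-check: full joint enumeration over both loci of a
# two-locus architecture for sib pairs (founder alleles and meioses at both
# loci enumerated simultaneously; 2^16 states).
sib_two_locus_cov <- function(arch) {
  stopifnot(n_loci(arch) == 2L)
  p <- arch$loci$alt_freq
  ap <- function(a, pp) ifelse(a == 1L, pp, 1 - pp)
  pick <- function(choice, first, second) ifelse(choice == 1L, first, second)
  g <- expand.grid(m11 = 0:1, m12 = 0:1, f11 = 0:1, f12 = 0:1,
                   m21 = 0:1, m22 = 0:1, f21 = 0:1, f22 = 0:1,
                   c1m1 = 1:2, c1f1 = 1:2, c1m2 = 1:2, c1f2 = 1:2,
                   c2m1 = 1:2, c2f1 = 1:2, c2m2 = 1:2, c2f2 = 1:2)
  w <- ap(g$m11, p[1]) * ap(g$m12, p[1]) * ap(g$f11, p[1]) * ap(g$f12, p[1]) *
    ap(g$m21, p[2]) * ap(g$m22, p[2]) * ap(g$f21, p[2]) * ap(g$f22, p[2]) *
    0.5^8
  dA <- cbind(pick(g$c1m1, g$m11, g$m12) + pick(g$c1f1, g$f11, g$f12),
              pick(g$c1m2, g$m21, g$m22) + pick(g$c1f2, g$f21, g$f22))
  dB <- cbind(pick(g$c2m1, g$m11, g$m12) + pick(g$c2f1, g$f11, g$f12),
              pick(g$c2m2, g$m21, g$m22) + pick(g$c2f2, g$f21, g$f22))
  mA <- architecture_mean(arch, dA)
  mB <- architecture_mean(arch, dB)
  sum(w * mA * mB) - sum(w * mA) * sum(w * mB)
}

#' Exact population moments of a trait architecture
#'
#' Computes, by enumeration of the genotype-to-mean table under the HWE
#' measure: the population mean; the genetic variance (variance of the
#' genotypic means); the additive variance (variance of the least-squares
#' projection of the mean function onto \{1, dose_1, ..., dose_L\}); the
#' epistatic (non-additive) remainder; the residual variance
#' (`components x residual_sd^2`); and the total variance.
#'
#' @param arch A `trait_architecture`.
#' @return An `exact_moments` object (a named list) with fields
#'   `population_mean`, `genetic_variance`, `additive_variance`,
#'   `epistatic_variance`, `residual_variance`, `total_variance`.
#' @export
exact_trait_moments <- function(arch) {
  stopifnot(inherits(arch, "trait_architecture"))
  mt <- mean_table(arch)
  mu <- sum(mt$prob * mt$mean)
  gvar <- sum(mt$prob * mt$mean^2) - mu^2
  L <- n_loci(arch)
  if (L == 0L || gvar < .Machine$double.eps) {
    avar <- 0
  } else {
    X <- as.matrix(mt[, paste0("dose_", seq_len(L))])
    fit <- stats::lm.wfit(cbind(1, X), mt$mean, w = mt$prob)
    fitted_means <- cbind(1, X) %*% ifelse(is.na(fit$coefficients), 0,
                                           fit$coefficients)
    avar <- sum(mt$prob * (fitted_means - mu)^2)
  }
  resid_var <- length(arch$components) * arch$residual_sd^2
  structure(
    list(population_mean = mu,
         genetic_variance = gvar,
         additive_variance = avar,
         epistatic_variance = max(0, gvar - avar),
         residual_variance = resid_var,
         total_variance = gvar + resid_var),
    class = "exact_moments"
  )
}

#' @export
print.exact_moments <- function(x, ...) {
  cat("<exact_moments>\n")
  for (f in names(x)) cat(sprintf("  %-18s %.6f\n", f, x[[f]]))
  invisible(x)
}

#' Exact genetic covariance between relative-pair members
#'
#' The exact covariance of the two members' genetic values (sum of component
#' means), computed by enumerating founder genotypes and Mendelian
#' transmission outcomes. Because components act on disjoint unlinked loci,
#' the covariance is the sum of per-component covariances, each enumerated
#' over the joint pair-genotype distribution of its own loci (the
#' `"factorized"` method). For sib pairs over a two-locus architecture,
#' `method = "joint"` instead enumerates all founder alleles and meioses at
#' both loci simultaneously without any factorisation — an independent route
#' used as a consistency check.
#'
#' Residuals are independent across individuals, so the phenotype covariance
#' equals this genetic covariance, and the expected phenotype correlation is
#' covariance / total variance.
#'
#' @param arch A `trait_architecture`.
#' @param relationship `"sib"`, `"half_sib"`, `"cousin"`, or `"mz"` (a pair
#'   sharing the full genotype, whose covariance is the genetic variance).
#' @param method Enumeration route; see Details.
#' @return Exact covariance, trait-variance units.
#' @export
exact_pair_covariance <- function(arch, relationship,
                                  method = c("factorized", "joint")) {
  stopifnot(inherits(arch, "trait_architecture"))
  method <- match.arg(method)
  if (!relationship %in% c("sib", "half_sib", "cousin", "mz")) {
    stop("unsupported relationship: ", relationship, call. = FALSE)
  }
  if (method == "joint") {
    if (relationship != "sib" || n_loci(arch) != 2L) {
      stop("`method = \"joint\"` supports sib pairs over two-locus architectures",
           call. = FALSE)
    }
    return(sib_two_locus_cov(arch))
  }
  sum(vapply(arch$components, component_pair_cov, numeric(1),
             loci = arch$loci, relationship = relationship))
}

#' Oracle expectations for every estimator
#'
#' Assembles the exact moments and pair covariances into the quantities the
#' estimators target: expected pair correlation, pair-based NSH
#' (correlation / relatedness), VC-based NSH (additive / total variance), and
#' BSH (genetic / total variance).
#'
#' @param arch A `trait_architecture`.
#' @param relationships Character vector of relationships to tabulate.
#' @return A tibble with one row per relationship: `relationship`,
#'   `relatedness`, `pair_covariance`, `expected_correlation`,
#'   `expected_nsh_pair`, `expected_nsh_vc`, `expected_bsh`.
#' @export
expected_estimates <- function(arch,
                               relationships = c("sib", "half_sib", "cousin")) {
  em <- exact_trait_moments(arch)
  covs <- vapply(relationships, function(rel) {
    exact_pair_covariance(arch, rel)
  }, numeric(1))
  corr <- covs / em$total_variance
  r <- relatedness_of[relationships]
  tibble::tibble(
    relationship = relationships,
    relatedness = unname(r),
    pair_covariance = unname(covs),
    expected_correlation = unname(corr),
    expected_nsh_pair = unname(corr / r),
    expected_nsh_vc = em$additive_variance / em$total_variance,
    expected_bsh = em$genetic_variance / em$total_variance
  )
}
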