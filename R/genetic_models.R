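# Genotype -> trait-mean architectures: additive, two-locus XOR epistasis,
# and sums of such components over disjoint unlinked loci.

#' Describe a biallelic locus
#'
#' A locus is a biallelic DNA sequence variant segregating at Hardy-Weinberg
#' equilibrium: at alternate-allele frequency `p` the genotype frequencies for
#' doses 0/1/2 are \eqn{(1-p)^2}, \eqn{2p(1-p)}, \eqn{p^2}. With `alt_freq =
#' 0.5` this is exactly (0.25, 0.5, 0.25).
#'
#' @param ref_allele,alt_allele Single-character allele labels (e.g. `"A"`,
#'   `"G"`). The alternate allele is the one counted by the 0/1/2 dose coding.
#' @param alt_freq Population frequency of the alternate allele, in \[0, 1\].
#' @return A one-row tibble with columns `ref_allele`, `alt_allele`,
#'   `alt_freq`. Bind rows of these to build a multi-locus table.
#' @examples
#' loci <- dplyr::bind_rows(locus_spec("A", "G"), locus_spec("T", "C"))
#' @export
locus_spec <- function(ref_allele, alt_allele, alt_freq = 0.5) {
  stopifnot(is.character(ref_allele), is.character(alt_allele),
            length(ref_allele) == 1L, length(alt_allele) == 1L)
  if (!is.numeric(alt_freq) || length(alt_freq) != 1L ||
      is.na(alt_freq) || alt_freq < 0 || alt_freq > 1) {
    stop("`alt_freq` must be a single probability in [0, 1]", call. = FALSE)
  }
  tibble::tibble(ref_allele = ref_allele, alt_allele = alt_allele,
                 alt_freq = alt_freq)
}

#' Hardy-Weinberg genotype probabilities
#'
#' @param p Alternate-allele frequency.
#' @return Numeric vector of length 3: probabilities of doses 0, 1, 2.
#' @export
hwe_probs <- function(p) {
  stopifnot(is.numeric(p), p >= 0, p <= 1)
  c(`0` = (1 - p)^2, `1` = 2 * p * (1 - p), `2` = p^2)
}

#' Additive trait component
#'
#' One locus contributing `base_mean + dose * per_allele_effect` to the trait
#' mean. The default parameters give genotypic means 10, 10.5, 11 for doses
#' 0, 1, 2: each copy of the alternate allele raises the mean by half a unit.
#'
#' @param locus Integer index of the locus this component acts on (position in
#'   the architecture's locus table).
#' @param base_mean Trait mean of the dose-0 homozygote, trait units.
#' @param per_allele_effect Additive effect of each alternate-allele copy.
#' @return A `trait_component` of kind `"additive"`.
#' @export
additive_component <- function(locus, base_mean = 10, per_allele_effect = 0.5) {
  stopifnot(length(locus) == 1L, is.numeric(base_mean),
            is.numeric(per_allele_effect))
  structure(
    list(kind = "additive", loci = as.integer(locus),
         base_mean = base_mean, per_allele_effect = per_allele_effect),
    class = "trait_component"
  )
}

#' XOR epistatic trait component
#'
#' Two unlinked loci interacting through an exclusive-OR penetrance pattern:
#' the trait mean is `low_mean` when exactly one of the two loci is
#' heterozygous, and `high_mean` otherwise (neither or both heterozygous).
#' The mean takes only these two values across the nine two-locus genotype
#' combinations, and at allele frequency 0.5 the two mean classes each have
#' probability 0.5, so no single-locus (additive) coding can capture any of
#' the genetic variance.
#'
#' @param loci Integer vector of length 2: indices of the interacting loci.
#' @param low_mean Trait mean of the exactly-one-heterozygote class.
#' @param high_mean Trait mean of the remaining genotype combinations.
#' @return A `trait_component` of kind `"xor"`.
#' @export
xor_component <- function(loci, low_mean = 10, high_mean = 11) {
  loci <- as.integer(loci)
  stopifnot(length(loci) == 2L, loci[1] != loci[2],
            is.numeric(low_mean), is.numeric(high_mean))
  structure(
    list(kind = "xor", loci = loci, low_mean = low_mean, high_mean = high_mean),
    class = "trait_component"
  )
}

#' Trait mean of an additive component
#'
#' @param component A `trait_component` of kind `"additive"`.
#' @param dose Integer allele dose(s) in \{0, 1, 2\}; vectorised.
#' @return Trait mean(s): `base_mean + dose * per_allele_effect`.
#' @export
additive_mean <- function(component, dose) {
  if (!inherits(component, "trait_component") || component$kind != "additive") {
    stop("`component` must be an additive trait_component", call. = FALSE)
  }
  check_dose(dose)
  component$base_mean + dose * component$per_allele_effect
}

#' Trait mean of an XOR epistatic component
#'
#' @param component A `trait_component` of kind `"xor"`.
#' @param dose1,dose2 Allele doses at the two interacting loci; vectorised.
#' @return `low_mean` where exactly one locus is heterozygous, else
#'   `high_mean`.
#' @export
xor_mean <- function(component, dose1, dose2) {
  if (!inherits(component, "trait_component") || component$kind != "xor") {
    stop("`component` must be an xor trait_component", call. = FALSE)
  }
  check_dose(dose1)
  check_dose(dose2)
  ifelse(xor(dose1 == 1L, dose2 == 1L), component$low_mean, component$high_mean)
}

check_dose <- function(dose) {
  if (!all(dose %in% c(0L, 1L, 2L))) {
    stop("allele doses must be 0, 1 or 2", call. = FALSE)
  }
  invisible(dose)
}

# Evaluate one component on an n x L dose matrix covering the full
# architecture; picks out the component's own loci.
component_values <- function(component, doses) {
  if (component$kind == "additive") {
    additive_mean(component, doses[, component$loci[1]])
  } else {
    xor_mean(component, doses[, component$loci[1]], doses[, component$loci[2]])
  }
}

#' Assemble a trait architecture
#'
#' A trait architecture is a set of components (additive and/or XOR) acting on
#' pairwise-disjoint, unlinked loci, plus a residual noise scale. The trait
#' mean of a multilocus genotype is the sum of the component means; each
#' component also carries an independent Normal(0, `residual_sd`) residual, so
#' the total residual variance is `length(components) * residual_sd^2`.
#'
#' @param components A `trait_component` or list of them, over disjoint loci.
#' @param loci Locus table built from [locus_spec()] rows.
#' @param residual_sd Residual (within-genotype) standard deviation per
#'   component, trait units. Default 0.3.
#' @return A `trait_architecture` object.
#' @seealso [trait_preset()] for the bundled additive / XOR / combined models.
#' @export
trait_architecture <- function(components, loci, residual_sd = 0.3) {
  if (inherits(components, "trait_component")) components <- list(components)
  stopifnot(is.list(components),
            all(vapply(components, inherits, TRUE, "trait_component")),
            is.data.frame(loci),
            is.numeric(residual_sd), residual_sd >= 0)
  used <- unlist(lapply(components, `[[`, "loci"))
  if (anyDuplicated(used)) {
    stop("component locus sets must be pairwise disjoint", call. = FALSE)
  }
  if (length(used) && (min(used) < 1L || max(used) > nrow(loci))) {
    stop("component locus indices outside the locus table", call. = FALSE)
  }
  structure(
    list(components = components, loci = loci, residual_sd = residual_sd),
    class = "trait_architecture"
  )
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(sprintf("<trait_architecture: %d component(s), %d locus/loci, residual_sd = %g>\n",
              length(x$components), n_loci(x), x$residual_sd))
  for (comp in x$components) {
    if (comp$kind == "additive") {
      cat(sprintf("  additive @ locus %d: mean = %g + %g * dose\n",
                  comp$loci, comp$base_mean, comp$per_allele_effect))
    } else {
      cat(sprintf("  xor @ loci %d,%d: mean = %g (one het) / %g (otherwise)\n",
                  comp$loci[1], comp$loci[2], comp$low_mean, comp$high_mean))
    }
  }
  invisible(x)
}

#' Number of loci in an architecture
#' @param arch A `trait_architecture`.
#' @export
n_loci <- function(arch) nrow(arch$loci)

#' Trait mean of a full multilocus genotype
#'
#' Sums the component means over their respective loci. Works on a single
#' genotype (dose vector of length `n_loci(arch)`) or on an n x L dose matrix.
#'
#' @param arch A `trait_architecture`.
#' @param doses Dose vector or matrix (columns = loci in locus-table order).
#' @return Trait mean(s), one per genotype row.
#' @export
architecture_mean <- function(arch, doses) {
  stopifnot(inherits(arch, "trait_architecture"))
  if (is.null(dim(doses))) doses <- matrix(doses, nrow = 1L)
  if (ncol(doses) != n_loci(arch)) {
    stop(sprintf("genotype has %d loci but architecture has %d",
                 ncol(doses), n_loci(arch)), call. = FALSE)
  }
  out <- numeric(nrow(doses))
  for (comp in arch$components) {
    out <- out + component_values(comp, doses)
  }
  out
}

#' Enumerate the genotype-to-mean table of an architecture
#'
#' Lists every multilocus genotype combination (all `3^L` dose vectors) with
#' its Hardy-Weinberg probability and trait mean. This enumeration underlies
#' the exact-moment oracle and is handy for inspecting a model.
#'
#' @param arch A `trait_architecture`.
#' @return A tibble with columns `dose_1 ... dose_L`, `prob`, `mean`.
#'   Probabilities sum to 1. An architecture over zero loci yields a single
#'   row with probability 1 and mean 0.
#' @export
mean_table <- function(arch) {
  stopifnot(inherits(arch, "trait_architecture"))
  L <- n_loci(arch)
  if (L == 0L) return(tibble::tibble(prob = 1, mean = 0))
  grid <- as.matrix(do.call(
    expand.grid, stats::setNames(rep(list(0:2), L), paste0("dose_", seq_len(L)))
  ))
  prob <- rep(1, nrow(grid))
  for (l in seq_len(L)) {
    prob <- prob * unname(hwe_probs(arch$loci$alt_freq[l]))[grid[, l] + 1L]
  }
  out <- tibble::as_tibble(grid)
  out$prob <- prob
  out$mean <- architecture_mean(arch, grid)
  out
}

#' Bundled study architectures
#'
#' Three preset architectures used throughout the package:
#' \describe{
#'   \item{`additive`}{One A/G locus at allele frequency 0.5 with genotypic
#'     means 10, 10.5, 11 (per-allele effect 0.5).}
#'   \item{`xor_epistasis`}{Two unlinked loci (A/G and T/C, both at frequency
#'     0.5) under the XOR model: mean 10 when exactly one locus is
#'     heterozygous, mean 11 otherwise.}
#'   \item{`combined`}{The sum of the two traits above over three loci
#'     (locus 1 additive, loci 2-3 XOR), each component independently noised.}
#' }
#'
#' @param name Preset name.
#' @param residual_sd Residual SD per component; default 0.3, giving residual
#'   variance 0.09 per component.
#' @return A `trait_architecture`.
#' @export
trait_preset <- function(name = c("additive", "xor_epistasis", "combined"),
                         residual_sd = 0.3) {
  name <- match.arg(name)
  ag <- locus_spec("A", "G", 0.5)
  tc <- locus_spec("T", "C", 0.5)
  switch(
    name,
    additive = trait_architecture(
      additive_component(1L), loci = ag, residual_sd = residual_sd),
    xor_epistasis = trait_architecture(
      xor_component(c(1L, 2L)), loci = dplyr::bind_rows(ag, tc),
      residual_sd = residual_sd),
    combined = trait_architecture(
      list(additive_component(1L), xor_component(c(2L, 3L))),
      loci = dplyr::bind_rows(ag, ag, tc), residual_sd = residual_sd)
  )
}

#' Write / read a trait architecture as YAML
#'
#' Serialises the locus table, components, and residual SD, so that a model
#' definition can live in a config file next to the data it generated.
#'
#' @param arch A `trait_architecture`.
#' @param path File path.
#' @return `write_architecture()` returns `path` invisibly;
#'   `read_architecture()` returns the reconstructed `trait_architecture`.
#' @export
write_architecture <- function(arch, path) {
  stopifnot(inherits(arch, "trait_architecture"))
  comp_list <- lapply(arch$components, function(comp) {
    unclass(comp)
  })
  loci_list <- lapply(seq_len(n_loci(arch)), function(l) {
    list(ref_allele = arch$loci$ref_allele[l],
         alt_allele = arch$loci$alt_allele[l],
         alt_freq = arch$loci$alt_freq[l])
  })
  yaml::write_yaml(
    list(residual_sd = arch$residual_sd, loci = loci_list,
         components = comp_list),
    path
  )
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  spec <- yaml::read_yaml(path)
  loci <- dplyr::bind_rows(lapply(spec$loci, function(l) {
    locus_spec(l$ref_allele, l$alt_allele, l$alt_freq)
  }))
  components <- lapply(spec$components, function(comp) {
    switch(
      comp$kind,
      additive = additive_component(comp$loci, comp$base_mean,
                                    comp$per_allele_effect),
      xor = xor_component(unlist(comp$loci), comp$low_mean, comp$high_mean),
      stop("unknown component kind: ", comp$kind, call. = FALSE)
    )
  })
  trait_architecture(components, loci, residual_sd = spec$residual_sd)
}
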