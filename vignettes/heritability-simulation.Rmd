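---
title: "Simulating epistasis and relative-pair heritability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating epistasis and relative-pair heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiherit)
```

## The model

`epiherit` studies a quantitative trait whose genotypic mean is a sum of
components over biallelic, unlinked loci segregating at Hardy–Weinberg
equilibrium (genotype probabilities $(1-p)^2,\,2p(1-p),\,p^2$ for allele
doses 0/1/2). Two component families are supported:

* **Additive**: mean $= \beta_0 + a \cdot d$ for dose $d$ at one locus. The
  default ($\beta_0 = 10$, $a = 0.5$, $p = 0.5$) gives genotypic means
  10, 10.5, 11 and additive variance $2pq\,a^2 = 0.125$.
* **XOR epistatic**: over two loci, mean $= 10$ when *exactly one* locus is
  heterozygous and $11$ otherwise. At $p = 0.5$ the exactly-one-het event has
  probability $\tfrac12$ at every single-locus genotype, so the conditional
  trait mean given any one locus is flat: the additive variance is exactly
  zero while the genetic (here entirely epistatic) variance is the Bernoulli
  variance $0.25$.

A phenotype adds, per component, an independent $\mathcal N(0,
\sigma_e)$ residual with $\sigma_e = 0.3$ by default, i.e. residual variance
$0.09$ per component. A composed trait (the `combined` preset: additive locus
plus an XOR pair on disjoint loci) is literally the sum of the two
independently noised component traits, so its residual variance is
$2 \times 0.09 = 0.18$ and its total variance $0.125 + 0.25 + 0.18 = 0.555$.

Treating 0.3 as the *residual standard deviation per component* is a
deliberate reading: it is the only convention under which the three presets'
exact moments are mutually consistent (e.g. XOR total variance
$0.25 + 0.09 = 0.34$ and BSH $0.25/0.34 \approx 0.735$). The parameter is
user-settable (`residual_sd` everywhere).

## Heritability estimators

Given a cohort of relative pairs with expected relatedness $r$ (sib $0.5$,
half-sib $0.25$, first cousin $0.125$):

* **Pair-based NSH**: the Pearson correlation of member phenotypes divided by
  $r$ — twice the sib correlation, eight times the cousin correlation. The
  estimator is unbounded; out-of-range values are reported unclipped (with a
  warning) because the correlation-vs-relatedness linearity diagnostic needs
  raw values.
* **Variance components** in unrelated founders: ordinary least squares of
  the phenotype on all 0/1/2 dose codings jointly; the per-locus component is
  $\hat\beta_l^2 \,\widehat{\mathrm{var}}(d_l)$ and components sum because
  the loci are independent. The epistatic component regresses on the 0/1
  indicator of the XOR mean class (0 = mean-10 combinations, 1 = mean-11).
  All sample variances use the $n-1$ convention.
* **Ratios**: VC-based NSH $= \hat V_A / \hat V_P$ and BSH
  $= (\hat V_A + \hat V_I)/\hat V_P$ are clipped to $[0,1]$ with a warning;
  raw pair-based estimates are not.

The additive regression includes the XOR loci's dose columns too (as the
combined-model analysis does); for purely additive architectures this is a
no-op, and for XOR architectures those slopes estimate exactly zero.

## The synthetic cohorts

Founder alleles are iid Bernoulli($p$) draws — two per locus — which induces
HWE; children receive one uniformly chosen allele from each parent per locus,
independently across loci (no linkage) and across meioses. Cohort
constructions are the minimal standard ones: sib pairs are the two children
of a fresh founder couple; half-sibs share a mother and have unrelated
fathers (one child each); cousins descend from one grandparental couple whose
two children each marry an unrelated founder. These yield expected
relatedness 0.5 / 0.25 / 0.125, which the simulator verifies empirically via
founder-allele identity-by-descent tags carried through every transmission.

Defaults: 2500 families per relationship, so the
sib cohort's founder generation holds 5000 unrelated parents, which is also
the sample used for the variance-components regression; founders are
phenotyped along with everyone else. Mating is random, monogamous, and
non-overlapping; there is no mutation, genotyping error, dominance, linkage
disequilibrium, assortative mating, or missing data — so passing tests speak
to estimator behaviour under the idealised model, not to the robustness of
heritability estimation against any of those real-data complications.

Because the two members of every pair are generated exchangeably (iid
transmissions given the parents), the member-1/member-2 scatter-axis
assignment is already uniform and no additional randomisation is applied;
the pair correlation is the plain Pearson correlation of the two member
columns (a double-entry intraclass variant can be computed by symmetrising
the pair table, but is not the default).

## The exact oracle

Every stochastic estimate is certified against closed-form enumeration:

* **Marginal moments** come from the $3^L$-row genotype-to-mean table;
  additive variance is the variance of the weighted least-squares projection
  of the mean function onto $\{1, d_1, \dots, d_L\}$ under the HWE measure.
* **Pair covariances** come from enumerating founder alleles and meiosis
  choices of the generating pedigree per locus (sib: $2^{12}$ states;
  cousin: $2^{16}$), giving the exact joint dose distribution of the pair,
  then combining loci by independence within each component. Residuals are
  independent across individuals, so the expected phenotype correlation is
  the genetic covariance over the total variance.
* Three independent routes are kept and cross-checked to $10^{-12}$:
  factorised per-locus enumeration, a closed-form moment formula for the XOR
  indicator, and (for sib pairs at two loci) a full joint enumeration over
  both loci simultaneously with no factorisation. A full joint enumeration
  for cousins would need $\sim 2^{32}$ states and is deliberately omitted.

Key oracle values for the presets: additive — sib covariance $V_A/2 =
0.0625$, correlation $0.0625/0.215 \approx 0.2907$, $h^2 = 0.5814$; XOR —
sib covariance $0.015625$ (correlation $\approx 0.046$), half-sib and cousin
covariances exactly 0; combined — sib correlation $0.1408$, pair-based NSH
$0.2815$, VC NSH $0.2252$, BSH $0.6757$. Note that for the combined model
the pair-based sib NSH ($0.2815$) legitimately exceeds the VC-based NSH
($0.2252$): the sib covariance contains an epistatic share that the $\times 2$
multiplier attributes to additivity, while half-sib and cousin pairs carry
none of it — their expected NSH is $0.2252$ by either multiplier convention.

## Numerical and design choices

* **Sample sizes in tests**: full-scale checks run at the default
  2500-family / 5000-founder sizes with tolerance bands of $\pm 3$ standard
  errors around the oracle values (correlation SE $\approx 1/\sqrt{n}$;
  variance-component SEs measured at $n = 5000$). The oracle-vs-simulation
  equivalence property uses 50,000 pairs per relationship at $\pm 4$ SE.
  Smaller structural tests use hundreds of families.
* **Degenerate inputs**: cohorts need $\ge 2$ families; correlations on
  fewer than 30 pairs warn about wide tolerances; zero-variance phenotype
  columns, constant indicators, and collinear dose codings are errors, not
  NaNs. Allele frequencies 0 and 1 are allowed and produce monomorphic
  founders.
* **Reproducibility**: one seeded RNG stream drives founders, meioses, and
  residuals in a fixed order, so a config plus seed reproduces cohorts — and
  the exported CSVs — byte for byte. Every CSV carries `# seed:` and
  `# config:` (hash) header lines; floats are written at 6 significant
  digits.
* **Bimodality diagnostic**: the XOR sib scatter's marginal is an equal
  mixture of $\mathcal N(10, 0.3)$ and $\mathcal N(11, 0.3)$ with kurtosis
  $1.918$, so Sarle's bimodality coefficient is $\approx 0.52$ — *below* the
  0.555 uniform benchmark despite the sharply bimodal density. The test
  threshold is therefore 0.45, comfortably above the unimodal-normal value
  of $1/3$ and below the mixture's value.
* **Relatedness multiplier convention**: half-sib and cousin NSH use the
  $1/r$ multipliers ($\times 4$, $\times 8$) throughout. For the combined
  model an alternative $\times 2$-of-the-correlation reading exists in the
  literature; the multiplier is exposed through
  `nsh_from_correlation(correlation, expected_relatedness)` so either can be
  computed, and the linearity checks are phrased against the oracle rather
  than against any single convention.

## A quick tour

```{r tour, eval = FALSE}
run <- run_experiment(run_config("combined", seed = 42), verbose = TRUE)
run$estimates            # estimates next to their oracle expectations
tidy(run$reports$sib)    # long form of one report
glance(run$reports$sib)  # wide one-row form

panels <- reproduce_figure1(seed = 42, out_dir = "fig1")
plot_pair_scatter(panels$b)                      # multimodal XOR scatter
plot_correlation_vs_relatedness(dplyr::bind_rows(panels$d, panels$e, panels$f))
```

## Limitations

The package models exactly two component families (additive, two-locus XOR)
over biallelic loci; dominance deviations, multi-allelic loci, linkage,
gene–environment structure, twins, and REML/kinship-matrix heritability
estimation are out of scope. The oracle supports sib, half-sib, cousin, and
the monozygotic self-check — not arbitrary pedigrees. All conclusions the
simulations support concern the idealised generative model described above.
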