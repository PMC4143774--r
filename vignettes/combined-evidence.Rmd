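---
title: "Combining linkage and family-based association evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining linkage and family-based association evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkassoc)
```

## The problem

Pedigree studies of quantitative traits produce two complementary evidence
streams per genomic region: multipoint linkage LOD scores, computed along a
genetic-map grid from identity-by-descent sharing, and family-based
association p-values, computed per gene from transmitted alleles. Linkage
is robust to population stratification but coarse; association is fine but
underpowered for modest effects. `linkassoc` combines the two into one
p-value per gene so that genes with moderate support in both tests can
outrank genes with strong support in only one.

## The model

**LOD to p.** A variance-components linkage test constrains the QTL
variance to be non-negative, so under the null the likelihood-ratio
statistic `2 ln(10) LOD` is asymptotically a 0.5:0.5 mixture of a χ²₁
variable and a point mass at zero. `lod_to_pvalue()` therefore returns
`0.5 * P(χ²₁ ≥ 2 ln(10) LOD)` for positive LOD — at most 0.5 — and exactly 1
for LOD ≤ 0: an observed statistic of zero has tail probability 1. The
resulting discontinuity at 0⁺ (p jumps from just under 0.5 to 1) is a
faithful consequence of the point mass, not an artifact; the alternative of
assigning 0.5 at zero would misstate the null law. A useful identity
follows: for LOD > 0 the inverse-normal transform of this p-value is
exactly `sqrt(2 ln(10) LOD)` (`z_from_lod()`), which the tests verify to
1e-6 across a grid.

**Inverse-normal transform.** `pvalue_to_z()` maps p to the standard-normal
score with that upper-tail probability, after clamping p into
`[1e-12, 1 - 1e-12]`. The clamp bounds |Z| at about 7.03, so p = 1 (every
unlinked gene) and underflowed p stay finite downstream; it changes nothing
for any p above 1e-12.

**Combination.** The unweighted Liptak (Stouffer) statistic is
`Zc = (Z1 + Z2) / sqrt(1'Φ1) = (Z1 + Z2) / sqrt(2 + 2 φ12)`, and the
combined p is the one-sided upper normal tail of `Zc`. Both inputs are
one-sided evidence p-values, so the combination is strictly one-sided. The
square root in the denominator is required for `Zc` to be standard normal
under the null — and it is the only reading that reproduces the documented
example (LOD 0.82 with association p 0.0137 giving combined p ≈ 0.00166).

**Correlation correction.** When the linkage and association statistics are
not independent, Φ's off-diagonal is estimated as the Pearson correlation
of the two statistics across N phenotype permutations, both statistics
evaluated on the *same* permutation each time
(`build_permutation_matrix()`, `estimate_phi()`). Permutation destroys any
genuine signal while preserving the tests' structural correlation, which is
exactly the quantity Φ needs. Phenotypes are shuffled uniformly (the
generic exchangeable scheme); within-family permutation schemes that respect
pedigree exchangeability are not implemented, a caveat for strongly
structured pedigrees.

## Genome mapping conventions

- Genes are read from BED, hence 0-based half-open; the position
  interpolated for the interval end is `end_bp - 1`, the last base inside
  the gene. Documented, bit-exact conventions beat ambiguity here.
- `bp_to_cm()` interpolates linearly between map anchors and *clamps*
  beyond the terminal anchors rather than extrapolating (extrapolation can
  produce negative cM).
- A gene's LOD is the unweighted mean of the LOD at the multipoint grid
  points inside its closed cM interval — grid-point averaging matches how
  multipoint output is tabulated. Genes too short to contain a grid point
  get the LOD interpolated at their interval midpoint. Whether one averages
  grid points or an interpolated curve is a genuinely open choice; it is
  isolated behind `assign_gene_lod()` so the policy can be swapped without
  touching anything else.
- Strand is ignored; chromosome labels are matched after stripping any
  `chr` prefix.

## The long-term mean blood-pressure trait

Repeated-visit SBP is turned into one trait value per individual in three
steps, each overridable: add 15 mmHg to measurements taken on
antihypertensive medication (`medication_adjust()`, `delta` configurable);
residualize each visit separately on intercept + age + sex by ordinary
least squares (`visit_residualize()`; per-visit fits because age advances
between visits — a pooled fit is available via `pooled = TRUE`); average
the available residuals per individual (`long_term_mean()`), dropping and
reporting individuals with no usable visit. The 15 mmHg constant and the
linear covariate model follow the conventional epidemiological adjustment
for treated blood pressure; the exact constants used in any particular
published analysis are rarely recoverable, which is why both are explicit
arguments rather than baked in.

## Ranking and evaluation

`combine_genes()` inner-joins linkage and association tables on `gene_id`
(skipped ids are reported — association panels rarely cover every gene),
and `rank_genes()` ranks by p-value with ties broken deterministically by
ascending gene id, so ranks are always a permutation of 1..n and output is
platform-stable. Detection uses a top-K rule: a causal gene counts as
detected in a replicate when its rank is at most K, and a replicate counts
as an *improvement* when the association-only rank is beyond K but the
combined rank is within K. K defaults to 49 — the threshold used in the
improvement definition of the evaluation this package reproduces, whose
"top 50" screening language and "within 49" rule differ by one; the number
actually used in the arithmetic wins. No multiple-testing correction is
applied: the decision rule is rank-based, though `glance()` reports the
count of genes below a configurable `alpha` screen (default 0.001).

## Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline consumes, with the
statistical structure the method assumes:

- `simulate_stat_pairs()` draws per-gene `(Z1, Z2)` bivariate normal with
  unit variances and correlation `rho`; causal genes get mean shifts. This
  is the method's asymptotic regime by construction.
- `simulate_permutation_matrix()` draws the matched null law — permutation
  destroys effects but preserves `rho`. Simulating the permutation matrix
  rather than literally permuting phenotypes through linkage/association
  engines reflects that those engines are external tools; the literal path
  is available through `build_permutation_matrix()` when a user supplies
  statistic computers.
- `simulate_lod_landscape()` draws null grid LOD as
  `max(0, N(0,1))² / (2 ln 10)` — the LOD-scale transform of the mixture
  null, so about half the grid sits exactly at zero — plus an optional
  Gaussian-shaped peak for a linked region.
- `simulate_genetic_map()`, `simulate_genes()` and `simulate_visit_table()`
  provide monotone maps, non-degenerate intervals and visit tables with
  known regression coefficients.

Defaults mirror the evaluation design being reproduced: 8047 genes, 10
replicates, alpha 0.001, K = 49. What the synthetic world does *not* have:
linkage disequilibrium between genes (neighbouring genes' statistics are
independent here but correlated in real data), pedigree structure, marker
informativeness varying along the genome, or finite-sample deviations from
normality of either test. Passing calibration and power tests on this
synthetic structure therefore validates the combination machinery, not the
upstream engines, and real-data false-positive rates can differ from the
nominal level even when the combination itself is exact.

## Experiments and problem sizes

`run_type1_experiment()` pools null genes across replicates and reports the
fraction of combined p below alpha; the test suite checks calibration with
100,000 null genes at alpha 0.001 (identity Φ) and, at rho = 0.5, with a
permutation-estimated Φ at alpha 0.05, each against exact binomial 99%
bounds computed by `qbinom` at run time. `run_power_experiment()` ranks
every gene per replicate and assembles per-causal-gene power and
improvement counts; the directional check uses effect shifts of 2.0 on both
scores, 8047 genes, 200 replicates and a majority vote over 5 seeds. The
identity-vs-corrected agreement check uses 5,000 independent null genes and
a 1,000-row permutation matrix. These sizes give sampling error comfortably
inside each test's bounds (binomial or 1/sqrt(n) scale) while keeping the
whole suite in the tens of seconds.

## Known limitations

- Hard-coded to combining exactly two tests; weighted Liptak variants and
  Fisher-style rules are out of scope.
- The permutation scheme is exchangeable-only (see above).
- Interpolation-based mapping assumes the genetic map brackets the genes;
  positions outside the anchored span are clamped, which understates
  genetic distance beyond the terminal anchors.
- The phenotype module implements a conventional adjustment, not any
  specific study's exact constants.
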