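# linkassoc

Combine multipoint linkage evidence with gene-based family-association
p-values to improve candidate-gene detection in family studies of
quantitative traits.

Linkage analysis of pedigrees localises broad regions that cosegregate with
a trait; family-based association tests (FBAT-style) localise finely but
lose power for variants of modest effect. Because the two look at different
parts of the genotype–phenotype correlation, their evidence is largely
non-redundant, and a gene with moderate support in both can outrank genes
with strong support in only one. `linkassoc` implements that combination as
a small, scriptable pipeline for geneticists who already have linkage and
association results in hand.

## The method

For each gene:

1. **Gene-level LOD.** Gene physical intervals (BED, 0-based half-open) are
   mapped to genetic positions by linear interpolation of a genetic map
   (bp → cM), and the gene is assigned the mean of the multipoint LOD over
   the grid points in its mapped interval.
2. **LOD → p.** Under the no-linkage null, 2 ln(10)·LOD is asymptotically a
   0.5:0.5 mixture of a χ²₁ variable and a point mass at zero, so
   p₁ = ½·P(χ²₁ ≥ 2 ln(10)·LOD) for LOD > 0, and p₁ = 1 at LOD ≤ 0.
3. **Inverse-normal transform.** Z₁ = Φ⁻¹(1 − p₁) and Z₂ = Φ⁻¹(1 − p₂),
   where p₂ is the gene-based association p-value.
4. **Unweighted Liptak (Stouffer) combination.**
   Z_c = (Z₁ + Z₂) / √(1ᵀΦ1), with Φ the 2×2 correlation matrix of
   (Z₁, Z₂): the identity when the tests are independent, otherwise
   estimated as the Pearson correlation of the two statistics across
   phenotype permutations. The combined p-value is the upper normal tail of
   Z_c.
5. **Ranking.** Genes are ranked by combined p; detection is judged by a
   top-K rule (default K = 49), mimicking a validation strategy that
   follows up the top candidates.

## Worked example

The two causal blood-pressure genes on chromosome 3, in a replicate where
linkage alone was unremarkable (LOD < 1.5 chromosome-wide):

```r
library(linkassoc)

we <- worked_examples()   # gene_id, mean_lod, p_assoc
linkage <- dplyr::mutate(we,
  p_linkage = lod_to_pvalue(mean_lod),
  z1        = pvalue_to_z(p_linkage))
combine_genes(linkage, we[, c("gene_id", "p_assoc")])
#>   gene_id mean_lod  p_linkage       z1 p_assoc        z2       zc  p_combined
#> 1    MAP4     0.82 0.02599268 1.943255  0.0137 2.2057715 2.933805 0.001674174
#> 2    FLNB     0.53 0.05911021 1.562287  0.1950 0.8596174 1.712545 0.043398149
```

MAP4's association p of 0.0137 would rank it far outside a top-50 screen of
8047 genes; combined with its moderate linkage signal (mean LOD 0.82) the
evidence sharpens to p ≈ 0.0017. FLNB moves from a null-looking 0.195 to
0.043 the same way.

The packaged rank fixture reproduces the published evaluation across 10
simulation replicates:

```r
table1_power_report()
#>   gene_id    trait  k  power_assoc power_combined n_improvements
#>   FLNB    mean_sbp 49          0.0            0.4              4
#>   MAP4    mean_sbp 49          0.5            1.0              5
#>   (Q1 rows: no improvements)
```

A command-line interface covers the same pipeline
(`inst/cli/linkassoc combine|simulate|power|table1`), reading linkage
tracks, genetic maps, gene BED and association TSVs and writing a ranked
combined table.

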