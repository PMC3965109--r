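# phenologr

Cross-species phenolog discovery and eQTL-centric workflows between
*Caenorhabditis elegans* and *Homo sapiens*.

Many human disease genes have worm orthologues, and even when the visible
phenotypes differ wildly (high incidence of male progeny versus breast
cancer), the underlying molecular machinery can be shared. A **phenolog**
is a pair of phenotypes — one per species — whose associated gene sets
share significantly more orthologous genes than expected by chance.
`phenologr` finds such pairs and connects them to worm expression-QTL
evidence, so that a human disease can be traced to candidate worm genes
with mappable expression variation, and vice versa.

## The statistic

Worm and human gene sets are projected into a shared background of *N*
ortholog groups (connected components of pairwise ortholog calls kept at
100% bootstrap support). For a worm phenotype hitting *n₁* groups and a
human disease hitting *n₂*, with *k* groups hit by both, significance is
the upper tail of the hypergeometric distribution:

```
P(X ≥ k) = Σ_{i=k}^{min(n1,n2)}  C(n1, i) · C(N−n1, n2−i) / C(N, n2)
```

computed with log-gamma binomials and log-sum-exp so that p-values far
below double underflow remain usable in log space.

QTL evidence comes from single-marker regression over strain panels:
for each expression trait and marker, `LOD = (n/2)·log10(RSS0/RSS1)`,
with group-mean fits over the two genotype classes. On top of the scan
sit peak detection, flanking-probe windows (50 per side by default),
genomic-region queries and eQTL-hotspot counting.

## Worked example

```r
library(phenologr)

# the published worked case: 16 worm / 12 human orthologues, 3 shared,
# on a background of 4649 ortholog groups
hypergeom_tail(4649, 16, 12, 3)
#> [1] 7.223561e-06

# a full synthetic study: background, catalogs with one planted phenolog,
# RIL genotypes, expression with planted cis eQTLs and one trans hotspot
scn  <- synthetic_scenario(seed = 7)
map  <- build_groups(gen_ortholog_map(scn))
map
#> ortholog_map (background = groups)
#>   genes:  4649 worm, 4649 human
#>   groups: 4417 (shared background N = 4417)

cats <- gen_catalogs(scn, map)
sw   <- broad_sweep(cats$worm, cats$human, map)
head(as.data.frame(sw)[, c("term1_id", "term2_id", "n1", "n2", "k", "p")], 3)
#>   term1_id term2_id n1 n2 k            p
#> 1   wp0001   hd0001 16 12 3 8.414539e-06
#> 2   wd0099   hx0193 14  5 2 9.280088e-05
#> 3   wd0173   hx0174 11  7 2 1.176258e-04
```

The planted worm phenotype / human disease pair (`wp0001`, `hd0001`)
ranks first: its 16- and 12-group sets overlap in 3 groups of the 4417
realized after many-to-many flattening, giving p ≈ 8.4 × 10⁻⁶.

```r
ril  <- gen_ril_genotypes(scn)
expr <- gen_expression(scn, ril$genotypes, ril$markers)
scan <- lod_scan(expr$traits, ril$genotypes, ril$markers)
hc   <- hotspot_counts(scan, 5)
hc
#> hotspot counts over 250 markers; argmax = m_V_25 (63 probes)
expr$hotspot_marker
#> [1] "m_V_25"
```

The planted trans hotspot (60 target probes at marker `m_V_25`) is
recovered as the marker where the most expression traits peak.

The four composed workflows — `disease2qtl()`, `region2disease()`,
`qtl2disease()` and `comparepheno()` — chain these pieces; a thin CLI
(`inst/cli/phenolog-kit.R`) exposes them as shell subcommands, including
`simulate` to write a complete synthetic data set as TSV files.

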