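---
title: "Phenolog discovery and eQTL workflows between worm and human"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenolog discovery and eQTL workflows between worm and human}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenologr)
```

## The problem and the model

Forward genetics in *C. elegans* produces two kinds of gene-level
evidence that are hard to connect to human disease by eye: curated
gene–phenotype associations, and expression-QTL (eQTL) maps from
recombinant inbred line (RIL) panels. On the human side sit gene–disease
catalogs of very different provenance (Mendelian curation, broad disease
annotation, genome-wide association hits). `phenologr` connects the two
species through orthology and a single, simple statistic.

**Ortholog-group background.** Pairwise worm–human ortholog calls, each
with a bootstrap support percentage, are filtered (default: keep only
100% support) and treated as edges of a bipartite gene graph. Connected
components of this graph are the ortholog groups; the number *N* of
groups containing at least one gene of each species is the background of
every cross-species test. Flattening many-to-many orthology into
components is a deliberate choice: it prevents a single expanded gene
family from being counted multiple times in either margin of the test.
Group identifiers are the lexicographically smallest member gene id, so
the partition is reproducible regardless of input order. An alternative
pair-level background (`background = "pairs"`) is available for users who
want each retained ortholog pair counted as its own unit.

**The phenolog test.** A worm phenotype's gene set projects to *n₁*
groups, a human disease's to *n₂*, overlapping in *k*. Under the null
that the two sets hit groups independently at random,

$$P(X \ge k) \;=\; \sum_{i=k}^{\min(n_1,n_2)}
  \frac{\binom{n_1}{i}\binom{N-n_1}{n_2-i}}{\binom{N}{n_2}},$$

the upper tail of the hypergeometric distribution, including *k* itself.
Including the observed count in the tail is what reproduces the worked
literature value `hypergeom_tail(4649, 16, 12, 3)` ≈ 7.2 × 10⁻⁶.
Counting is done in group space by default; `counting = "genes"` reports
gene-level margins instead (the overlap *k* always stays in group space,
the only space the species share). Results are reported with uncorrected
p-values by default, matching how such catalog-versus-catalog scans are
usually read; Benjamini–Hochberg adjustment is opt-in and uses the full
number of tested pairs — including zero-overlap pairs whose p is exactly
1 — as its denominator.

**LOD scans.** Expression traits are mapped by single-marker regression:
for each trait and marker, strains missing either value are dropped
pairwise, and with the two-genotype group-mean fit
$\mathrm{LOD} = (n/2)\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$. This is
algebraically identical to $(n/2)\log_{10}(1/(1-r^2))$ with $r$ the
point-biserial correlation, which the tests exploit as an independent
cross-check.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_bootstrap` | 100 (%) | ortholog support needed to keep a pair |
| `threshold` in `filter_by_pvalue` | — | strict upper bound on association p (GWAS-style inputs use 10⁻⁵ or 10⁻¹⁰) |
| `keep_unscored` | `TRUE` | keep catalog rows with no p-value (curated sources carry none) |
| `lod_threshold` | user-set, strict `>` | minimum LOD for a reported peak |
| `count_per_side` | 50 probes | flanking window around a peak marker |
| `eps` in `lod_scan` | 10⁻¹² | clamp for perfect fits, capping LOD at `(n/2)·12` |

Genomic coordinates are 1-based inclusive throughout; probe position for
ordering and window selection is the integer midpoint of the probe
interval, with ties broken by probe id; windows never leave the peak
marker's chromosome.

## The synthetic test bed

`synthetic_scenario()` defines the study conditions the package is
validated under; its generators emit every input format the toolkit
reads.

* **Background**: 4649 one-to-one ortholog pairs — the size of the
  worm–human orthologue complement at full bootstrap support — plus 5%
  extra cross-edges (realistic many-to-many orthology, which merges
  components to a realized *N* ≈ 4400) and 5% sub-100-bootstrap decoy
  pairs that the default filter must remove.
* **Catalogs**: one planted phenolog with *n₁* = 16, *n₂* = 12, *k* = 3
  (the worked literature configuration), built by picking groups and one
  member gene per group so the counts are recovered *exactly*; plus 200
  decoy terms per species with 3–15 genes drawn uniformly — set sizes
  typical of per-disease gene lists in curated catalogs. Because decoys
  are genuinely random, the planted pair's first rank is probabilistic,
  not guaranteed: decoy pairs of size ~10–15 occasionally reach *k* = 3
  by chance, and validation requires first rank in at least 95% of 100
  seeds rather than always.
* **Genotypes**: 100 RIL strains, 5 chromosomes × 50 evenly spaced
  markers, biallelic A/B; per chromosome the first marker is
  Bernoulli(1/2) and each subsequent marker flips with probability 0.1 —
  a two-state Markov chain giving adjacent-marker correlation 0.8, a
  plausible RIL linkage decay at this marker density.
* **Expression**: 500 probes; 60 are trans targets of a single hotspot
  marker (middle of chromosome V) with effect twice the noise standard
  deviation; 80% of the rest carry a cis effect (same size) at the marker
  nearest their own locus; the remainder are pure noise. An
  allele-substitution effect of 2σ puts the expected single-marker
  r² at 0.5 and the expected LOD near 15 at n = 100 — strong but within
  the range reported for real worm cis-eQTL.

One random stream per artifact is derived from the master seed, so
regenerating one file never shifts the others, and the whole file set is
byte-identical under a fixed seed.

What the generator does **not** emulate: array-specific noise (probe
effects, batch structure), polygenic trans architecture beyond the one
hotspot, linkage-map distortions, and any identifier messiness (aliases,
retired gene ids). Passing the planted-recovery checks therefore shows
the machinery is correct, not that real catalogs are clean; on real data
the dominant error source is identifier reconciliation, which this
package deliberately treats as out of scope (exact string matching
only).

## Numerical choices

* The tail is assembled from `lchoose` (log-gamma) terms with a
  log-sum-exp pivot at the row maximum; relative agreement with exact
  Pascal-triangle integer arithmetic is ~10⁻¹⁴ over every admissible
  parameter set with N ≤ 40 (all binomials there are below 2⁵³, so the
  oracle's integer arithmetic in doubles is exact).
* Tails are clamped at log 1 = 0 against floating-point noise; `k = 0`
  returns exactly 1.
* Perfect LOD fits (RSS₁ = 0) are clamped by `RSS₁ ≥ ε·RSS₀` with
  ε = 10⁻¹², keeping comparisons total; traits with no variance and
  monomorphic markers score 0 by convention; pairs with fewer than 3
  complete strains get a missing LOD rather than a misleading number.
* All rankings break ties lexicographically (term ids; marker position
  then id), making every workflow a pure function of its inputs:
  identical reruns produce byte-identical output files.

## Validation problem sizes

The shipped checks run the worked overlap example; exhaustive oracle
comparison over all N ≤ 40 (~2.6 × 10⁵ parameter sets); symmetry and
monotonicity over 10⁴ random draws up to N = 5000; planted-phenolog
recovery over 100 seeds of the default scenario (200 × 200 decoy pairs
each); planted cis/hotspot recovery over 100 seeds of the default
genome; and null calibration on a 32 × 32 pure-decoy catalog pair
(1024 tests), where the discrete test's false-positive fraction at
α = 0.05 stays below α plus three binomial standard errors — the exact
test is conservative.

## Known limitations

* Literature p-values from catalog snapshots other than the synthetic
  one are not reproducible, because they depend on the snapshot's
  background N and term definitions; the package reproduces structures
  (counts, windows, rankings) rather than those numbers, and
  `N_override` exists precisely to re-evaluate a reported configuration
  on a stated background.
* Single-marker regression has no interval estimation and no
  permutation thresholds; LOD profiles are emitted as plot-ready tables
  rather than drawn.
* Genotypes are strictly biallelic; heterozygotes are not modelled.
* Within-species enrichment uses plain gene space, so its background is
  the catalog's own gene universe, not the ortholog-group background.
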