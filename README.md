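# lowoxmeta

Meta-analysis of low-oxygen (hypoxia/anoxia) transcriptome responses
within and across species.

Plants such as rice tolerate — and even germinate under — low to no
oxygen, while Arabidopsis treats oxygen deprivation much like a generic
abiotic stress. Asking *how unique* a species' low-oxygen response is
requires comparing many independent microarray comparisons within and
between species on a common statistical footing. `lowoxmeta` provides
that footing as a reusable R pipeline for anyone combining replicated,
normalized expression studies: detection-call filtering, regularized
differential expression, hierarchical category enrichment, ortholog
mapping, and the cross-study consensus rules that turn per-comparison
results into conserved, condition-specific, species-specific and
marker-gene summaries.

## The statistics at the core

* **Cyber-T-style regularized t-test.** Per-gene variance is shrunk
  toward a local background estimated from the `w = 101` genes nearest in
  mean expression: σ̃² = (v₀σ₀² + (n−1)s²)/(v₀ + n − 1) with prior weight
  v₀ = 10, then t = (m_b − m_a)/√(σ̃²_a/n_a + σ̃²_b/n_b) on
  n_a + n_b − 2 + 2v₀ degrees of freedom. With v₀ = 0 the classical Welch
  statistic is recovered exactly.
* **PPDE from a beta-uniform mixture.** The p-value distribution is
  fitted as f(p) = λ + (1−λ)·a·p^(a−1); the posterior probability of
  differential expression is the posterior weight of the beta component.
  A gene is called up/down only when fold > 2, p < 0.05 **and**
  PPDE > 0.96.
* **PageMan-style ORA.** Per bin of a MapMan-style hierarchy
  (ancestor-closed membership), a two-sided Fisher exact test against the
  presence-filtered background, reported as a signed z-score
  (z = Φ⁻¹(1 − p/2)); |z| > 1.96 is significant.
* **Consensus rules.** Conserved categories (over-represented in every
  study, with step-interval timing), condition-specific categories
  (target ∩ co-required, minus excluded), species consensus at k-of-n
  quorums (3-of-4 / 4-of-5 by default), low-oxygen × abiotic overlap
  counts, and marker genes (>50-fold induction in a quorum of
  comparisons, optionally excluding genes up-regulated under any abiotic
  stress).
* **Orthology.** Union of a similarity-based and an Inparanoid-style pair
  table, many-to-many, with provenance; contrast results project across
  species through the map.

A synthetic-data module generates single studies, step-responder time
courses and a full two-species compendium with planted ground truth
(effects, enriched bins, ortholog conservation classes, marker genes), so
the whole pipeline is testable end to end without any download.

## Worked example

```r
library(lowoxmeta)

comp <- generate_species_pair(seed = 1)   # two-species synthetic compendium
out  <- run_lowox_pipeline(comp)          # DE -> ORA -> consensus -> markers

subset(out$consensus$up, class != "neither")
#>    bin direction count_a count_b  class
#> 1   25        up       4       5   both
#> 2 25.1        up       4       5   both
#> 3 25.2        up       4       5   both
#> 4   26        up       3       0 a_only
#> 5 26.1        up       3       0 a_only
#> 6   27        up       0       4 b_only
#> 7 27.1        up       0       4 b_only
```

Bins 25.1/25.2 were planted as conserved (up in every comparison of both
species, hence `both`, together with their ancestor bin 25); bin 26.1 was
planted to respond in 3 of the 4 species-a comparisons and never in
species b, and is recovered as `a_only` at the 3-of-4 quorum; 27.1 is the
symmetric `b_only` case. Marker genes:

```r
out$markers$a
#>         gene n_passing  max_fold abiotic_up
#> 1 osa_g00544         3 137.19121      FALSE
#> 2 osa_g00543         3 124.33748      FALSE
#> 3 osa_g00541         3 120.95605      FALSE
#> 4 osa_g00542         3  93.43811      FALSE
#> 5 osa_g00545         3  78.74967      FALSE
```

Exactly the five planted markers: each was induced >50-fold in at least 2
of the 4 low-oxygen comparisons and never up-regulated under abiotic
stress; the planted decoys (abiotic-induced, or capped below 50-fold) are
correctly excluded. Per-contrast results carry the full statistics:

```r
res <- out$de_a$anoxia_1
head(res[res$call == "up", ], 3)
#>         gene   log2fc        t            p ppde call
#> 1 osa_g00001 2.946318 14.96048 1.149842e-13    1   up
#> 2 osa_g00002 2.404186 12.32585 7.163335e-12    1   up
#> 4 osa_g00004 2.218217 12.37157 6.630892e-12    1   up
```

## The analysis workflow

The `analysis/` directory is a numbered file-handoff pipeline over the
package functions; each stage reads the previous stage's TSVs and writes
its own under `results/`:

| script | writes |
|---|---|
| `01_simulate.R` | synthetic fixtures (`results/fixtures/`): single study, germination time-course trio, two-species compendium, `truth.json` |
| `02_differential_expression.R` | one contrast TSV per comparison (`results/de/`) |
| `03_enrichment.R` | per-contrast ORA tables, conserved categories (`fig1_conserved.tsv`), condition-specific categories (`fig2_specific.tsv`) |
| `04_cross_species.R` | species consensus (`fig3_species.tsv`), overlap matrices, ortholog map and projection (`fig4_*.tsv`) |
| `05_markers.R` | marker genes per species (`table2_markers.tsv`) |

Run them in order from the repository root:
`for s in analysis/0*.R; do Rscript $s; done`

File formats (all TSV, tab-separated, UTF-8, `.` decimal, no quoting):
expression matrix (gene ids in column 1, sample ids in the header), design
(`sample`, `condition`, optional `timepoint` rank, `replicate`), presence
calls (`P:0.003`-style call:p cells, or two parallel files), bin
annotation (`bin_path`, `bin_name`, `gene_id`), ortholog pairs (`gene_a`,
`gene_b`, optional `pct_identity`).

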