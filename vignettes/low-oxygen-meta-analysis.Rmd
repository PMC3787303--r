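---
title: "Methods: cross-species low-oxygen meta-transcriptomics"
author: "lowoxmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species low-oxygen meta-transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`lowoxmeta` implements a meta-analysis workflow for comparing
transcriptomic responses to low oxygen (hypoxia/anoxia) within and across
species, of the kind applied to compendia of rice and Arabidopsis
microarray studies. The pipeline consumes *already normalized* log2-scale
expression matrices — normalization (MAS5, GC-RMA and kin) is upstream
array processing, not part of this package — together with a sample design
(condition, optional timepoint rank, replicate), MAS5-style detection
calls, a MapMan-style hierarchical functional-category ("bin") annotation,
and ortholog pair tables from two evidence sources. Each analysis stage is
a pure function over these containers, so stages compose through files
(the `analysis/` drivers) or in memory (`run_lowox_pipeline()`).

# Detection filtering

Genes never reliably detected on the array contribute only noise to
downstream tests, so probesets are filtered on their detection calls
before anything else. A cell is "present" when its detection p-value is
below 0.05; marginal calls are conservatively treated as not-present. The
default keep-rule, `all_reps_of_any_condition`, requires presence in every
replicate of at least one condition: it is the standard detection-filter
practice and is unbiased with respect to which condition a gene responds
in (a gene switched fully off by anoxia is still kept, because it is
present in all aerated replicates). `any_sample` and `all_samples` are
available for sensitivity analyses; the kept gene sets are provably nested
across the three policies. Filtering is applied per study: detection
quality is an array-level property, and pooling calls across laboratories
would let one noisy study veto genes everywhere.

# Regularized differential expression

With 2–3 replicates per group, per-gene variance estimates are unstable
and the ordinary t-test is dominated by variance noise. The package uses a
Cyber-T-style Bayesian regularized t-test: genes are ranked by within-group
mean expression and each gene's variance prior $\sigma_0^2$ is the mean of
the squared observed standard deviations over a `window_size`-wide window
centered on the gene in that ranking (truncated, not shifted, at the
edges). The regularized variance is the convex combination

$$\tilde\sigma^2 = \frac{v_0\,\sigma_0^2 + (n-1)\,s^2}{v_0 + n - 1},$$

with prior weight `v0` acting as pseudo-replicates. We deliberately use
the $v_0 + n - 1$ denominator rather than the $v_0 + n - 2$ posterior-mean
form: the convex form guarantees the estimate lies between the background
and the observed variance for every gene, and it reduces *exactly* to the
classical Welch statistic at `v0 = 0`, which makes the estimator's
behaviour easy to reason about and test. Defaults `window_size = 101` and
`v0 = 10` are the long-standing Cyber-T web-interface defaults; both are
exposed in `cybert_params()`. The statistic is referred to Student's t
with $n_a + n_b - 2 + 2v_0$ degrees of freedom (the prior contributes its
pseudo-replicates; `df_mode = "classical"` switches to $n_a+n_b-2$).
Observed variances are floored at $10^{-8}$ so replicated ties cannot
produce infinite statistics.

## PPDE via a beta-uniform mixture

Instead of a per-gene FDR from permutation, the posterior probability of
differential expression is computed from the shape of the whole p-value
distribution, modelled as a uniform null plus one beta(a, 1) component
spiking at zero:

$$f(p) = \lambda + (1-\lambda)\,a\,p^{a-1}, \qquad
\mathrm{PPDE}(p) = \frac{(1-\lambda)\,a\,p^{a-1}}{f(p)}.$$

The fit is maximum likelihood by EM; the M-step for $a$ has the closed
form $a = -\sum r_i / \sum r_i \log p_i$ under the responsibilities
$r_i$. EM on this two-parameter mixture can stall in flat regions, so the
fit is restarted from a fixed 5×2 grid of $(\lambda, a)$ starting values
and the highest-likelihood solution kept — deterministic restarts give the
same robustness as random ones without consuming RNG state inside an
estimator. P-values are clipped to $[10^{-12}, 1]$ before fitting, and
$\lambda$ is kept inside $[10^{-6}, 1-10^{-6}]$ so the likelihood stays
finite. The mixture is fitted per contrast: studies differ in power and
signal fraction, and a compendium-wide fit would let a strong study
inflate PPDEs in a weak one.

## The three-part call

A gene is called `up` when all of: linear fold-change strictly above 2
(`log2fc > 1`), `p < 0.05`, and `PPDE > 0.96`; symmetrically for `down`.
Fold-change is the difference of group means on the log2 scale ("mean of
logs"), matching how variance-stabilized array intensities are normally
summarized. "Greater than 2-fold" is read strictly, so a 1.87-fold gene
with excellent p and PPDE is still `ns`.

# Over-representation analysis

For each contrast, the up- and down-regulated sets are tested separately
(never pooled) against every bin of the hierarchy with at least one
background member. Membership is ancestor-closed — a gene assigned to
"10.2.1" counts in "10.2" and "10" — so enrichment is evaluated at every
level. The test is the two-sided Fisher exact probability of the 2×2
table, converted to a signed z-score $z = \Phi^{-1}(1 - p/2)$, positive
for over-representation and negative for under-representation;
significance is $|z| > 1.96$, the two-sided 0.05 rule. Two-sided tests
were chosen because figure-style outputs report both over- and
under-representation; a Bonferroni option across bins exists but is off
by default, matching the plain 1.96 convention of this analysis style.

The background is the set of genes surviving the presence filter in that
study, not the whole array: enrichment should be judged relative to what
was measurable. With a fixed DE set, adding background genes outside a bin
can only strengthen that bin's over-representation — a monotonicity the
tests verify.

# Cross-study consensus rules

All consensus rules count a bin as a "hit" only when it is significantly
**over**-represented ($z > +1.96$) in the stated direction's gene set.
Under-representation never counts: the rules describe categories enriched
among responders, and counting a significant depletion as a hit would
invert their meaning.

* **Conserved categories** — bins hit in *every* supplied study (any
  step-wise interval counts); for time courses each bin carries the
  intervals where it was hit, plus a flag for whether two designated
  studies (e.g. aerobic and anaerobic germination in the same species)
  share an interval.
* **Condition-specific categories** — hit in the target comparison AND a
  co-required comparison AND in none of the excluded comparisons, same
  direction throughout. "Not over-represented" is implemented as "not a
  significant over-representation hit", not as "significant in the
  opposite direction"; absence of evidence for enrichment is what the rule
  means to capture.
* **Species consensus** — per bin, count hit comparisons per species;
  `a_only` requires the species-a quorum (default 3 of 4) with *zero*
  hits in species b, symmetrically `b_only` (default 4 of 5); `both`
  requires at least one hit in each species; otherwise `neither`. The
  asymmetric quorums reflect the different numbers of available
  comparisons per species and are configurable.
* **Stress overlap** — gene-level intersection counts between each
  low-oxygen comparison's DE set and each abiotic-stress contrast's,
  reported both ignoring direction (`any_direction`, the default, since
  "overlapping responses" does not assert a direction) and requiring
  matched calls. Contrasts published in the opposite orientation are
  re-oriented upstream via the `orientation = -1` flag of the contrast
  spec, so signs are comparable here.
* **Marker genes** — called up with linear fold strictly above 50 in a
  quorum of the low-oxygen comparisons (defaults: 2 of 4 for the first
  species, 3 of 5 for the second), using the *maximum* fold across passing
  comparisons for reporting. The abiotic exclusion — drop any gene called
  up under any abiotic stress — defaults ON for the first species and OFF
  for the second, mirroring the asymmetric marker definitions this rule
  set descends from; both are overridable. With the degenerate parameters
  (fold 2, quorum 1, no exclusion) the rule collapses to the union of
  up-called genes, which the tests use as an identity check.

# Orthology

Ortholog pairs are accepted when *either* a sequence-similarity resource
*or* an Inparanoid-style method reports them; provenance
(`similarity` / `inparanoid` / `both`) is recorded and the relation is
many-to-many in both directions. Similarity percentages are carried as
annotation only, never used as a filter. `project_contrasts()` pushes a
gene set through the map and reports every ortholog's fold-change and call
in every partner-species contrast, with genes missing from a partner
result flagged `not_detected` — deliberately distinct from a measured but
non-significant `ns`.

# The synthetic-data generators

Because the original compendium lives behind array-repository accessions,
every stage is validated on synthetic data with planted, machine-readable
truth. The generators emulate: Gaussian replicate noise (sd 0.25) on the
log2 scale around per-gene baselines (Normal(8, 2)) — appropriate for
variance-stabilized intensities; planted effects spanning 2-fold to
beyond 100-fold; detection-absent genes; step-responder time courses
whose profiles are flat except at their planted interval; and a
two-species compendium with ortholog conservation classes (conserved
up/down, divergent, opposite, unrelated), planted conserved and
species-specific bins at the quorum structure the consensus rules expect,
and planted marker genes with two decoy families (strong induction that
is also abiotic-induced; broad induction below the 50-fold bar).

Choices worth knowing:

* In the two-species generator, background DE effects are capped at log2 5
  (32-fold) while planted markers draw from log2 6–7 (64–128-fold).
  Background responses are shared across a species' comparisons by
  construction, so a background tail past 50-fold would plant unintended
  marker genes; the markers themselves provide the >100-fold regime.
* Bin annotations are two-level hierarchies (10 top bins × 2 children)
  with log-uniform leaf probabilities, giving realized bin sizes of
  roughly 10–200 genes at 2000 genes, plus dedicated planted bins.
* All randomness flows from one integer seed through a documented
  splitting scheme (`seed * 97 + offset * 1009 mod 2^31 - 19`), so
  sub-generators are independently reproducible and identical inputs give
  bit-identical outputs.

What the generators do **not** emulate: probe-level artifacts, cross-lab
batch effects, heavier-tailed noise, or biological co-expression
structure. Passing recovery tests therefore demonstrates that the
*methods* are implemented correctly and are well calibrated under their
own assumptions — not that those assumptions hold for any particular real
compendium.

# Problem sizes and numerical notes

The shipped tests and the acceptance script run at 2000 genes, 3 vs 3
replicates, 4 + 5 low-oxygen and 4 + 4 abiotic comparisons, 300 ortholog
pairs and 20,000 mixture p-values — sizes chosen so every recovery
property is statistically comfortable while the whole suite stays quick on
a laptop. Other numerical conventions: Fisher two-sided sums use a
relative tolerance of $10^{-7}$ when comparing table probabilities (ties
broken only by floating-point noise must count as ties); `p = 1` maps to
`z = 0`; a contrast against an empty DE set returns an all-zero table with
a warning rather than an error, so batch runs survive a powerless
comparison.

# Limitations

Paired designs, multi-group ANOVA-style tests and probe-level
summarization are out of scope. The consensus rules operate on bin
*identities*, so cross-species category comparison assumes the two
annotations share bin paths (true for MapMan-style ontologies). No
multiple-testing correction is applied across bins by default; with ~30
bins and two directions per contrast, a handful of false hits per run is
expected and the consensus quorums are what controls them.
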