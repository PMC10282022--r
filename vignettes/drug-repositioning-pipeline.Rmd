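---
title: "Methods: a transcriptomics-driven drug-repositioning pipeline for diabetic foot ulcer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a transcriptomics-driven drug-repositioning pipeline for diabetic foot ulcer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`dfurepo` distils two ulcer-versus-normal-skin expression cohorts into a
ranked list of drug-repositioning candidates in five stages: per-cohort
differential expression, cross-cohort intersection, protein-interaction
network expansion, six-category annotation scoring, and drug mapping. This
vignette documents the statistical model behind each stage, the parameters
that matter and their defaults, the design decisions that were genuinely
open, what the synthetic-data generator does and does not emulate, and the
package's known limitations.

# Differential expression

Inputs are pre-normalized log2 intensity matrices (genes × samples) with a
design table assigning each sample to `case` (ulcer) or `control` (normal)
and, for paired cohorts, a pair identifier. The package performs no
normalization or probe-level preprocessing, and rejects missing values
rather than imputing: the intended inputs are complete, already-normalized
matrices, and silent imputation would change the downstream DEG counts.

For a **paired** cohort the per-gene statistic is a one-sample t on the
within-pair case-minus-control differences: logFC is the mean difference
and the residual degrees of freedom are `n_pairs − 1`. For an **unpaired**
cohort it is the pooled-variance two-sample t with
`n_case + n_control − 2` degrees of freedom. Pairing matters: the
generator's shared per-pair offset (biological variation between patients)
cancels inside a pair, so a paired analysis of paired data is strictly more
powerful than an unpaired analysis of the same matrix.

With the default `moderation = "eBayes"`, gene-wise residual variances s²
are shrunk toward a prior estimated from all genes. The hierarchical model
takes s² as scaled-F distributed around a prior variance s0² with prior
degrees of freedom d0; matching the mean and variance of log s² to their
digamma/trigamma expectations gives

- `trigamma(d0/2) = var(log s²) − trigamma(df/2)`, inverted by Newton
  iteration, and
- `log s0² = mean(log s²) − digamma(df/2) + log(df/2) + digamma(d0/2) −
  log(d0/2)`.

The posterior variance `(d0·s0² + df·s²)/(d0 + df)` is a convex combination
of prior and sample variance, and the moderated t uses `df + d0` degrees of
freedom. Two boundary regimes are handled explicitly: when the spread of
log s² is at or below its pure sampling floor `trigamma(df/2)`, the prior is
taken as infinitely strong (`d0 = ∞`; every posterior variance equals the
geometric-mean-based s0²), and with fewer than two positive variances
moderation is not estimable and the ordinary statistics are used with a
warning. Under ordinary statistics a zero residual variance makes the
t-statistic infinite; the p-value is reported as 0 with a warning, since on
zero-noise fixtures the planted effect is unambiguously present.

**DEG rule.** A gene is called differentially expressed when
`|logFC| > 2` (strict inequality, log2 units) and `p ≤ 0.05` (inclusive, on
the raw two-sided p-value). The fold-change rule is strict because both up-
and down-regulated genes come from the same absolute-value rule; the
p-value rule is inclusive because the cutoff is conventionally quoted as
"0.05" without direction — only boundary genes are affected, and the test
suite pins both choices. No multiple-testing correction is applied at this
stage; the DEG counts this pipeline is designed to reproduce are consistent
with raw-p screening, and the FDR machinery is reserved for the enrichment
stage where it conventionally belongs.

# Intersection

The two cohorts' DEG lists are intersected by exact, case-sensitive gene
symbol, ignoring direction: a gene up in one cohort and down in the other
still counts as replicated differential signal, but such
direction-discordant genes are flagged in the Venn summary and the overlap
artifact rather than silently merged. An empty overlap aborts the pipeline
with a stage error — every downstream stage would be vacuous.

# Network expansion

The overlap genes seed an expansion against a scored undirected edge list
(STRING-style `combined_score` integers in [0, 1000]). Every non-seed gene
touching the seed set is ranked by its **maximum** combined score to any
seed, descending, with ties broken by gene symbol ascending, and the top
`k = 50` are added. The "50 interactions" threshold is read as "add the 50
top-scoring new interactor genes": it is the only reading under which a
31-gene seed set grows to 81 genes, and that arithmetic is asserted in the
acceptance tests. Max-score ranking (rather than sum or mean over seed
edges) is the simplest rule consistent with how interaction databases
present first-shell neighbors; it is a package choice, recorded here
because the upstream procedure does not state one, and the ranking rule is
isolated in `expand_seed_set()` so alternatives can be swapped in. No
minimum score cutoff is applied by default. Degenerate inputs degrade
explicitly: fewer than `k` candidates takes all of them with a warning,
`k = 0` returns the seeds, and a network with no seed-to-candidate edges
returns the seeds with a warning. Self-loops are dropped and duplicate
unordered pairs collapse to their maximum score at read time, so row order
and duplication in the edge file cannot affect results.

# Annotation scoring

Each of six collections — knockout-mouse phenotype (KMP/MP), primary
immunodeficiency (PID), KEGG, GO BP, CC and MF — is tested for
over-representation of the expanded gene set. The p-value is the
hypergeometric upper tail `P(X ≥ k)` for `X ~ Hypergeom(N, K, n)`; terms
are accumulated in log space (`lchoose` + log-sum-exp) so large universes
and deep overlaps cannot underflow.

Two rules differ by category:

- **KMP, KEGG, BP, CC, MF**: one test per set, Benjamini–Hochberg within
  the category, significant when `q < 0.05` (strict).
- **PID** is a single curated gene list, not a set collection; it is
  collapsed to one list and judged on the raw `p < 0.05` (strict), with no
  FDR.

**Universe.** The default reference universe for a category is the set of
genes annotated anywhere in that category's collection, the convention of
annotation-based ORA tools. For a single-list category like PID this is
degenerate (the universe would equal the list), so the pipeline passes the
measured-gene universe for PID by default (`pid_universe = "measured"`,
configurable). A gene absent from a category's universe simply cannot earn
that category's point — the "white box" in a score heat map.

**Score.** A gene earns one point per category in which it belongs to at
least one significant set (for PID: the list-level test must pass *and* the
gene must be in the list — the stricter of the two readings, since awarding
the point without list-level significance would let a single immune gene in
the query score on membership alone). The score is the 0–6 sum, and genes
with `score ≥ 2` (inclusive) are the biological risk genes. Sets with a
single member are accepted but logged; empty categories contribute zero
points to every gene.

# Drug mapping

Risk genes are joined to a drug–gene interaction snapshot
(`drug_name`, `gene`, `interaction_type`, `approved`). "Approved drugs with
clear interaction types" is implemented as `approved == "yes"` and a
non-empty interaction type after whitespace trimming — interaction
databases export blank types for unvetted claims. Duplicate drug–gene pairs
(drug names compared case-insensitively) collapse to the union of their
interaction types, approved if any row was. No other drug-name
normalization is attempted. The candidate report counts distinct drugs and
distinct genes, and the chord-diagram export (sectors + links, TSV and
JSON) is lossless with respect to the candidate rows.

# The synthetic-data generator

The generator exists so that every stage has inputs with known answers, and
its defaults are the package's study conditions rather than tuning knobs:

- **Cohorts**: gene baselines drawn once from Normal(7, 1) on the
  log2-microarray-like scale; per-sample Gaussian noise with SD 0.5 log2
  units; planted effects of magnitude 3 log2 units; a paired cohort of 14
  pairs with a shared per-pair Normal(0, 1) offset, and an unpaired cohort
  of 6 cases versus 3 controls. These mirror the sample sizes of the
  reference cohorts; the planted-effect size is set where recovery at the
  |logFC| > 2 rule is expected but not trivially certain for the small
  unpaired cohort.
- **Annotations**: one planted enriched set per category plus decoy sets
  drawn away from the query, so that planted sets are significant and
  decoys are not. In the demo bundle the planted memberships are laid out
  by a bipartite degree-sequence construction so per-category point totals
  are exactly KMP 31, PID 7, KEGG 28, BP 47, CC 22, MF 38 and exactly 50 of
  the 81 expanded genes reach score ≥ 2, five of them scoring 5. The demo
  places the high-scoring and druggable genes among the network-added
  interactors, whose identity is fully determined by the emitted network
  file.
- **Network**: exactly the requested number of distinct non-seed neighbors,
  each wired to one or more seeds with integer scores, plus seed–seed edges
  so that deduplication is exercised. The demo wires 60 neighbors around
  the 31 planted overlap genes, so expansion at k = 50 yields 81 genes.
- **Drugs**: each druggable gene receives a fixed number of rows; the demo
  plants 12 druggable genes sharing 31 distinct approved typed drugs, plus
  decoy genes outside the expanded set with partially unapproved and
  untyped rows to exercise the filters.

Every generator takes an integer seed that fully determines its output, and
file writing uses fixed conventions, so identical seeds give byte-identical
artifacts; the tests assert this for the whole simulate-plus-run path.

What the generator does **not** emulate: probe-level microarray artifacts,
batch effects, platform annotation mapping, correlated gene–gene noise,
realistic annotation-term overlap structure, or drug-name messiness beyond
case. Passing tests therefore demonstrate that the pipeline's logic is
correct on data matching its declared input contract — not that the
thresholds are well calibrated for any particular real cohort.

# Numerical and testing choices

- Hypergeometric tails and BH q-values are checked against brute-force
  enumeration (all instances with N ≤ 25) and the hand step-up definition
  (random p-vectors up to m = 1000) at 1e-10 and 1e-12 respectively;
  ordinary paired statistics match `t.test` to 1e-10; the moderation
  estimator matches the established empirical-Bayes reference
  implementation to 1e-6 on a 500-gene fixture.
- Power is characterized by simulation at the study conditions: 40 planted
  effects of ±3 log2 units among 1000 genes, 14 pairs, noise SD 0.5, over
  20 seeds — the suite requires a median of at least 38 planted genes
  recovered and at most 1 false call. Problem sizes throughout the tests
  (universes of 500–1000 genes, 20-seed repetitions) are chosen so the full
  suite characterizes behavior well while running in seconds.
- All orderings are total and deterministic: DEGs by (|logFC| descending,
  symbol), expansion candidates by (score descending, symbol), risk genes
  by (score descending, symbol), candidates by (gene, drug). Determinism
  under input row shuffling is asserted for the network stage.

# Optional GEO adapter

`read_geo_series_matrix()` parses a GEO series-matrix file and collapses
probes to symbols by **maximum mean intensity** — a package choice, since
the collapse rule for the reference cohorts is not stated; it is logged on
use and affects which boundary genes pass the fold-change rule.
`replicate_geo_counts()` runs the DE and intersection stages on the two
real cohorts when their files are available locally and reports each
count's percent deviation from the published reference counts with a ±5%
band; offline it returns a structured "unavailable" result. Exact count
equality is not expected: it depends on probe-collapse and moderation
details the reference analysis leaves unstated.

# Limitations

- Enrichment is flat-set ORA; no GO topology-aware (parent–child) testing.
- The expansion is single-shell; no second-neighborhood growth and no live
  interaction-database client.
- Approval status is a column of the snapshot, not a live registry lookup,
  and clinical-trial annotation of candidates is out of scope.
- The DEG rule with raw p-values is a screening rule, not an inferential
  claim; with ~1000 null genes at α = 0.05 the fold-change filter, not the
  p-value, is what keeps false calls rare.
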