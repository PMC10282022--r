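# dfurepo

Transcriptomics-driven drug repositioning for diabetic foot ulcer (DFU).

Diabetic foot ulcers are a common, debilitating complication of diabetes
with few approved drugs. One practical route to new treatment options is to
compare ulcer tissue with normal skin at the transcriptome level, distil the
differential signal down to a small set of biologically credible risk genes,
and ask which of those genes can already be hit by approved drugs. `dfurepo`
implements that analysis as a tested, reusable five-stage pipeline for
bioinformaticians working with bulk expression cohorts:

1. **Differential expression** per cohort on pre-normalized log2 matrices,
   with paired or unpaired linear contrasts and empirical-Bayes moderated
   t-statistics. A gene is a DEG when |logFC| > 2 (strict, log2 units) and
   p ≤ 0.05 (raw, two-sided).
2. **Cross-cohort intersection** of the two DEG lists (Venn summary;
   direction-discordant overlap genes are kept and flagged).
3. **Network expansion** of the overlap set against a STRING-style scored
   edge list: the 50 top-scoring new interactors (ranked by maximum combined
   score to any seed, ties broken alphabetically) are added to the seeds.
4. **Six-category annotation scoring**: hypergeometric over-representation
   analysis against knockout-mouse phenotypes (KMP), a primary
   immunodeficiency gene list (PID), KEGG pathways, and GO BP/CC/MF.
   A gene earns one point per category in which it belongs to a significant
   set (q < 0.05 after Benjamini–Hochberg within category; PID is a single
   list judged at raw p < 0.05). Genes scoring **≥ 2 of 6** are the
   biological DFU risk genes.
5. **Drug mapping**: risk genes are joined to a DGIdb-style drug–gene
   snapshot and filtered to approved drugs with a clear (non-empty)
   interaction type; the result is the repositioning candidate table plus
   chord-diagram data exports.

The statistical core is written in the package: the moderated t uses the
classic hierarchical model for gene variances, estimating the prior
(d0, s0²) by method of moments on log s² and shrinking each gene's variance
to (d0·s0² + df·s²)/(d0 + df) with d0 extra degrees of freedom; the
over-representation p-value is the hypergeometric upper tail
P(X ≥ k) for X ~ Hypergeom(N, K, n), summed in log space; q-values follow
the Benjamini–Hochberg step-up. Each of these is cross-checked in the test
suite against an independent reference (`limma::squeezeVar`,
brute-force enumeration, `p.adjust`).

Because the real inputs (GEO series GSE37265 and GSE80178, WebGestalt
collections, STRING, DGIdb) require downloads, the package ships a
**synthetic-data generator** that emulates all four input artifacts with
planted ground truth — planted log fold changes, planted enriched sets,
guaranteed network neighbors, a planted druggable gene subset — so the whole
pipeline is exercisable and verifiable offline. An optional GEO adapter
(`read_geo_series_matrix()`, `replicate_geo_counts()`) supports running the
real cohorts when the series-matrix files are available locally.

## Worked example

```r
library(dfurepo)

bundle <- simulate_bundle("demo_inputs", seed = 42)
cfg    <- pipeline_config(input_dir = "demo_inputs", outdir = "demo_out")
report <- run_pipeline(cfg)
```

which logs, stage by stage:

```
[dge] cohortA: 40 DEGs (7 up / 33 down) of 1000 genes
[dge] cohortB: 45 DEGs (9 up / 36 down) of 1000 genes
[set_ops] overlap: 31 genes (only A 9, only B 14)
[network] expanded 31 seeds by 50 interactors (k = 50) -> 81 genes
[enrichment] KMP: 1/21 sets significant
[enrichment] PID: 1/1 sets significant
...
[enrichment] 50 risk genes at score >= 2
[drug_mapping] 31 drugs across 12 druggable risk genes
```

Reading the numbers: each cohort's DEG count equals its planted truth
(40 and 45 planted effects of ±3 log2 units recovered at |logFC| > 2,
p ≤ 0.05); the 31 genes planted in both cohorts survive the intersection;
expansion at k = 50 grows them to 81; the planted annotation design yields
exactly 50 genes at score ≥ 2 (five of them scoring 5); and 12 of those risk
genes carry 31 distinct approved, typed drugs — the candidate list written
to `demo_out/candidates.tsv`:

```
drug    gene    interaction_type
DRUG001 G0081   inhibitor
DRUG002 G0081   agonist
DRUG003 G0081   inhibitor
...
```

All stage artifacts (DE tables, volcano exports, Venn JSON, the expanded
gene list with provenance, per-category enrichment tables, the gene × six
category score matrix, risk-gene list, candidate table, chord-diagram data)
land in the output directory together with `report.json`, whose counts are
consistency-checked before writing. A thin command-line front end is
installed at `inst/scripts/dfurepo` (`simulate`, `run`, `report`
subcommands; exit codes 0/2/3 for success / invalid config / stage
failure).

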