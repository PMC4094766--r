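---
title: "Methods: staged lncRNA/miRNA/mRNA integration in triome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged lncRNA/miRNA/mRNA integration in triome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triome)
```

## The study design and what it permits

The pipeline targets a specific and constrained design: three RNA classes
(lncRNA, miRNA, mRNA) profiled by microarray across five stages of
esophageal carcinogenesis, where stage 1 is normal epithelium and stages
2–5 are disease stages, and where the RNA of all patients in a stage was
pooled into a single hybridization. One pooled sample per stage means no
replicates, hence no within-stage variance estimate, hence no moderated
t-statistics or dispersion modeling. Everything downstream is built on what
the design does permit:

* **detection calls** (is the probe above an intensity floor?),
* **fold changes** against the stage-1 reference, and
* **set algebra** over the resulting calls.

This is a deliberate scope decision, not a missing feature: limma-style
inference needs replication the design does not have.

## Normalization and detection

Each class's table is median-normalized: the probes with intensity above a
floor (default 50, the vendor convention for the miRNA arrays; we apply one
configurable floor to all classes rather than an undocumented per-vendor
rule) in **all five** stages form the normalization-factor set; each stage
column is divided by that set's median in that stage and rescaled by the
grand mean of the five medians, so values keep their original magnitude and
the floor keeps its meaning after normalization.

Two consequences worth stating precisely:

* After normalization, the factor-set median is identical in every stage.
* Multiplying one stage column by a constant c > 0 changes the normalized
  table by at most a single global factor (the grand mean absorbs c).
  Cross-stage ratios — and therefore every fold-change call — are exactly
  invariant. A stronger form of invariance (bitwise-identical tables) is
  impossible for any normalization that also preserves the data's scale,
  since *some* data-dependent anchor must set the output magnitude.

Detection distinguishes two quantities with different roles: the
*detection rate* counts probes expressed in at least one stage (a
per-array summary, reported as a percentage truncated to two decimals,
matching the convention of published detection rates), while the
*co-expressed* set requires expression in all five stages and is the
universe intersected with the differential-expression collections.

## Differential expression as set algebra

Fold change for probe i in disease stage s is
FC_i(s) = x_i(s) / x_i(1). Calls use an inclusive two-fold threshold:
up if FC ≥ 2, down if FC ≤ 0.5 ("minimum difference threshold" reads as
inclusive). Probes whose stage-1 intensity is at or below the floor cannot
yield a trustworthy ratio; they are excluded from calling and counted,
rather than being assigned near-infinite fold changes.

From the per-stage calls, two collections: the **union** (DE in ≥ 1
disease stage) and the **intersection** (DE in all four), with the
selected-for-analysis set = intersection ∩ co-expressed. "Significantly
upregulated" in the stage-3/4 selection is interpreted as the same
fold-change criterion — the design offers no test statistic to attach a
p-value to, and the miRNA analysis states fold-change filtering explicitly.

Directional stage patterns (UP34, DOWN34, DOWN3_UP4, or any named
direction vector) are evaluated per stage and intersected; ties and
orderings are deterministic throughout (sets are kept sorted).

## Clustering

Log2 fold-change profiles over the four disease stages are clustered with
Euclidean distance and average linkage — the sources name neither, so we
use the most conventional pair and expose both as arguments. Rows are
sorted lexicographically by probe id before clustering, which pins the
agglomeration order under distance ties and makes the tree invariant to
input row order. Only rows (probes) are clustered: the four stage columns
are an ordered progression, so column clustering would discard their
meaning. Trees export to Newick via `ape`.

## miRNA-target integration and cis-neighbor annotation

Target prediction is out of scope by design: the paper consumed database
exports (TargetScan and others), so the pipeline takes a two-column
miRNA→mRNA map as input and is agnostic to how multiple databases were
merged. Associated mRNAs of a selected miRNA are its targets intersected
with the DOWN34 set; per-miRNA sets and their pooled union are both
reported, since both appear in the study's count narrative.

Each selected lncRNA is assigned its two flanking coding genes — the
field's standard first-pass functional annotation for lncRNAs, motivated by
cis-regulation. Distance is the interval gap in bp (0-based half-open
coordinates), ignoring strand, since the sources specify neither a
TSS-to-TSS convention nor strandedness; a coding gene overlapping the
lncRNA is assigned at distance 0 on the side of its midpoint. Distance ties
break toward the lexicographically smaller gene id for determinism. The
implementation binary-searches per-chromosome sorted indexes and is checked
in the tests against an exhaustive linear scan.

## Enrichment

Enrichment replaces a web service with a local, auditable computation. For
a population of N background genes, a term with K members, a study set of
n genes and overlap k, the p-value is the hypergeometric upper tail at k;
the EASE score is the same tail at k−1 (so k = 1 is never significant) — a
deliberately conservative variant popularized by the DAVID service, which
is the default since that service is what the analysis being reproduced
used. Both statistics are always reported. Terms with overlap below
`min_overlap` (default 2) are not tested; Benjamini–Hochberg q-values are
computed across tested terms.

The background population is the set of GO-annotated coding genes detected
on the mRNA array — standard enrichment practice when the assay, not the
genome, defines what could have been observed. Study sets are intersected
with the population before testing.

Null behavior of discrete tests deserves care: with hypergeometric
p-values the achieved level at α is at most α and depends on the
support. The calibration test simulates 500 random annotations over a
2,000-gene population with a 600-gene study set and term sizes 300–900 —
sizes chosen so the discrete support is fine enough that the achieved
level sits near the nominal one — and checks the fraction of p < 0.05
against a 3-standard-error Monte-Carlo band.

## The tripartite network

A GO term joins the network only when it is enriched on **both** sides
(q ≤ 0.05 by default): among the miRNA-associated mRNAs and among the
lncRNA neighbor genes. The sources never define a "functional similarity"
score, so we operationalize the minimal one: for a (miRNA, lncRNA) pair,
the number of shared enriched terms hit by both the miRNA's associated
mRNAs and the lncRNA's neighbor genes, with a Jaccard index reported
alongside. Edges are typed (targets, neighbor, annotated), node and edge
order is deterministic, and the JSON export round-trips losslessly
(GraphML and edge-list TSV are also provided). Stage-pattern labels on
nodes carry the presentation information; plotting is a convenience, not a
contract.

## The synthetic-data generator

The generator emulates the study's design, not its biology: one column per
stage; log-normal baseline intensities (log2 mean 8, sd 2.5, which puts
the detection rate near 80%, in the range of the published lncRNA/mRNA
arrays); per-stage planted DE at fraction 0.05 and fold change 4 (well
clear of the 2-fold threshold); exactly two miRNAs forced up in stages 3
and 4 (coincidental extras are demoted so the planted count is exact); 40
lncRNAs and 100 mRNAs forced into the up-3/4 and down-3/4 patterns; a
small all-stage block per class so the intersection collection is
non-empty (downregulated for miRNAs, to avoid colliding with the exact
up-3/4 guarantee); a genome of 4,000 loci on 5 chromosomes with 5% of
lncRNAs shifted to overlap a coding gene; a target map whose planted
miRNAs draw each target from the down-3/4 set with probability 0.8
(binomially, so realized overlaps fluctuate); and a GO annotation whose
planted terms over-represent both the associated mRNAs and the neighbor
genes of the planted lncRNAs.

Choices that matter for testability:

* Planting is restricted to probes whose baseline exceeds
  floor × fold-change, so planted probes stay detected in every stage even
  when downregulated, and zero-noise runs are recovered exactly.
* The co-expressed truth is recorded on the scale the pipeline sees (after
  median normalization): planting shifts stage medians slightly, so
  raw-scale and normalized-scale detection can disagree for probes within
  a hair of the floor. The drift is orders of magnitude below the 2-fold
  threshold, so fold-change truth is unaffected.
* Planted GO terms draw their signal genes from co-expressed mRNAs only —
  enrichment planted among never-detected genes could not be recovered by
  any analysis.
* Noise is multiplicative log-normal (log2 sd 0.2 by default). The pooled
  design gives no empirical variance to fit, so this is an assumption,
  stated rather than inferred; zero noise is the fully reconstructible
  limit used by the recovery tests.

What the generator does **not** emulate: probe sequences, hybridization
chemistry, spatial artifacts, background correction, correlated
probe blocks, or biologically structured GO hierarchies (annotations are
flat; no ancestor propagation). Passing the planted-recovery tests
therefore demonstrates the pipeline's bookkeeping and statistics are
correct, not that the pipeline is robust to every artifact of real arrays.

## Numerical and degenerate-input conventions

* Medians of even-sized sets are the mean of the central pair (R's
  default).
* An empty normalization-factor set is an explicit error suggesting a
  lower floor, not a silent fallback.
* Fold changes with a zero stage-1 intensity are `NA` and the probe is
  excluded from calling; at-or-below-floor stage-1 probes are likewise
  excluded and counted.
* Clustering requires ≥ 2 finite profiles and names the offending probe
  otherwise; hypergeometric tails use `phyper` directly (no factorial
  overflow); empty networks export headers-only files.
* All randomness flows from a single integer seed; generator sub-streams
  use fixed small offsets from it, and identical seeds give bit-identical
  outputs.

## Problem sizes

The end-to-end recovery analyses run at the generator's default scale —
2,000 lncRNA, 2,000 mRNA and 100 miRNA probes, 50 GO terms — which
preserves the relative proportions of a real array study at a size where a
full pipeline run takes a few seconds. Module tests use smaller fixtures
(hundreds of probes) and the exhaustive oracles run at the largest sizes
where enumeration is exact (e.g. all draws for N ≤ 25 in the
hypergeometric check).

## Known limitations

* Fold-change-only calling cannot separate biological signal from pooling
  noise; with no replicates this is irreducible.
* The cis-neighbor rule (two flanking genes, strand-ignorant, interval
  gap) is a heuristic; expression-correlation-based cis/trans inference is
  deliberately out of scope.
* Enrichment takes the annotation as given: no GO-graph ancestor
  propagation (an extension point), and "cancer-related" labeling of terms
  is a manual curation step the pipeline only exposes a hook for.
* The printed detection-rate convention (truncation to two decimals) is
  reproduced as such; one published miRNA rate is arithmetically
  inconsistent with its own ratio and is not reproduced.
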