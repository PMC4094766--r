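# triome

Integrative analysis of lncRNA, miRNA and mRNA expression across five stages
of esophageal carcinogenesis.

## The problem

Esophageal squamous cell carcinoma develops through a recognizable
progression: normal epithelium, low- and high-grade intraepithelial
neoplasia, early and then advanced carcinoma. Profiling all three RNA
classes (lncRNA, miRNA, mRNA) across these five stages — with one pooled
RNA sample per stage, so no replicates and no variance estimate — raises a
specific analysis problem: how to call differential expression, relate the
three RNA classes to each other, and assign putative functions to lncRNAs,
using only fold changes, genomic positions, a miRNA target map and a GO
annotation.

`triome` implements that pipeline as reusable, tested R functions:

1. **Normalization and detection.** Replicate probes are averaged; each
   stage column is median-normalized over the probes with intensity above a
   floor (default 50) in all five stages; a probe is *detected* when it
   exceeds the floor in at least one stage and *co-expressed* when it
   exceeds it in all five.
2. **Fold-change set algebra.** For each disease stage *s* ∈ {2..5}, probe
   *i* is called up if FC_i(s) = x_i(s)/x_i(1) ≥ T and down if
   FC_i(s) ≤ 1/T, with T = 2 (inclusive). The *union* set collects probes
   differentially expressed in ≥ 1 disease stage, the *intersection* set
   those in all four; the selected-for-analysis set is the intersection
   restricted to co-expressed probes.
3. **Stage-pattern selection.** Directional patterns over stages 3–4 (the
   critical transition): miRNAs up in both (UP34), mRNAs down in both
   (DOWN34), lncRNAs up in both.
4. **miRNA-target integration.** For each selected miRNA *m*, associated
   mRNAs = targets(m) ∩ DOWN34.
5. **Cis-neighbor annotation.** Each selected lncRNA is assigned its two
   flanking coding genes (nearest upstream and downstream by interval gap;
   overlap ⇒ distance 0).
6. **Local GO enrichment.** Hypergeometric upper tail
   p = Σ_{i≥k} C(K,i)·C(N−K,n−i)/C(N,n), plus the conservative EASE variant
   (tail at k−1), with Benjamini–Hochberg correction.
7. **Tripartite cross-linking.** GO terms enriched on *both* the
   miRNA-associated-mRNA side and the lncRNA-neighbor side define a network
   joining miRNAs, mRNAs, lncRNAs and shared terms, with a shared-function
   score per (miRNA, lncRNA) pair.

Because the study's raw arrays are not deposited, a synthetic-data
generator (`simulate_triome()`) emits all inputs with planted truth —
per-stage 2-fold DE sets, two miRNAs up in stages 3–4 whose targets are
enriched among DOWN34 mRNAs, lncRNAs whose flanking genes carry planted GO
terms — so every stage of the pipeline is testable end to end.

## Worked example

```r
library(triome)
report <- run_pipeline(triome_config(simulate = list(noise_log2_sd = 0),
                                     seed = 1))
print(report)
#> Five-stage integrative pipeline report
#>   detection rate: lncRNA 82.15% / miRNA 89.00% / mRNA 83.35%
#>   co-expressed in all 5 stages: 1611 lncRNA / 88 miRNA / 1635 mRNA
#>   selected (co-expressed & DE in every stage): 25 / 1 / 25
#>   stage-3/4 patterns: 2 up miRNAs, 101 down mRNAs, 66 up lncRNAs
#>   miRNA-associated mRNAs (pooled): 98; lncRNAs with neighbors: 66
#>   enriched GO terms: 3 (miRNA side) / 3 (lncRNA side), 3 shared
```

Reading the report: of 2,000 simulated mRNA probes, 83.35% are detected and
1,635 are co-expressed in all five stages. Exactly the two planted miRNAs
come out upregulated in stages 3 and 4; their predicted targets intersected
with the 101 down-in-3/4 mRNAs give 98 associated mRNAs:

```r
print(report$assoc)
#> miRNA-associated mRNAs (targets intersected with down-3/4 mRNAs):
#>   MIR0056: 83 associated mRNAs
#>   MIR0096: 75 associated mRNAs
#>   pooled: 98 distinct mRNAs of 101 down-3/4
```

The three planted GO terms are enriched on both the miRNA and the lncRNA
side and form the shared-function core of the tripartite network
(`report$network`). With `noise_log2_sd = 0` every planted count is
recovered exactly (`report$truth` holds the planted record); with noise the
same pipeline runs on realistically perturbed intensities.

File-based runs use the same interface with paths instead of a simulate
block (see `?triome_config`); `write_sim_inputs()` materializes a synthetic
study as TSV/BED/GMT files, and `inst/cli/triome.R` wraps both modes for
shell use.

## Package layout

- `R/` — simulation (`simulate_triome`), expression I/O and normalization,
  differential set algebra, clustering, target integration, cis neighbors,
  enrichment, cross-link network, pipeline orchestration.
- `tests/testthat/` — unit, property and end-to-end tests, including
  brute-force oracles for the set algebra, neighbor search, hypergeometric
  tail and clustering.
- `vignettes/triome-methods.Rmd` — the methods vignette: model,
  assumptions, parameter choices, limitations.
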