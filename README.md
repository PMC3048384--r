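# causalflow

Simultaneous identification of causal genes and dysregulated pathways in
disease cohorts with both expression and copy-number data.

Complex diseases are heterogeneous: different patients carry different
genomic lesions, yet the same pathways end up dysregulated.  Starting from
a tumor/control expression matrix, a genome-ordered copy-number profile and
a typed molecular interaction network (protein–protein, protein–DNA,
phosphorylation), `causalflow`:

1. **selects target genes** — per-case differential expression calls
   (Z-test against controls, p < 0.01) feed a greedy *minimum multi-set
   cover*: every case except at most β outliers must be covered by at
   least α selected genes;
2. **maps associations** — loci are compressed into *tag loci* (runs of
   neighbors whose copy-number profiles correlate > 0.9 with the tag) and
   each target's expression is regressed on each tag's copy number
   (OLS slope t-test, p < 0.01);
3. **scores candidate causal genes by current flow** — for each associated
   (target, region) pair the target injects unit current into the network,
   region genes are grounded, and edge conductances are the mean absolute
   expression correlation of the endpoints with the target, so current
   preferentially traverses paths supported by co-expression.  A
   transcription-factor constraint at the target and a directed-edge
   heuristic enforce regulatory logic; empirical p-values come from 30
   degree-preserving network rewirings solved at unit conductance
   (normal-fit Z-test).  Candidates need ≥ 70% of the region's maximum
   current and empirical p < 0.05;
4. **picks the final causal set and its pathways** — a greedy *weighted
   multi-set cover* chooses genes whose altered loci plus differentially
   expressed targets explain (almost) all cases, and maximum-current
   (bottleneck) paths through the significant part of the network connect
   each causal gene to its targets, yielding causal subnetworks and
   pathway hubs.

A synthetic-cohort generator (`simulate_cohort()`) with planted causal
structure — correlated copy-number loci, dosage-responsive targets,
conductive network paths ending in a TF→target edge — makes every stage
testable end to end without external data.

## Worked example

```r
library(causalflow)

sim <- simulate_cohort(simulation_config(n_tumor = 150, seed = 1))
res <- run_pipeline(sim$expr, sim$cnv, sim$network,
                    alpha = 2, beta = 15,    # cover depth for a small cohort
                    gamma = 2, delta = "auto",
                    n_perm = 30, seed = 1001)
res
#> causalflow pipeline result
#>   targets selected:       18
#>   tag loci:               30
#>   associated pairs:       18
#>   candidate causal genes: 7 (7 pairs)
#>   final causal genes:     6
#>   causal paths:           6 (hubs: 0)

sim$truth$causal_genes
#> [1] "g068" "g129" "g043" "g014"
res$final_causal
#> [1] "g068" "g014" "g129" "g102" "g060" "g155"
```

Three of the four planted causal genes are recovered in this cohort, plus
three false positives — typical behavior at this signal strength (the
planted-recovery experiment in the test suite averages ~85% recovery at
~60% precision over 20 cohorts).  `res$paths` holds the extracted causal
paths — e.g. `g051 → g074 → g037 → g068`, target through TF and
intermediate to causal gene — each with its bottleneck current objective;
`res$candidates` the per-region currents and empirical p-values;
`overlap_significance()` tests the final set against reference gene sets
read with `read_gmt()`.

On-disk formats are plain text throughout: tab-separated expression /
copy-number tables with sidecar files for sample groups and locus→gene
maps, SIF edge lists with a node-attribute table for TF flags, GMT gene
sets (`read_expression()`, `read_copy_number()`, `read_network()`,
`write_cohort()` …).

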