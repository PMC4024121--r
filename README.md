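# tspclust

Somatic mutation clustering on protein structures via traveling-salesman
linearization.

## The problem

Recurrent somatic missense mutations that pile up in a small region of a
protein are a classic signal of positive selection — candidate activating
driver mutations in oncogenes.  Purely sequence-based cluster tests treat the
protein as a line, so mutations that sit far apart in the chain but touch each
other in the folded structure (a hallmark of multi-domain proteins) are
invisible to them.  `tspclust` is for cancer genomicists and structural
bioinformaticians who want a structure-aware cluster scan that still enjoys
the closed-form order-statistic machinery of the linear test.

## The method

1. **Linearize the fold.**  The Cα atoms of a structure form a complete
   Euclidean graph with edge weights d(i, j).  A short Hamiltonian path
   through this graph — found with the classical TSP insertion heuristics
   (*cheapest*, *nearest* and *farthest* insertion) plus a zero-distance
   dummy-vertex reduction — visits spatial neighbors consecutively, so it is a
   1-D ordering of the protein that respects domains.  Cheapest and nearest
   insertion carry the spanning-tree guarantee of at most twice the optimal
   tour length on metric instances.

2. **Scan for clusters.**  Pooling the n mutations of m samples along the
   path gives order statistics X(1) ≤ … ≤ X(n) on the N analyzed residues.
   Under the uniform null, the scaled gap C = (X(k) − X(i))/N is
   asymptotically Beta(k − i, i + n − k + 1), so every pair (i, k) gets a
   closed-form p-value

   Pr(C ≤ c) = pbeta(c, k − i, i + n − k + 1),

   Bonferroni-corrected over the n(n−1)/2 pairs.  Significant spans are
   unmapped back to the original residue numbering.

3. **Control across structures.**  Per-cluster p-values are multiplied by a
   structure-level factor (p\*) and compared against the rFDR threshold
   α(k + 1)/(2k) over all k = structures × methods tests.

## Worked example

A synthetic two-domain fold in which residues 10 and 90 — 80 positions apart
in sequence — are spatial neighbors, with 4 and 3 mutations planted on them:

```r
library(tspclust)
tr  <- make_contact_domains(100, list(c(10, 90, 6)), seed = 1)
mut <- plant_mutations(c(`10` = 4, `90` = 3), n_samples = 7)
fit <- mutation_clusters(tr, mut, include_identity = TRUE)
print(fit)
#> Mutation cluster scan of 'domains_s1' (chain A)
#>   n = 7 mutations on N = 100 mapped residues; methods: cheapest, nearest, farthest
#>   37 of 84 pairwise tests significant at alpha = 0.05 (Bonferroni)
#>   best cluster: residues 10-90 (cheapest), p_bonf = 9.25e-09
head(summary(fit)[, c("method", "start_residue", "end_residue", "n_mut", "p_bonf")], 2)
#>     method start_residue end_residue n_mut       p_bonf
#> 1 cheapest            10          90     7 9.246720e-09
#> 2 farthest            10          90     7 9.246720e-09
```

The path heuristics place residues 10 and 90 adjacently, so all 7 mutations
fall into a span of 2 path positions: the cluster 10–90 reaches
p_bonf ≈ 9.2 × 10⁻⁹.  The same data scanned in plain sequence order
(`method == "identity"` rows) only reach p_bonf ≈ 7.1 × 10⁻⁴, from the four
recurrent mutations at residue 10 alone — the cross-domain contact is lost.
`fit$rearrangement` reports the Kendall tau distance of each path from
sequence order (how much the linearization shuffled the protein).

For real data, `read_calpha_trace()` parses a PDB file,
`read_mutation_table()` + `filter_mutations()` ingest a COSMIC-style mutation
TSV, and `run_pipeline()` (or the wrapper in `inst/scripts/run-clusters.R`)
batches structures and writes `clusters.tsv`, `path_orders.tsv`,
`diagnostics.tsv` and a dropped-structures log.

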