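---
title: "Structure-aware mutation clustering: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-aware mutation clustering: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tspclust)
```

# The model

`tspclust` tests whether somatic missense mutations cluster more tightly on a
protein than a uniform scatter would, while honoring the tertiary structure.
The analysis has three layers.

**Linearization.**  The Cα coordinates of the analyzed residues define a
complete Euclidean graph.  A short Hamiltonian path through that graph is a
one-dimensional reordering of the protein in which spatial neighbors tend to
be consecutive; unlike a global embedding (e.g. multidimensional scaling),
the path construction is local, so residues of one domain do not drag the
positions of another.  Exact shortest paths are hopeless ((N−1)!/2
candidates), so the package uses the three classical TSP insertion
heuristics — cheapest, nearest and farthest insertion — each of which grows a
tour by inserting the selected vertex where the length increase is minimal.
Cheapest and nearest insertion inherit the minimal-spanning-tree bound of at
most twice the optimal tour length on metric instances; farthest insertion
empirically approaches 3/2 but carries no such guarantee here.

**Order-statistic test.**  Given n pooled mutations on N analyzed residues,
with path positions sorted into order statistics X(1) ≤ … ≤ X(n), the null
model takes mutation positions i.i.d. uniform on the N residues.  In the
continuum limit the scaled gap (X(k) − X(i))/N is Beta(k − i, i + n − k + 1),
so each of the n(n−1)/2 index pairs receives a closed-form p-value, followed
by a Bonferroni factor n(n−1)/2.  The test lives entirely in rank space: only
the ordering produced by the path matters, not its edge lengths, which is
also why a path and its reversal give identical p-values.

**Across-structure control.**  Each cluster's Bonferroni p-value is
multiplied by a structure-level factor to give p\*, and p\* is compared with
the rFDR threshold α(k + 1)/(2k), k being the total number of structure ×
method tests.  The threshold lies in (α/2, α] and decreases in k.

# Tunable parameters

* `methods` (default all three insertion heuristics).  There is no biological
  reason to prefer one; the per-structure summary reports the method with the
  most significant cluster, and k counts all methods run.
* `span_convention` (default `"inclusive"`): the scaled span is
  (X(k) − X(i) + 1)/N rather than the literal limiting form
  (X(k) − X(i))/N.  The literal form assigns p = 0 to a recurrent hotspot
  (two mutations on the same residue, span 0), which both overstates
  significance and collides with the discrete nature of residue positions;
  counting the residues *inclusively* keeps single-residue hotspots testable
  with a finite, slightly conservative p-value.  Both conventions are
  exposed on every relevant function.
* `structure_multiplier` (default 1 in `mutation_clusters()`); the pipeline
  default is max(1, s(s−1)/2) with s the number of configured structures of
  the same protein.  The appropriate family for this factor genuinely
  depends on the study design (how many near-duplicate structures exist per
  protein), so the factor is exposed rather than hidden.
* Alignment scores for numbering reconciliation (match 2, mismatch −1, gap
  open −2, extend −0.5; identity threshold 30 %).  These are ordinary
  protein global-alignment defaults; the threshold guards against aligning
  against the wrong chain.  All are arguments of `align_canonical()`.
* `alpha` (0.05) and `round_down` (flooring the rFDR threshold to three
  decimals, e.g. 0.025007… → 0.025), matching the conventional reporting of
  the threshold.

# Numerical and procedural choices

* **Dummy-vertex path reduction.**  The shortest-path problem is reduced to
  a TSP by adding a vertex at distance 0 to everything and cutting the final
  cycle there.  A zero-distance dummy breaks the nearest/farthest *selection*
  rules (every unvisited vertex is at distance 0 from the tour once the
  dummy has joined it), so the dummy is inserted immediately after tour
  initialization and excluded from selection distances; insertion-position
  costs still use the augmented matrix.  This makes the two rules the path
  forms of their classical selves: inserting next to the dummy is appending
  at a path end at cost d(end, k).
* **Initialization and ties.**  Cheapest and nearest start from the globally
  shortest edge, farthest from the longest; ties prefer the lowest vertex
  index, then the earliest insertion position.  The construction is thereby
  deterministic and reproducible across platforms.
* **Path orientation.**  A path and its reversal are the same object for the
  test; the stored orientation puts the endpoint with the smaller structure
  index first, purely for stable output.
* **Missing residues.**  Residues without coordinates are removed and the
  survivors re-indexed 1..N in structure order before testing, because the
  Beta null assumes uniformity over the *observable* residues.  Structures
  retaining fewer than two mutations are dropped (signalled as a typed
  condition and logged by the pipeline, never fatal to a batch).
* **PDB selection rules.**  First model only, first-listed altLoc per
  residue, first chain containing the marker atom when none is named,
  HETATM ignored.  Any backbone atom can serve as the residue marker
  (`atom_name`), Cα being the default.
* **Degenerate inputs.**  Duplicate coordinates only warn (distance 0 is
  legal); non-symmetric or negative matrices error; brute-force enumerators
  refuse N > 10.

# The synthetic generators

`make_helix()` produces an ideal α-helix (radius 2.3 Å, rise 1.5 Å, 100° per
residue — constants chosen to reproduce the canonical ~3.8 Å Cα–Cα virtual
bond).  `make_contact_domains()` emulates the multi-domain situation that
motivates the whole method: for each requested contact (a, b) the
intervening segment is excised onto its own helical axis placed ~30 Å away,
so a and b become spatial neighbors (~3.8 Å) despite |b − a| sequence
separation; seeded Gaussian jitter (0.15 Å) makes replicates distinct but
bit-reproducible.  `plant_mutations()` writes COSMIC-style missense records
realizing a chosen per-residue count map.

What the fixtures do *not* emulate: real side-chain packing, loop geometry,
crystallographic disorder, inhomogeneous mutational processes (CpG
hypermutability, tissue composition), or mixed mutation classes beyond the
filter vocabulary.  Passing tests therefore demonstrate the correctness of
the machinery and its behavior under the stated null and a planted
alternative — not calibration on any real mutational landscape.

`close_far_test()` implements the sanity check that a linearization keeps
spatially close residue pairs (e.g. < 5 Å) closer *along the path* than
distant pairs (> 25 Å): per structure, sampled residue pairs are classified
by Euclidean distance, mean path-rank separations are averaged, and the
per-structure means are compared with a one-sided Welch t-test (far >
close).  Rank separation is used rather than summed edge length because the
downstream test is rank-based; the direction of the comparison holds under
either metric.

# Problem sizes in the shipped tests

The test suite runs at desk scale by design: 100–150-residue fixtures,
20 planted-cluster replicates, 500 null structures for the type-I check,
200 random instances of 5–9 points for the 2× tour bound, and a
Monte-Carlo grid at 10⁵ replicates per configuration.  All generators and
samplers are explicitly seeded; the full suite completes in a few minutes.
Two comparisons deserve a note:

* The Beta form is continuous while residue positions are a lattice; its
  quality is therefore assessed against the Monte-Carlo null at half-step
  midpoints c = (d + 0.5)/N, the usual continuity-corrected evaluation
  points, where the empirical CDF is unambiguous.
* Path-optimality spot checks against the exhaustive oracle cover all three
  heuristics on colinear instances, and cheapest/nearest on convex
  positions; farthest insertion can miss the optimal path on convex
  polygons (e.g. a regular pentagon), consistent with its weaker tour
  guarantee not surviving the path reduction.

# Known limitations

* Heuristic paths are approximations; no optimality is claimed beyond the
  metric bounds above, and different heuristics can disagree (which is why
  all are run and jointly corrected).
* The uniformity assumption requires the mutation status of all analyzed
  residues to be observable and equal mutability across them; unequal
  mutagenesis (sequence context, hypermutable regions) is not modeled.
* Deduplication of mutation records is exact-tuple; study- or cell-line
  level redundancy cannot be resolved without metadata the table schema does
  not carry.
* The structure-level multiplier is a design input, not an inference; with
  many near-identical structures per protein a plain Bonferroni over
  structures would be too conservative and the rFDR threshold is only an
  approximation to FDR control under positive dependence.
* Insertions, deletions and nonsense mutations are excluded by construction;
  the test speaks only to single-residue missense substitutions.
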