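---
title: "Discovering conserved accessible surface patches on protein structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering conserved accessible surface patches on protein structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Protein interaction interfaces and active sites are usually visible as
patches of unusually conserved residues on an otherwise faster-evolving
surface. Picking them out requires separating *functional* constraint from
*structural* constraint: buried core residues are conserved because they
hold the fold together, and only accessible residues are candidates for
interfaces. `surfpatch` combines three sources of evidence — topology
(residue proximity in 3-D), accessibility (side-chain surface exposure)
and conservation (orthologue alignment identity) — into a single directed
graph per folded unit, and extracts the most conserved connected surface
patch by eigenvector centrality.

## The pipeline

For a predicted model with per-residue confidence (pLDDT) and a predicted
aligned error (PAE) matrix:

1. **Autonomous structural modules.** Residues with pLDDT > 70 become
   nodes; pairs with symmetrised PAE < 5 Å are joined by edges weighted by
   the inverse PAE. Greedy agglomerative modularity maximisation (with a
   resolution parameter scaling the null-model term) partitions this graph;
   communities of fewer than 30 residues — below the size of a stably
   folded domain — are discarded. Each surviving module is analysed
   independently, which lets intramolecular interfaces between modules
   count as surface. For experimental structures without a PAE the whole
   chain is treated as one module.
2. **Surface geometry.** The heavy atoms of one module are tessellated by
   a 3-D Delaunay triangulation. Faces belonging to exactly one
   tetrahedron form the boundary; their vertices are the surface atoms. A
   residue is *accessible* when at least one of its side-chain heavy atoms
   is a surface atom — backbone exposure does not count, which is the
   point of using a tessellation instead of a rolling-probe SASA. Two
   accessible residues are *adjacent* when a tetrahedron contains a
   surface atom of each.
3. **Conservation.** For every alignment column where the query is not
   gapped, the weighted conservation score (WCS) is the summed weight of
   orthologues carrying the identical residue; weights are proportional to
   the guide-tree (patristic) distance from the query and sum to one, so
   identity retained in divergent orthologues counts for more.
4. **The TAC graph.** Nodes are accessible residues; each adjacency pair
   contributes both directed edges; every incoming edge of a node carries
   `conservation / indegree`, so the incoming weights of each node sum to
   its conservation score (a node with conservation 0.5 and five
   neighbours receives five edges of 0.1).
5. **Centrality, clustering, extraction.** Eigenvector centrality scores
   each residue by the conservation of its neighbourhood, not just its
   own. The 1-D centrality scores are split into a high and a low cluster
   by minimum within-cluster variance, and the connected component of the
   high cluster containing the top-scoring residue is the patch.
6. **Scoring.** Absolute conservation (mean patch WCS), relative
   conservation (patch mean minus non-patch surface mean) and a one-sided
   Mann–Whitney p-value (patch stochastically greater than the remaining
   surface).
7. **Iteration.** The patch is removed, edge weights (indegrees changed)
   and centrality are recomputed, and the next patch is extracted, until
   the iteration cap, graph exhaustion, or a non-significant patch.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `plddt_min` | 70 | pLDDT (0–100) | below this, predicted coordinates are unreliable; strict `>` |
| `pae_max` | 5 | Å | pairs predicted to be mutually well-placed; strict `<` |
| `pae_floor` | 0.2 | Å | clamp before inversion so near-zero PAE cannot dominate edge weights |
| `min_module_size` | 30 | residues | lower bound for a stably folded domain; strict `<` excluded |
| `resolution` | 0.8 | — | community granularity; `optimize_resolution()` re-derives it from any annotated domain set by scanning 1 → 0 in 0.01 steps for the largest value that never splits a reference domain |
| `interface_cutoff` | 6 | Å | heavy-atom distance defining benchmark interface residues; strict `<` |
| `max_patches` | 3 | — | iteration cap for multi-patch extraction |
| `p_cutoff` | 1e-10 | — | iteration stops after the first patch whose relative-conservation p-value exceeds it (that patch is still reported); the value used to filter proteome-scale runs |
| `tol`, `max_iter` | 1e-8, 1000 | — | power-iteration convergence (L1 change of normalised iterates) |

## Design choices where the design was open

* **PAE symmetrisation.** PAE is asymmetric; both the edge threshold and
  the inverse weight use the arithmetic mean of the two directions.
* **Two-cluster split.** The split of centrality scores is specified as
  minimum-variance hierarchical clustering cut at two clusters. For
  one-dimensional data the optimal two-cluster minimum-variance partition
  is always a threshold split, so `split_clusters()` computes that exact
  optimum directly by a sorted prefix-sum scan over the distinct-value
  cuts, rather than running a greedy Ward agglomeration that can return a
  slightly suboptimal cut. Ward agglomeration (`stats::hclust`,
  `ward.D2`) serves as an independent cross-check in the tests.
* **Centrality orientation and iteration.** A node accumulates score from
  its in-neighbours (`x(v) ∝ Σ w(u→v) x(u)`), which makes "a residue next
  to conserved residues scores higher" literally true. The update is the
  shifted form `x ← x + Wᵀx` followed by L2 normalisation: on reducible
  TAC graphs (e.g. a hub whose leaves all have zero conservation) pure
  power iteration oscillates or collapses to zero, while the identity
  shift leaves the eigenvectors unchanged and always converges on
  non-negative matrices. This matches the behaviour of the standard graph
  library implementations.
* **WCS formula.** The conservation score is tree-weighted
  identity-to-query, with orthologue gaps as mismatches, query-gap columns
  skipped, and the query's trivial self-match excluded. The match
  function is pluggable (`match_fun`) so a substitution-similarity scheme
  can be swapped in; weights are likewise an explicit input, so any
  external weighting scheme can replace the patristic-distance default.
* **Glycine.** Strictly, glycine has no side-chain heavy atom and can
  never be accessible; `glycine_ca_proxy = TRUE` opts into treating its
  CA as a side-chain stand-in.
* **Iterated scoring.** From iteration two onward, relative conservation
  and the Mann–Whitney test compare the patch against the non-patch
  surface of the *current* (reduced) graph; iteration one is identical to
  the single-patch definition.
* **Mann–Whitney implementation.** Exact enumeration of all pooled-rank
  assignments (midranks for ties) when `min(n, m) ≤ 8` and the
  enumeration is small; otherwise the normal approximation with tie and
  continuity corrections. Complete degeneracy (all values tied) yields
  p = 1 exactly.

## Numerical choices

* **Delaunay robustness.** The tessellation is a Bowyer–Watson
  incremental construction with ghost tetrahedra (a point at infinity)
  and long-double predicates. Inputs are centred and scaled, then
  perturbed by a deterministic radial-inflation-plus-jitter term
  (relative magnitude 1e-6, far below the 1e-3 Å precision of structure
  files). The inflation component pushes points lying on flat hull facets
  outward — never inward — so degenerate inputs such as cubic lattices
  resolve to the expected surface; the jitter breaks cospherical ties
  reproducibly (the perturbation stream is fixed, not user-seeded). The
  result is validated (face multiplicities, vertex coverage) and rebuilt
  from a fresh deterministic stream on the rare failure. Exactly coplanar
  inputs are rejected as degenerate before perturbation.
* **Greedy modularity determinism.** Merges take the largest modularity
  gain; ties are broken by the lexicographically smallest pair of
  community labels (a community is labelled by its smallest member), so
  partitions are reproducible across platforms.
* **Determinism end to end.** Nothing in the analysis path draws random
  numbers; repeated runs on identical inputs produce byte-identical
  results JSON apart from the provenance timestamp.

## The synthetic world

`fixture_spec()` / `make_structure()` / `make_alignment()` generate the
test fixtures: stylised pseudo-proteins, not chemistry. Each module
places ~85% of its residues on a jittered quasi-uniform sphere whose
radius gives ≈ 6 Å neighbour spacing, and the rest in a buried core;
each residue is four backbone pseudo-atoms slightly inside its anchor and
two side-chain pseudo-atoms pointing outward. The planted patch is a
spherical cap, hence spatially contiguous and Delaunay-connected. The
PAE matrix is block structured (2 Å within modules, 20 Å between, seeded
asymmetric noise), pLDDT is drawn from U[85, 98]. The alignment holds
the per-column identity to the query at 0.9 on patch columns versus 0.4
elsewhere (truncated-normal column noise, sd 0.05, 50 orthologues), with
a star guide tree of randomised branch lengths. Defaults are chosen once
to represent a clearly folded domain with a strongly conserved interface
over a moderately conserved background — roughly the contrast between an
interface and a surface in divergent-orthologue alignments.

What a green test on this world establishes: the geometric, graph and
statistical machinery recovers a planted contiguous conserved patch and
stays quiet when no contrast exists. What it does not establish:
performance on real structures, whose surfaces are rougher, whose
alignments have gaps, fragmented coverage and phylogenetic structure, and
whose modules can be partially misfolded; no claim about benchmark
recovery rates on experimental datasets follows from these tests.

## Known limitations

* The WCS here is declared, not proven, to match the original
  column-weighting scheme it is modelled on; the exact historical formula
  is not recoverable from the description alone, which is why the match
  function and weights are pluggable.
* The structure-to-sequence cross-mapping is a user-supplied offset map,
  not a full mapping service; experimental structures with unmodelled
  loops need a correct map for the alignment numbering.
* Alignments with very sparse columns produce noisy WCS; column coverage
  is reported in the profile but not used to down-weight scores.
* A single dominant patch can absorb neighbouring conserved residues
  (centrality is smooth); iteration mitigates but does not eliminate
  this.
* Tessellation-based accessibility is binary; it does not grade partial
  exposure, and slightly-buried side chains adjacent to surface clefts
  can be classified as accessible.
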