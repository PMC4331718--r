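---
title: "Predicting protein complexes from attributed PPI networks: methods and design notes"
author: "ontoclique"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein complexes from attributed PPI networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoclique)
```

## The model

Protein complexes tend to appear in PPI networks as dense subgraphs whose
members share function. Neither signal alone is reliable: high-throughput
interaction screens are noisy, and functional annotation without topology
over-groups. `ontoclique` combines three ingredients in one graph object,
the *attributed PPI network* `G = (V, E, A_v, A_e, F_v, F_e)`:

* topology — an undirected simple graph of proteins and interactions;
* vertex attributes — each protein's set of GO-slim terms (`F_v`, possibly
  empty);
* edge attributes — the non-empty set of evidence sources supporting each
  interaction (`F_e`), here `T1` (high-throughput) and `T2`
  (literature-extracted), though the data model accepts any number of
  sources.

Three scores connect the ingredients.

**Edge weight.** Each source `T_i` has a contribution weight `w_i` with
`sum(w) = 1`; an edge weighs the sum of the weights of its sources. An
interaction confirmed by every source weighs 1 regardless of `w` — the
weights only arbitrate between partially supported edges.

**Structural correlation `eta(S)`.** For an annotation set `S`, take the
subgraph `G(S)` induced by the proteins annotated with every term of `S`
(isolated vertices included). `eta(S)` is the fraction of `G(S)`'s vertices
lying in a clique of size at least 3 *within* `G(S)`. Because every clique
of size ≥ 3 contains a triangle and every triangle is such a clique, this
equals the triangle-vertex fraction, which is how it is computed (and how
the test suite's independent oracle checks it). `eta` is the prior
plausibility that sharing `S` indicates co-complex membership.

**Clique score.** A clique `C` with common annotation set
`S = intersect(F_v over C)` and weighted density
`2 * sum(Weight(e in C)) / (|C| (|C|-1))` scores
`eta(S) * |C| * |S| * Density(C)`. Cliques with empty `S` score 0 and are
excluded from candidacy: without a shared term the ontology-correlation
machinery has nothing to say about them.

## The two-phase procedure

**Phase 1 — source weighting.** For each source separately: build the
single-source network, generate candidates at equal initial weights, select
disjoint seeds, and compute the contribution degree
`C_Degree(T_i) = sum(score_j * |E_cj|) / |E_Ti|`, where `|E_Ti|` is the
size of that source's *entire* edge set (a literal reading of the
definition: a source is penalized for edges that support no good seed).
Weights are the normalized contribution degrees; if every source has
contribution 0 (no scoring cliques anywhere) the weights fall back to
equal, a case the original procedure never meets but a robust tool must.
Note that in a single-source network every edge weighs 0.5 under the
initial equal weights, so all densities are uniformly halved; this is
accepted as stated since only the *ratio* of contribution degrees matters.

**Phase 2 — prediction.** On the combined network, candidates are all
maximal cliques (pivoted Bron–Kerbosch via `igraph::max_cliques`) of size
≥ 3 with non-empty `S`, ranked by score. Seed selection repeatedly takes
the top candidate, deletes its vertices from every remaining candidate,
drops candidates falling below 3 vertices, re-scores the pruned survivors
(a subset of a clique is a clique; its `S` can only grow, so re-scoring is
required), re-ranks and repeats. Each seed then grows independently: every
adjacent vertex is scored against the *fixed* seed and attached when its
closeness score reaches `extend_thres`.

**Closeness score.** The closeness of vertex `P_k` (annotations `S_k`) to
seed `(C_j, S_j)` is the *product*

```
|S_k ∩ S_j| / (|S_j| + 1)  ×  sum over edges P_k–C_j of Weight(e) / |C_j|
```

Both factors lie in `[0, 1)`, so a high score requires shared annotation
*and* well-supported connectivity, and the score is bounded by
`|S_j| / (|S_j| + 1) < 1`; in particular thresholds above ~2/3 admit
almost nothing, which is why sweeps flatten out at high `extend_thres`. A
consequence worth knowing: an unannotated neighbor can never be attached
(its similarity factor is 0), so unannotated proteins enter predictions
only through seed cliques — and seeds require shared annotations — i.e.
predictions are confined to the annotated part of the network plus nothing.
Unannotated vertices are still retained in the network and are not inert:
because candidacy is restricted to *maximal* cliques, an unannotated
vertex completing a larger clique can absorb an annotated sub-clique into
a maximal clique with empty `S`, removing it from candidacy. This is the
stated behavior of mining maximal ontology-correlated cliques, but it is
worth knowing when annotation coverage is poor.

## Tunable parameters

| parameter | default | meaning / rationale |
| --- | --- | --- |
| `extend_thres` | 0.1 | closeness needed for attachment, in [0, 1]. The sweep protocol (`sweep_extend_thres()`) re-augments fixed seeds per threshold; 0.1 is the default operating point, with small values flooding seeds with neighbors and values above ~0.6 attaching almost none. |
| `na_threshold` | 0.2 | neighborhood-affinity match cut, *strict* (NA exactly 0.2 does not match). |
| `min_clique_size` | 3 | smallest clique that can witness structural correlation (a triangle). |
| `weight_mode` | `"auto"` | `"auto"` runs phase 1; `"equal"` is the no-weighting ablation; `"fixed"` takes user weights (normalized). |
| `seed_method` | `"prune"` | overlap reduction. `"prune"` subtracts seeded vertices as described; `"discard"` instead drops candidates overlapping an accepted seed by ≥ `overlap_threshold` (default 0.5) *and* subtracts residual overlap, since the output must stay disjoint. |
| `digits` (in `clique_score()`) | `NULL` | optional rounding of `eta` and density before composing the score — the reporting convention of the worked-example table, whose printed scores are recomposed from 3-decimal entries (e.g. 1 × 4 × 2 × 0.833 = 6.664, where full precision gives 6.667). Internal arithmetic elsewhere is always full precision. |

## Determinism and numerical choices

Every stage is deterministic. Maximal cliques are ordered by size
descending then lexicographic member tuple; candidates and pruned
survivors by score descending, size descending, member tuple ascending.
Ties therefore always resolve to the lexicographically smallest member
set, and identical inputs give byte-identical outputs across runs (a test
asserts this end to end). `eta` is memoized per distinct annotation set
within a mining pass. Degenerate inputs are contracts, not silent
defaults: empty edge sets, self-loops, non-clique score requests,
zero-edge sources and empty complex lists raise errors; empty *prediction
files* in `run_evaluate()` produce a zero-metric report with a warning,
because a pipeline that predicts nothing is a result, not a bug.

## The synthetic generator

`synthetic_spec()` / `generate_network()` plant `n_complexes` disjoint
complexes (cliques at `p_within = 1`), each annotated with its own
complex-specific term on all members, optionally sprinkled with distractor
terms; background vertices receive random terms; background edges appear
uniformly at rate `p_background`; and every realized edge is observed by
each source according to per-source retention probabilities (an edge seen
by neither source is assigned one at random, keeping `F_e` non-empty).
`add_random_edges()` implements the random-interaction degradation
control, and `two_source_benchmark_spec()` is the preset in which source
T1 is a reliable assay and T2 a noisy one.

What the generator emulates: annotated dense modules observed through two
complementary, differently noisy evidence channels — the structural
assumptions the scoring machinery exploits. What it does not emulate:
overlapping ground-truth complexes, degree-dependent (hub-biased) false
positives, systematic literature-extraction errors correlated with
well-studied proteins, or incomplete/biased annotation coverage of real
GO slims. Passing the synthetic recovery tests therefore shows the
machinery is implemented correctly under its own assumptions, not that
those assumptions hold for any particular organism's interactome.

Two observed behaviors on this benchmark are worth stating plainly, since
the test suite relies on them:

* At zero background noise the planted complexes are recovered exactly
  (recall 1 across seeds): with `p_within = 1` each planted clique is its
  own maximal candidate with a private term.
* Automatic weighting on the biased benchmark drives the weights strongly
  toward the reliable source (around 0.95 / 0.05), but the downstream
  F-score *ties* the equal-weight ablation at the noise levels exercised:
  candidate and seed existence do not depend on the weights, and
  NA-threshold-0.2 matching is insensitive to the one-or-two-member
  attachment differences the weights produce. The directional test
  (auto ≥ equal mean F over 10 seeds) holds with equality; on real,
  incomplete data the weighting has more room to matter than on clean
  planted cliques.

## Problem sizes

The test suite verifies clique enumeration and `eta` against brute-force
subset/triangle oracles on 30+ random graphs of up to 12 vertices (where
exhaustive enumeration is exact and fast), and runs the full pipeline on
synthetic networks of roughly 40–90 vertices across 10 seeds; the whole
suite completes in well under a minute. These sizes were chosen so the
oracles remain exhaustive; the pipeline itself is limited only by maximal
clique enumeration, which is standard at PPI scale (thousands of proteins)
for graphs of realistic sparsity.

## Known limitations

* Annotation terms are opaque labels: no ontology-graph reasoning, no
  term specificity weighting — a shallow GO-slim term counts as much as a
  specific one in `|S|`.
* One ID namespace is assumed across edge lists and annotations; no
  identifier mapping is attempted.
* Seed growth scores neighbors against the immutable seed in one batch.
  An incremental variant (re-scoring after each addition) would need an
  ordering rule to stay deterministic and is not provided.
* Highly overlapping final predictions are not merged; only seeds are
  disjoint by construction.
* The contribution-weight estimate is per-source, not per-edge; a source
  with heterogeneous internal quality is averaged into one weight.
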