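---
title: "Predicting drug-target interactions from a decomposed heterogeneous network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-target interactions from a decomposed heterogeneous network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Drug repurposing asks which approved drugs bind protein targets nobody has
tested them against. Experimentally screening the full drug x target space is
infeasible, so computational drug-target interaction (DTI) prediction ranks
the untested pairs. The working assumption throughout this package is
*guilt by association*: similar drugs tend to interact with similar targets.

heteroDTI treats the data as a heterogeneous network and deliberately
decomposes it into three kinds of sub-network rather than embedding
everything at once:

* a **bipartite interaction network** `G_b` (m drugs x n targets, binary
  weights; every known interaction is a 1, everything else a 0 -- there is no
  missing-value state);
* **drug-drug similarity networks** `G_d` (m x m) and **target-target
  similarity networks** `G_t` (n x n), consumed as precomputed matrices
  (chemical fingerprints, sequence kernels, GO semantic similarity, GIP,
  ...). Computing these similarities from raw structures or sequences is out
  of scope;
* **implicit-transition (Co-HITS) networks** `G_b G_b^T` and `G_b^T G_b`,
  derived from the bipartite network itself, whose entry (i, j) counts the
  partners shared by two same-type entities.

The pipeline has four stages, each exposed as ordinary functions:

1. `train_bine()` learns drug and target embeddings from the bipartite
   network (Co-HITS matrices -> truncated random walks -> skip-gram with
   negative sampling, jointly with a logistic model of the observed edges);
2. `build_composite()` screens the similarity matrices by entropy and
   redundancy and fuses the survivors with similarity network fusion (SNF);
3. `build_all_pairs()` turns vertex embeddings + composite similarities +
   bipartite path counts into one embedding per drug-target pair;
4. `run_cv()` / `case_study()` score pairs with a class-weighted random
   forest and evaluate under cold-start cross-validation.

The method is *transductive*: the entity sets are fixed, embeddings are
learned once over the whole network, and only the labels of unknown pairs
are predicted. Embedding vertices unseen at training time is a non-goal.

## Stage 1: bipartite embedding

**Objective.** Training ascends a three-part objective. For every observed
edge (i, j), the explicit part is `gamma * w_ij * log sigma(u_i' v_j)` with
`sigma` the logistic function -- the gradient step implemented by
`explicit_update()` moves `u_i` by
`lr * gamma * w_ij * (1 - sigma(u_i'v_j)) * v_j` and symmetrically for `v_j`.
The implicit parts maximize, with weights `alpha` (drugs) and `beta`
(targets), the skip-gram likelihood of each walk corpus under negative
sampling; `implicit_update()` implements the standard center/context
two-sided step. The joint probability model behind the explicit term follows
the established bipartite-embedding convention (edge-frequency `P` against
`sigma(u'v)`); the gradient steps above are the binding contract and are
verified against finite differences of the written objective in the test
suite.

**Walks.** Each Co-HITS matrix (diagonal excluded -- a self-transition
carries no information) is converted into a corpus of truncated random walks:
a walk stops at each step with probability `stop_prob` (default 0.15),
otherwise steps to a weight-proportional neighbor, and the chosen step is
replaced by the walk's start vertex with probability `restart_prob` (default
0.7). The high restart rate keeps sequences centered on their start vertex,
which sharpens the local similarity the skip-gram model learns; setting
`restart_prob = 0` gives plain truncated walks and is fully supported. Walks
per vertex scale with Co-HITS centrality (row sum of the walk graph) between
`min_walks = 1` and `max_walks = 32`; the number of walks is not part of the
published hyperparameter profile, so it follows the cited
bipartite-embedding convention and is configurable. A hard length cap
(`max_walk_len = 100`) guards the `stop_prob = 0` corner.

**Numerics.** Embeddings initialize uniformly in `[-0.5/dim, 0.5/dim]`,
context vectors at zero (the usual skip-gram convention; the first implicit
steps then move context vectors first, driven by the initialized centers).
Negative samples are drawn from corpus token frequencies raised to 0.75;
draws colliding with the center or the true context are redrawn a bounded
number of times and dropped if unresolved. Edge and context-pair orders are
reshuffled every epoch under the run seed. `max_iter` counts epochs (full
passes over the edge set and both corpora); the published iteration counts
are interpreted this way.

## Stage 2: composite similarity generation

Real pipelines bring several partially redundant similarity sources per
side. Two screens run before fusion:

* **Entropy screen.** Each matrix is flattened, normalized to sum one, and
  its Shannon entropy (natural log) compared against `c1 * log(k)`, `k` the
  entry count -- `log(k)` is the attainable maximum, reached by a uniform
  matrix. Matrices *above* the threshold (default `c1 = 0.7`, strictly
  greater) are discarded: a near-uniform similarity matrix says every entity
  resembles every other, which carries no discriminative signal. The
  alternative reading of the reference point -- the largest entropy observed
  in the collection -- is available as
  `entropy_reference = "max_observed"`.
* **Redundancy screen.** Matrices are ordered by ascending entropy (ties
  broken lexicographically by name for determinism); scanning from the most
  structured matrix, any later matrix whose redundancy index
  `Es = 1 / (1 + d)` (with `d` the Euclidean distance between flattened
  matrices) exceeds `c2 = 0.6` is dropped. `Es` is 1 exactly for identical
  matrices, so duplicates are removed while genuinely different sources
  survive.

Survivors are fused by SNF cross-diffusion: each view becomes a
row-stochastic full kernel (half the mass pinned on the diagonal) and a
K-nearest-neighbor local kernel; for `t = 20` rounds each view diffuses the
average of the other views through its local kernel
(`P_v <- S_v P_avg S_v'`, then symmetrization), and the composite is the
average of the final views. A single surviving view diffuses against itself,
which makes "fuse one matrix" and "fuse two copies of one matrix" coincide
exactly -- a convenient invariance the tests exploit. Because the inputs are
already similarities, no distance-to-affinity kernel (and hence no kernel
bandwidth) is involved. `K = 20` follows the common SNF default and is
clipped to `k - 1` inside `build_composite()` for small collections.

## Stage 3: pair embeddings

For a pair (d, t), the five nearest drugs of d and five nearest targets of t
are read off the composite matrices (self excluded, zero weights never
padded in). Two components are built per side, exactly as the method's
equations are printed:

* *similarity component*: the entity's own embedding scaled by the sum of
  its neighbor weights;
* *path component*: the partner's embedding scaled by the number of the
  entity's neighbors that are known to interact with the partner (the
  drug-side component counts d's neighbor drugs hitting target t, and vice
  versa).

The per-side components are summed and the two sides concatenated, so pair
embeddings are exactly twice the vertex embedding dimension and linear in
the vertex embeddings. Note the printed equations scale a *fixed* vector by
summed weights -- they do not mix neighbor embeddings. We implement them
verbatim as the default and expose the plausible alternative
(`neighbor_mix = "neighbor_embeddings"`, which averages neighbor vectors by
weight) as an explicit config variant.

**Leakage control.** Pair construction happens after the cross-validation
split. Whether the held-out fold's edges should stay visible to the path
component is ambiguous in the transductive setting; both behaviors are
provided. The default (`masking = "honest"`) zeroes test-fold edges inside
the path counts, which cannot leak labels; `masking = "transductive"`
reproduces the method's whole-network usage, in which pair construction sees
the full interaction matrix. The distinction matters quantitatively. Under
honest masking a cold-start evaluation on block-structured data can only use
block membership, and when edges are independent given blocks no method can
push within-block precision above `p_within` -- an information ceiling on
PR-AUC. The transductive protocol deliberately trades that honesty for the
better use of the fixed pair space (the method's published stance), and is
what the package's benchmark reproduction uses; the honest mode is the
recommended default for judging real generalization. Embeddings themselves
are trained once on the full network by default; `run_cv(honest_cv = TRUE)`
retrains them per fold on training edges only for a fully leakage-free (and
slower) protocol.

## Stage 4: scoring and evaluation

A random forest with 100 trees, Gini splits and fully grown trees
(`min.node.size = 1`, the convention of the reference forest implementation
this mirrors) scores pairs, with class weights inversely proportional to
class frequencies (`n / (2 n_c)`) to counter the heavy negative imbalance of
DTI matrices. Evaluation uses
entity-wise tenfold cross-validation: under the drug-split task all pairs of
one tenth of the drugs form the test fold (the target-split task is
analogous), which measures cold-start generalization rather than
interpolation. PR-AUC is the primary metric -- under strong imbalance it
punishes false positives much harder than ROC-AUC, which is reported as
auxiliary. PR-AUC uses step-wise (average-precision) interpolation over
distinct score thresholds; fold metrics are averaged. The case-study
protocol mirrors realistic discovery: all positives always train, the
unknown pairs are split into ten groups, each group is scored by a forest
trained on everything else, and the top-scoring unknown pairs are reported.

## The synthetic benchmark

`generate_dataset()` plants recoverable structure: drugs and targets are
assigned to `n_blocks` latent classes and interact with probability
`p_within` (matched blocks) or `p_between` (mismatched). The default study
conditions are 60 drugs x 40 targets, 3 blocks, `p_within = 0.3`,
`p_between = 0.01` -- about 10% positive pairs, denser than public DTI
benchmarks but sized so a tenfold cold-start CV still has ~250 positives to
distribute across folds at desk scale.

Similarity sources are *within-block geometric decay profiles*: entities of
a block are ordered and similarity decays as `rho^distance` (rho between 0.2
and 0.3 across sources, so sources agree on the block structure without
being redundant), perturbed by multiplicative truncated-Gaussian noise
(default sd 0.1; multiplicative so that cross-block zeros stay zero).
A deliberate design point: a plain block-indicator matrix with blocks this
large would have flattened entropy above `0.7 log(k)` and the entropy screen
would discard *every* informative matrix -- the screen, taken at its
published threshold, only admits matrices whose similarity mass is
concentrated. The decay profile emulates what real chemical or sequence
similarity matrices look like after normalization (a few strong neighbors
per entity, a long near-zero tail) and keeps the screen's expected behavior
analytically predictable: injected near-uniform matrices sit at maximal
entropy and are removed by the entropy screen; injected near-duplicates
(copies of the first source with a small half-normal floor, which keeps
their entropy strictly above their source's) are removed by the redundancy
screen, never instead of their original.

`holdout_fraction` hides a fraction of realized positives from the emitted
network and records them as ground truth. For hidden-positive retrieval the
package's benchmark uses denser blocks (`p_within = 0.8`): with sparse
blocks a hidden positive is statistically exchangeable with every other
unobserved within-block pair -- its edge was removed before any stage saw
it, so no method could single it out. Retrieval into the top decile is only
identifiable when the within-block unknowns fit inside the decile, i.e.
`m*n*(1 - p_within)/n_blocks <= m*n*(1 - p_within/n_blocks)/10`, which at
the 60 x 40 x 3-block scale requires `p_within >= 0.78`. Any vertex isolated by
edge-sampling or holdout is re-wired with one random edge (the benchmark
property that every node has at least one interaction; held-out pairs are
never re-added).

What the generator does *not* emulate: continuous similarity distributions
of real fingerprints, hub drugs with hundreds of targets, correlated noise
between sources, or biased discovery (positives are missing at random here).
Passing tests therefore demonstrate that the machinery recovers clean
planted structure, not that it matches published benchmark figures.

## Problem sizes and runtime

The shipped tests and the acceptance script run the full pipeline at the
60 x 40 default scale with the default hyperparameter profile (dim 64, 100
epochs), which takes a few minutes on one core; unit tests use smaller
instances (tens of entities, dim 6-16, a handful of epochs). All stages are
single-threaded and bit-reproducible from one master seed, from which each
stage derives its own seed by fixed offsets.

## Known limitations

* Transductive by construction: adding a new drug or target requires
  retraining.
* The entropy screen at `c1 = 0.7` rejects any similarity source whose mass
  is spread over more than roughly `k^0.7` entries; dense continuous
  similarity matrices may need `entropy_reference = "max_observed"` or a
  higher `c1`.
* The gradient inner loops are compiled, but pair construction materializes
  the full `(m*n) x 2dim` feature matrix; at DrugBank scale (1482 x 1408
  drugs x targets) that is ~2 GB per fold and would want a blocked
  implementation.
* The case-study protocol scores each unknown pair with a forest that saw
  the other nine groups' unknowns as negatives; scores are comparable within
  a run but are not calibrated probabilities of interaction.
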