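---
title: "Pattern-constrained random walks for knowledge-graph link prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern-constrained random walks for knowledge-graph link prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patternwalk)
```

## The problem

Understudied ("dark") kinases carry few annotations, so they sit in sparse
corners of any knowledge graph (KG) built from curated resources.  Direct
lookup cannot place them in pathways; what remains is their *context* —
interaction partners, shared domains, GO terms, PTMs.  `patternwalk`
propagates that context: it samples random walks constrained to walk shapes
that are informative for a chosen link type, embeds nodes from the walk
corpus with a skip-gram model, and casts link prediction as binary
classification of node-pair features.

## The walk model

A KG here is an undirected-traversable multigraph with typed nodes
(`Protein` with `DarkKinase`/`LightKinase` subtypes, `Pathway`, GO
namespaces, `FunctionalDomain`, `PTM`, `Chemical`, `Disease`, ...) and
typed edges.  Walks are constrained by a *regular pattern* over node-type
labels; the default for protein-to-pathway prediction is

```
Protein [^Pathway]+ Protein Pathway
```

start at a protein, cross one or more non-pathway nodes, then a protein
immediately followed by a pathway.  Unlike a fixed meta-path, a single
pattern covers walks of many shapes and lengths.  The pattern is compiled
(Thompson construction, then subset construction) to a DFA whose undefined
transitions carry zero probability.  Pattern labels are expanded through
the type hierarchy at compile time, so a `DarkKinase` node is admitted
wherever `Protein` is written.

Each admissible step from node $v^i$ in DFA state $s$ is sampled with an
inverse-degree bias.  Writing $g(r)$ for the fraction of $v^i$'s incident
edges carrying relation $r$ and $|N_v|$ for the degree of $v$, the
two-stage default first draws a relation $r$ with probability proportional
to $g(r)$ (restricted to relations with at least one admissible neighbor),
then a neighbor $v^{i+1}$ within $r$ with probability proportional to
$1/|N_{v^{i+1}}|$, normalized among the relation's admissible neighbors.
Two natural readings of this bias exist; the other one normalizes
$g(r)\,/\,|N_{v^{i+1}}|$ jointly over all admissible steps, and is
available as `bias = "single-stage"`.  The two agree whenever one relation
is in play; we default to the two-stage form because it keeps the
relation-choice and node-choice semantics separate, and we expose the
alternative rather than silently picking one.  A `"uniform"` mode (uniform
over admissible steps) exists as the no-bias control; on hub-skewed graphs
the inverse-degree bias measurably lowers the mean degree of visited
nodes, which is the point: hubs would otherwise dominate the corpus and
drown out low-degree dark nodes.

When a walk reaches an accepting state with budget remaining, the terminal
node is emitted a second time and the walk continues *in reverse* through
the pattern positions: the DFA state stack recorded on the way forward is
popped one position per step, and at each reversed position any neighbor
whose label reproduces the recorded state path may be chosen — not
necessarily the node visited on the way forward.  This harvests additional
context around the terminal node, which matters most where data are
sparse.  One reversal pass is performed per walk; nothing in the model
motivates oscillating forward again, and a single pass keeps walks within
the length budget.  A walk that gets stuck before acceptance is kept,
truncated: those prefixes still carry usable context.

## Hyperparameters

| parameter | default | meaning |
|---|---|---|
| `walk_length` (L) | 5 | nodes collected per walk; 5 follows the method's illustrative walk diagrams, and short walks suit the short pattern |
| `num_walks` (NW) | 40 | walks per eligible start node; 40 is where replicate overlap stabilises in the robustness sweep |
| `dim` (d) | 128 | embedding dimension, the word2vec/metapath2vec lineage default |
| `window`, `negative`, `epochs` | 5, 5, 5 | standard skip-gram settings; all config-exposed |
| `holdout_fraction` | 0.5 | fraction of target-relation edges held out for evaluation |
| confidence cutoff | 0.95 | strict (`>`) threshold on reported predictions |

Walks are seeded per (start node, repetition) by a documented counter
scheme (`derive_seed`), so corpora are byte-reproducible and independent
of generation order; the master seed fans out to the split, the embedding
and the negative draws.

## Embedding

Skip-gram with negative sampling is trained single-threaded in C++ over
the walk lines, with its own RNG stream, so a fixed seed reproduces the
matrix bit for bit.  Negative targets come from a unigram$^{0.75}$ table.
With `type_coarsening = TRUE` negatives are drawn within the coarse group
of the output node, using the three-way grouping Protein / Pathway /
Others — the heterogeneous variant; it is opt-in because the plain
objective is the well-understood default and the grouping is otherwise an
analysis-time device (it also colors the PCA diagnostic in
`plot.patternwalk`).  The returned representation is the *sum* of a
node's input and output vectors.  The sum preserves the shared-context
similarity that the input matrix carries and adds first-order
co-occurrence similarity, which the input matrix alone provably lacks in
degenerate corpora (two nodes that only ever co-occur with each other
have disjoint contexts, so their input vectors never align);
`vectors = "input"` restores the input-only convention.

## Link prediction

A pair (protein, pathway) is featurized as the Hadamard (elementwise)
product of its embeddings.  Positives are the relation's edges; negatives
are typed non-edges sampled under the closed-world assumption, count
matched to the positives, distinct, and disjoint from all known positive
edges.  The classifier is logistic regression with a light ridge penalty
($\lambda = 1/n$), which keeps the fit defined when the classes are
linearly separable; a one-vs-rest mode trains one binary model per pathway
with per-class negatives drawn from the other classes' positives, matching
counts.  The binary mode is the default — both formulations are natural,
and binary matches the evaluation protocol below.

The fit holds out 50% of the relation's edges *before* walking, so held
out links cannot leak through the corpus into the embedding.  AUC is
computed as the Mann-Whitney rank statistic and F1 at the 0.5 threshold;
10-fold cross-validation runs on the training half only, with the holdout
scored once — cross-validating on everything would mix the two.  Negative
sampling in the pipeline is restricted to the embedding vocabulary
(pairs outside it cannot be featurized), and in synthetic benchmarks the
planted-but-withheld dark memberships are passed as `forbidden_negatives`
so that pairs known (to the generator) to be true are not mislabeled as
negatives during either training or evaluation.

Robustness across the stochastic stages is summarised by replicate
overlap: fit the model several times under identical hyperparameters but
different seeds, keep predictions above the cutoff, and report per protein
the count of predictions present in every replicate and that count over
the protein's unique predictions across replicates (and the global
"all overlap" intersection across every run of an NW sweep).

## The synthetic generator

`generate_synthetic_kg()` plants the structure the method is supposed to
exploit: pathways with protein members that share context nodes (GO
terms, domains, PTMs, chemicals, diseases) and within-pathway PPIs; a
`dark_fraction` of members (default 20%) lose their direct pathway edge —
recorded in the ground truth, absent from the graph — while keeping
context and PPIs; a decoy hub layer with power-law degrees exercises the
inverse-degree bias.  Defaults (3 pathways x 30 proteins, seed 17) are
the package's benchmark condition: large enough that embeddings separate
the communities, small enough for test suites.  Shared context nodes are
the main signal carrier because walk tracing attributes predictions to
shared intermediates; PPIs are a secondary carrier.

What the generator does *not* emulate: real annotation noise and bias,
overlapping pathway membership, the six-orders-of-magnitude scale of a
production KG, or correlated evidence between sources.  Passing the
recovery benchmark therefore shows the machinery is sound — constrained
sampling, embedding, classification and bookkeeping do what they claim —
not that real-KG headline numbers transfer.

## Numerical and policy choices

* All curation thresholds are strict inequalities ("more than 700" keeps
  701, not 700); confidence cutoffs likewise.
* Degree counts incident edges (parallel edges included), the same
  convention $g(r)$ is defined over.
* Node self-loops are rejected at load; the type-level loop (PPI at the
  `Protein` type) is schema structure, not an instance self-loop.
* Ordering is deterministic (sorted ids) everywhere order is observable;
  ties in AUC rank count one half.
* Hierarchy pruning of pathway tables takes explicit exclude/keep root
  sets (keep overrides exclude) rather than a depth cutoff: both the
  "whole subtree" and "children only" readings of removing over-general
  pathways are expressible.
* `relation_profile` is undefined (an error) on isolated nodes, and an
  empty transition table is the stuck-walk signal, not an error.

## Problem sizes in the test suite

The suite compiles each tested pattern against an exhaustive
recursive-descent matcher on all 5,461 strings of length at most 6 over a
4-letter alphabet; validates more than 10,000 seeded walks step by step
against the DFA and the reversal rule; checks the step distribution in
exact integer arithmetic and against 100,000 sampled first steps on a
controlled star; and runs the full recovery benchmark at the default
synthetic condition (holdout AUC at least 0.85, F1 at least 0.75, dark
recovery at least 80%).  These sizes were chosen as the smallest that make
the respective checks decisive.

## Known limitations

Edge types do not enter the pattern language (only endpoint node types
constrain walks).  Classifier probabilities are not calibrated; the 0.95
cutoff is a ranking device, not a posterior.  Whether a reverse walk may
re-reach a terminal type and reverse again is undefined in the model
description; this implementation performs a single reversal pass and
documents it.  The one-vs-rest mode inherits the class imbalance of
whatever pathway set it is given.
```{r session}
sessionInfo()
```
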