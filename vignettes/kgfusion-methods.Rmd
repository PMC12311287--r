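---
title: "Hybrid semantic-structural knowledge graph completion with kgfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid semantic-structural knowledge graph completion with kgfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgfusion)
```

## The problem

Biomedical knowledge graphs store facts as triples $(h, r, t)$ over entities
such as diseases, genes, drugs and chemicals. Both completion (predicting a
missing direct link) and reasoning (inferring a multi-hop consequence)
reduce to answering queries $(q_e, q_r, ?)$: rank every entity as a
candidate tail. Two families dominate: knowledge-embedding models, which
score triples from learned latent vectors and capture global semantics but
ignore multi-hop structure, and graph neural networks, which propagate
messages along edges and capture local structure but little global context.
`kgfusion` implements a hybrid of the two in which the embedding model
initializes and continuously steers the propagation, and the final score
fuses both branches.

## The model

**Global semantics (CP branch).** The graph's adjacency tensor is
factorized canonically (CP) into three matrices $E_h, E_r, E_t$ with shared
dimension $D$; the semantic compatibility of a triple is the trilinear
product
$$\phi(h, r, t) = \sum_{d=1}^{D} e_h(d)\, e_r(d)\, e_t(d).$$
The factors are free parameters trained jointly with everything else (no
separate ALS or pretraining phase; an optional CP-only warm start is exposed
via `warmupEpochs` and defaults to 0). `cpScore()` accepts an explicit
relation vector so a *refined* relation embedding can stand in for the
stored row.

**Query-guided subgraph propagation (structural branch).** Starting from the
frontier $\{q_e\}$, each of $\ell$ layers (i) expands all outgoing augmented
edges of the frontier, (ii) refines relation embeddings, (iii) passes
query-attentive messages, and (iv) keeps the top-$K$ candidates by a learned
relevance score. Message passing is
$$h_t^{(\ell)} = \tanh\Big(W^{(\ell)} \sum_{(h,r,t)} \alpha_{h,r,t}
\big(h_h^{(\ell-1)} + e_r^{(\ell)}\big)\Big), \qquad
\alpha = \sigma\big(w_\alpha^\top \mathrm{ReLU}(W_\alpha (h_h^{(\ell-1)} +
e_r^{(\ell)} + e_{qr}^{(\ell)}))\big).$$
We read the attention nonlinearity $\sigma$ as a per-edge logistic gate, not
a softmax over the edge set: nothing in the formulation normalizes over
edges, and the per-edge gate is what the propagation lineage this design
follows (RED-GNN, AdaProp) uses. This choice is deliberate and tested;
changing it would require re-validating the acceptance runs.

**Contextual relation refinement (CRR).** Relation meaning depends on the
entities involved, so a gated recurrent (LSTM) cell re-embeds each edge
relation once per layer with the *static* head-entity embedding as hidden
state, and likewise the query relation with the query-entity embedding:
$e_r^{(\ell)} = \mathrm{LSTM}(e_r^{(\ell-1)}, e_h)$. Design choices made
where the formulation is open:

* the cell state is reset to zero at every call — the recurrence has two
  arguments and no carried cell, so statefulness across layers is not
  introduced. A consequence is that the forget gate multiplies a zero cell
  and its weights receive no gradient; the gate is kept because it is part
  of the standard cell.
* one shared set of gate weights serves both edge and query refinement (the
  dual application of one mechanism), and the weights are shared across
  layers; per-layer parameters would inflate the model without support in
  the formulation.
* the hidden state is the static CP row $e_h$, not the evolving node
  representation, matching the formulation's wording; at layer $\ell$ an
  edge's embedding is therefore the $\ell$-th iterate of a fixed map, which
  the implementation computes batched per unique (head, relation) pair.

**Top-K relevance filtering.** Candidate scores $s_t = W_{\mathrm{samp}}
h_t^{(\ell)}$ pick the $K$ most relevant nodes. The relevance vector is
initialized equal to the readout vector $w$ (they decouple freely during
training): at the start of optimization the filter then keeps exactly the
nodes the readout scores highest, so the selection and scoring heads
bootstrap each other instead of fighting — with an uninformative filter
the answer falls out of the subgraph for a fraction of queries and the
readout receives correspondingly less signal. At inference the selection
is the exact top-$K$ with ties broken by ascending entity index (runs are
reproducible). During training each score is perturbed with
`temperature * Gumbel(0,1)` noise and $K$ iterative hard argmax selections
are taken without replacement; the forward pass is always a valid hard
selection, while the backward pass routes gradient to the scores through
the softmax relaxation of each selection step (straight-through). The
query node is always retained in the frontier regardless of its score, so
the subgraph cannot detach from the query; a message is logged when the
rule fires.

**Hybrid score and loss.** The final score fuses the structural readout
$f = w^\top h_{qa}^{(\ell)}$ (zero for entities outside the final subgraph
— zero rather than $-\infty$ so the full-vocabulary softmax stays finite
and the semantic branch can still rank unreached entities) with the
semantic score $\phi$ computed using the refined final-layer query
relation:
$$\tilde f = \lambda f + (1 - \lambda)\, \phi, \qquad \lambda \in [0, 1].$$
Training minimizes the multi-class log-loss over all entities plus
$\gamma$ times an N3 penalty (sum of cubed absolute values) on the query
entity, refined query relation and answer entity embeddings; L1/L2
alternatives are selectable via `regKind`. The softmax denominator spans
every entity including other true answers; filtering applies only at
evaluation, which uses the standard filtered protocol with *pessimistic*
tie handling (the answer loses ties), the strictest convention.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `D` | 32 | embedding dimension (published configuration) |
| `nLayers` | 6 | propagation layers (published configuration) |
| `K` | 100 | frontier size kept per layer, constant across layers |
| `lambda` | 0.7 | fusion weight between branches (published configuration) |
| `gamma` | 0.01 | regularization strength |
| `temperature` | 1.0 | Gumbel perturbation scale; no annealing by default |
| `temperatureFinal` | NULL | if set, geometric annealing target across epochs |
| `lr` | 0.001 | Adam step size |
| `clipNorm` | 1.0 | global gradient-norm clip (Inf disables) |
| `batchSize` | 16 | queries per gradient step (published configuration) |

The experiment scripts in this package use smaller problem-matched values
(see below); `kgConfig()` documents every field.

## Training mechanics

Gradients are computed by a small reverse-mode tape built into the package
(R has no automatic differentiation substrate); the tape processes a whole
query batch at once, sharing relation refinement across queries per unique
(head, relation) pair. Its forward value is tested to agree exactly with
the composition of the modular per-query operations, and its analytic
gradient is tested against central finite differences of that independent
modular path (relative error below $10^{-4}$).

Two details of the training loop are the package's own design choices:

* **Query-edge masking.** A training query's own answer edge (and its
  inverse) is excluded from expansion for that query. Training triples are
  also graph facts, and without masking the propagation branch simply
  learns to copy the direct edge, which generalizes to nothing; masking
  forces path-based reasoning and is the standard practice in the
  propagation lineage the model builds on.
* **Inverse queries.** For every training fact $(h, r, t)$ the inverse
  query $(t, r_{\mathrm{inv}}, ?)$ is trained as well (toggle
  `inverseQueries`), consistent with reverse-relation augmentation.

Optimization details that proved load-bearing on the synthetic study
conditions: the loss surface of the coupled recurrent/propagation model is
sharp (a vanilla gradient step descends at small step sizes but overshoots
an order of magnitude higher), so global gradient-norm clipping
(`clipNorm`) is on by default; and the gated cell's input/output gate
biases initialize at +1 (open gates), the standard recurrent-network
device that keeps repeated refinement roughly norm-preserving — with
closed-gate initialization the relation embeddings contract toward zero
across layers and the deep layers receive neither signal nor gradient.
Optional geometric temperature annealing (`temperatureFinal`) moves
selection from exploratory to score-driven across training.

Early stopping monitors validation MRR every `evalEvery` epochs with
patience `patience`; the best-validation parameters are restored. All
randomness (initialization, shuffling, Gumbel noise) derives from
`config$seed`, so a run is exactly reproducible, and evaluation is
deterministic.

## Ablation variants

Four variants isolate the components: `no_gsp` removes propagation
entirely (scores are raw CP — the scale factor $(1-\lambda)$ is dropped
deliberately: irrelevant to ranking, and the variant is then exactly the
standard factorization model); `random_query` replaces the query entity and
relation embeddings with frozen random vectors drawn at initialization
(the strictest reading of "randomly initialized" replacement — they never
train, so semantic alignment stays disrupted); `no_crr` turns the refiner
into an exact identity at every layer; `no_phi` forces $\lambda = 1$ and
drops the semantic branch from the score while the loss keeps its
regularizer. All four are exact behavioral switches, tested as such.

## Synthetic data: what it emulates and what it does not

Real benchmark graphs (disease–gene, protein–chemical, ontology triples)
require external downloads; the package instead ships two seeded
generators that plant exactly the two kinds of structure the model's
branches assume, so each branch can be stress-tested in isolation —
mirroring the ablation logic:

* `generateCpKG()` plants rank-`cpRank` CP factors and emits every triple
  whose planted trilinear score clears the quantile threshold matching the
  requested density. A factorization model should recover these links; a
  purely structural model has no path signal to exploit.
* `generateRuleKG()` samples random body facts and materializes every
  rule-head triple implied by composing them (e.g. $r_3 \Leftarrow r_1
  \circ r_2$); a held-out fraction of rule heads becomes the validation
  and test queries, with their edges removed from the graph, so answering
  them requires genuine multi-hop composition. Noise facts are injected at
  `noiseRate`, never colliding with held-out triples.

The default rule spec (50 entities, 3 base relations, one rule of body
length 2, density 8 facts per entity, 5% noise, seed 7, splits
0.8/0.05/0.15) yields roughly a hundred held-out test queries. Entity
names carry biomedical-style prefixes purely cosmetically. What the
generators do **not** emulate: the heavy-tailed degree distributions,
relation heterogeneity and ontology hierarchies of real biomedical graphs.
Passing the synthetic recovery experiments shows the machinery optimizes
and generalizes as designed; it does not certify performance on any real
dataset.

The background-fact cap used on real data (supplementary sample limits) is
exposed in spirit through the generator's density/noise parameters; the
package makes no claim about which sampling rule the original protocol
used.

## Numerical choices and degenerate inputs

* Index layout is 1-based throughout (the R convention): base relations
  $1..n$, inverses $n{+}1..2n$, identity $2n{+}1$.
* Vocabularies sort by radix (byte) order, so builds are locale-independent
  and byte-identical across runs.
* `logLoss` uses a shifted log-sum-exp; non-finite scores are an error, and
  training aborts with a diagnostic on a non-finite loss.
* Ties in top-K selection and in ranking break by ascending entity index
  (selection) and pessimistically (ranking).
* An empty frontier (possible only in degenerate graphs without identity
  augmentation) stops propagation with a warning and keeps the last
  non-empty layer.
* `nLayers = 0` returns the query node alone with its initial
  representation.
* Embeddings are not L2-normalized or bounded beyond the chosen
  regularizer; nothing in the formulation requests it.
* The N3 penalty uses the refined final-layer query relation
  $e_{qr}^{(\ell)}$ (as printed in the formulation), not the static row.
* The reported subgraph's edge set defaults to all traversed edges among
  the finally selected nodes across layers (`subgraphEdges = "all"`); the
  alternative reading (final layer only) is a config flag.

## Experiment scale

The shipped experiments (tests and `scripts/acceptance.R`) run at sizes a
laptop CPU handles comfortably: rule-structured graphs of 50 entities with
$D = 16$, $\ell = 3$, $K = 20$, and planted-CP graphs of 40 entities at
rank 4 with a CP-only model, three seeds each. These sizes are the
package's chosen study conditions for demonstrating link recovery and the
ablation ordering (full model above its CP-only ablation); the published
configuration ($D = 32$, $\ell = 6$) remains the default of `kgConfig()`
for real-scale use.

## Known limitations

* **Over-smoothing on dense miniature graphs.** Propagation aggregates
  unnormalized sums of attention-gated messages, so on a graph whose
  degree is a large fraction of its entity count every node's
  representation mixes most of the graph after two layers, and running
  one layer beyond the planted rule's body length re-mixes the signal the
  readout needs. In the package's own experiments the full model solves
  sparse rule graphs essentially perfectly at a depth matching the rule
  length, while on the default dense 50-entity conditions at three layers
  the structural branch stops improving over the CP-only ablation — the
  acceptance script reports both numbers side by side. Real biomedical
  graphs are orders of magnitude sparser relative to their entity count,
  which is the regime the propagation design (and its published depth of
  six) assumes; treat the dense miniature setting as a stress test of the
  machinery, not as the architecture's operating point.
* Training cost grows with frontier size times edge density; the pure-R
  tape is sized for the synthetic study conditions, not for graphs with
  hundreds of thousands of facts.
* The straight-through gradient of the top-K selection is a biased
  estimator (forward hard, backward soft); this is inherent to the method,
  not an implementation artifact.
* GRU or vanilla-RNN refiners are not provided; the refiner sits behind a
  class that could host them.
* Background facts (`facts.txt`) shape the graph but contribute no
  training queries, and known-answer filtering uses the three query splits
  only.
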