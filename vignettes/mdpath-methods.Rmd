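---
title: "Metapath-aggregated attention for microbe-disease association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metapath-aggregated attention for microbe-disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Microbial communities influence the onset and course of many diseases,
and microbes also modulate (and are modulated by) drugs. `mdpath`
predicts unobserved microbe-disease associations from three undirected,
unweighted relations — microbe-disease, microbe-drug and disease-drug —
assembled into a tripartite heterogeneous network. Known associations
form a binary matrix $B \in \{0,1\}^{n_m \times n_d}$; link prediction
means scoring the zero cells of $B$.

## The model

Each node type $a$ (microbe, drug, disease) starts from a learned linear
projection of its one-hot encoding, i.e. a free embedding row
$h_i^0 = W_a X_i^a \in \mathbb{R}^d$. One aggregation layer then has
three stages, repeated $L$ times.

**Metapath instance encoding.** A metapath is a type pattern such as
microbe-drug-microbe (`m-c-m`); an instance is a concrete node sequence
following it, and intermediate nodes are kept, not discarded. An
instance $(th_1, \dots, th_n)$ is encoded with a relational-rotation
(RotatE-style) recursion in complex space,
$$o_1 = h_{th_1}, \qquad o_t = h_{th_t} + o_{t-1} \odot r_{t-1}, \qquad
h_{M(i,j)} = o_n / n,$$
where each relation vector $r$ has unit modulus coordinate-wise. The $d$
real coordinates are read as $d/2$ complex pairs, and relations are
stored as phase angles, so unit modulus is structural rather than
penalised; traversing a relation in the opposite direction applies the
conjugate (negated phase). Phases are shared across layers: they encode
relation semantics, which we take to be layer-independent. Dividing the
final accumulator by the instance length keeps encodings on the scale of
single node embeddings regardless of metapath length. With all phases
zero the recursion collapses exactly to the arithmetic mean of the node
vectors — the `avg` ablation — which the test suite exploits as an
identity check.

**Intra-metapath attention.** For a target node $i$ and metapath $M$,
every sampled instance is scored per head $k$ as
$e = \mathrm{LeakyReLU}(\delta_k^\top [h_i \| h_{M(i,j)}])$ (slope
0.01), normalised by a softmax over $i$'s instances, and the encodings
are aggregated with those weights followed by an ELU. When several
instances connect $i$ to the same neighbour $j$, each instance is a
separate attention term — the normalisation runs over instances, not
distinct endpoints. The $K$ heads are concatenated at full width, so the
per-metapath vector has dimension $K d$ and the layer's output matrix
$W_o^l$ maps $K d \to d$. (An alternative would be to give each head
dimension $d/K$ so the concatenation stays at $d$; with the default
$d = 32$, $K = 6$ that is not integral, and full-width heads with a
projecting output map are the convention in metapath-aggregation
networks, so we use them.) A node with no instance of a metapath falls
back to a self-instance — the length-1 sequence containing only the node
— so every node always receives an embedding.

**Inter-metapath (semantic) attention.** Each metapath $M_p$ of a type
is summarised by $s_{M_p} = \frac{1}{|V_a|}\sum_i \tanh(W_a h_i^{M_p} +
b_a)$, scored as $e_{M_p} = c_a^\top s_{M_p}$, and the softmax weights
$\beta$ fuse the per-metapath vectors. Because the summary is
type-level, $\beta$ is shared by all nodes of the type; per-node
semantic attention is a known alternative, but we implement the
type-level form exactly. The layer ends with
$h_i^l = \mathrm{ELU}(W_o^l \, h_i^{M_a})$, and the final embedding is
the last layer's output, $h_i = h_i^L$.

**Scoring and loss.** A pair is scored by
$C_{md} = \sigma(h_m^\top h_d)$ and trained with binary cross-entropy
$-\sum_{\mu} \log C_{md} - \sum_{\mu^-} \log(1 - C_{md})$ over observed
positives and sampled negatives.

## Metapath catalog

Microbes use `m-c-m` and `m-d-m`; diseases use `d-m-d` and `d-c-d`.
Drugs appear in those metapaths only as intermediates, which leaves
their layer-$l$ embeddings undefined in a multi-layer model; we
therefore also refresh drugs with the symmetric `c-m-c` and `c-d-c`
metapaths. The catalog is configurable (`metapaths` in
`training_config()`), and schemas up to length 5 are supported.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `hidden_dim` | 32 | embedding dimension $d$ (even; complex pairing) |
| `heads` | 6 | attention heads $K$ |
| `attention_dim` | 64 | dimension of the semantic attention vector $c_a$ |
| `neighbors` | 150 | max instances sampled per node per metapath |
| `layers` | 2 | stacked aggregation layers $L$ |
| `dropout` | 0.5 | on attention coefficients and layer inputs, training only |
| `lr`, `weight_decay` | 0.005, 0.001 | Adam settings |
| `epochs`, `patience` | 100, 5 | cap and early stopping on validation AUC |
| `neg_ratio` | 1 | negatives per positive |
| `split` | 0.8/0.1/0.1 | train/validation/test fractions |

Hidden dimension, head count, attention dimension and the 150-instance
cap follow the sensitivity analysis of the underlying method; the layer
count is never stated there, and 2 is our choice (exposed in the
config). The attention-vector dimension is applied to the semantic
attention $c_a$; the instance-attention vectors $\delta_M$ are sized by
the concatenation they score ($2d$). Learning rate, weight decay and the
early-stopping criterion (validation AUC, patience 5) are unstated in
the protocol we follow; the defaults are conventional for attention
GNNs. "Training 100 times" is read as 100 epochs, not 100 restarts.

## Training protocol

Negative sampling happens once, before splitting, so validation and
test negatives are fixed. The split is stratified per label. By default
validation and test *positive* edges are removed from the
message-passing graph during training (`mask_eval_edges = TRUE`):
held-out links otherwise leak into the metapath instances and inflate
held-out metrics. The protocol we implement does not state this removal;
the flag documents and controls the choice. Instance sampling is
re-drawn each epoch from the full enumeration (cap `neighbors` per
node); `freeze_sampling = TRUE` fixes one draw for exact
reproducibility studies. All randomness — negatives, split,
initialisation, dropout, per-epoch sampling — derives from the single
`seed`, so runs are bit-reproducible.

Gradients are computed by a hand-written reverse-mode pass that mirrors
the vectorised forward computation (including through the rotation
phases, the group-wise softmax and the dropout masks); the test suite
verifies every parameter family against central finite differences, and
the layer output against a naive straight-line implementation.

## Ablation variants

* `nb` — instances are encoded from target and endpoint only; the
  composite rotation (sum of the step phases) is still applied, but
  intermediate node features are dropped.
* `sm` — a single metapath per type; the singleton catalog is chosen by
  best validation AUC among the candidates.
* `avg` — the mean encoder replaces the rotation encoder.

## The synthetic generator

`generate_synthetic()` plants `n_blocks` communities spanning all three
node types and links every cross-type pair with `p_in` within a block
and `p_out` across blocks. The defaults (150 microbes, 40 drugs, 60
diseases, 3 blocks, `p_in = 0.3`, `p_out = 0.02`, seed 1) form the
standard fixture used by the test suite. This is the simplest structure
that makes all four default metapaths informative: same-block microbes
and diseases share drug neighbourhoods, so the association signal is
transitive through intermediates, exactly the regime metapath
aggregation targets.

What the generator does *not* emulate: heavy-tailed degree
distributions, ontology-linked identifiers, relation-specific densities,
or the extreme sparsity of real catalogs (the integrated real dataset is
~0.7% dense; the fixture is ~11% so that a 150-node problem still
contains signal). Passing tests on the fixture therefore demonstrate
correct mechanics and structure recovery, not real-data performance.

A property worth being explicit about: because the generator draws
edges independently given blocks, the best possible held-out score for
a cell depends only on block co-membership and takes just two values.
With the default parameters the positive test pairs are in-block with
probability $\approx 0.88$ and uniformly sampled negatives with
probability $\approx 0.26$, which caps the achievable held-out AUC of
*any* method near $0.81$ in the large-size limit (perfect block
recovery, ties counted one half). The fixture is therefore a mechanics
benchmark with a known ceiling, and measured AUCs just below that
ceiling indicate essentially complete recovery of the planted
structure. On this fixture all four variants operate near the same
ceiling, so ablation orderings are dominated by noise — unlike on real
data, where metapaths carry complementary information.

## Numerical choices and degenerate inputs

* Softmax normalisations subtract the per-group maximum before
  exponentiation; attention weights sum to 1 within $10^{-6}$.
* Scores numerically equal to 0 or 1 are clamped by $10^{-12}$ in the
  loss (with a message), keeping it finite.
* Ranking ties are broken lexicographically by microbe id, so candidate
  tables are deterministic.
* Nodes absent from every edge list can be declared via the catalog
  argument and participate through the self-instance fallback.
* A non-finite training loss aborts with a diagnostic rather than
  continuing.
* The per-epoch evaluation pass runs without dropout.

## Problem sizes used by the test suite

Unit tests run on networks of 8-40 nodes, where brute-force oracles
(depth-first instance enumeration, complex-arithmetic encoding,
all-pairs AUC) are exact and fast. The acceptance-style checks train the
full model and its `sm` ablation on the 250-node default fixture for up
to 100 epochs with early stopping, three training seeds each — sizes
chosen so the whole suite completes in minutes on one CPU while still
exercising every stage at realistic density.

## Known limitations

* Full-graph gradient descent only; no minibatching. Scaling to the
  integrated real catalog (~3,000 nodes, dense metapath neighbourhoods)
  works but is slow in pure R; the 150-instance cap is what keeps cost
  bounded.
* Transductive only: a microbe or disease absent from training receives
  an embedding only through its typed catalog entry and self-instances.
* No edge weights, no directed relations, no metapaths longer than 5.
* The `sm` variant's singleton selection retrains per candidate, which
  multiplies its cost by the catalog width.
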