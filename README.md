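# mdpath

Microbe-disease association prediction on a tripartite
microbe-drug-disease heterogeneous network, using a metapath-aggregated
graph attention model.

## The problem and the model

Imbalances of the human microbiome are implicated in many diseases, and
microbes interact with the drugs used to treat those diseases.
`mdpath` integrates three undirected, unweighted relations —
microbe-disease associations, microbe-drug interactions and
disease-drug interactions — into one tripartite network, learns
embeddings for every node, and scores unobserved microbe-disease pairs
by reconstructing the binary association matrix
*B* ∈ {0,1}<sup>*n*<sub>m</sub> × *n*<sub>d</sub></sup>.

Embeddings are learned layer-wise. Within each layer, for every
metapath (a node-type pattern such as microbe-drug-microbe):

1. **Instance encoding** — each metapath instance
   (*th*₁, …, *th*<sub>n</sub>) is encoded by a relational-rotation
   recursion in complex space,
   *o*₁ = *h*<sub>th₁</sub>, *o*<sub>t</sub> = *h*<sub>th_t</sub> +
   *o*<sub>t−1</sub> ⊙ *r*<sub>t−1</sub>, output *o*<sub>n</sub>/*n*,
   with unit-modulus relation vectors *r* stored as phase angles, so the
   order of nodes along the path matters and intermediate nodes
   contribute.
2. **Intra-metapath attention** — per head,
   *e* = LeakyReLU(δᵀ[*h*<sub>i</sub> ∥ *h*<sub>M(i,j)</sub>]),
   softmax-normalised over the node's instances; *K* heads are
   concatenated.
3. **Inter-metapath attention** — each metapath is summarised by
   *s* = mean tanh(*W h* + *b*), scored by *c*ᵀ*s*, and a softmax over
   metapaths fuses the per-metapath embeddings.

A pair's score is sigmoid(*h*<sub>m</sub>ᵀ*h*<sub>d</sub>), trained
with binary cross-entropy against negatives sampled 1:1 from
unobserved cells, an 8:1:1 stratified train/validation/test split,
Adam, dropout 0.5, and early stopping on validation AUC. Gradients are
computed by a hand-written reverse-mode pass, verified against finite
differences in the test suite. See the methods vignette
(`vignettes/mdpath-methods.Rmd`) for the full account, including
ablation variants (`nb`, `sm`, `avg`) and design choices.

## Worked example

Simulate a sparse tripartite network with three planted communities,
train the full model, and evaluate held-out pairs:

```r
library(mdpath)

sim <- generate_synthetic(synthetic_spec())   # 150 microbes, 40 drugs,
print(sim$network)                            # 60 diseases, 3 blocks
#> Tripartite microbe-drug-disease network
#>   nodes: 150 microbes, 40 drugs, 60 diseases
#>   edges: 996 microbe-disease, 704 microbe-drug, 280 disease-drug
#>   microbe-disease density: 11.07%

fit <- train_model(sim$network, training_config(seed = 1))
print(fit)
#> Metapath-aggregation association model (variant: full )
#>   2 layer(s), hidden dim 32, 6 heads
#>   trained 27 epoch(s); best validation epoch 21 (AUC 0.7623)

evaluate_model(fit, "test")
#> Evaluation on test partition (200 pairs)
#>   AUC  0.7158
#>   AUPR 0.6807

rank_candidates(fit, "d001", top = 5)
#>   rank microbe     score
#> 1    1    m036 0.7137593
#> 2    2    m046 0.6974219
#> 3    3    m015 0.6907458
#> 4    4    m013 0.6839478
#> 5    5    m009 0.6792757
```

The held-out AUC of ~0.72 sits close to this fixture's information
ceiling (~0.81; edges are conditionally independent given blocks, so no
scorer can beat block-posterior scoring — see the vignette), and the
top-ranked candidates for disease `d001` are microbes from its own
planted block: the model recovers the planted structure from the
training edges alone. The ranking table mirrors the case-study
protocol: microbes with known associations are removed first, the rest
are sorted by score.

Real data enter through plain delimited edge lists:

```r
md <- read_edge_list("md.csv", c("microbe", "disease"))
mc <- read_edge_list("mc.csv", c("microbe", "drug"))
dc <- read_edge_list("dc.csv", c("disease", "drug"))
net <- build_network(md = md, mc = mc, dc = dc)
```

A command-line launcher with `simulate`, `train`, `evaluate`, `rank`,
`ablate` and `sweep` subcommands is installed at
`system.file("cli", "mdpath", package = "mdpath")`.

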