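# treessm

Animal-behavior recognition from short video clips with a **tree
state-space model (TreeSSM)** backbone, implemented natively in R (with
Rcpp kernels), including training, evaluation and a synthetic
behavior-video generator.

The package is aimed at researchers in quantitative ethology and
computational image analysis who want a transparent, dependency-light
reference implementation of tree-structured state-space feature
aggregation — every algorithmic step, including the reverse-mode
gradients, is plain R/C++ that can be read, tested and modified.

## The method

A state space model maps an input signal through a linear dynamical
system `h' = A h + B x`, `y = C h + D x`, discretized by the zero-order
hold (`Ā = exp(ΔA)`, `B̄ = ΔB`, `C̄ = C`, `D̄ = D`) with an
input-dependent step `Δ = softplus(W_Δ x + b_Δ)`.

TreeSSM replaces the 1-D scan of sequence SSMs with aggregation over the
image itself:

1. each frame's feature grid becomes a 4-connected pixel graph whose
   edges carry the cosine similarity of adjacent feature vectors;
2. Borůvka's algorithm extracts the minimum spanning tree of the cosine
   distances `1 − sim`, discarding edges across strong feature
   boundaries;
3. hidden states aggregate every vertex's source term `m_j = B̄_j ⊙ x_j`
   along the tree, weighted by the product of edge weights on the unique
   tree path:

   `h_i = Σ_j ( Π_{e ∈ path(i,j)} w_e ) m_j`

   computed in linear time by a two-pass (rerooting) scan whose
   correctness is tested against an explicit O(V²) oracle;
4. the output is `y_i = Σ_n C̄_n LN(h_i)_{n,·} + D̄ ⊙ x_i`.

Frames pass through a convolutional stem and hierarchical TreeMamba
stages (TreeSSM + MLP blocks with pre-LayerNorm, residuals and
stochastic depth); pooled per-frame features are fused over the sampled
frame sequence (order-invariant mean fusion, or a temporal-difference
fusion that captures motion) and classified by a linear head. Training
is mini-batch Adam with decoupled weight decay, step learning-rate decay
and mean cross-entropy; evaluation reports confusion matrices, accuracy
and macro precision/recall/F1.

The synthetic generator renders five behavior classes (Eating, Standing,
Walking, Lying, Diarrhea) of a textured "calf" ellipse. Walking and
Standing are *pixel-identical in every frame* when the motion amplitude
is zero — the two classes are separable only through temporal
information, so the dataset certifies that a model distinguishing them
uses the sequence, not appearance.

## Worked example

Graph, tree and layer primitives on one synthetic frame:

```r
library(treessm)

cfg   <- synthetic_config(videos_per_class = 6, seed = 42)
video <- generate_synthetic_video("Walking", cfg, seed = 7)
grid  <- feature_grid(video$frames[[1]])     # 32 x 32 x 3

graph <- build_grid_graph(grid)
mst   <- boruvka_mst(graph)
tree  <- bfs_tree(mst, graph$num_vertices, root = 0)
c(graph$num_vertices, nrow(graph$edges), nrow(mst))
#> [1] 1024 1984 1023
sum(mst$distance)          # total cosine distance of the spanning tree
#> [1] 0.7007608
path_weight(tree, 0, 527)  # product of edge weights along the tree path
#> [1] 0.981639

ssm <- continuous_ssm(state_size = 16, channels = 3, seed = 1)
dim(tree_ssm_forward(grid, ssm, seed = 1))   # shape-preserving layer
#> [1] 32 32  3
```

The 1024-vertex lattice has `2·32·32 − 32 − 32 = 1984` edges; the MST
keeps the 1023 most-similar links, and its small total distance says the
frame is mostly smooth. The path weight near 1 means those two pixels
are connected through a chain of highly similar neighbors, so they
exchange almost unattenuated signal in the scan.

The full scaled study — generate 250 videos, train the two-stage model
(sequence length 8) for 30 epochs, evaluate, and contrast with a
sequence-length-1 model:

```r
res <- run_desk_experiment(seed = 1)   # ~5 minutes on one core
res$report
#> accuracy 96.00% | macro P 96.36% R 96.00% F1 95.87%
#>      [,1] [,2] [,3] [,4] [,5]
#> [1,]    8    0    0    1    1
#> [2,]    0   10    0    0    0
#> [3,]    0    0   10    0    0
#> [4,]    0    0    0   10    0
#> [5,]    0    0    0    0   10
c(res$pair_seq, res$pair_seq1)
#> [1] 100  35
```

Rows/columns follow `BEHAVIOR_CLASSES` (Eating, Standing, Walking,
Lying, Diarrhea); rows are true classes. The model reaches 96% test
accuracy, and the Walking/Standing pair — separable only temporally — is
classified at 100% by the sequence model but at 35% (around chance) by
the same architecture restricted to a single frame: the temporal
pathway, not appearance, carries that distinction.

## Command line

```sh
exec/treessm generate --out data --videos-per-class 20 --frames 40 --size 32 --seed 1
exec/treessm train    --data data --out run --seed 1
exec/treessm eval     --checkpoint run/best.ckpt --data data/test --report report.json
```

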