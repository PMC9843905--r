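---
title: "Predicting piRNA-disease associations with projection subgraphs and a graph convolutional encoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting piRNA-disease associations with projection subgraphs and a graph convolutional encoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdalink)
```

## The problem

Piwi-interacting RNAs (piRNAs) are 26–31 nt small non-coding RNAs with
mounting evidence of disease involvement, but experimentally confirmed
piRNA–disease associations (PDAs) are scarce relative to the number of
candidate pairs. `pdalink` treats PDA discovery as transductive link
prediction on a heterogeneous graph: given a curated bipartite
association list, piRNA sequences and disease positions in a MeSH-style
hierarchy, it scores every unobserved (piRNA, disease) pair.

The model has three stages: (1) intra-side subgraphs built by
*median-centrality bipartite projection*, (2) node features built by
*residual scaling* of similarity profiles followed by autoencoder
compression, and (3) a two-layer graph convolutional network (GCN) with
a three-layer fully-connected link predictor, trained end to end under a
dual loss (cross-entropy plus a sensitivity–specificity error term).

## Graph construction

The association list becomes a binary incidence matrix
$A^{pd} \in \{0,1\}^{N \times M}$. piRNAs of degree 1 are removed in a
single pass before modelling (`filter_low_degree()`, threshold 2):
degree-1 nodes dominate curated PDA lists and carry almost no
topological information for a graph method. The pass is deliberately not
iterated and the disease side is left untouched, so `N` is predictable.

The heterogeneous adjacency is the block matrix

$$A = \begin{bmatrix} A^{pp} & A^{pd} \\ (A^{pd})^\top & A^{dd} \end{bmatrix},
\qquad G = D^{-1/2}(A + I)\,D^{-1/2},$$

with $D$ the degree matrix of $A + I$. The symmetric normalization makes
$G$ contractive (spectral radius at most 1), which the test suite checks
on random instances.

### Median-centrality projection subgraphs

The plain bipartite projection connects two piRNAs whenever they share a
disease. With the heavy-tailed disease degrees typical of curated data,
one hub disease generates on the order of its squared degree of
piRNA–piRNA edges, drowning the subgraph in clique noise. The package
therefore restricts the projection to $k$ nodes whose PageRank
(damping $\alpha = 0.85$, power iteration, uniform teleportation,
dangling mass redistributed uniformly) lies nearest the *median* score —
the median being the robust representative of a long-tailed centrality
distribution. The subsample size is

$$k = \left\lfloor \frac{C_{pd}}{(d_{\max} - d_{\min})\,\mu} \right\rfloor$$

with $C_{pd}$ the number of known associations, $d_{\max}, d_{\min}$ the
extreme degrees of the *opposite* side, and dilution $\mu$ from
$\{1, 10, 100, 1000, \dots\}$ — defaults 100 for the piRNA side and 1
for the disease side. $k$ is clamped to $[1, \text{side size}]$, and the
degenerate case $d_{\max} = d_{\min}$ keeps the whole side. Ties at the
median break by node index so the selection is deterministic.

Two readings of "select $k$ nodes" are defensible: selecting nodes *of*
the projected subgraph (the default, `mode = "induced"`) or selecting
median-central *intermediary* nodes on the opposite side and projecting
only through them (`mode = "intermediary"`). Both are implemented;
the induced reading is the default because the selection is described
inside the already-projected subgraph.

## Similarity profiles

* **piRNA / sequence**: binary 3-mer presence profiles (T and U merged,
  lexicographic column order) compared with the Jaccard coefficient.
  Presence rather than counts is used because the Jaccard coefficient is
  defined on binary vectors; at 26–31 nt almost every 3-mer occurs at
  most a few times, so counts add little.
* **disease / semantic**: diseases sit in a directed acyclic hierarchy
  built from dot-delimited tree numbers (every prefix is an ancestor) or
  an explicit child–parent table. Each ancestor term $t$ contributes
  $D_d(t) = \Delta_{sem}^{\text{hops}}$ along the best path
  ($\Delta_{sem} = 0.5$), $DV(d) = \sum_{t \in T(d)} D_d(t)$, and two
  diseases are compared by the shared-ancestor mass
  $\sum_{t \in T(i) \cap T(j)}(D_i(t) + D_j(t)) / (DV(i) + DV(j))$.
* **GIP fallback**: both sides also get a Gaussian interaction profile
  kernel $\exp(-\gamma\,\lVert A(i) - A(j)\rVert^2)$ whose bandwidth is
  the raw bandwidth (1) divided by the mean squared profile norm *of the
  side being compared* — the standard convention; normalizing a piRNA
  kernel by disease counts would be dimensionally inconsistent.
  Integration keeps the primary similarity where it is nonzero and falls
  back to half the GIP value elsewhere, so the integrated matrix is only
  zero where both sources are.

Inside cross-validation the GIP profiles are rebuilt per fold from
training positives only; using full-data profiles would leak held-out
edges into the features.

## Residual scaling and node features

For node $i$ with association degree $\deg_i$ and similarity row mass
$m_i$, the ratio $\delta_i = \deg_i / m_i$ measures how much observed
association the node carries per unit of similarity. The residual

$$R_i = \lvert \ln(\delta_i + 1) - \bar\mu \rvert \cdot \Delta_{scale}$$

reweights row $i$ of the similarity matrix ($S' = \mathrm{diag}(R)\,S$),
injecting degree information into the feature magnitudes.
$\Delta_{scale}$ defaults to 10, the middle of the candidate set
$\{0.1, 10, 100\}$.

Two centerings $\bar\mu$ are provided. The default is the mean
association degree (`raw_degree_mean`): it yields residuals that vary
smoothly across nodes and never annihilate a row. The alternative
(`log_ratio_mean`) centers in the transformed scale,
$\bar\mu = \overline{\ln(\delta + 1)}$; it is dimensionally tidy but by
construction sends the residual of near-average nodes to zero, so their
scaled rows — and with them their feature identity — vanish before the
autoencoder ever sees them. The mean-degree centering avoids that
degenerate annihilation, which is why it is the default. Both remain
available; the choice is exposed as `mu_mode`.

Because $\Delta_{scale}$ spans three orders of magnitude and only the
*relative* row weights carry information, the scaled matrix is
normalized to unit root-mean-square before autoencoder training; this
keeps the fixed-learning-rate optimization well conditioned and makes
the pipeline robust to degenerate scales (a $\Delta_{scale} \to 0$ input
still returns finite features).

Each side is then compressed by a symmetric denoising autoencoder
(input → hidden → code → hidden → input; hidden
$= \min(256, \text{width})$, linear code and output, ReLU hidden layers,
full-batch Adam at 0.01 for 200 epochs, mandatory seed). Both sides
share the code width $d_0$ (default 64, auto-shrunk to the narrower
input — on a 12-disease problem $d_0$ becomes 12) so the stacked
$(N + M) \times d_0$ feature matrix feeds a single GCN. Ablation modes
replace this pipeline: `raw_similarity` encodes the unscaled similarity,
`constant` uses a single all-ones column.

## Encoder, predictor and loss

$$H^{(1)} = \mathrm{ReLU}(G H^{(0)} W^{(0)}), \qquad
  H^{(2)} = G H^{(1)} W^{(1)}$$

The second layer is linear by default (common for embedding outputs; a
ReLU variant is a config switch). A pair $(i, j)$ is scored by the
three-layer fully-connected head on the concatenated embeddings
$[z_{p_i} \,\Vert\, z_{d_j}]$ (Hadamard product available), widths
$2h_2 \to 64 \to 32 \to 1$, ReLU–ReLU–sigmoid. Dropout 0.2 is applied to
the GCN hidden layer and both FC hidden layers during training.

The loss is $L = L_{CE} + L_{SS}$ where $L_{CE}$ is binary cross-entropy
and $L_{SS} = w(1 - sp) + (1 - w)(1 - se)$ with *soft* rates
($se$ = mean score over positives, $sp$ = mean complement score over
negatives) so the term is differentiable; $w = 0.1$ by default. Two
numerical choices deserve note: the cross-entropy is averaged rather
than summed so the default learning rate (0.002) behaves identically
across batch sizes, and the sensitivity–specificity term is the *error
complement* — a term that rewarded raw $sp$/$se$ would be minimized by
degrading them, which cannot serve as a training objective. Training is
full batch (the graphs are small) with Adam, manual backpropagation, and
a mandatory seed; the gradient of the dual loss is verified against
finite differences in the test suite. Weight initialization is
fan-based (uniform Glorot). Defaults: $h_1 = h_2 = 64$, 12000 epochs for
real-scale runs; the synthetic benchmark uses 500.

## Evaluation protocol

Negatives are sampled uniformly without replacement from unlabeled
cells, once per experiment, then folded together with the positives into
5 near-equal parts, so train and test negatives are disjoint. Per fold,
*everything* derived from associations — GIP profiles, projection (or
similarity) subgraphs, residual profiles, the $A^{pd}$ adjacency block
and the supervised pairs — is rebuilt from training positives;
`audit_leakage()` re-checks every fold. A permissive variant
(`static_subgraphs = TRUE`) that builds intra-side subgraphs from all
known edges exists for comparison and is excluded from the audit's
guarantees.

Metrics: AUC by the rank (Mann–Whitney) statistic with ties averaged;
AUPR by step-wise precision–recall integration (average precision, no
interpolation, which avoids the optimistic bias of trapezoidal
interpolation under imbalance); accuracy, precision, recall and F1 at a
fixed 0.5 threshold (the protocol never states a tuned threshold, and a
fixed one keeps folds comparable).

## The synthetic benchmark: what it does and does not show

`fixture_spec()` defaults define the planted-structure benchmark used by
the acceptance suite: 120 piRNAs × 12 diseases in 3 aligned
community/group blocks, within-block edge probability 0.9, cross-block
0.02, disease popularity skewed as rank$^{-0.5}$ (≈ 430 edges, every
node topped up to degree ≥ 1), 26–31 nt sequences carrying a 12-nt
community motif, and a toy 4-ary disease hierarchy of depth 2 under a
shared root whose subtrees coincide with the disease groups. The
within-block probability is deliberately high: the benchmark's ceiling
is set by within-block *non*-edges (which look exactly like held-out
positives to any method), and weaker blocks would cap even a perfect
model well below the acceptance level, turning the benchmark into a test
of the fixture rather than the method. The class-imbalance study uses a
sparser variant (240 × 24, 8 blocks, within-block 0.55, ≈ 8% density)
because 1:10 negative sampling needs at least 11× more cells than
positives.

Benchmark problem sizes were chosen for single-CPU runs: 5-fold CV at
500 epochs takes tens of seconds per replicate; the acceptance suite
uses 10 replicates for the full model and the label-permuted null, 5 for
each feature ablation, and one replicate per imbalance ratio.

What passing shows: the pipeline recovers genuinely planted
association structure from the combination of topology and features,
does not leak held-out edges, degrades to chance when labels are
permuted, and orders ablations and imbalance ratios as expected. What it
does not show: performance on real curated data — real similarity
profiles are noisier, higher-dimensional and more redundant than the
synthetic ones (where the residual-scaling gain over raw similarity
encoding is accordingly small), and real degree distributions are more
extreme.

## Known limitations

* Projections are unweighted; shared-neighbor counts are discarded.
* The autoencoder and GCN are plain dense implementations sized for
  graphs of a few thousand nodes; there is no sparse or GPU path.
* MeSH parsing expects pre-extracted tree numbers; raw descriptor XML is
  out of scope.
* Identifier unification across source databases must happen upstream.

## Worked example

```{r example, eval = FALSE}
library(pdalink)

fx <- generate_fixture(fixture_spec(seed = 1), dir = "fixture")
res <- planted_benchmark(1)
res[, c("auc", "aupr", "accuracy", "f1")]

# or, file-based, end to end:
cfg <- run_config(associations = fx$paths$edges, fasta = fx$paths$fasta,
                  tree_numbers = fx$paths$tree, out_dir = "run",
                  seed = 1, epochs = 500)
report <- run_full_pipeline(cfg)
```
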