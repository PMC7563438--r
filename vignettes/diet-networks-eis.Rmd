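---
title: "Diet Networks with element-wise input scaling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet Networks with element-wise input scaling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Somatic-mutation profiles are an extreme "wide data" setting: a cohort of a
few hundred tumors, each described by the presence or absence of mutations in
roughly twenty thousand genes ($N \ll N_d$). A plain multilayer perceptron
(MLP) on such input spends almost all of its capacity in the first affine
layer: with $N_d$ input genes and $N_h$ hidden units the encoder matrix
$W_e \in \mathbb{R}^{N_d \times N_h}$ alone holds $N_d N_h$ free parameters —
the *fat layer* — which invites overfitting and makes per-gene contributions
hard to read off.

`dietnets` implements a family of four fully-connected classifiers for binary
mutation matrices $X \in \{0,1\}^{N \times N_d}$ that addresses both issues,
together with the preprocessing, cross-validation and interpretability
pipeline around them.

## The model family

All four variants share a three-layer basic network

$$\hat{Y} = f_d(H), \qquad H = f_e(X),$$

with a hidden layer of $N_h$ units, softmax output over $N_c$ classes, and an
optional reconstruction head $\hat{X} = f_r(H)$.

* **`mlp`** — $H = \mathrm{relu}(X W_e + b_e)$ with $W_e$ free.
* **`mlp_eis`** — adds *element-wise input scaling* (EIS): a learnable
  vector $u_e \in \mathbb{R}^{N_d}$, one multiplicative scalar per gene,
  $H = \mathrm{relu}(X\,\mathrm{diag}(u_e)\,W_e + b_e)$.
* **`diet`** — Diet Networks: $W_e$ is not free. A small auxiliary network
  $G_e$ (affine $N_{\text{train}} \to N_j$, ReLU, affine $N_j \to N_h$, both
  with bias) is applied to each row of the transposed training matrix
  $X^T \in \mathbb{R}^{N_d \times N_{\text{train}}}$, so each gene's weight
  vector is predicted from that gene's mutation pattern across the training
  samples: $W_e = G_e(X^T)$. The parameter count drops from
  $O(N_d N_h)$ to $O(N_{\text{train}} N_j + N_j N_h)$.
* **`diet_eis`** — Diet Networks plus EIS:
  $H = \mathrm{relu}(X\,\mathrm{diag}(u_e)\,W_e)$,
  $\hat{X} = \mathrm{sigmoid}(H W_r^T \mathrm{diag}(u_r))$. The scaling
  vectors give the network $N_d$ directly backpropagated degrees of freedom
  even though the fat weights remain auxiliary-network outputs, which is what
  stabilizes training when the transposed matrix carries too little
  variation.

Training minimizes

$$L = H(\hat{Y}, Y) + \gamma\,\|\hat{X} - X\|^2 + \delta\,\|u_e\|_1,$$

cross-entropy plus an optional reconstruction term and an optional L1
sparsity penalty on the input scales (which turns EIS into a soft feature
selector).

### Conventions fixed by the parameter-count table

The published per-architecture counts (2,299,394 / 2,317,355 / 227,970 /
245,931 at $N_d = 17{,}961$, $N_h = 128$, $N_j = 256$, $N_c = 2$) pin down
three conventions that prose alone leaves open, and `count_parameters()`
reproduces them exactly:

* the MLP encoder has a hidden bias ($+N_h$), the diet encoder has none;
* both auxiliary layers and the classifier head carry biases;
* the auxiliary input width equals the *training-fold* size (760 under
  5-fold cross-validation of 950), not the full cohort. `initialize_state()`
  therefore takes `n_train`, and `cross_validate()` rebuilds $X^T$ from each
  fold's training samples.

The number of unique gene symbols (17,961) is used as $N_d$ throughout; it
is the only value consistent with the printed counts.

### Gradient flow through the fat weights

Describing the fat weights as computed "without keeping gradient
information" is ambiguous: the auxiliary parameters are counted as
learnable, so some gradient path must exist. The package implements both
readings. By default gradients propagate end-to-end through $W_e$ into
$G_e$, and $W_e$ is merely not an optimizer-managed tensor (it is
re-predicted after every update). With `detach_fat_weights = TRUE` the
auxiliary networks receive no gradient and stay frozen at initialization,
the literal reading, kept for comparison; the EIS vector is backpropagated
directly in either mode.

### Other numerical choices

* **Reconstruction error.** The objective uses the element-wise *mean*
  squared error by default rather than the summed norm: at
  $N_d \approx 18{,}000$ a summed norm with $\gamma = 0.1$ would dwarf the
  cross-entropy term. `reconstruction_loss = "sum"` restores the literal
  sum.
* **Activations.** ReLU hidden layer and sigmoid reconstruction are applied
  uniformly to all four variants so they differ only where intended; the
  output nonlinearity is softmax paired with cross-entropy.
* **Initialization.** Affine weights draw from the scaled-uniform fan-in
  scheme $U(-1/\sqrt{\text{fan-in}}, 1/\sqrt{\text{fan-in}})$; biases start
  at zero; $u_e, u_r$ start at all-ones, so a fresh EIS model is exactly its
  non-EIS counterpart.
* **Optimizer.** Adam (learning rate $5 \times 10^{-3}$, weight decay
  $5 \times 10^{-4}$, batch size 100, coupled weight decay added to the
  gradient). Weight decay is applied uniformly, including to $u_e$; this
  interacts with the L1 penalty and is configurable. The final partial
  mini-batch of each epoch is kept.
* **Prediction ties.** Arg-max prediction breaks ties toward the lower
  class index; the L1 subgradient at zero is taken as 0.
* **Determinism.** Every stochastic step (cohort generation, fold
  shuffling, initialization, mini-batch order) draws from a stream keyed by
  an explicit integer seed; fold $f$ derives its stream as `seed + f - 1`.
  Runs are bit-reproducible in single-threaded BLAS.

## Preprocessing

Real cohorts enter as a MAF-style mutation table plus a clinical label
table. Records at silent or splice regions are excluded by default
(`Silent`, `Splice_Site`, `Splice_Region` — the smallest set matching the
stated rule; the list is configurable for stricter vocabularies). Counts
are binarized to presence/absence, genes are ordered by descending total
mutation count with lexicographic tie-break (the published rule is silent
on ties; a deterministic order makes matrices reproducible), and labeled
samples without surviving mutations are kept as all-zero rows (dropping
them is available but not the default, since nothing states they were
removed). For equal-size folds the cohort is truncated to the largest
multiple of $k$ (954 cases $\to$ 950, five folds of 190).

## The synthetic cohort generator

`generate_synthetic_cohort()` emulates the statistical structure of the
binarized matrix so the whole pipeline is testable without any download: a
balanced two-class cohort, binary entries, a small minority of planted
class-associated genes (Bernoulli `p_high` in the associated class,
`p_low` in the other) over an exchangeable background (`p_background`
everywhere). The default *strong-signal cohort* — 400 samples, 200 genes,
20 planted genes per class, $p_{\text{high}} = 0.4$,
$p_{\text{low}} = 0.05$, background 0.05 — uses mutation rates in the range
of recurrently mutated lung-cancer genes and a sample-to-gene ratio scaled
down proportionally from the real task, and is deliberately separable so
that recovery failures indicate implementation faults rather than
statistical noise.

What the generator does **not** model: per-sample mutational burden
variation, gene-length effects, linkage or co-mutation structure between
genes, and class-imbalanced cohorts. Genes are independent given the
class, exactly the assumption the dominance t-test makes. Passing tests on
this cohort therefore demonstrate mechanical correctness and recoverability
of planted signal, not performance on real tumor data.

## Interpretability pipeline

Because inputs are binary, switching gene $i$ on adds row $i$ of the
effective first-layer matrix to the hidden pre-activation, so that row
(with $u_e$ absorbed for EIS variants: $u_{e,i} W_{e,i\cdot}$) is the
gene's *hidden representation*. On these embeddings the package provides:

* **Centered PCA** (`pca_decompose()`), with component signs fixed by
  making each component's largest-magnitude coordinate positive. The
  rank-$K$ approximation re-adds the centering mean by default — the
  standard low-rank reconstruction, consistent with near-perfect accuracy
  reproduction at full rank; a literal mean-free mode exists
  (`include_mean = FALSE`).
* **Accuracy under approximation** (`evaluate_approximation()`): the
  effective first-layer matrix is replaced by the approximated embeddings
  and validation accuracy recomputed; with $K$ = all components this
  reproduces the unapproximated accuracy, and comparing $K=(1)$, $K=(2)$,
  $K=(1,2)$ shows how much of the classifier lives in the leading
  principal subspace.
* **Dominance t-tests** (`dominance_ttest()`): per gene, a two-sided Welch
  test on the binary indicator between classes, labeling genes by the
  class of higher frequency at $p < 0.05$. Welch is chosen over Student as
  the safer default on binary indicators with unequal class variances; no
  multiple-testing correction is applied by default (raw $p < 0.05$, as in
  the original analysis), with a Benjamini–Hochberg option. Genes constant
  in both classes get $p = 1$ (equal frequencies) or $p = 0$ (maximal
  separation), where the Welch statistic is undefined.
* **PC-score rankings** (`rank_genes_by_pc_score()`) along a chosen
  component, and a seeded t-SNE layout (`project_tsne()`) for plots only.

PCA is fit per trained model (one fold's encoder); the reference analysis
likewise evaluates the first split's model rather than pooling folds.

## Problem sizes used by the tests

The package's own test and acceptance runs train `diet_eis`
($\gamma = 0.1$) on the strong-signal cohort with 5-fold cross-validation
for 200 epochs, summarizing accuracy over epochs 150–200; at these sizes a
full cross-validation completes in well under two minutes on one core,
reaches mean validation accuracy above 0.95, and the planted genes separate
by sign along the accuracy-dominant principal component. The published
17,961-gene task is represented in the tests only where it is exactly
reproducible at desk scale: the parameter-count table and the fold
arithmetic. The accuracy grid of the original study (around 0.79 for
`diet_eis` at $\gamma = 0.1$) requires the TCGA Pan-Lung download and
5,000-epoch training, and is out of scope here; the cBioPortal TSV pair it
ships as is exactly what `read_mutation_table()` / `read_clinical_labels()`
consume if a user supplies it.

## Known limitations

* The training loop is plain R matrix algebra; it is fast at desk scale
  but not tuned for the full 18k-gene cohort at 5,000 epochs (hours, not
  minutes, on one core).
* Only fully-connected architectures and a single hidden layer are
  implemented; multi-class tasks work through `n_classes` but are
  untested beyond binary.
* The t-SNE projection inherits the usual caveats (non-convex, seed
  dependent); it is a visualization aid and feeds no quantitative result.
* Checkpoints serialize parameters as JSON text with ~15 significant
  digits; restored models agree to numerical precision but not bit-for-bit
  with in-memory states.
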