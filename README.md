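# dietnets

Parameter-reduced fully-connected networks for classifying tumors from
high-dimensional binary somatic-mutation profiles — with the preprocessing,
cross-validation and interpretability pipeline around them.

## The problem

Mutation profiles are extreme "wide data": a few hundred tumor samples, each
a 0/1 vector over ~20,000 genes (mutated / not mutated after binarization).
A plain multilayer perceptron on input dimension N<sub>d</sub> with
N<sub>h</sub> hidden units spends N<sub>d</sub>·N<sub>h</sub> parameters on
its first ("fat") layer alone, which overfits small cohorts and obscures
per-gene contributions. The motivating task is binary histology prediction
for lung cancer — adenocarcinoma (LUAD) vs. squamous cell carcinoma (LUSC) —
from a binarized somatic-mutation matrix.

## The models

Four fully-connected variants over a binary data matrix
X ∈ {0,1}<sup>N×N<sub>d</sub></sup>, all with hidden layer
H ∈ ℝ<sup>N×N<sub>h</sub></sup> and softmax output:

| variant    | encoder                                              | fat weights W<sub>e</sub>  |
|------------|-------------------------------------------------------|----------------------------|
| `mlp`      | H = relu(X W<sub>e</sub> + b<sub>e</sub>)              | free parameter             |
| `mlp_eis`  | H = relu(X diag(u<sub>e</sub>) W<sub>e</sub> + b<sub>e</sub>) | free parameter      |
| `diet`     | H = relu(X W<sub>e</sub>)                              | W<sub>e</sub> = G<sub>e</sub>(Xᵀ) |
| `diet_eis` | H = relu(X diag(u<sub>e</sub>) W<sub>e</sub>)          | W<sub>e</sub> = G<sub>e</sub>(Xᵀ) |

In the *Diet Networks* variants the fat matrix is predicted, gene by gene,
by a small auxiliary network G<sub>e</sub> applied to the transposed
training matrix — each gene's weight vector is a function of that gene's
mutation pattern across training samples — collapsing the parameter count
from O(N<sub>d</sub>N<sub>h</sub>) to
O(N<sub>train</sub>N<sub>j</sub> + N<sub>j</sub>N<sub>h</sub>).
*Element-wise input scaling* (EIS) adds one learnable scalar per gene
(vector u<sub>e</sub>, length N<sub>d</sub>), directly optimized by
backpropagation, which restores learning capacity and stabilizes training
when the transposed matrix varies too little. Training minimizes

&nbsp;&nbsp;&nbsp;&nbsp;L = H(Ŷ, Y) + γ‖X̂ − X‖² + δ‖u<sub>e</sub>‖₁

— cross-entropy, an optional reconstruction term through a mirror-image fat
decoder, and an optional L1 penalty that turns EIS into a soft feature
selector. At the published sizes (N<sub>d</sub> = 17,961, N<sub>h</sub> =
128, N<sub>j</sub> = 256, N<sub>train</sub> = 760) the counts from
`count_parameters()` are 2,299,394 (`mlp`), 2,317,355 (`mlp_eis`), 227,970
(`diet`) and 245,931 (`diet_eis`).

Because the input is binary, row i of the effective first-layer matrix
(u<sub>e,i</sub>·W<sub>e,i·</sub> for EIS variants) is gene i's learned
embedding. The interpretability tools decompose these embeddings by
centered PCA, measure how much classification accuracy survives a rank-K
approximation of the encoder, rank genes by principal-component score, and
compare everything against per-gene Welch t-tests of mutation frequency
between classes.

## Worked example

Train Diet Networks with EIS (γ = 0.1) on the default synthetic cohort —
400 samples × 200 genes, 20 planted class-associated genes per class
(mutation rate 0.4 in the associated class, 0.05 elsewhere) — with 5-fold
cross-validation:

```r
library(dietnets)

coh <- generate_synthetic_cohort(synthetic_spec(seed = 1))
m <- coh$matrix
m
#> mutation_matrix: 400 samples x 200 genes
#>   classes: LUAD=200, LUSC=200
#>   matrix density: 0.0852

ncfg <- network_config(n_features = ncol(m$X), variant = "diet_eis", gamma = 0.1)
tcfg <- train_config(max_epochs = 200, eval_window = c(150, 200), seed = 1)
cv <- cross_validate(m, ncfg, tcfg)
cv
#> cv_result: diet_eis, 5 folds x 200 epochs
#>   accuracy over epochs 150-200: 0.992 +/- 0.010
```

The pooled validation accuracy over epochs 150–200 is 0.992 ± 0.010: the
planted signal is essentially solved. Now read the trained encoder as gene
embeddings and rank genes along the leading principal component:

```r
fit <- cv$fits[[1]]
E <- extract_hidden_representations(fit$state, m$gene_symbols)
basis <- pca_decompose(E)
rank_genes_by_pc_score(basis, pc_index = 1, top_n = 3)
#> $positive
#>   gene_symbol    score
#> 1     G000004 17.22140
#> 2     G000011 12.79557
#> 3     G000020 11.88133
#>
#> $negative
#>   gene_symbol     score
#> 1     G000025 -9.297115
#> 2     G000033 -8.778109
#> 3     G000040 -8.378791
```

The generator planted genes G000001–G000020 for class A ("LUAD-like") and
G000021–G000040 for class B: the two sign groups of the PC score recover the
two planted sets, which is exactly how PC scores read as class preference
on the real task. The frequency-based view agrees:

```r
dom <- dominance_ttest(m)
head(dom[order(dom$p_value), ], 3)
#>    gene_symbol freq_LUAD freq_LUSC mean_diff      p_value         group
#> 8      G000024     0.035     0.460    -0.425 3.506879e-24 LUSC-dominant
#> 1      G000011     0.485     0.065     0.420 1.624804e-22 LUAD-dominant
#> 34     G000001     0.395     0.010     0.385 2.813760e-22 LUAD-dominant
```

Real cohorts enter through `read_mutation_table()` (MAF-style TSV),
`read_clinical_labels()` and `build_mutation_matrix()`, which apply the
silent/splice-region filter, binarize, and order genes by mutation count.
A thin command-line wrapper over the same functions lives at
`inst/cli/dietnets.R` (subcommands `simulate`, `train`, `grid`,
`interpret`).

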