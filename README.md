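# alcyto — active-learning histocytometry

`alcyto` quantifies cell populations in multiplex-immunostained tumor tissue.
It is aimed at quantitative-pathology and image-analysis groups who need to
identify a sparse cell type — prototypically tumor endothelial cells (EC),
marked by perinuclear CD34 staining — across large batches of spectrally
unmixed histopathology images, and then measure molecular analytes (Ki67,
p-ERK, p-STAT3 and the like, detected with DAB) in exactly that population.

The pipeline: segment nuclei from the hematoxylin channel, compute
per-nucleus shape/intensity features plus inside-and-surround statistics of
every marker channel, train an EC classifier with **active learning** (the
machine chooses which cells the expert should label), then background-correct
analyte channels and report per-image and per-tumor positivity among EC.
Inter-rater and rater-vs-machine agreement tooling (Cohen's κ, agreement
partitions, cluster bootstrap intervals) closes the loop.

## The core algorithm

Cells are feature vectors $x_i$ (leading 1 for the intercept) with labels
$y_i \in \{-1,+1\}$; the classifier is L1-regularised logistic regression

$$\hat\beta = \arg\max_\beta \sum_i \ln\sigma(y_i\,\beta^\top x_i)
  - \lambda\lVert\beta_{-0}\rVert_1,$$

smoothed via $|\beta_j|\approx\sqrt{\beta_j^2+\epsilon_s}$ (eps-L1) and
followed by an unpenalised refit on the selected support, so uninformative
features end at exactly zero without shrinking the useful ones. Training
examples are chosen sequentially by D-optimal design on the Fisher
information $I(\beta)=\sum_i w_i x_i x_i^\top + \epsilon D$ with
$w_i=\sigma(\beta^\top x_i)(1-\sigma(\beta^\top x_i))$: each iteration
queries the unlabeled cell maximising $\det(I + w(x)\,xx^\top)$, evaluated
through the determinant lemma as the score $w(x)\,x^\top I^{-1}x$. The run
stops when the information gain $\ln\det I$ plateaus. Everything is
deterministic given the seed and the oracle's answers.

A synthetic-data module renders multi-channel images (elliptical nuclei,
CD34 rings around elongated EC nuclei, analyte channels with optional DAB
background, Poisson noise) and tabular two-class feature sets with a known
informative/noise split, so the whole pipeline is testable without any
external data.

## Worked example

```r
library(alcyto)

# render one field of view: 20 nuclei, 25% EC with CD34 rings, Poisson noise
img <- make_image(image_spec(n_nuclei = 20, seed = 1))

# hybrid segmentation: Poisson-mixture threshold -> LoG seeds -> clustering
# -> score-based merging
labels <- segment_nuclei(img$channels$nuclear)
max(labels)
#> [1] 21

feats <- compute_features(labels, img$channels, image_id = 1)
dplyr::select(feats, cell_id, area, elongation, cd34_surround)[1:4, ]
#> # A tibble: 4 x 4
#>   cell_id  area elongation cd34_surround
#>     <int> <int>      <dbl>         <dbl>
#> 1       1   200       1.07          3.01
#> 2       2   169       1.05          3.24
#> 3       3   207       1.08          3.2
#> 4       4   181       1.05          3.16
```

The segmenter found 21 regions for 20 rendered nuclei (one elongated nucleus
stayed split); these four are non-EC — near-circular (`elongation` ≈ 1) and
sitting in a CD34-dark neighbourhood (`cd34_surround` ≈ 3, the dim
nonspecific background level).

Pool several images, let active learning pick its training cells from a
simulated trainer, and score the held-out cells against ground truth:

```r
imgs <- lapply(1:5, function(i) make_image(image_spec(seed = i)))
pool <- build_ec_pool(imgs)
state <- run_active_learning(pool, simulated_oracle(pool),
                             al_config(max_iterations = 25, seed = 1))
state
#> <al_state> 27 labeled cells, 26 iterations, not converged
#>   information gain: -244.765

head(selected_features(state$model), 5)
#> [1] "cd34_surround" "eccentricity"

evaluate_ec_classification(state, pool) |>
  dplyr::select(sensitivity, specificity, ppv, npv, n_evaluated)
#> # A tibble: 1 x 5
#>   sensitivity specificity   ppv   npv n_evaluated
#>         <dbl>       <dbl> <dbl> <dbl>       <int>
#> 1           1           1     1     1          74
```

After 27 labels (one initial example per class plus 25 queries) the L1
penalty has zeroed all but two features — the CD34 ring signal and nuclear
shape, exactly the cues that define an EC here — and the remaining 74 cells
are classified with sensitivity and specificity 1.0 on this synthetic set.

`benchmark_learning_curves()` reproduces the comparator experiment (random
sampling, PCA, t-test and mRMR pre-selection vs active learning, 25
replicates, 50-label budget) and `autoplot()` draws the mean ± SEM learning
curves. `background_subtract()`, `measure_expression()`,
`classify_positive()` and `summarize_analyte()` carry an analyte channel from
raw pixels to per-tumor positivity quartiles, and `cohen_kappa()`,
`kappa_matrix()`, `agreement_partition()` and `cluster_bootstrap_ci()` cover
the agreement analyses. A thin command-line launcher (`inst/cli/alcyto`)
exposes `simulate / segment / features / train / classify / analyte /
evaluate / benchmark` subcommands over the same functions.

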