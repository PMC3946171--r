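---
title: "Active-learning histocytometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-learning histocytometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alcyto)
```

# The problem

Endothelial cells (EC) line tumor blood vessels and are the direct target of
antiangiogenic therapy, yet they are sparse, pleiomorphic, and scattered
through disorganised tumor tissue, which makes visual identification in
immunostained histopathology slow and subjective. `alcyto` implements an
automated histocytometry pipeline for this setting: nuclei are segmented from
the hematoxylin channel of spectrally unmixed images, each nucleus is
described by intrinsic (shape, size, intensity, texture) and associative
(per-channel, inside and perinuclear) features, and a binary classifier
separates EC from non-EC nuclei. Because experts choose training examples
poorly — informative cells are exactly the ones that look ambiguous — the
classifier is trained by *active learning*: the algorithm, not the expert,
decides which cells are worth labeling.

# The classifier and the query rule

Each cell is a feature vector $x_i$ (with a leading 1 accommodating the
intercept) and a label $y_i \in \{-1, +1\}$ (+1 = EC). The model is logistic
regression, $P(y_i = 1 \mid x_i) = \sigma(\beta^\top x_i)$ with
$\sigma(t) = 1/(1+e^{-t})$, fitted by maximising the penalised log-likelihood

$$\ell(\beta) \;=\; \sum_i \ln \sigma(y_i\, \beta^\top x_i)
\;-\; \lambda \lVert \beta_{-0} \rVert_1 .$$

The L1 penalty drives the weights of uninformative features to zero, so the
model performs feature selection as a side effect of training ("auto-select"
behaviour). To use a quasi-Newton optimiser on the non-differentiable L1 term
we apply the eps-L1 smoothing $|\beta_j| \approx \sqrt{\beta_j^2 +
\epsilon_s}$ with $\epsilon_s = 10^{-6}$.

Queries are chosen by sequential D-optimal design. The Fisher information of
logistic regression over points $x_i$ is

$$I(\beta) = \sum_i w_i\, x_i x_i^\top, \qquad
  w_i = \sigma(\beta^\top x_i)\,\bigl(1 - \sigma(\beta^\top x_i)\bigr),$$

and its inverse lower-bounds the covariance of $\hat\beta$; maximising
$\det I(\beta)$ therefore shrinks the parameter-uncertainty ellipsoid
fastest. A ridge $\epsilon D$ (with $D = I$ and $\epsilon = 10^{-9}$) keeps
the matrix invertible before any labels exist. Scoring a candidate $x$ uses
the matrix determinant lemma,

$$\det\!\bigl(I + w(x)\, x x^\top\bigr)
  = \det(I)\,\bigl(1 + w(x)\, x^\top I^{-1} x\bigr),$$

so the per-candidate score is $w(x)\, x^\top I^{-1} x$ — a weighted leverage.
The information matrix is always estimated from the cells labeled so far, in
the spirit of sequential optimal experiment design; the acceptance suite
verifies that this rank-one scoring picks the same cell as brute-force
determinant evaluation on every random pool it tries.

After each oracle answer the model is refitted on all labeled cells, the
information gain $\ln \det(I(\hat\beta) + \epsilon D)$ is appended to a
history, and the run stops when the gain plateaus (below) or a query budget
is exhausted. Given the same pool, seed and oracle, the algorithm queries the
same cells and returns bit-identical coefficients.

# Tunable parameters

* **`lambda`** (penalty weight, likelihood units). Default: the schedule
  $\lambda = 0.15\, n_{\text{labeled}}$, combined with a **relaxed-lasso
  refit**: after the L1 stage fixes the support, the retained coefficients
  are refitted without penalty. The schedule keeps the penalty proportional
  to the likelihood as labels accrue. The factor 0.15 is sized against the
  null distribution of the score statistic: for a feature carrying no signal,
  $\bigl|\partial \ell / \partial \beta_j\bigr|$ at the optimum is of order
  $\sqrt{n}/2$ times the usual $\sqrt{2 \ln p}$ extreme-value factor, about
  $0.14 n$ at $n = 50$, $p = 44$ — a penalty below that level (for example
  $0.01 n$) leaves roughly half of the pure-noise features active, while much
  larger values begin to mask weak informative features. The relaxed refit
  decouples the two jobs of $\lambda$: sparsity no longer costs prediction
  accuracy, because selection and estimation are separate stages. Coefficients
  whose optimised magnitude falls below the smoothing resolution
  $\sqrt{\epsilon_s} = 10^{-3}$ are truncated to exact zero ("polish"), which
  restores the exact sparsity the ideal L1 penalty would produce.
* **`plateau_tol`, `plateau_patience`** (dimensionless; 10^-3 and 5).
  Convergence is declared when the relative gain increase
  $(G_t - G_{t-1}) / \max(|G_{t-1}|, 1)$ stays below the tolerance for
  `patience` consecutive iterations. "Plateau" is not otherwise defined by
  the method, so both knobs are exposed.
* **`n_init_per_class`** (default 1): the trainer supplies one EC and one
  non-EC example to start. **`batch_size`** (default 1): for larger batches
  the information matrix is updated with each pick's *expected* (label-free)
  contribution $w(x)\,xx^\top$ before re-scoring, since the Fisher
  information of logistic regression does not depend on the unseen label.
* **Standardization.** Features are z-scored with unlabeled-pool statistics
  before training — an L1 penalty compares coefficient magnitudes across
  features, which is meaningless on heterogeneous scales (areas in pixels vs
  intensities in gray levels). Constant features are dropped with a warning.
* **Prediction threshold.** Strict: label +1 iff $p > 0.5$; exact 0.5 is
  classified negative. Query-score ties break to the smallest cell id.

# Segmentation

The nuclear channel is binarized by modelling its gray-level histogram as a
two-component Poisson mixture and exhaustively minimising the total negative
log-likelihood of the split (minimum-error thresholding). Two components keep
the mixture identifiable on images that are essentially background plus
chromatin; the threshold provably falls between well-separated component
means. Refinement is either an exact binary graph cut (Poisson data terms,
Potts smoothness, solved by max-flow) or a light morphological clean-up (hole
fill plus isolated-pixel removal) — both leave a noise-free mask untouched.

Seeds come from scale-normalised Laplacian-of-Gaussian filtering of the
*binary mask* at six geometrically spaced sigmas (`scale_min` 2.5 px to
`scale_max` 8 px by default; a nucleus of equivalent radius $r$ responds most
strongly near $\sigma = r/\sqrt2$, so the ladder should bracket the expected
radii). Mask pixels are then assigned to seeds by steepest ascent on the
across-scale maximum response (ties to the lower label id; isolated plateaus
go to the nearest seed), giving a partition of the foreground. Regions
outside `[min_size, max_size]` (40–4000 px by default) are dropped before
merging.

Fragment merging uses a surrogate plausibility score, since the trained
nucleus-appearance models of the original hybrid algorithms are defined only
by citation: `merge_alpha` × (log-normal size-prior log-density of the
region's area) + (1 − `merge_alpha`) × (ellipse-fit quality = area / area of
the ellipse with the region's second moments, capped at 1). Adjacent
fragments are merged whenever the union outscores both parts, sweeping pairs
in ascending id order until a fixed point; a merge replaces two regions with
a higher-scoring one, so the minimum score in the map never decreases, and
the procedure is idempotent and deterministic. The size prior defaults to the
median area of the initial label map.

# Features

Nine intrinsic features (area, perimeter, elongation, eccentricity,
convexity, mean/total intensity, intensity variance, gradient energy as a
chromatin-texture surrogate) plus three associative features per non-nuclear
channel: `_average` and `_total` inside the nucleus and `_surround`, the mean
in a ring obtained by dilating the nucleus by `ring_width` (default 2 px,
mirroring the two-pixel perimeter convention for membrane-proximal markers)
and excluding pixels of *any* nucleus. Elongation is the square root of the
eigenvalue ratio of the second central moment matrix; a 1/12 pixel-extent
term keeps single-pixel regions finite. The full feature list of the original
software is not public; this set contains every feature named in the source
material (CD34 average, total, surround; elongated morphology) and the
feature *names* are stable API even though the formulas are this package's
own.

# Analyte quantification

Nonspecific DAB background varies between tumors and between regions of one
tumor; thresholding uncorrected intensities misclassifies cells. The
correction estimates the background as the mean intensity over extranuclear
pixels — outside every nucleus dilated by 2 px, so perinuclear analyte bleed
does not inflate the estimate — and subtracts it from the whole image,
clamping at zero (8-bit semantics). Background-free images pass through
essentially unchanged, and per-cell values are invariant to a constant
offset: the acceptance suite checks both on paired renders.

Per-cell expression is the *mean* corrected intensity in the compartment (not
the sum), so the positivity threshold has intensity units independent of
nucleus size; nuclear analytes (Ki67-like, p-STAT3-like) use the nucleus
itself, membrane/cytoplasm-adjacent analytes (p-ERK-like) use the nucleus
dilated by 2 px (0.5 µm at 400X and 0.25 µm/px), with contested dilation
pixels claimed by the nearer nucleus (ties to the lower id). Positivity is
strict (`value > threshold`). Summaries report, per image, the EC fraction of
all cells and the positive fraction among EC (`NA`, not 0, when an image has
no EC), and per tumor the median and 25th/75th percentiles across its images.

# Agreement statistics

Confusion-matrix metrics use the four standard ratios with zero-denominator
cases reported as missing. Cohen's $\kappa = (P_o - P_e)/(1 - P_e)$ uses
marginal-proportion chance agreement; two constant, equal raters have
$P_e = 1$ and get `NA` rather than 1. The original analysis used an
unspecified "model-based" variance estimator accounting for clustered
sampling of nuclei within images; this package substitutes a transparent
cluster (per-image) percentile bootstrap (default 2000 resamples), which
makes no distributional assumptions and is exactly reproducible from its
seed. Point estimates are always the plug-in formulas.

# What the synthetic data emulates — and what it does not

The tabular generator draws two-class Gaussian features: informative features
separated by `effect_size` within-class standard deviations, noise features
identically distributed in both classes, and additive per-cluster shifts
shared by all cells of an "image" (emulating region-to-region variability
within a tumor). The image generator renders non-overlapping elliptical
nuclei (EC elongated by a fixed axis ratio, non-EC near-circular), a CD34
ring of configurable width and intensity around EC nuclei only, and an
analyte channel bright inside positive nuclei over a constant nonspecific
background, with Poisson noise on the rendered means (matching the
segmentation's Poisson mixture model).

Defaults describe the study conditions used throughout the tests: tabular —
1000 cells, 4 informative + 40 noise features, effect size 2, EC fraction
0.25, 5 clusters of standard deviation 0.2; images — 200×200 px, 20 nuclei of
radius 7±1 px, EC fraction 0.25, elongation 2.5, CD34 ring intensity 200,
analyte intensity 150 with positivity fraction 0.3. Benchmarks run 25
replicates to a 50-label budget; the end-to-end classification check uses 20
rendered images (≈400 cells).

What passing these tests shows is that the algorithmic machinery is correct
and beats random sampling when informative features exist and classes are
reachable; it does *not* show performance on real tissue. Real images carry
touching and overlapping nuclei, uneven illumination, chromatic bleed-through
that survives unmixing, staining-batch effects, and EC whose CD34 ring is
broken or shared between vessels — none of which the renderer produces.
Synthetic separability (a clean `cd34_surround` signal) makes the end-to-end
sensitivity/specificity check considerably easier than the clinical problem.

# Numerical choices and degenerate inputs

Optimisation is BFGS on the smoothed objective with analytic gradients
(relative tolerance 10^-6, at most 500 iterations). The sigmoid and
log-sigmoid are computed in their numerically stable branches. Determinants
go through Cholesky factorisation on the log scale; non-positive-definite
inputs raise an error rather than returning `-Inf`. Degenerate cases are
contracts, not crashes: a blank image segments to zero nuclei; an empty mask
yields no seeds; a non-empty mask with no seeds becomes a single region with
a warning; single-class training sets are an error (the baselines' harness
instead carries the previous model forward when random sampling temporarily
sees one class); a histogram with one occupied bin is a degenerate-histogram
error. Poisson log-likelihoods with $\mu = 0$ use the $0 \ln 0 = 0$
convention and graph capacities are clamped at 10^6.

# Known limitations

Two-dimensional only; two-component Poisson mixture only; the merge score is
a geometric surrogate, not a trained appearance model; MRMR uses fixed 3-bin
discretisation at $\mu \pm \sigma$ (MID form); the comparator benchmark
follows the pre-selection protocol (feature selection on the fully labeled
design) with the restricted alternative exposed as a flag; kappa is binary
and unweighted. The CD34-average/total features of perfectly rendered
synthetic nuclei can be constant across a pool and are then dropped by
standardization — real images do not trigger this.
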