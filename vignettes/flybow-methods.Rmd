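---
title: "Sparse spatial bag-of-visual-words for embryo expression images: methods and design"
author: "flybow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse spatial bag-of-visual-words: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flybow)
```

# The problem

In situ hybridization produces images of where a gene is expressed in the
developing embryo. In the standard curation workflow these images arrive
pre-scaled and pre-aligned to a common template, grouped by gene and
developmental stage range, and each *image group* is annotated with a set of
controlled-vocabulary (CV) terms naming the anatomical structures that express
the gene. Curating these labels by hand does not scale, which motivates two
computational tasks:

* **annotation** — predict the set of CV terms for an image group
  (a multi-label classification problem), and
* **retrieval** — given a query image, return the most similar images in a
  database (to find genes with similar spatial expression).

Both tasks need an image representation that is robust to staining noise but
preserves *where* expression occurs, because CV terms are intrinsically
spatial.

# The representation

## Dense circular patches and an upright SIFT descriptor

Every image is covered with a dense grid of overlapping circular patches of
radius $r$ (default $r = 16$ px, grid stride $= r$, i.e. 50% linear overlap;
the patch count for an image is $I$). Each patch is described by an upright
SIFT-style descriptor $y \in \mathbb{R}^{128}$: gradient magnitudes weighted
by a Gaussian ($\sigma = r/2$), distributed by trilinear interpolation over a
$4\times4$ spatial grid of cells times 8 orientation bins, L2-normalized,
clipped at 0.2 and renormalized.

Two deliberate deviations from the textbook keypoint descriptor:

* **No dominant-orientation normalization.** The images are aligned to a
  common template; rotating descriptors to a local dominant orientation would
  throw away exactly the anatomical orientation information the spatial
  pooling relies on.
* **Restricted gradient support.** The descriptor is computed on the
  circularly masked patch, but only pixels whose central-difference stencil
  lies entirely inside the disk (distance $\le r-1$ from the center)
  contribute. This avoids the artificial intensity step at the mask boundary,
  and makes the descriptor *exactly* invariant to a global additive intensity
  shift — a property the test suite asserts bit-for-bit.

Patches with no gradient energy at all (flat background or uniform interior)
yield the zero vector and are flagged; they carry no visual-word mass
downstream rather than being assigned to an arbitrary word.

## Visual codebook

A codebook $D \in \mathbb{R}^{d \times c}$ (one centroid, or *visual word*,
per column) is fitted by k-means on descriptors pooled from a seeded random
subset of images (default: half of them; the fraction is a free parameter of
the protocol). The default codebook size is $c = 2000$ words; small studies
and the test suite use $c \approx 50$, which is ample for the synthetic
fixtures. Fitting uses Lloyd's algorithm from k-means++ seeding with 10
seeded restarts; the within-cluster sum of squares after every assignment
step is recorded in the codebook's training metadata and is non-increasing
by construction (asserted per iteration in the tests, and cross-checked
against `stats::kmeans` run from the same initialization). Centroids are kept
in raw descriptor units — no renormalization — so reconstruction residuals
below are in descriptor units too.

## Hard words and sparse visual sentences

The classic bag-of-words model quantizes each descriptor to its nearest
visual word:

$$\min_e \tfrac12 \lVert De - y\rVert_2^2
  \quad\text{s.t.}\quad e_i \in \{0,1\},\ \textstyle\sum_i e_i = 1,$$

whose solution is the indicator of the nearest centroid (ties go to the
lowest index). A descriptor that sits between several similar words loses
all but one of those relationships, so the sparse alternative represents a
patch as a *visual sentence* — a non-negative combination of a few words:

$$\min_x \tfrac12 \lVert Dx - y\rVert_2^2 + \lambda \lVert x\rVert_1
  \quad\text{s.t.}\quad x \ge 0,$$

with $\lambda = 0.01$ by default. One formulation note: the relaxed problem
is sometimes written with an unsquared residual norm, but the hard-assignment
problem it relaxes uses the squared form and the problem is of the lasso
family, so this package adopts the squared-residual objective throughout and
interprets $\lambda$ on that scale.

The solver is cyclic coordinate descent (compiled code), initialized at
$x = 0$, with exact single-coordinate minimization
$x_j \leftarrow \max\!\big(0, (b_j - \lambda - (Gx)_j + G_{jj}x_j)/G_{jj}\big)$
where $G = D^\top D$ and $b = D^\top y$, stopping when the relative objective
change over a sweep falls below $10^{-10}$ or after 10,000 sweeps. Because
the problem is convex and separable per coordinate under the non-negativity
constraint, this converges to the global optimum; the test suite verifies the
objective against an exhaustive support-enumeration oracle (all $2^c$
supports solved in closed form) to $10^{-6}$ on hundreds of random problems,
and checks the analytic limits: $x = y$ for an identity dictionary at
$\lambda = 0$, and $x = 0$ whenever $\lambda \ge \max_j (D^\top y)_j$ (the
KKT threshold).

## Global and spatial pooling

Patch codes are summed into histograms. The global bag is
$H = (h_1,\dots,h_J)$ with $h_j = \sum_{i=1}^{I} e_{ij}$ for hard codes (and
the analogous sum of sparse code rows). The spatial bag divides the image
into a $3\times6$ grid of half-open rectangles (remainder pixels absorbed by
the last row/column; a patch belongs to the cell containing its center, with
boundary centers going to the higher-index cell) and concatenates the
per-cell bags: $M_n = (H_1, \dots, H_n)$, $n = 18$, so the spatial vector is
18 times longer than the global one. Summing the blocks of $M_n$ recovers
$H$ exactly — a conservation identity the tests assert exactly for hard
counts and to $10^{-9}$ for sparse mass.

Group-level representations are the element-wise sum of the group's image
bags followed by L1 normalization, so group size does not scale the feature.
The aggregation rule for multiple images per group is a genuinely open
design point (curation databases mix views and replicate stainings); plain
summation preserves the counting semantics of the histogram and is what this
package uses, with normalization switchable off.

Four representation modes result, named as in the experiment tables:
`global-hard`, `global-sparse`, `spatial-hard`, `spatial-sparse`.

# The annotation protocol

* **Term selection.** Terms are ranked by the number of groups carrying
  them (ties alphabetical); experiments retain the top $N$ terms, growing
  $N$ in steps, so successive term sets are nested. Groups carrying none of
  the retained terms are dropped; every retained term must keep at least 2
  positive and 2 negative groups or selection fails loudly.
* **Splits.** Each experiment uses repeated (default 30; the acceptance runs
  use 10) random 1:1 train/test partitions, stratified per term. Exact
  simultaneous stratification of overlapping label sets is infeasible in
  general, so stratification is greedy: terms are processed from rarest to
  most frequent, and each term's not-yet-assigned positives are placed to
  balance that term. Rarest-first ordering is the deliberate choice: a rare
  term's two or three positives are impossible to rebalance once other terms
  have claimed them, while a frequent term processed late still has many
  unassigned positives with which to correct its count (this is the same
  insight as iterative stratification in the multi-label literature).
* **Classifiers.** One-vs-rest binary classifiers per term. The default is a
  linear-kernel SVM (libsvm) with regularization parameter $C = 1$; for
  classifier comparisons, L2-regularized logistic regression and ridge
  regression are available, with the regularization value chosen per term by
  4-fold cross-validation over $\{0.01, 0.1, 1, 10, 100\}$ maximizing
  validation F1. Because L1-normalized bags have entry magnitude
  $\sim 1/(18J)$ and a linear model at a *fixed* regularization level is
  scale-sensitive, features are rescaled to unit mean L2 row norm at
  training time (label-free and deterministic; the same factor is applied at
  prediction). Decision-score orientation is normalized so that positives
  score higher on the training data, since libsvm's raw decision-value sign
  depends on label ordering.
* **Metrics.** AUC is the Mann–Whitney rank statistic with midrank tie
  handling (invariant to monotone transforms of the scores). Binary
  predictions at decision threshold 0 give F1, sensitivity and specificity.
  Macro values are unweighted means over terms; means ± SD are reported
  across partitions. A term missing one class in a test half is excluded
  from the macro with a warning.
* **Over-sampling.** Rare terms can be balanced before training by
  resampling the positive examples with replacement until they match the
  negative count; negatives are never touched, and the draw is seeded. This
  targets the low-sensitivity regime that fixed-threshold prediction hits
  when positives are scarce.

# Retrieval

Retrieval operates per image, not per group. Each image's bag vector
(default mode: `global-sparse`) is L1-normalized and stored in an index;
queries rank all other images by cosine similarity, descending, ties broken
by image id, returning the top $k = 8$. Cosine makes self-similarity exactly
1, which is why a query made by id is removed from its own result list. The
similarity metric and the normalization of retrieval vectors are package
choices — cosine on normalized histograms is the standard bag-of-words
pairing.

# The synthetic image generator

All tests and the acceptance script run on synthetic embryo-like images, so
the package is exercisable end-to-end without any external database. The
generator emulates the *statistical structure the method assumes*:

* a fixed 192×96 8-bit canvas (an embryo-like 2:1 aspect ratio, large enough
  for a 3×6 grid of radius-16 patches, small enough for fast tests);
* an elliptical embryo mask (background exactly 0 outside);
* named expression patterns — periodic stripes, horizontal bands, discs,
  monotone ramps — whose geometry is fixed in embryo-normalized coordinates
  $(u, v) \in [0,1]^2$, mirroring the template alignment of real curated
  images. One term maps to one pattern, so per-term separability is
  controlled, and co-occurrence arises only from independent per-term
  sampling;
* additive Gaussian pixel noise inside the mask (default SD 8 gray levels on
  the 0–255 scale — visible but far below the pattern amplitude of 140),
  clipped to the valid range.

Default study conditions used by the acceptance runs: 200 groups, 3 images
per group, 4 spatially localized terms at prevalence 0.4 (the middle of a
0.3–0.5 band), codebook of 50 words trained on half the images, 10
partitions; retrieval uses 5 single-pattern clusters of 20 images each. At
these scales the synthetic task is *easy* for a spatially aware
representation — that is intentional. What passing shows is that the
machinery (descriptors, coding, pooling, protocol, metrics) is correct and
that the expected ordering (spatial-sparse ≥ global-hard for annotation,
sparse ≥ hard for retrieval) emerges; it does not show that these margins
transfer to real stained embryos, whose noise is structured (staining
artifacts, illumination, residual misalignment, multiple views) rather than
i.i.d. Gaussian.

# Numerical choices and degenerate inputs

* Sparse solver: objective tolerance $10^{-10}$ per sweep, 10,000-sweep cap,
  deterministic initialization at 0; coordinates with $G_{jj} = 0$ are
  skipped (a zero dictionary column never enters the support).
* Hard assignment ties: lowest column index, deterministically.
* k-means: empty clusters are re-seeded at the point farthest from its
  centroid, which preserves the monotone objective; restarts and seeding are
  derived from one integer seed.
* Flat patches: zero descriptor, flagged, zero code row in both modes — the
  one-hot invariant is relaxed only for flagged rows.
* All-zero bag vectors (an image with no usable patches) are left
  unnormalized rather than producing NaN.
* Every stochastic step (label draws, noise, image sampling, k-means
  seeding, partitioning, over-sampling, CV folds) flows from explicit
  integer seeds through one derivation function, which is what makes two
  runs of the CLI byte-identical.

# Limitations

* Only dense fixed layouts (no interest-point detection) and the single
  upright SIFT-style descriptor are provided, with a plug-in seam at
  `describeImage()` for alternatives.
* Only one spatial partition (3×6) plus the global bag; no multi-level
  pyramid weighting.
* The aggregation of multiple views of an embryo is not modeled; all images
  of a group are pooled symmetrically.
* JPEG input is not supported (PNG/TIFF only).
* The synthetic generator does not simulate staining artifacts, rotation or
  scale misalignment; conclusions about robustness to those must come from
  real data.

# Scales used by the shipped checks

The test suite and `scripts/acceptance.R` choose problem sizes as a package
decision: oracle comparisons at $d = 8$, $c = 5$ over 300 random problems;
conservation on 5 rendered images with a 20-word codebook; the annotation
recovery study at 200 groups × 3 images, 4 terms, $c = 50$, 10 partitions;
retrieval at 100 images, $c = 50$. A full-scale run ($c = 2000$, 30
partitions, thousands of groups) uses identical code paths through the same
configuration list.
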