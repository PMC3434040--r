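# flybow — sparse spatial bag-of-visual-words for embryo expression images

`flybow` implements a sparse, spatially aware bag-of-visual-words
representation for standardized 2-D gene-expression pattern images (e.g.
whole-embryo in situ hybridization images aligned to a common template),
together with the two workflows such representations exist for:

* **multi-label annotation** of image groups with controlled-vocabulary (CV)
  terms, via one-vs-rest linear SVMs with a repeated stratified 1:1 split
  protocol, AUC / macro-F1 / sensitivity / specificity reporting, and
  optional positive-class over-sampling;
* **content-based retrieval** of the top-k most similar images by cosine
  similarity.

It is aimed at computational biologists building or benchmarking automated
curation pipelines for spatial expression databases, and it ships a synthetic
embryo-image generator so everything is testable end-to-end with no external
data.

## The model

Each image is covered by dense overlapping circular patches (radius 16 px,
stride 16 px), each described by an upright 128-d SIFT descriptor
*y* ∈ ℝ<sup>d</sup>. A k-means codebook *D* ∈ ℝ<sup>d×c</sup> (default
c = 2000 visual words) quantizes patches either by **hard assignment**

> min<sub>e</sub> ½‖De − y‖² s.t. e ∈ {0,1}<sup>c</sup>, Σe = 1,

(the nearest visual word) or by a non-negative ℓ1-sparse **visual sentence**

> min<sub>x</sub> ½‖Dx − y‖² + λ‖x‖₁ s.t. x ≥ 0, λ = 0.01,

solved by coordinate descent and verified in the tests against an exhaustive
support-enumeration oracle. Codes are pooled into a global histogram
H = (h₁, …, h<sub>J</sub>), h<sub>j</sub> = Σᵢ e<sub>ij</sub>, or into the
spatial concatenation M<sub>n</sub> = (H₁, …, H<sub>n</sub>) over a 3×6 grid
(n = 18), whose block-sum reproduces H exactly. Group-level features are the
L1-normalized sum of the group's image bags. The four resulting modes are
`global-hard`, `global-sparse`, `spatial-hard`, `spatial-sparse`.

## Worked example

Generate 60 synthetic embryo groups carrying 4 spatially localized terms,
then compare the spatial-sparse representation against the plain global
bag-of-words on the annotation task:

```r
library(flybow)

spec <- syntheticSpec(noiseSd = 8, seed = 42)
gs <- generateGroupSet(spec, nGroups = 60, imagesPerGroup = 2,
                       termCatalog = c("stripe_triplet", "anterior_spot",
                                       "posterior_spot", "dorsal_band"),
                       prevalence = 0.4, seed = 42)
gs
#> LabeledGroupSet: 60 groups, 120 images, 4 terms
#>   term frequencies:
#>     dorsal_band: 30
#>     anterior_spot: 29
#>     posterior_spot: 28
#>     stripe_triplet: 23

res <- runAnnotationExperiment(gs, list(codebookSize = 50L, partitions = 5L,
                                        seed = 42L,
                                        modes = c("spatial-sparse",
                                                  "global-hard")))
print(res, digits = 3)
#>   n_terms           mode      metric  mean     sd
#> 1       4 spatial-sparse         auc 1.000 0.0000
#> 2       4 spatial-sparse          f1 1.000 0.0000
#> 3       4 spatial-sparse sensitivity 1.000 0.0000
#> 4       4 spatial-sparse specificity 1.000 0.0000
#> 5       4    global-hard         auc 0.930 0.0248
#> 6       4    global-hard          f1 0.887 0.0251
#> 7       4    global-hard sensitivity 0.905 0.0345
#> 8       4    global-hard specificity 0.856 0.0564
```

Each row is a macro metric averaged over terms, reported as mean ± SD across
the 5 stratified 1:1 train/test partitions. On these cleanly localized
synthetic patterns the spatial-sparse representation separates every term
perfectly, while the global hard histogram — which discards *where* words
occur — misclassifies some groups: the expected ordering for spatially
defined labels.

Retrieval works per image:

```r
images <- list(a = generateImage(spec, "stripe_triplet", noiseSeed = 1),
               b = generateImage(spec, "stripe_triplet", noiseSeed = 2),
               c = generateImage(spec, "dorsal_band",    noiseSeed = 3))
lay <- makeLayout(192, 96)
smp <- do.call(rbind, lapply(images, function(im)
  descriptorMatrix(describeImage(im, lay))))
cb  <- buildCodebook(smp[rowSums(smp) > 0, ], c = 20, seed = 1)
idx <- buildIndex(images, cb, mode = "global-sparse")
queryIndex(idx, "a", k = 2)
#>   rank image_id similarity
#> 1    1        b  0.9993233
#> 2    2        c  0.4808064
```

The noise-replicate of the same stripe pattern ranks first; the band-pattern
image trails it.

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
FLYBOW=$(Rscript -e 'cat(system.file("cli/flybow.R", package = "flybow"))')
Rscript $FLYBOW simulate --out imgs --groups 40 --seed 1
Rscript $FLYBOW codebook --images imgs --out cb --codebook-size 50 --seed 1
Rscript $FLYBOW encode   --images imgs --codebook cb --out vectors.tsv
Rscript $FLYBOW annotate --images imgs --codebook cb --out metrics.csv
Rscript $FLYBOW retrieve --images imgs --codebook cb --query g0001/1 --k 8
```

Subcommands read/write plain PNG, CSV and TSV; every run logs the seed and a
hash of the effective configuration, and identical configuration + seed gives
byte-identical outputs.

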