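#' @import methods
#' @importFrom stats rnorm runif rbinom sd
#' @importFrom utils write.csv read.csv head
#' @useDynLib flybow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' PatchLayout: dense grid of overlapping circular patches
#'
#' Records where local descriptors are computed on an image: an ordered set of
#' circle centers (0-based pixel coordinates, x right / y down) plus the common
#' patch radius. Centers are stored row-major (top-to-bottom, left-to-right).
#'
#' @slot centers integer matrix with one row per patch and columns `x`, `y`.
#' @slot radius patch radius in pixels.
#' @slot imageWidth,imageHeight dimensions of the image the layout was built for.
#' @seealso [makeLayout()], [extractPatch()]
#' @export
setClass("PatchLayout",
  representation(centers = "matrix", radius = "integer",
                 imageWidth = "integer", imageHeight = "integer"))

setValidity("PatchLayout", function(object) {
  ctr <- object@centers
  r <- object@radius
  if (ncol(ctr) != 2L) return("centers must have two columns (x, y)")
  if (anyDuplicated(ctr)) return("duplicate patch centers")
  if (any(ctr[, 1] < r) || any(ctr[, 1] > object@imageWidth - r) ||
      any(ctr[, 2] < r) || any(ctr[, 2] > object@imageHeight - r))
    return("a patch circle extends beyond the image bounds")
  ord <- order(ctr[, 2], ctr[, 1])
  if (!identical(ord, seq_len(nrow(ctr))))
    return("centers must be ordered row-major")
  TRUE
})

#' DescriptorSet: per-image local feature vectors
#'
#' One fixed-length descriptor per patch, aligned one-to-one with the patch
#' centers of the [PatchLayout-class] it was computed from. Patches with no
#' gradient signal (flat patches) yield the zero vector and are flagged rather
#' than dropped, so row order always matches center order.
#'
#' @slot vectors numeric matrix, one row per patch (I x d).
#' @slot centers patch centers carried from the layout.
#' @slot zeroFlag logical, `TRUE` for flat (all-zero descriptor) patches.
#' @slot imageWidth,imageHeight image dimensions, carried for spatial pooling.
#' @export
setClass("DescriptorSet",
  representation(vectors = "matrix", centers = "matrix", zeroFlag = "logical",
                 imageWidth = "integer", imageHeight = "integer"))

setValidity("DescriptorSet", function(object) {
  if (nrow(object@vectors) != nrow(object@centers))
    return("descriptor rows and centers must align")
  if (length(object@zeroFlag) != nrow(object@vectors))
    return("zeroFlag length must equal descriptor count")
  if (!all(is.finite(object@vectors))) return("non-finite descriptor entries")
  n2 <- sqrt(rowSums(object@vectors^2))
  if (any(n2 > 1 + 1e-6)) return("descriptor L2 norm exceeds 1")
  TRUE
})

#' VisualCodebook: the visual-word dictionary
#'
#' The dictionary matrix D (d x c); each column is a k-means centroid, i.e. one
#' visual word in descriptor space. `trainingMeta` records how the codebook was
#' fitted: sample size, seed, iteration count and the per-iteration
#' within-cluster sum of squares (which is non-increasing for Lloyd's
#' algorithm).
#'
#' @slot D numeric matrix, descriptors along rows dimension (d x c).
#' @slot trainingMeta list with at least `sampleSize`, `seed`, `iterations`,
#'   `objectiveTrace`.
#' @seealso [buildCodebook()], [saveCodebook()]
#' @export
setClass("VisualCodebook",
  representation(D = "matrix", trainingMeta = "list"))

setValidity("VisualCodebook", function(object) {
  if (!all(is.finite(object@D))) return("codebook has non-finite entries")
  if (ncol(object@D) < 2L) return("codebook needs at least 2 words")
  if (anyDuplicated(t(object@D))) return("duplicate codebook columns")
  TRUE
})

#' PatchCodes: per-patch code vectors for one image
#'
#' The I x c matrix of patch codes: each row is either a one-hot hard
#' assignment to the nearest visual word, or a non-negative sparse code
#' ("visual sentence"). Flat patches carry a zero row and stay flagged.
#'
#' @slot codes numeric I x c matrix.
#' @slot centers patch centers carried through from the descriptors.
#' @slot mode `"hard"` or `"sparse"`.
#' @slot lambda sparsity weight used (`NA` for hard mode).
#' @slot objectives per-patch solver objective at the solution.
#' @slot zeroFlag flags carried from the [DescriptorSet-class].
#' @slot imageWidth,imageHeight image dimensions.
#' @export
setClass("PatchCodes",
  representation(codes = "matrix", centers = "matrix", mode = "character",
                 lambda = "numeric", objectives = "numeric",
                 zeroFlag = "logical",
                 imageWidth = "integer", imageHeight = "integer"))

setValidity("PatchCodes", function(object) {
  if (!object@mode %in% c("hard", "sparse")) return("mode must be hard or sparse")
  if (any(object@codes < 0)) return("codes must be non-negative")
  if (object@mode == "hard") {
    live <- !object@zeroFlag
    ok <- apply(object@codes[live, , drop = FALSE], 1,
                function(z) sum(z == 1) == 1 && sum(z != 0) == 1)
    if (!all(ok)) return("hard codes must be one-hot for non-flagged patches")
  }
  TRUE
})

#' BagVector: a (spatial) bag-of-words representation
#'
#' A global bag is the length-J histogram of visual-word mass over a whole
#' image; a spatial bag is the concatenation of per-cell bags over a
#' rows x cols grid partition, giving length rows*cols*J. Block b (0-based,
#' row-major cells) occupies entries `b*J + 1:J`. Summing the blocks of a
#' spatial bag recovers the global bag computed from the same codes.
#'
#' @slot values non-negative numeric vector of length rows*cols*J.
#' @slot grid integer pair (rows, cols); `c(1,1)` for the global bag.
#' @slot J codebook size.
#' @slot level `"image"` or `"group"`.
#' @export
setClass("BagVector",
  representation(values = "numeric", grid = "integer", J = "integer",
                 level = "character"))

setValidity("BagVector", function(object) {
  if (length(object@grid) != 2L || any(object@grid < 1L))
    return("grid must be two positive integers")
  if (length(object@values) != prod(object@grid) * object@J)
    return("values length must equal rows*cols*J")
  if (any(object@values < -1e-12)) return("bag values must be non-negative")
  if (!object@level %in% c("image", "group")) return("level must be image or group")
  TRUE
})

#' SyntheticSpec: parameters of the synthetic embryo-image generator
#'
#' Describes a standardized embryo-like canvas: a fixed-size 8-bit grayscale
#' image, an elliptical embryo mask centered on the canvas, and a catalog of
#' named expression patterns (stripes, bands, spots, gradients) whose geometry
#' is expressed in embryo-normalized coordinates: (u, v) in \[0,1\]^2 spanning
#' the bounding box of the ellipse, u along the anterior-posterior (major)
#' axis, v along the dorsal-ventral (minor) axis. Rendering a pattern for a
#' term simulates a spatially localized expression domain; the presence of a
#' pattern defines the term's ground-truth label.
#'
#' @slot canvasWidth,canvasHeight canvas size in pixels.
#' @slot embryoAxes numeric pair (semi-major, semi-minor) in pixels.
#' @slot patterns named list: term name -> pattern parameter list (see
#'   [syntheticSpec()]).
#' @slot baseIntensity gray level of unstained embryo tissue.
#' @slot amplitude gray-level increment of an expressed pattern.
#' @slot noiseSd standard deviation of additive Gaussian noise (gray levels).
#' @slot seed base seed for reproducible noise.
#' @export
setClass("SyntheticSpec",
  representation(canvasWidth = "integer", canvasHeight = "integer",
                 embryoAxes = "numeric", patterns = "list",
                 baseIntensity = "numeric", amplitude = "numeric",
                 noiseSd = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (object@canvasWidth < 1L || object@canvasHeight < 1L)
    return("canvas dimensions must be positive")
  if (length(object@embryoAxes) != 2L || any(object@embryoAxes <= 0))
    return("embryoAxes must be two positive semi-axis lengths")
  if (2 * object@embryoAxes[1] > object@canvasWidth ||
      2 * object@embryoAxes[2] > object@canvasHeight)
    return("embryo ellipse does not fit in the canvas")
  if (is.null(names(object@patterns)) && length(object@patterns) > 0)
    return("patterns must be a named list")
  for (nm in names(object@patterns)) {
    p <- object@patterns[[nm]]
    if (!p$kind %in% c("stripe", "band", "spot", "gradient"))
      return(sprintf("unknown pattern kind for term '%s'", nm))
  }
  TRUE
})

#' LabeledGroupSet: image groups with multi-term labels
#'
#' The unit of annotation: an image group (in the motivating application, all
#' images of one gene in one developmental stage range) carries a set of
#' controlled-vocabulary term labels that apply to the group collectively.
#'
#' @slot groups named list; each element a list of grayscale image matrices
#'   (gray values 0-255, rows = y, cols = x) sharing the canvas size.
#' @slot labels named list parallel to `groups`; each element a character
#'   vector of term names (possibly empty).
#' @slot canvas integer pair (width, height).
#' @seealso [generateGroupSet()], [termFrequencies()]
#' @export
setClass("LabeledGroupSet",
  representation(groups = "list", labels = "list", canvas = "integer"))

setValidity("LabeledGroupSet", function(object) {
  if (!identical(names(object@groups), names(object@labels)))
    return("groups and labels must share names")
  if (any(vapply(object@groups, length, 1L) < 1L))
    return("every group needs at least one image")
  dims <- unique(t(vapply(object@groups, function(g)
    dim(g[[1]]), integer(2))))
  if (nrow(dims) > 1L) return("all images must share canvas dimensions")
  TRUE
})

#' AnnotationDataset: features and binary term labels per group
#'
#' Group-level representation matrix X paired with the binary label matrix Y.
#' Term columns are ordered by descending frequency (ties broken
#' alphabetically), matching the protocol of growing the term set from the most
#' frequent terms downward.
#'
#' @slot X numeric groups x features matrix of group bag vectors.
#' @slot Y binary groups x terms matrix.
#' @slot termNames term names in column order of Y.
#' @slot termFrequencies positive-group count per term, same order.
#' @export
setClass("AnnotationDataset",
  representation(X = "matrix", Y = "matrix", termNames = "character",
                 termFrequencies = "integer"))

setValidity("AnnotationDataset", function(object) {
  if (nrow(object@X) != nrow(object@Y)) return("X and Y row counts differ")
  if (!all(object@Y %in% c(0, 1))) return("Y must be binary")
  if (ncol(object@Y) != length(object@termNames)) return("term names misaligned")
  f <- object@termFrequencies
  if (is.unsorted(rev(f))) return("terms must be ordered by descending frequency")
  if (any(colSums(object@Y) != f)) return("termFrequencies inconsistent with Y")
  TRUE
})

#' RetrievalIndex: per-image representation vectors for similarity search
#'
#' @slot ids unique image identifiers.
#' @slot M numeric matrix, one L1-normalized representation row per image.
#' @slot metric similarity metric name (only `"cosine"` is implemented).
#' @slot mode encoding mode used to build the index.
#' @export
setClass("RetrievalIndex",
  representation(ids = "character", M = "matrix", metric = "character",
                 mode = "character"))

setValidity("RetrievalIndex", function(object) {
  if (anyDuplicated(object@ids)) return("image ids must be unique")
  if (length(object@ids) != nrow(object@M)) return("ids and matrix rows differ")
  TRUE
})

## ---- show methods ----

setMethod("show", "PatchLayout", function(object) {
  cat(sprintf("PatchLayout: %d circular patches, radius %d px, image %dx%d\n",
              nrow(object@centers), object@radius,
              object@imageWidth, object@imageHeight))
})

setMethod("show", "DescriptorSet", function(object) {
  cat(sprintf("DescriptorSet: %d descriptors of length %d (%d flat)\n",
              nrow(object@vectors), ncol(object@vectors), sum(object@zeroFlag)))
})

setMethod("show", "VisualCodebook", function(object) {
  m <- object@trainingMeta
  cat(sprintf("VisualCodebook: %d words of length %d (k-means on %s descriptors, seed %s)\n",
              ncol(object@D), nrow(object@D),
              m$sampleSize %||% "?", m$seed %||% "?"))
})

setMethod("show", "PatchCodes", function(object) {
  cat(sprintf("PatchCodes: %d patches x %d words, mode %s%s\n",
              nrow(object@codes), ncol(object@codes), object@mode,
              if (object@mode == "sparse")
                sprintf(" (lambda %g)", object@lambda) else ""))
})

setMethod("show", "BagVector", function(object) {
  cat(sprintf("BagVector (%s level): grid %dx%d, %d words, length %d, L1 mass %.4g\n",
              object@level, object@grid[1], object@grid[2], object@J,
              length(object@values), sum(object@values)))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %dx%d canvas, embryo axes (%g, %g), %d patterns, noise sd %g\n",
              object@canvasWidth, object@canvasHeight,
              object@embryoAxes[1], object@embryoAxes[2],
              length(object@patterns), object@noiseSd))
})

setMethod("show", "LabeledGroupSet", function(object) {
  f <- termFrequencies(object)
  cat(sprintf("LabeledGroupSet: %d groups, %d images, %d terms\n",
              length(object@groups),
              sum(vapply(object@groups, length, 1L)), length(f)))
  if (length(f)) {
    cat("  term frequencies:\n")
    for (i in seq_along(f))
      cat(sprintf("    %s: %d\n", names(f)[i], f[i]))
  }
})

setMethod("show", "AnnotationDataset", function(object) {
  cat(sprintf("AnnotationDataset: %d groups x %d features, %d terms (freq %s)\n",
              nrow(object@X), ncol(object@X), ncol(object@Y),
              paste(object@termFrequencies, collapse = ", ")))
})

setMethod("show", "RetrievalIndex", function(object) {
  cat(sprintf("RetrievalIndex: %d images, %d features, metric %s, mode %s\n",
              nrow(object@M), ncol(object@M), object@metric, object@mode))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
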