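# Image- and group-level representation building: the glue between the
# encoding/pooling primitives and the annotation / retrieval protocols.

modeGrid <- function(mode, grid = c(3L, 6L)) {
  switch(mode,
    "global-hard"    = list(enc = "hard",   grid = c(1L, 1L)),
    "global-sparse"  = list(enc = "sparse", grid = c(1L, 1L)),
    "spatial-hard"   = list(enc = "hard",   grid = as.integer(grid)),
    "spatial-sparse" = list(enc = "sparse", grid = as.integer(grid)),
    stop(sprintf("unknown representation mode '%s'", mode)))
}

#' Represent a single image as a bag vector
#'
#' Convenience wrapper: describe, encode, pool.
#'
#' @param image grayscale image matrix.
#' @param codebook a [VisualCodebook-class].
#' @param mode one of `"global-hard"`, `"global-sparse"`, `"spatial-hard"`,
#'   `"spatial-sparse"`.
#' @param grid spatial grid used by the spatial modes (default 3 x 6).
#' @param lambda sparsity weight for the sparse modes.
#' @param radius,stride patch layout parameters.
#' @param layout optional precomputed [PatchLayout-class].
#' @return A [BagVector-class] at image level.
#' @export
representImage <- function(image, codebook, mode = "spatial-sparse",
                           grid = c(3L, 6L), lambda = 0.01,
                           radius = 16L, stride = radius, layout = NULL) {
  mg <- modeGrid(mode, grid)
  if (is.null(layout))
    layout <- makeLayout(ncol(image), nrow(image), radius, stride)
  ds <- describeImage(image, layout)
  poolImage(encodeImage(ds, codebook, mode = mg$enc, lambda = lambda),
            grid = mg$grid)
}

# Describe every image of a group set once; returns a nested list parallel to
# the groups. Used to share descriptor work across representation modes.
describeGroupSet <- function(groupSet, layout, verbose = FALSE) {
  ids <- groupIds(groupSet)
  out <- lapply(seq_along(ids), function(k) {
    if (verbose && k %% 50L == 0L)
      message(sprintf("  described %d/%d groups", k, length(ids)))
    lapply(groupImages(groupSet, ids[k]), describeImage, layout = layout)
  })
  names(out) <- ids
  out
}

#' Group-level feature matrices for one or more representation modes
#'
#' Computes descriptors once per image, encodes them (hard and/or sparse as
#' the requested modes require), pools per image and aggregates per group
#' (sum + L1 normalization).
#'
#' @param groupSet a [LabeledGroupSet-class].
#' @param codebook a [VisualCodebook-class].
#' @param modes character vector of representation modes (see
#'   [representImage()]).
#' @param grid spatial grid for the spatial modes.
#' @param lambda sparsity weight.
#' @param radius,stride patch layout parameters.
#' @param normalize L1-normalize group vectors?
#' @param descriptorCache optional result of a previous internal description
#'   pass (one list of [DescriptorSet-class] per group).
#' @param verbose print progress?
#' @return Named list of groups x features matrices, one per mode, with group
#'   ids as row names.
#' @export
groupFeatureMatrices <- function(groupSet, codebook,
                                 modes = c("global-hard", "global-sparse",
                                           "spatial-hard", "spatial-sparse"),
                                 grid = c(3L, 6L), lambda = 0.01,
                                 radius = 16L, stride = radius,
                                 normalize = TRUE, descriptorCache = NULL,
                                 verbose = FALSE) {
  ids <- groupIds(groupSet)
  canvas <- groupSet@canvas
  layout <- makeLayout(canvas[1], canvas[2], radius, stride)
  if (is.null(descriptorCache))
    descriptorCache <- describeGroupSet(groupSet, layout, verbose)
  encModes <- unique(vapply(modes, function(m) modeGrid(m, grid)$enc, ""))
  out <- lapply(modes, function(m) NULL)
  names(out) <- modes
  rows <- lapply(modes, function(m) vector("list", length(ids)))
  names(rows) <- modes
  for (k in seq_along(ids)) {
    dss <- descriptorCache[[ids[k]]]
    codes <- lapply(encModes, function(e)
      lapply(dss, encodeImage, codebook = codebook, mode = e, lambda = lambda))
    names(codes) <- encModes
    for (m in modes) {
      mg <- modeGrid(m, grid)
      bags <- lapply(codes[[mg$enc]], poolImage, grid = mg$grid)
      rows[[m]][[k]] <- bagValues(poolGroup(bags, normalize = normalize))
    }
    if (verbose && k %% 50L == 0L)
      message(sprintf("  encoded %d/%d groups", k, length(ids)))
  }
  for (m in modes) {
    X <- do.call(rbind, rows[[m]])
    rownames(X) <- ids
    out[[m]] <- X
  }
  out
}

#' Pair a feature matrix with the binary term-label matrix
#'
#' Builds an [AnnotationDataset-class]: Y has one column per term observed in
#' the group set, ordered by descending frequency (alphabetical on ties).
#'
#' @param groupSet a [LabeledGroupSet-class].
#' @param X groups x features matrix with group ids as row names (e.g. from
#'   [groupFeatureMatrices()]).
#' @return An [AnnotationDataset-class].
#' @export
makeAnnotationDataset <- function(groupSet, X) {
  ids <- groupIds(groupSet)
  if (!identical(rownames(X), ids)) stop("X rows must match group ids")
  freq <- termFrequencies(groupSet)
  terms <- names(freq)
  lab <- groupLabels(groupSet)
  Y <- vapply(terms, function(t)
    as.numeric(vapply(lab, function(l) t %in% l, TRUE)), numeric(length(ids)))
  Y <- matrix(Y, nrow = length(ids), dimnames = list(ids, terms))
  new("AnnotationDataset", X = X, Y = Y, termNames = terms,
      termFrequencies = unname(freq))
}
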