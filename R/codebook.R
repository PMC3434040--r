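#' Pool descriptors from a random subset of images
#'
#' Codebook training does not need every image: a seeded random subset of the
#' images is described and their non-flat descriptors pooled into one sample
#' matrix. The number of images drawn is `ceiling(fraction * nImages)`.
#'
#' @param groupSet a [LabeledGroupSet-class].
#' @param layout a [PatchLayout-class] matching the canvas.
#' @param fraction proportion of images to draw, in (0, 1\].
#' @param seed integer seed for the image draw.
#' @return Numeric matrix (descriptors x 128) with attribute `sourceImages`,
#'   the number of images sampled.
#' @export
sampleDescriptors <- function(groupSet, layout, fraction = 0.5, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  ids <- groupIds(groupSet)
  all <- do.call(rbind, lapply(ids, function(id)
    data.frame(id = id, img = seq_along(groupImages(groupSet, id)))))
  nDraw <- ceiling(fraction * nrow(all))
  pick <- withSeed(seed, sample.int(nrow(all), nDraw))
  mats <- lapply(pick, function(k) {
    ds <- describeImage(groupImages(groupSet, all$id[k])[[all$img[k]]], layout)
    descriptorMatrix(ds)[!zeroFlags(ds), , drop = FALSE]
  })
  out <- do.call(rbind, mats)
  if (is.null(out) || nrow(out) == 0L)
    stop("no usable descriptors in the sampled images")
  attr(out, "sourceImages") <- nDraw
  out
}

# Squared Euclidean distances between sample rows and centroid rows.
crossDist2 <- function(X, C) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
  pmax(d2, 0)
}

# k-means++ seeding: first centroid uniform, then D^2-weighted draws.
kmeansppInit <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums((X - rep(centers[1, ], each = n))^2)
  for (j in seq_len(k - 1L) + 1L) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- X[sample.int(n, 1L, prob = probs), ]
    d2 <- pmin(d2, rowSums((X - rep(centers[j, ], each = n))^2))
  }
  centers
}

# One Lloyd run from a given init; records the objective after every
# assignment step, which is non-increasing by construction. Empty clusters
# are re-seeded at the point currently farthest from its centroid.
lloyd <- function(X, centers, maxIter) {
  trace <- numeric(0)
  assign <- NULL
  for (it in seq_len(maxIter)) {
    d2 <- crossDist2(X, centers)
    assign <- max.col(-d2, ties.method = "first")
    obj <- sum(d2[cbind(seq_len(nrow(X)), assign)])
    trace <- c(trace, obj)
    if (it > 1L && (trace[it - 1L] - obj) <= 1e-10 * max(1, trace[it - 1L]))
      break
    newC <- rowsum(X, assign)        # rows sorted by cluster id
    counts <- tabulate(assign, nbins = nrow(centers))
    present <- sort(unique(assign))
    centers[present, ] <- newC / counts[present]
    empty <- which(counts == 0L)
    if (length(empty)) {
      far <- order(d2[cbind(seq_len(nrow(X)), assign)], decreasing = TRUE)
      centers[empty, ] <- X[far[seq_along(empty)], , drop = FALSE]
    }
  }
  list(centers = centers, objective = trace[length(trace)], trace = trace,
       assign = assign)
}

#' Build the visual codebook by k-means
#'
#' Clusters the descriptor sample with Lloyd's algorithm from k-means++
#' seeding, keeping the best of `nRestarts` seeded restarts. The
#' within-cluster sum of squares after every assignment step is recorded in
#' `trainingMeta(codebook)$objectiveTrace` and is non-increasing within a run.
#' The default codebook size is 2000 visual words; tests and small studies
#' typically override it downward.
#'
#' @param sample descriptor sample matrix (rows = descriptors), e.g. from
#'   [sampleDescriptors()].
#' @param c codebook size (number of visual words).
#' @param seed integer seed for initialization.
#' @param maxIter Lloyd iteration cap per restart.
#' @param nRestarts number of seeded restarts.
#' @return A [VisualCodebook-class]; the dictionary matrix is d x c with one
#'   centroid per column, in descriptor units (no renormalization, so sparse
#'   reconstruction residuals stay in descriptor units too).
#' @export
buildCodebook <- function(sample, c = 2000L, seed = 1L, maxIter = 100L,
                          nRestarts = 10L) {
  c <- as.integer(c)
  if (nrow(sample) < c)
    stop(sprintf("sample has %d descriptors but %d words were requested",
                 nrow(sample), c))
  best <- NULL
  for (r in seq_len(nRestarts)) {
    fit <- withSeed(deriveSeed(seed, r), {
      init <- kmeansppInit(sample, c)
      lloyd(sample, init, maxIter)
    })
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  new("VisualCodebook", D = t(best$centers),
      trainingMeta = list(sampleSize = nrow(sample), seed = as.integer(seed),
                          iterations = length(best$trace),
                          objectiveTrace = best$trace,
                          objective = best$objective,
                          restarts = as.integer(nRestarts)))
}

#' Persist / reload a codebook
#'
#' The dictionary is stored as a flat little-endian double array
#' (`<path>.bin`, column-major) next to a JSON sidecar (`<path>.json`)
#' carrying `d`, `c`, the training metadata, a format version and an MD5
#' checksum of the binary file. `loadCodebook()` verifies version, shape and
#' checksum and errors on any mismatch; the round-trip is bit-exact.
#'
#' @param codebook a [VisualCodebook-class].
#' @param path path prefix (without extension).
#' @return `saveCodebook()` the prefix, invisibly; `loadCodebook()` the
#'   reloaded [VisualCodebook-class].
#' @export
saveCodebook <- function(codebook, path) {
  D <- codebookMatrix(codebook)
  bin <- paste0(path, ".bin")
  con <- file(bin, "wb")
  writeBin(as.numeric(D), con, size = 8L, endian = "little")
  close(con)
  meta <- trainingMeta(codebook)
  side <- list(format = "flybow-codebook", version = 1L,
               d = nrow(D), c = ncol(D),
               checksum = unname(tools::md5sum(bin)),
               trainingMeta = meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname saveCodebook
#' @export
loadCodebook <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(side$format, "flybow-codebook") || side$version != 1L)
    stop("not a recognized codebook file (wrong format/version)")
  bin <- paste0(path, ".bin")
  if (!identical(unname(tools::md5sum(bin)), side$checksum))
    stop("codebook binary checksum mismatch")
  vals <- readBin(bin, "numeric", n = file.size(bin) / 8L, size = 8L,
                  endian = "little")
  if (length(vals) != side$d * side$c)
    stop(sprintf("codebook shape mismatch: sidecar says %dx%d, file has %d values",
                 side$d, side$c, length(vals)))
  meta <- side$trainingMeta
  meta$seed <- as.integer(meta$seed)
  new("VisualCodebook", D = matrix(vals, side$d, side$c), trainingMeta = meta)
}
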