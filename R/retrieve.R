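# Content-based retrieval over per-image bag vectors: pairwise cosine
# similarity, top-k ranking with the query removed.

#' Build a retrieval index
#'
#' Computes one representation vector per image (per image, not per group),
#' L1-normalized. The default mode is the global sparse representation: for
#' retrieval the sparse features alone carry most of the signal, with the
#' spatial modes available when the layout matters.
#'
#' @param images named list of grayscale image matrices; names become image
#'   ids.
#' @param codebook a [VisualCodebook-class].
#' @param mode representation mode (see [representImage()]).
#' @param grid spatial grid for the spatial modes.
#' @param lambda sparsity weight.
#' @param radius,stride patch layout parameters.
#' @return A [RetrievalIndex-class].
#' @export
buildIndex <- function(images, codebook, mode = "global-sparse",
                       grid = c(3L, 6L), lambda = 0.01,
                       radius = 16L, stride = radius) {
  if (length(images) == 0L) stop("empty image set")
  ids <- names(images)
  if (is.null(ids)) ids <- sprintf("img%04d", seq_along(images))
  layout <- makeLayout(ncol(images[[1]]), nrow(images[[1]]), radius, stride)
  M <- do.call(rbind, lapply(images, function(im)
    l1Normalize(bagValues(representImage(im, codebook, mode = mode,
                                         grid = grid, lambda = lambda,
                                         layout = layout)))))
  rownames(M) <- ids
  new("RetrievalIndex", ids = ids, M = M, metric = "cosine", mode = mode)
}

cosineSim <- function(M, q) {
  qn <- sqrt(sum(q^2))
  rn <- sqrt(rowSums(M^2))
  s <- as.numeric(M %*% q)
  ok <- rn > 0 & qn > 0
  out <- numeric(nrow(M))
  out[ok] <- s[ok] / (rn[ok] * qn)
  out
}

#' Query the retrieval index
#'
#' Ranks all indexed images by cosine similarity to the query, in descending
#' order with ties broken by image id, and returns the top `k` (default 8).
#' When querying by id, the query image itself is removed from the results --
#' it is always its own best match with similarity 1.
#'
#' @param index a [RetrievalIndex-class].
#' @param query an image id present in the index, or a numeric representation
#'   vector of matching length.
#' @param k number of hits to return (default 8).
#' @return Data frame with columns `rank`, `image_id`, `similarity`.
#' @export
queryIndex <- function(index, query, k = 8L) {
  if (k < 1L) stop("k must be >= 1")
  ids <- indexIds(index)
  M <- indexMatrix(index)
  exclude <- character(0)
  if (is.character(query)) {
    if (!query %in% ids) stop(sprintf("unknown image id '%s'", query))
    q <- M[match(query, ids), ]
    exclude <- query
  } else {
    if (length(query) != ncol(M))
      stop("query vector length does not match the index")
    q <- l1Normalize(as.numeric(query))
  }
  sims <- cosineSim(M, q)
  keep <- !(ids %in% exclude)
  ord <- order(-sims[keep], ids[keep])
  topk <- head(ord, k)
  data.frame(rank = seq_along(topk),
             image_id = ids[keep][topk],
             similarity = sims[keep][topk])
}
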