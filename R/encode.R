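# Patch-to-code mapping: hard single-word assignment or non-negative
# L1-sparse "visual sentence".
#
# The sparse problem is
#     min_x 1/2 ||D x - y||_2^2 + lambda ||x||_1   s.t. x >= 0,
# the non-negative lasso. The squared residual form is used (the objective is
# then a standard lasso-type quadratic and the hard-assignment problem is its
# one-hot-constrained special case); lambda defaults to 0.01 on this scale.

#' Hard-assign a descriptor to its nearest visual word
#'
#' Solves the one-hot-constrained least-squares assignment: the selected word
#' minimizes the Euclidean distance between the descriptor and the dictionary
#' column; distance ties are broken toward the lowest column index.
#'
#' @param y descriptor vector of length d.
#' @param codebook a [VisualCodebook-class].
#' @return List with `x` (one-hot length-c vector), `index` (selected word),
#'   `mode = "hard"` and `objective` (`0.5 * ||D e - y||^2`).
#' @export
hardAssign <- function(y, codebook) {
  D <- codebookMatrix(codebook)
  if (length(y) != nrow(D)) stop("descriptor length does not match codebook")
  d2 <- colSums((D - y)^2)
  j <- which.min(d2)              # which.min takes the first (lowest) index
  x <- numeric(ncol(D)); x[j] <- 1
  list(x = x, index = j, mode = "hard", objective = 0.5 * d2[j])
}

#' Sparse-encode a descriptor as a visual sentence
#'
#' Minimizes `0.5 * ||D x - y||^2 + lambda * ||x||_1` subject to `x >= 0` by
#' cyclic coordinate descent with deterministic initialization at `x = 0`
#' (relative objective tolerance 1e-10, at most 10000 sweeps). With
#' `lambda = 0` and an identity dictionary this reproduces `y` exactly; for
#' `lambda >= max(D'y)` the KKT conditions force `x = 0`.
#'
#' @param y descriptor vector of length d (finite).
#' @param codebook a [VisualCodebook-class].
#' @param lambda sparsity weight, `>= 0` (default 0.01).
#' @return List with `x` (non-negative length-c vector), `mode = "sparse"`,
#'   `objective` (value of the full objective at the solution) and `sweeps`.
#' @export
sparseEncode <- function(y, codebook, lambda = 0.01) {
  D <- codebookMatrix(codebook)
  if (length(y) != nrow(D)) stop("descriptor length does not match codebook")
  if (!all(is.finite(y)) || !all(is.finite(D)))
    stop("non-finite values in descriptor or dictionary")
  if (lambda < 0) stop("lambda must be >= 0")
  G <- crossprod(D)
  b <- crossprod(D, y)
  fit <- nnlasso_cd_batch(G, matrix(b, ncol = 1), lambda, 1e-10, 10000L)
  list(x = as.numeric(fit$x), mode = "sparse",
       objective = fit$objective[1] + 0.5 * sum(y^2),
       sweeps = fit$sweeps[1])
}

#' Encode all patches of an image
#'
#' Row i of the result is the code of descriptor i. Flat patches (flagged zero
#' descriptors) encode to the all-zero row in both modes instead of being
#' assigned to an arbitrary word; they are excluded from bag mass.
#'
#' @param descriptors a [DescriptorSet-class].
#' @param codebook a [VisualCodebook-class] with matching descriptor length.
#' @param mode `"hard"` or `"sparse"`.
#' @param lambda sparsity weight for sparse mode.
#' @return A [PatchCodes-class] (I x c), centers carried through.
#' @export
encodeImage <- function(descriptors, codebook, mode = c("sparse", "hard"),
                        lambda = 0.01) {
  mode <- match.arg(mode)
  D <- codebookMatrix(codebook)
  V <- descriptorMatrix(descriptors)
  if (ncol(V) != nrow(D))
    stop(sprintf("descriptor length %d does not match codebook d = %d",
                 ncol(V), nrow(D)))
  live <- !zeroFlags(descriptors)
  n <- nrow(V); c <- ncol(D)
  codes <- matrix(0, n, c)
  objectives <- numeric(n)
  if (any(live)) {
    Vl <- V[live, , drop = FALSE]
    if (mode == "hard") {
      d2 <- crossDist2(Vl, t(D))
      j <- max.col(-d2, ties.method = "first")
      codes[cbind(which(live), j)] <- 1
      objectives[live] <- 0.5 * d2[cbind(seq_len(nrow(Vl)), j)]
    } else {
      G <- crossprod(D)
      B <- crossprod(D, t(Vl))
      fit <- nnlasso_cd_batch(G, B, lambda, 1e-10, 10000L)
      codes[live, ] <- t(fit$x)
      objectives[live] <- fit$objective + 0.5 * rowSums(Vl^2)
    }
  }
  new("PatchCodes", codes = codes, centers = patchCenters(descriptors),
      mode = mode, lambda = if (mode == "sparse") lambda else NA_real_,
      objectives = objectives, zeroFlag = zeroFlags(descriptors),
      imageWidth = descriptors@imageWidth, imageHeight = descriptors@imageHeight)
}
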