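# Independent oracles and small shared fixtures, built in code.

# Non-negative lasso oracle by support enumeration: for every subset S of
# words, solve the restricted equality-stationarity system
#   D_S' D_S x_S = D_S' y - lambda
# and keep the candidate if x_S >= 0; return the smallest objective
# 0.5 ||D x - y||^2 + lambda ||x||_1 over all feasible candidates (the empty
# support, x = 0, is always feasible). Exhaustive, so valid only for small c.
nnlassoOracle <- function(D, y, lambda) {
  c <- ncol(D)
  objective <- function(x) 0.5 * sum((D %*% x - y)^2) + lambda * sum(abs(x))
  best <- objective(numeric(c))
  for (mask in seq_len(2^c - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(c) - 1)) > 0)
    Ds <- D[, S, drop = FALSE]
    xs <- tryCatch(solve(crossprod(Ds), crossprod(Ds, y) - lambda),
                   error = function(e) NULL)
    if (is.null(xs) || any(xs < 0)) next
    x <- numeric(c); x[S] <- xs
    best <- min(best, objective(x))
  }
  best
}

# Random dictionary wrapped as a VisualCodebook (validity needs distinct,
# finite columns; Gaussian draws satisfy that almost surely).
randomCodebook <- function(d, c, seed = 1L) {
  set.seed(seed)
  new("VisualCodebook", D = matrix(rnorm(d * c), d, c),
      trainingMeta = list(sampleSize = 0L, seed = seed, iterations = 0L,
                          objectiveTrace = numeric(0)))
}

# Count strict local maxima of a 1-d profile, treating a flat plateau that is
# higher than both flanks as one maximum.
countLocalMaxima <- function(p) {
  keep <- c(TRUE, diff(p) != 0)         # collapse plateaus
  q <- p[keep]
  if (length(q) < 3) return(0L)
  inner <- 2:(length(q) - 1)
  sum(q[inner] > q[inner - 1] & q[inner] > q[inner + 1])
}

# A PatchCodes object with arbitrary codes at given centers, for pooling
# tests that need full control of the code matrix.
manualCodes <- function(codes, centers, W, H, mode = "sparse") {
  new("PatchCodes", codes = codes, centers = centers, mode = mode,
      lambda = if (mode == "sparse") 0.01 else NA_real_,
      objectives = numeric(nrow(codes)),
      zeroFlag = rep(FALSE, nrow(codes)),
      imageWidth = as.integer(W), imageHeight = as.integer(H))
}

# Small labeled group set on a 32x32 canvas (one radius-16 patch per image),
# cheap enough for sampling/codebook unit tests.
tinyGroupSet <- function(nGroups = 4L, imagesPerGroup = 1L, seed = 5L,
                         noiseSd = 10) {
  spec <- syntheticSpec(canvasWidth = 32L, canvasHeight = 32L,
                        embryoAxes = c(14, 14),
                        patterns = list(left_half = list(
                          kind = "band", center = 0.5, width = 1)),
                        noiseSd = noiseSd, seed = seed)
  generateGroupSet(spec, nGroups = nGroups, imagesPerGroup = imagesPerGroup,
                   prevalence = 0.5, seed = seed)
}
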