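# Upright SIFT-style descriptor on circular patches.
#
# 4x4 spatial bins x 8 orientation bins = 128 values per patch. Gradients are
# taken by central differences, weighted by a Gaussian of sigma = radius/2
# centered on the patch, distributed over spatial and orientation bins by
# (tri)linear interpolation, then L2-normalized, clipped at 0.2 and
# renormalized. Orientation is NOT normalized to a dominant direction: the
# images this is meant for are pre-aligned, and an upright descriptor keeps
# the spatial semantics that the grid pooling relies on.
#
# Only pixels whose central-difference stencil lies fully inside the patch
# disk (distance <= radius - 1) contribute. This keeps the descriptor exactly
# invariant to a global additive intensity shift: the artificial step at the
# circular mask edge never enters the gradient field.

.siftGeomCache <- new.env(parent = emptyenv())

siftGeometry <- function(radius) {
  key <- as.character(radius)
  if (!is.null(.siftGeomCache[[key]])) return(.siftGeomCache[[key]])
  side <- 2L * radius + 1L
  off <- -radius:radius
  vmat <- matrix(off, side, side)        # row offset (y)
  umat <- matrix(off, side, side, byrow = TRUE)  # col offset (x)
  keep <- which(umat^2 + vmat^2 <= (radius - 1)^2)
  u <- umat[keep]; v <- vmat[keep]
  sigma <- radius / 2
  gauss <- exp(-(u^2 + v^2) / (2 * sigma^2))
  # neighbor linear indices in the side x side patch matrix (column-major)
  idx <- function(du, dv) (u + du + radius) * side + (v + dv + radius) + 1L
  # spatial bin coordinate in [-0.5, 3.5] along each axis
  sbin <- function(w) (w + radius) / side * 4 - 0.5
  bx <- sbin(u); by <- sbin(v)
  bx0 <- floor(bx); by0 <- floor(by)
  fx <- bx - bx0; fy <- by - by0
  # accumulate weights into a 16 x npix matrix over the 4 neighboring cells
  W <- matrix(0, 16L, length(keep))
  addCell <- function(r, c, w) {
    ok <- r >= 0 & r <= 3 & c >= 0 & c <= 3 & w > 0
    if (!any(ok)) return()
    s <- r[ok] * 4 + c[ok]              # row-major spatial index, 0-based
    W[cbind(s + 1L, which(ok))] <<- W[cbind(s + 1L, which(ok))] + w[ok]
  }
  addCell(by0,     bx0,     (1 - fy) * (1 - fx) * gauss)
  addCell(by0,     bx0 + 1, (1 - fy) * fx       * gauss)
  addCell(by0 + 1, bx0,     fy       * (1 - fx) * gauss)
  addCell(by0 + 1, bx0 + 1, fy       * fx       * gauss)
  geom <- list(side = side,
               ixp = idx(1L, 0L), ixm = idx(-1L, 0L),
               iyp = idx(0L, 1L), iym = idx(0L, -1L),
               W = W, npix = length(keep))
  .siftGeomCache[[key]] <- geom
  geom
}

#' Compute the SIFT-style descriptor of one patch
#'
#' @param patch square patch matrix of odd side `2*radius + 1`, as produced by
#'   [extractPatch()].
#' @return Numeric vector of length 128 (spatial cell-major: entries
#'   `s*8 + 1:8` are the 8 orientation bins of row-major 4x4 cell `s`).
#'   Flat patches (no gradient energy) give the zero vector with attribute
#'   `zero = TRUE`.
#' @export
describePatch <- function(patch) {
  side <- nrow(patch)
  if (side != ncol(patch) || side %% 2L == 0L)
    stop("patch must be square with odd side 2*radius + 1")
  radius <- (side - 1L) %/% 2L
  g <- siftGeometry(radius)
  p <- as.numeric(patch)
  gx <- (p[g$ixp] - p[g$ixm]) / 2
  gy <- (p[g$iyp] - p[g$iym]) / 2
  m <- sqrt(gx^2 + gy^2)
  out <- numeric(128L)
  if (all(m == 0)) { attr(out, "zero") <- TRUE; return(out) }
  theta <- atan2(gy, gx) %% (2 * pi)
  o <- theta / (2 * pi) * 8
  o0 <- floor(o); fo <- o - o0
  o0 <- as.integer(o0) %% 8L
  o1 <- (o0 + 1L) %% 8L
  O <- matrix(0, g$npix, 8L)
  O[cbind(seq_len(g$npix), o0 + 1L)] <- m * (1 - fo)
  O[cbind(seq_len(g$npix), o1 + 1L)] <- O[cbind(seq_len(g$npix), o1 + 1L)] + m * fo
  hist16x8 <- g$W %*% O
  vec <- as.numeric(t(hist16x8))
  n2 <- sqrt(sum(vec^2))
  if (n2 < 1e-12) { attr(out, "zero") <- TRUE; return(out) }
  vec <- pmin(vec / n2, 0.2)
  vec <- vec / sqrt(sum(vec^2))
  attr(vec, "zero") <- FALSE
  vec
}

#' Describe every patch of an image
#'
#' Applies [extractPatch()] + [describePatch()] at each layout center, in
#' center order.
#'
#' @param image numeric image matrix (rows = y, cols = x).
#' @param layout a [PatchLayout-class] valid for this image.
#' @return A [DescriptorSet-class] with one 128-vector per patch.
#' @export
describeImage <- function(image, layout) {
  assertImage(image)
  if (ncol(image) != layout@imageWidth || nrow(image) != layout@imageHeight)
    stop("layout was built for a different image size")
  ctr <- patchCenters(layout)
  r <- patchRadius(layout)
  n <- nrow(ctr)
  vectors <- matrix(0, n, 128L)
  zero <- logical(n)
  for (i in seq_len(n)) {
    d <- describePatch(extractPatch(image, ctr[i, ], r))
    vectors[i, ] <- d
    zero[i] <- isTRUE(attr(d, "zero"))
  }
  new("DescriptorSet", vectors = vectors, centers = ctr, zeroFlag = zero,
      imageWidth = layout@imageWidth, imageHeight = layout@imageHeight)
}
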