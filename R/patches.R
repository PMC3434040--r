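#' Lay out overlapping circular patches on an image
#'
#' Centers form a regular grid starting at (radius, radius), stepping by
#' `stride` along x and y, and keeping only centers with
#' `x <= width - radius` and `y <= height - radius`, so every patch circle
#' stays inside the image. With the default `stride = radius` adjacent circles
#' overlap by 50% of their diameter.
#'
#' @param imageWidth,imageHeight image dimensions in pixels.
#' @param radius patch radius in pixels (default 16).
#' @param stride grid step in pixels (default = `radius`).
#' @return A [PatchLayout-class] with row-major ordered centers.
#' @examples
#' makeLayout(64, 64)          # 3 x 3 grid of radius-16 patches
#' @export
makeLayout <- function(imageWidth, imageHeight, radius = 16L, stride = radius) {
  radius <- as.integer(radius); stride <- as.integer(stride)
  if (radius < 1L || stride < 1L) stop("radius and stride must be >= 1")
  if (imageWidth < 2L * radius || imageHeight < 2L * radius)
    stop("image smaller than one patch")
  xs <- as.integer(seq.int(radius, imageWidth - radius, by = stride))
  ys <- as.integer(seq.int(radius, imageHeight - radius, by = stride))
  centers <- cbind(x = rep(xs, times = length(ys)),
                   y = rep(ys, each = length(xs)))
  new("PatchLayout", centers = centers, radius = radius,
      imageWidth = as.integer(imageWidth), imageHeight = as.integer(imageHeight))
}

#' Extract one circularly masked patch
#'
#' Returns the square sub-image of side `2*radius + 1` centered on `center`,
#' with pixels outside the inscribed disk set to 0 (the descriptor's support
#' is the circle, so corner pixels never leak in). The rare disk-boundary
#' pixels that fall outside the image -- possible only when the center sits at
#' the layout margin -- are edge-replicated, so a constant image yields a
#' constant disk.
#'
#' @param image numeric matrix (rows = y, cols = x), gray values.
#' @param center integer pair (x, y), 0-based pixel coordinates.
#' @param radius patch radius in pixels.
#' @return Numeric matrix of side `2*radius + 1`.
#' @export
extractPatch <- function(image, center, radius) {
  assertImage(image)
  radius <- as.integer(radius)
  cx <- center[1]; cy <- center[2]
  H <- nrow(image); W <- ncol(image)
  if (cx < radius || cx > W - radius || cy < radius || cy > H - radius)
    stop(sprintf("center (%d, %d) violates layout bounds for radius %d",
                 cx, cy, radius))
  side <- 2L * radius + 1L
  xs <- pmin(pmax((cx - radius):(cx + radius), 0L), W - 1L)   # 0-based, clamped
  ys <- pmin(pmax((cy - radius):(cy + radius), 0L), H - 1L)
  patch <- image[ys + 1L, xs + 1L]
  off <- matrix(-radius:radius, side, side)
  disk <- off^2 + t(off)^2 <= radius^2
  patch * disk
}
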