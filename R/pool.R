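#' Assign patches to spatial grid cells
#'
#' The image is divided into `rows x cols` rectangles of equal nominal size
#' `floor(H/rows) x floor(W/cols)`; remainder pixels are absorbed by the last
#' row / column. Rectangles are half-open (`[x0, x1) x [y0, y1)`), so a center
#' sitting exactly on an interior boundary falls into the higher-index cell.
#' Cells are numbered row-major from 0.
#'
#' @param centers matrix of 0-based (x, y) patch centers.
#' @param imageWidth,imageHeight image dimensions in pixels.
#' @param grid integer pair (rows, cols).
#' @return Integer vector of 0-based cell indices, one per center.
#' @export
assignCells <- function(centers, imageWidth, imageHeight, grid = c(3L, 6L)) {
  grid <- as.integer(grid)
  if (length(grid) != 2L || any(grid < 1L)) stop("grid must be (rows, cols) >= 1")
  x <- centers[, 1]; y <- centers[, 2]
  if (any(x < 0 | x >= imageWidth | y < 0 | y >= imageHeight))
    stop("patch center out of image bounds")
  ch <- imageHeight %/% grid[1]
  cw <- imageWidth %/% grid[2]
  row <- pmin(y %/% ch, grid[1] - 1L)
  col <- pmin(x %/% cw, grid[2] - 1L)
  as.integer(row * grid[2] + col)
}

#' Pool patch codes into a (spatial) bag vector
#'
#' Block b of the output is the column-sum of the code rows assigned to cell
#' b; with hard codes and the global grid `c(1, 1)` this is the classic
#' visual-word count histogram whose total equals the number of non-flat
#' patches. Summing the blocks of any spatial bag reproduces the global bag
#' from the same codes.
#'
#' @param codes a [PatchCodes-class].
#' @param grid integer pair (rows, cols); `c(1, 1)` gives the global bag,
#'   the default `c(3, 6)` the spatial bag.
#' @return A [BagVector-class] at image level, length `rows*cols*c`.
#' @export
poolImage <- function(codes, grid = c(3L, 6L)) {
  grid <- as.integer(grid)
  cells <- assignCells(patchCenters(codes), codes@imageWidth,
                       codes@imageHeight, grid)
  n <- prod(grid)
  M <- codeMatrix(codes)
  pooled <- matrix(0, n, ncol(M))
  rs <- rowsum(M, cells)                      # empty cells stay all-zero
  pooled[as.integer(rownames(rs)) + 1L, ] <- rs
  new("BagVector", values = as.numeric(t(pooled)), grid = grid,
      J = ncol(M), level = "image")
}

#' Aggregate image bags into a group-level bag
#'
#' Element-wise sum over the group's image bags; with `normalize = TRUE`
#' (the default, used for annotation and retrieval) the sum is divided by its
#' L1 norm so group size does not scale the representation. An all-zero sum is
#' left as-is.
#'
#' @param imageBags list of [BagVector-class] objects sharing grid and length.
#' @param normalize divide by the L1 norm?
#' @return A [BagVector-class] at group level.
#' @export
poolGroup <- function(imageBags, normalize = TRUE) {
  if (length(imageBags) == 0L) stop("empty group")
  g0 <- bagGrid(imageBags[[1]])
  if (!all(vapply(imageBags, function(b)
        identical(bagGrid(b), g0) &&
        length(bagValues(b)) == length(bagValues(imageBags[[1]])), TRUE)))
    stop("image bags have mixed grids or lengths")
  v <- Reduce(`+`, lapply(imageBags, bagValues))
  if (normalize) v <- l1Normalize(v)
  new("BagVector", values = v, grid = g0, J = imageBags[[1]]@J,
      level = "group")
}
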