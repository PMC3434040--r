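#' Describe a synthetic embryo-image generator
#'
#' Builds a [SyntheticSpec-class] for rendering standardized embryo-like
#' grayscale images: a fixed canvas, an elliptical "embryo" mask on a black
#' background, and named expression patterns drawn inside the mask. Pattern
#' geometry is given in embryo-normalized coordinates (u, v) in \[0,1\]^2 over
#' the ellipse bounding box (u anterior to posterior, v dorsal to ventral), so
#' a pattern occupies the same anatomical position in every image -- emulating
#' images that have been scaled and aligned to a common template.
#'
#' Supported pattern kinds, with their parameters:
#' \describe{
#'   \item{stripe}{`count` vertical stripes (periodic along u, e.g. pair-rule
#'     stripes), each of normalized width `width`, centered at
#'     `(i - 0.5)/count`.}
#'   \item{band}{a horizontal band: `|v - center| < width/2`.}
#'   \item{spot}{one or more discs; `centers` is a matrix of (u, v) rows,
#'     `radius` a normalized radius.}
#'   \item{gradient}{a linear intensity ramp along `axis` (`"u"` or `"v"`),
#'     optionally `reverse`d.}
#' }
#'
#' @param canvasWidth,canvasHeight canvas size in pixels (default 192 x 96,
#'   an embryo-like 2:1 aspect ratio).
#' @param embryoAxes semi-major and semi-minor axis of the embryo ellipse, in
#'   pixels.
#' @param patterns named list mapping each term name to a pattern parameter
#'   list with at least a `kind` entry; `NULL` selects
#'   [defaultPatternCatalog()].
#' @param baseIntensity gray level of unstained tissue inside the mask.
#' @param amplitude gray-level increment where a pattern is expressed.
#' @param noiseSd standard deviation of additive Gaussian pixel noise, in gray
#'   levels on the 0-255 scale (applied inside the mask only).
#' @param seed base seed for noise reproducibility.
#' @return A [SyntheticSpec-class] object.
#' @examples
#' spec <- syntheticSpec(noiseSd = 0)
#' img <- generateImage(spec, "stripe_triplet")
#' dim(img)
#' @export
syntheticSpec <- function(canvasWidth = 192L, canvasHeight = 96L,
                          embryoAxes = c(88, 40), patterns = NULL,
                          baseIntensity = 60, amplitude = 140,
                          noiseSd = 8, seed = 1L) {
  if (is.null(patterns)) patterns <- defaultPatternCatalog()
  new("SyntheticSpec", canvasWidth = as.integer(canvasWidth),
      canvasHeight = as.integer(canvasHeight),
      embryoAxes = as.numeric(embryoAxes), patterns = patterns,
      baseIntensity = baseIntensity, amplitude = amplitude,
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' Default catalog of spatially localized expression patterns
#'
#' Six named patterns in distinct anatomical locations, one pattern per term,
#' so per-term separability is controlled and spatial pooling cells carry
#' stable meaning.
#'
#' @return Named list of pattern parameter lists, usable as the `patterns`
#'   argument of [syntheticSpec()].
#' @export
defaultPatternCatalog <- function() {
  list(
    stripe_triplet  = list(kind = "stripe", count = 3L, width = 0.08),
    anterior_spot   = list(kind = "spot",
                           centers = matrix(c(0.15, 0.5), ncol = 2),
                           radius = 0.16),
    posterior_spot  = list(kind = "spot",
                           centers = matrix(c(0.85, 0.5), ncol = 2),
                           radius = 0.16),
    dorsal_band     = list(kind = "band", center = 0.2, width = 0.2),
    ventral_band    = list(kind = "band", center = 0.8, width = 0.2),
    posterior_ramp  = list(kind = "gradient", axis = "u", reverse = FALSE)
  )
}

# Normalized-coordinate fields and the elliptical mask for a spec's canvas.
canvasGeometry <- function(spec) {
  W <- spec@canvasWidth; H <- spec@canvasHeight
  a <- spec@embryoAxes[1]; b <- spec@embryoAxes[2]
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  x <- matrix(0:(W - 1), H, W, byrow = TRUE)
  y <- matrix(0:(H - 1), H, W)
  mask <- ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
  u <- (x - cx) / (2 * a) + 0.5
  v <- (y - cy) / (2 * b) + 0.5
  list(mask = mask, u = u, v = v)
}

renderPattern <- function(p, geom) {
  u <- geom$u; v <- geom$v
  field <- switch(p$kind,
    stripe = {
      ctr <- (seq_len(p$count) - 0.5) / p$count
      hit <- Reduce(`|`, lapply(ctr, function(cc) abs(u - cc) < p$width / 2))
      hit * 1
    },
    band = (abs(v - p$center) < p$width / 2) * 1,
    spot = {
      hit <- Reduce(`|`, lapply(seq_len(nrow(p$centers)), function(i)
        (u - p$centers[i, 1])^2 + (v - p$centers[i, 2])^2 <= p$radius^2))
      hit * 1
    },
    gradient = {
      ax <- if (identical(p$axis, "v")) v else u
      if (isTRUE(p$reverse)) pmax(0, pmin(1, 1 - ax)) else pmax(0, pmin(1, ax))
    },
    stop(sprintf("unknown pattern kind '%s'", p$kind)))
  field * geom$mask
}

#' Render one synthetic embryo image
#'
#' Pixels outside the elliptical embryo mask are exactly 0; inside, the image
#' is `baseIntensity` plus `amplitude` times each active term's pattern field,
#' plus (for `noiseSd > 0`) Gaussian noise, clipped to the 8-bit range
#' \[0, 255\].
#'
#' @param spec a [SyntheticSpec-class].
#' @param activeTerms character vector of term names to express; each must
#'   name a configured pattern.
#' @param noiseSeed seed for the noise draw (defaults to the spec's seed);
#'   the rendered pattern itself is deterministic.
#' @return Numeric matrix `canvasHeight x canvasWidth` with gray values in
#'   \[0, 255\] (rows = y, cols = x, 0-based pixel (x, y) at `[y+1, x+1]`).
#' @export
generateImage <- function(spec, activeTerms = character(0),
                          noiseSeed = spec@seed) {
  activeTerms <- as.character(activeTerms)
  unknown <- setdiff(activeTerms, names(spec@patterns))
  if (length(unknown))
    stop(sprintf("unknown term%s: %s", if (length(unknown) > 1) "s" else "",
                 paste(unknown, collapse = ", ")))
  geom <- canvasGeometry(spec)
  img <- spec@baseIntensity * geom$mask
  for (term in activeTerms)
    img <- img + spec@amplitude * renderPattern(spec@patterns[[term]], geom)
  if (spec@noiseSd > 0) {
    noise <- withSeed(noiseSeed,
      matrix(rnorm(length(img), sd = spec@noiseSd), nrow(img), ncol(img)))
    img <- img + noise * geom$mask
  }
  pmin(pmax(img, 0), 255)
}

#' Generate a labeled set of synthetic image groups
#'
#' Each group's term set is drawn independently per term with the configured
#' prevalence; all images in a group are rendered with that same term set and
#' differ only in their noise realization. The draw is fully deterministic
#' under `seed`.
#'
#' @param spec a [SyntheticSpec-class].
#' @param nGroups number of image groups (at least 2, so train/test splits
#'   remain possible).
#' @param imagesPerGroup replicate images rendered per group.
#' @param termCatalog terms to sample labels for; defaults to all patterns in
#'   the spec.
#' @param prevalence scalar or per-term named vector of label probabilities in
#'   (0, 1\].
#' @param seed integer seed governing both label draws and image noise.
#' @return A [LabeledGroupSet-class].
#' @examples
#' gs <- generateGroupSet(syntheticSpec(noiseSd = 0), nGroups = 4,
#'                        imagesPerGroup = 1, seed = 7)
#' termFrequencies(gs)
#' @export
generateGroupSet <- function(spec, nGroups, imagesPerGroup = 3L,
                             termCatalog = names(spec@patterns),
                             prevalence = 0.4, seed = spec@seed) {
  if (nGroups < 2L) stop("need at least 2 groups (downstream splits impossible)")
  if (length(prevalence) == 1L && is.null(names(prevalence)))
    prevalence <- stats::setNames(rep(prevalence, length(termCatalog)),
                                  termCatalog)
  if (!all(termCatalog %in% names(prevalence)))
    stop("prevalence missing for some terms")
  prevalence <- prevalence[termCatalog]
  if (any(prevalence <= 0 | prevalence > 1))
    stop("prevalences must lie in (0, 1]")
  ids <- sprintf("g%04d", seq_len(nGroups))
  labels <- withSeed(deriveSeed(seed, 0L), {
    lapply(seq_len(nGroups), function(g)
      termCatalog[stats::runif(length(termCatalog)) < prevalence])
  })
  names(labels) <- ids
  groups <- lapply(seq_len(nGroups), function(g) {
    lapply(seq_len(imagesPerGroup), function(i)
      generateImage(spec, labels[[g]],
                    noiseSeed = deriveSeed(seed, g * 1009L + i)))
  })
  names(groups) <- ids
  new("LabeledGroupSet", groups = groups, labels = labels,
      canvas = c(spec@canvasWidth, spec@canvasHeight))
}

#' Write / read a labeled group set on disk
#'
#' Images are written as 8-bit grayscale PNG under
#' `<dir>/<group_id>/<index>.png`; labels as a CSV with columns
#' `group_id,term`, one row per (group, term) pair. `readGroupSet()` inverts
#' the layout: every subdirectory of `dir` is one group, its images read in
#' numeric filename order (PNG or TIFF; JPEG is not supported). Groups absent
#' from the label file carry an empty term set.
#'
#' @param groupSet a [LabeledGroupSet-class].
#' @param dir output (input) directory.
#' @param labelsCsv path of the label CSV; defaults to `labels.csv` inside
#'   `dir`.
#' @return `writeGroupSet()` returns `dir` invisibly; `readGroupSet()` returns
#'   a [LabeledGroupSet-class].
#' @export
writeGroupSet <- function(groupSet, dir, labelsCsv = file.path(dir, "labels.csv")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in groupIds(groupSet)) {
    gdir <- file.path(dir, id)
    dir.create(gdir, showWarnings = FALSE)
    imgs <- groupImages(groupSet, id)
    for (i in seq_along(imgs))
      png::writePNG(imgs[[i]] / 255, file.path(gdir, sprintf("%d.png", i)))
  }
  lab <- groupLabels(groupSet)
  df <- do.call(rbind, lapply(names(lab), function(id) {
    if (length(lab[[id]]) == 0L) return(NULL)
    data.frame(group_id = id, term = lab[[id]])
  }))
  if (is.null(df)) df <- data.frame(group_id = character(0), term = character(0))
  write.csv(df, labelsCsv, row.names = FALSE, quote = FALSE)
  invisible(dir)
}

readImageFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = stop("JPEG input is not supported; convert to PNG or TIFF"),
    stop(sprintf("unsupported image format '.%s'", ext)))
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]   # grayscale channel
  arr * 255
}

#' @rdname writeGroupSet
#' @export
readGroupSet <- function(dir, labelsCsv = file.path(dir, "labels.csv")) {
  gdirs <- sort(list.dirs(dir, recursive = FALSE))
  if (length(gdirs) == 0L) stop(sprintf("no group directories under %s", dir))
  groups <- lapply(gdirs, function(gd) {
    files <- list.files(gd, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                        ignore.case = TRUE, full.names = TRUE)
    ord <- order(suppressWarnings(as.numeric(tools::file_path_sans_ext(basename(files)))),
                 basename(files))
    lapply(files[ord], readImageFile)
  })
  names(groups) <- basename(gdirs)
  lab <- if (file.exists(labelsCsv)) {
    df <- read.csv(labelsCsv, stringsAsFactors = FALSE)
    split(df$term, factor(df$group_id, levels = names(groups)))
  } else stats::setNames(rep(list(character(0)), length(groups)), names(groups))
  lab <- lapply(lab, as.character)
  new("LabeledGroupSet", groups = groups, labels = lab[names(groups)],
      canvas = c(ncol(groups[[1]][[1]]), nrow(groups[[1]][[1]])))
}
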