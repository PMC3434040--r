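#' Accessor generics
#'
#' Small accessor layer over the S4 containers, so downstream code never
#' touches slots directly.
#'
#' @param x an object of one of the package's S4 classes.
#' @return The requested component; see the class documentation pages.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patchCenters", function(x) standardGeneric("patchCenters"))
#' @rdname accessors
#' @export
setGeneric("patchRadius", function(x) standardGeneric("patchRadius"))
#' @rdname accessors
#' @export
setGeneric("descriptorMatrix", function(x) standardGeneric("descriptorMatrix"))
#' @rdname accessors
#' @export
setGeneric("zeroFlags", function(x) standardGeneric("zeroFlags"))
#' @rdname accessors
#' @export
setGeneric("codebookMatrix", function(x) standardGeneric("codebookMatrix"))
#' @rdname accessors
#' @export
setGeneric("numWords", function(x) standardGeneric("numWords"))
#' @rdname accessors
#' @export
setGeneric("trainingMeta", function(x) standardGeneric("trainingMeta"))
#' @rdname accessors
#' @export
setGeneric("codeMatrix", function(x) standardGeneric("codeMatrix"))
#' @rdname accessors
#' @export
setGeneric("codeMode", function(x) standardGeneric("codeMode"))
#' @rdname accessors
#' @export
setGeneric("bagValues", function(x) standardGeneric("bagValues"))
#' @rdname accessors
#' @export
setGeneric("bagGrid", function(x) standardGeneric("bagGrid"))
#' @rdname accessors
#' @export
setGeneric("groupIds", function(x) standardGeneric("groupIds"))
#' @rdname accessors
#' @export
setGeneric("groupImages", function(x, id) standardGeneric("groupImages"))
#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
#' @rdname accessors
#' @export
setGeneric("termFrequencies", function(x) standardGeneric("termFrequencies"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))
#' @rdname accessors
#' @export
setGeneric("termNames", function(x) standardGeneric("termNames"))
#' @rdname accessors
#' @export
setGeneric("indexIds", function(x) standardGeneric("indexIds"))
#' @rdname accessors
#' @export
setGeneric("indexMatrix", function(x) standardGeneric("indexMatrix"))

#' @rdname accessors
setMethod("patchCenters", "PatchLayout", function(x) x@centers)
#' @rdname accessors
setMethod("patchCenters", "DescriptorSet", function(x) x@centers)
#' @rdname accessors
setMethod("patchCenters", "PatchCodes", function(x) x@centers)
#' @rdname accessors
setMethod("patchRadius", "PatchLayout", function(x) x@radius)
#' @rdname accessors
setMethod("descriptorMatrix", "DescriptorSet", function(x) x@vectors)
#' @rdname accessors
setMethod("zeroFlags", "DescriptorSet", function(x) x@zeroFlag)
#' @rdname accessors
setMethod("zeroFlags", "PatchCodes", function(x) x@zeroFlag)
#' @rdname accessors
setMethod("codebookMatrix", "VisualCodebook", function(x) x@D)
#' @rdname accessors
setMethod("numWords", "VisualCodebook", function(x) ncol(x@D))
#' @rdname accessors
setMethod("trainingMeta", "VisualCodebook", function(x) x@trainingMeta)
#' @rdname accessors
setMethod("codeMatrix", "PatchCodes", function(x) x@codes)
#' @rdname accessors
setMethod("codeMode", "PatchCodes", function(x) x@mode)
#' @rdname accessors
setMethod("bagValues", "BagVector", function(x) x@values)
#' @rdname accessors
setMethod("bagGrid", "BagVector", function(x) x@grid)
#' @rdname accessors
setMethod("groupIds", "LabeledGroupSet", function(x) names(x@groups))
#' @rdname accessors
setMethod("groupImages", "LabeledGroupSet", function(x, id) x@groups[[id]])
#' @rdname accessors
setMethod("groupLabels", "LabeledGroupSet", function(x) x@labels)

#' @rdname accessors
setMethod("termFrequencies", "LabeledGroupSet", function(x) {
  tab <- table(unlist(x@labels, use.names = FALSE))
  if (length(tab) == 0L) return(integer(0))
  f <- as.integer(tab)
  names(f) <- names(tab)
  f[order(-f, names(f))]
})

#' @rdname accessors
setMethod("termFrequencies", "AnnotationDataset", function(x) {
  f <- x@termFrequencies
  names(f) <- x@termNames
  f
})

#' @rdname accessors
setMethod("featureMatrix", "AnnotationDataset", function(x) x@X)
#' @rdname accessors
setMethod("labelMatrix", "AnnotationDataset", function(x) x@Y)
#' @rdname accessors
setMethod("termNames", "AnnotationDataset", function(x) x@termNames)
#' @rdname accessors
setMethod("indexIds", "RetrievalIndex", function(x) x@ids)
#' @rdname accessors
setMethod("indexMatrix", "RetrievalIndex", function(x) x@M)
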