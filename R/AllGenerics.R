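#' @import methods
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the pixel-grid data classes
#' (\linkS4class{MSIDataset}, \linkS4class{PeakTable},
#' \linkS4class{PixelPartition}, \linkS4class{CellAssignment}) and the
#' clustering result container (\linkS4class{ConsensusClustering}).
#'
#' @param object an object of one of the classes above.
#' @param ... further arguments passed to methods.
#' @return The slot contents documented on each class page.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensityMatrix", function(object, ...) standardGeneric("intensityMatrix"))

#' @rdname accessors
#' @export
setGeneric("pixelCoords", function(object) standardGeneric("pixelCoords"))

#' @rdname accessors
#' @export
setGeneric("gridShape", function(object) standardGeneric("gridShape"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("mzValues", function(object) standardGeneric("mzValues"))

#' @rdname accessors
#' @export
setGeneric("featureMz", function(object) standardGeneric("featureMz"))

#' @rdname accessors
#' @export
setGeneric("sampleInfo", function(object) standardGeneric("sampleInfo"))

#' @rdname accessors
#' @export
setGeneric("rawTic", function(object) standardGeneric("rawTic"))

#' @rdname accessors
#' @export
setGeneric("isCell", function(object) standardGeneric("isCell"))

#' @rdname accessors
#' @export
setGeneric("cellIds", function(object) standardGeneric("cellIds"))

#' @rdname accessors
#' @export
setGeneric("organization", function(object) standardGeneric("organization"))

#' @rdname accessors
#' @export
setGeneric("consensusMatrix", function(object, K) standardGeneric("consensusMatrix"))

#' @rdname accessors
#' @export
setGeneric("selectedK", function(object) standardGeneric("selectedK"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname ticNormalize
#' @export
setGeneric("ticNormalize", function(object, ...) standardGeneric("ticNormalize"))
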