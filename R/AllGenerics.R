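#' @include AllClasses.R
NULL

#' @title Accessors for pvla result and volume classes
#' @description \code{voxels} returns the raw 3D label array;
#'   \code{labelMap}, \code{caseId} and \code{videoId} return the
#'   corresponding metadata; \code{indexValue} extracts the scalar index from
#'   a \code{PLDResult} or \code{PLAResult}; \code{sliceTable} returns the
#'   per-slice provenance table (k, d) or (k, theta).
#' @param x a \code{LabelVolume}, \code{PLDResult} or \code{PLAResult}.
#' @return See description; accessors return the slot contents.
#' @name pvla-accessors
#' @examples
#' v <- LabelVolume(array(0L, c(2, 3, 3)))
#' dim(voxels(v))
#' labelMap(v)
NULL

#' @rdname pvla-accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname pvla-accessors
#' @export
setMethod("voxels", "LabelVolume", function(x) x@voxels)

#' @rdname pvla-accessors
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))
#' @rdname pvla-accessors
#' @export
setMethod("labelMap", "LabelVolume", function(x) x@labelMap)

#' @rdname pvla-accessors
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))
#' @rdname pvla-accessors
#' @export
setMethod("caseId", "LabelVolume", function(x) x@caseId)
#' @rdname pvla-accessors
#' @export
setMethod("caseId", "PLDResult", function(x) x@caseId)
#' @rdname pvla-accessors
#' @export
setMethod("caseId", "PLAResult", function(x) x@caseId)

#' @rdname pvla-accessors
#' @export
setGeneric("videoId", function(x) standardGeneric("videoId"))
#' @rdname pvla-accessors
#' @export
setMethod("videoId", "LabelVolume", function(x) x@videoId)

#' @rdname pvla-accessors
#' @export
setGeneric("indexValue", function(x) standardGeneric("indexValue"))
#' @rdname pvla-accessors
#' @export
setMethod("indexValue", "PLDResult", function(x) x@pld)
#' @rdname pvla-accessors
#' @export
setMethod("indexValue", "PLAResult", function(x) x@pla)

#' @rdname pvla-accessors
#' @export
setGeneric("sliceTable", function(x) standardGeneric("sliceTable"))
#' @rdname pvla-accessors
#' @export
setMethod("sliceTable", "PLDResult", function(x) x@distances)
#' @rdname pvla-accessors
#' @export
setMethod("sliceTable", "PLAResult", function(x) x@angles)
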