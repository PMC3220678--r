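#' Accessors for retrotrack classes
#'
#' Accessor generics for the central data objects: pixel data and validity
#' masks of images, the live-frame list and fixed references of a field, and
#' label matrices of segmentation maps.
#'
#' @param object an \linkS4class{IntensityImage}, \linkS4class{Field} or
#'   \linkS4class{LabelMap}.
#' @return \code{pixels} and \code{validMask} return matrices;
#'   \code{liveFrames} a list of \linkS4class{IntensityImage};
#'   \code{fixedTarget}/\code{fixedNuclear} an \linkS4class{IntensityImage};
#'   \code{nFrames} and \code{frameInterval} scalars; \code{labelMatrix} an
#'   integer matrix; \code{mapKind} a character scalar; \code{cellIds} the
#'   sorted non-zero labels.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("liveFrames", function(object) standardGeneric("liveFrames"))
#' @rdname accessors
#' @export
setGeneric("fixedTarget", function(object) standardGeneric("fixedTarget"))
#' @rdname accessors
#' @export
setGeneric("fixedNuclear", function(object) standardGeneric("fixedNuclear"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(object) standardGeneric("labelMatrix"))
#' @rdname accessors
#' @export
setGeneric("mapKind", function(object) standardGeneric("mapKind"))
#' @rdname accessors
#' @export
setGeneric("cellIds", function(object) standardGeneric("cellIds"))

#' @rdname accessors
setMethod("pixels", "IntensityImage", function(object) object@pixels)
#' @rdname accessors
setMethod("validMask", "IntensityImage", function(object) object@valid)
#' @rdname accessors
setMethod("liveFrames", "Field", function(object) object@liveFrames)
#' @rdname accessors
setMethod("fixedTarget", "Field", function(object) object@fixedTarget)
#' @rdname accessors
setMethod("fixedNuclear", "Field", function(object) object@fixedNuclear)
#' @rdname accessors
setMethod("nFrames", "Field", function(object) length(object@liveFrames))
#' @rdname accessors
setMethod("frameInterval", "Field", function(object) object@frameIntervalMin)
#' @rdname accessors
setMethod("labelMatrix", "LabelMap", function(object) object@labels)
#' @rdname accessors
setMethod("mapKind", "LabelMap", function(object) object@kind)
#' @rdname accessors
setMethod("cellIds", "LabelMap", function(object)
  sort(setdiff(unique(as.vector(object@labels)), 0L)))
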