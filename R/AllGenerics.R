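#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes; use these
#' rather than reaching into slots.
#'
#' @param x an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("countyIds", function(x) standardGeneric("countyIds"))

#' @rdname accessors
#' @export
setGeneric("studyYears", function(x) standardGeneric("studyYears"))

#' @rdname accessors
#' @export
setGeneric("diseaseIds", function(x) standardGeneric("diseaseIds"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname accessors
#' @export
setGeneric("expectedCounts", function(x) standardGeneric("expectedCounts"))

#' @rdname accessors
#' @export
setGeneric("codedMask", function(x) standardGeneric("codedMask"))

#' @rdname accessors
#' @export
setGeneric("isImputed", function(x) standardGeneric("isImputed"))

#' @rdname accessors
#' @export
setGeneric("neighbors", function(x) standardGeneric("neighbors"))

#' @rdname accessors
#' @export
setGeneric("nNeighbors", function(x) standardGeneric("nNeighbors"))

#' @rdname accessors
#' @export
setGeneric("isStandardized", function(x) standardGeneric("isStandardized"))

#' @rdname accessors
#' @export
setGeneric("drawMatrix", function(x) standardGeneric("drawMatrix"))

#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname accessors
#' @export
setGeneric("pointwiseLogLik", function(x) standardGeneric("pointwiseLogLik"))

#' @rdname accessors
#' @export
setGeneric("yRep", function(x) standardGeneric("yRep"))

#' @rdname accessors
#' @export
setGeneric("cellIndex", function(x) standardGeneric("cellIndex"))

#' @rdname accessors
#' @export
setGeneric("modelVariant", function(x) standardGeneric("modelVariant"))
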