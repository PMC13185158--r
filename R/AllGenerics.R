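#' @name rhlBminer-generics
#' @title Accessor generics
#' @description Small accessor generics shared by the package's S4 classes.
#' @param x an object
#' @param ... passed to methods
#' @return The slot value the accessor is named after.
NULL

#' @rdname rhlBminer-generics
#' @export
setGeneric("reference", function(x, ...) standardGeneric("reference"))

#' @rdname rhlBminer-generics
#' @export
setGeneric("members", function(x, ...) standardGeneric("members"))

#' @rdname rhlBminer-generics
#' @export
setGeneric("seqKind", function(x, ...) standardGeneric("seqKind"))

#' @rdname rhlBminer-generics
#' @export
setGeneric("memberMeta", function(x, ...) standardGeneric("memberMeta"))

#' @rdname rhlBminer-generics
#' @export
setGeneric("mutations", function(x, ...) standardGeneric("mutations"))

#' @rdname rhlBminer-generics
#' @export
setGeneric("identityPercent", function(x, ...) standardGeneric("identityPercent"))

#' @rdname rhlBminer-generics
#' @export
setGeneric("alignmentScore", function(x, ...) standardGeneric("alignmentScore"))

#' @rdname rhlBminer-generics
#' @export
setGeneric("alignedSeqs", function(x, ...) standardGeneric("alignedSeqs"))

#' @rdname rhlBminer-generics
#' @export
setGeneric("curveSlope", function(x, ...) standardGeneric("curveSlope"))

#' @rdname rhlBminer-generics
#' @export
setGeneric("curveIntercept", function(x, ...) standardGeneric("curveIntercept"))

#' @rdname rhlBminer-generics
#' @export
setGeneric("lod", function(x, ...) standardGeneric("lod"))

#' @rdname rhlBminer-generics
#' @export
setGeneric("mape", function(x, ...) standardGeneric("mape"))
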