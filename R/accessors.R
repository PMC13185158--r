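## ---- accessors -------------------------------------------------------------
#' @rdname rhlBminer-generics
setMethod("reference", "SeqRepository", function(x, ...) x@reference)

#' @rdname rhlBminer-generics
setMethod("members", "SeqRepository", function(x, ...) x@members)

#' @rdname rhlBminer-generics
setMethod("seqKind", "SeqRepository", function(x, ...) x@kind)

#' @rdname rhlBminer-generics
setMethod("memberMeta", "SeqRepository", function(x, ...) x@meta)

#' @rdname rhlBminer-generics
setMethod("mutations", "MutationProfile", function(x, ...) x@mutations)

#' @rdname rhlBminer-generics
setMethod("identityPercent", "MutationProfile", function(x, ...) x@identityPercent)

#' @rdname rhlBminer-generics
setMethod("identityPercent", "GlobalAlignment", function(x, ...) x@identityPercent)

#' @rdname rhlBminer-generics
setMethod("alignmentScore", "GlobalAlignment", function(x, ...) x@score)

#' @rdname rhlBminer-generics
setMethod("alignedSeqs", "GlobalAlignment",
          function(x, ...) c(a = x@alignedA, b = x@alignedB))

#' @rdname rhlBminer-generics
setMethod("curveSlope", "StandardCurve", function(x, ...) x@slope)

#' @rdname rhlBminer-generics
setMethod("curveIntercept", "StandardCurve", function(x, ...) x@intercept)

#' @rdname rhlBminer-generics
setMethod("lod", "StandardCurve", function(x, ...) x@lod)

#' @rdname rhlBminer-generics
setMethod("mape", "StandardCurve", function(x, ...) x@mape)
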