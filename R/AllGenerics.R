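#' @rdname belief
#' @export
setGeneric("belief", function(bba, A) standardGeneric("belief"))

#' @rdname belief
#' @export
setGeneric("plausibility", function(bba, A) standardGeneric("plausibility"))

#' @rdname pignistic
#' @export
setGeneric("pignistic", function(bba) standardGeneric("pignistic"))

#' @rdname frameElements
#' @export
setGeneric("frameElements", function(x) standardGeneric("frameElements"))

#' @rdname focalElements
#' @export
setGeneric("focalElements", function(x) standardGeneric("focalElements"))

#' @rdname massValues
#' @export
setGeneric("massValues", function(x) standardGeneric("massValues"))

#' @rdname isBayesian
#' @export
setGeneric("isBayesian", function(x) standardGeneric("isBayesian"))

#' @rdname transformMatrix
#' @export
setGeneric("transformMatrix", function(x) standardGeneric("transformMatrix"))
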