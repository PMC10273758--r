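#' @rdname featureMatrix
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname sampleIds
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname cohortLabels
#' @export
setGeneric("cohortLabels", function(x) standardGeneric("cohortLabels"))

#' @rdname trueOffsets
#' @export
setGeneric("trueOffsets", function(x) standardGeneric("trueOffsets"))

#' @rdname predictRisk
#' @export
setGeneric("predictRisk", function(object, newdata, ...)
  standardGeneric("predictRisk"))
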