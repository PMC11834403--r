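#' @rdname AsvExperiment
#' @export
setGeneric("asvCounts", function(x) standardGeneric("asvCounts"))

#' @rdname AsvExperiment
#' @export
setGeneric("sampleDates", function(x) standardGeneric("sampleDates"))

#' @rdname AsvExperiment
#' @export
setGeneric("sampleDepths", function(x) standardGeneric("sampleDepths"))

#' @rdname AsvExperiment
#' @export
setGeneric("taxonomyKeys", function(x) standardGeneric("taxonomyKeys"))

#' @rdname PrecisionGraph-accessors
#' @export
setGeneric("edges", function(x, ...) standardGeneric("edges"))

#' @rdname PrecisionGraph-accessors
#' @export
setGeneric("precisionMatrix", function(x) standardGeneric("precisionMatrix"))

#' @rdname PrecisionGraph-accessors
#' @export
setGeneric("chosenLambda", function(x) standardGeneric("chosenLambda"))

#' @rdname PrecisionGraph-accessors
#' @export
setGeneric("featureKinds", function(x) standardGeneric("featureKinds"))

#' @rdname StabilityPath-accessors
#' @export
setGeneric("instability", function(x, monotone = FALSE)
  standardGeneric("instability"))

#' @rdname StabilityPath-accessors
#' @export
setGeneric("lambdaPath", function(x) standardGeneric("lambdaPath"))

#' @rdname InteractionDB-accessors
#' @export
setGeneric("dbRecords", function(x) standardGeneric("dbRecords"))
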