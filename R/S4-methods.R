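#' Accessors for InteractionDB
#'
#' @param x an \linkS4class{InteractionDB}
#' @return \code{dbRecords} returns the record data.frame.
#' @name InteractionDB-accessors
NULL

#' @rdname InteractionDB-accessors
#' @export
setMethod("dbRecords", "InteractionDB", function(x) x@records)

setMethod("show", "InteractionDB", function(object) {
  rec <- object@records
  cat("InteractionDB:", nrow(rec), "records (",
      sum(rec$multiplicity), "incl. duplicates )\n")
  if (nrow(rec)) {
    tt <- table(rec$interaction_type)
    cat("  types:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "),
        "\n")
  }
  cat("  provenance:", object@provenance, "\n")
})

#' Accessors for PrecisionGraph
#'
#' @param x a \linkS4class{PrecisionGraph}
#' @param kind optional filter for \code{edges}: \code{"asv-asv"},
#'   \code{"asv-env"} or \code{"env-env"}
#' @param ... unused
#' @name PrecisionGraph-accessors
NULL

#' @rdname PrecisionGraph-accessors
#' @export
setMethod("edges", "PrecisionGraph", function(x, kind = NULL, ...) {
  e <- x@edges
  if (!is.null(kind)) e <- e[e$kind_pair %in% kind, , drop = FALSE]
  e
})

#' @rdname PrecisionGraph-accessors
#' @export
setMethod("precisionMatrix", "PrecisionGraph", function(x) x@theta)

#' @rdname PrecisionGraph-accessors
#' @export
setMethod("chosenLambda", "PrecisionGraph", function(x) x@lambda)

#' @rdname PrecisionGraph-accessors
#' @export
setMethod("featureKinds", "PrecisionGraph", function(x) x@kinds)

setMethod("show", "PrecisionGraph", function(object) {
  p <- nrow(object@theta)
  cat("PrecisionGraph:", p, "features,", nrow(object@edges),
      "edges, lambda =", signif(object@lambda, 4), "\n")
  if (nrow(object@edges)) {
    tt <- table(object@edges$kind_pair)
    cat("  edge kinds:", paste(sprintf("%s=%d", names(tt), tt),
                               collapse = ", "), "\n")
  }
})

#' Accessors for StabilityPath
#'
#' @param x a \linkS4class{StabilityPath}
#' @param monotone return the monotonized instability instead of the raw one
#' @name StabilityPath-accessors
NULL

#' @rdname StabilityPath-accessors
#' @export
setMethod("instability", "StabilityPath", function(x, monotone = FALSE)
  if (monotone) x@monotone else x@instability)

#' @rdname StabilityPath-accessors
#' @export
setMethod("lambdaPath", "StabilityPath", function(x) x@lambdas)

#' @rdname StabilityPath-accessors
#' @export
setGeneric("optimalLambda", function(x) standardGeneric("optimalLambda"))

#' @rdname StabilityPath-accessors
#' @export
setMethod("optimalLambda", "StabilityPath", function(x)
  x@lambdas[x@optIndex])

setMethod("show", "StabilityPath", function(object) {
  cat("StabilityPath:", length(object@lambdas), "lambdas,",
      object@rep, "subsamples of size", object@b, "\n")
  cat("  selected lambda =", signif(optimalLambda(object), 4),
      "(index", object@optIndex, "), beta =", object@beta, "\n")
})
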