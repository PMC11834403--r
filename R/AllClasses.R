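#' AsvExperiment: an ASV count time series with dates, depth and taxonomy
#'
#' Container for a monthly amplicon time series. Extends
#' \linkS4class{SummarizedExperiment}: rows are ASVs (features), columns are
#' samples. \code{colData} must carry a \code{date} (class \code{Date}) and a
#' \code{depth} label per sample (e.g. \code{"surface"} / \code{"DCM"});
#' \code{rowData} carries the semicolon-delimited 8(or 9)-rank lineage and
#' the matching keys derived from it (genus, Syndiniales group, MAST clade,
#' radiolarian host class).
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @aliases AsvExperiment-class
#' @exportClass AsvExperiment
setClass("AsvExperiment", contains = "SummarizedExperiment")

setValidity("AsvExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(cts))) msg <- c(msg, "counts must be finite")
    else if (any(cts < 0)) msg <- c(msg, "counts must be >= 0")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("date", "depth") %in% colnames(cd)))
    msg <- c(msg, "colData must have 'date' and 'depth' columns")
  else if (!inherits(cd$date, "Date"))
    msg <- c(msg, "colData$date must be of class Date")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate ASV ids")
  rd <- SummarizedExperiment::rowData(object)
  if (!"lineage" %in% colnames(rd))
    msg <- c(msg, "rowData must have a 'lineage' column")
  if (length(msg)) msg else TRUE
})

#' InteractionDB: typed taxon-pair interaction records
#'
#' A curated set of pairwise protist interaction records in the style of
#' literature interaction databases. Each record keys two taxa at the
#' granularity their taxonomy supports (\code{genus},
#' \code{syndiniales_group}, \code{radiolarian_class} or \code{mast_clade})
#' and carries one of four interaction types: \code{parasitism},
#' \code{predation}, \code{symbiosis} or \code{unresolved}.
#'
#' @slot records data.frame with columns \code{record_id},
#'   \code{taxon_a_key}, \code{taxon_a_rank}, \code{taxon_b_key},
#'   \code{taxon_b_rank}, \code{interaction_type}, \code{multiplicity}
#' @slot provenance character scalar describing the source
#' @aliases InteractionDB-class
#' @exportClass InteractionDB
setClass("InteractionDB",
         representation(records = "data.frame", provenance = "character"))

DB_RANKS <- c("genus", "syndiniales_group", "radiolarian_class", "mast_clade")
DB_TYPES <- c("parasitism", "predation", "symbiosis", "unresolved")

setValidity("InteractionDB", function(object) {
  rec <- object@records
  need <- c("record_id", "taxon_a_key", "taxon_a_rank",
            "taxon_b_key", "taxon_b_rank", "interaction_type", "multiplicity")
  msg <- character()
  if (!all(need %in% colnames(rec)))
    msg <- c(msg, paste("records must have columns:",
                        paste(setdiff(need, colnames(rec)), collapse = ", ")))
  else {
    if (nrow(rec)) {
      if (any(!nzchar(rec$taxon_a_key)) || any(!nzchar(rec$taxon_b_key)))
        msg <- c(msg, "empty taxon keys")
      if (!all(rec$interaction_type %in% DB_TYPES))
        msg <- c(msg, "interaction_type outside the closed set")
      if (!all(rec$taxon_a_rank %in% DB_RANKS) ||
          !all(rec$taxon_b_rank %in% DB_RANKS))
        msg <- c(msg, "unknown taxon rank")
    }
  }
  if (length(msg)) msg else TRUE
})

#' PrecisionGraph: an estimated sparse precision matrix and its edges
#'
#' Result of a graphical lasso fit. Off-diagonal non-zeros of the precision
#' matrix Theta are the network edges; their strength is reported as the
#' partial correlation \eqn{\rho_{ij} = -\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}}.
#'
#' @slot theta symmetric precision matrix (features x features)
#' @slot lambda regularization value the fit used
#' @slot edges data.frame: \code{feature_a}, \code{feature_b}, \code{theta},
#'   \code{partial_cor}, \code{kind_pair}
#' @slot kinds named character vector, \code{"asv"} or \code{"env"} per feature
#' @slot converged logical
#' @aliases PrecisionGraph-class
#' @exportClass PrecisionGraph
setClass("PrecisionGraph",
         representation(theta = "matrix", lambda = "numeric",
                        edges = "data.frame", kinds = "character",
                        converged = "logical"))

setValidity("PrecisionGraph", function(object) {
  th <- object@theta
  msg <- character()
  if (nrow(th) != ncol(th)) msg <- c(msg, "theta must be square")
  else {
    if (max(abs(th - t(th))) > 1e-8) msg <- c(msg, "theta must be symmetric")
    if (any(diag(th) <= 0)) msg <- c(msg, "theta diagonal must be > 0")
    up <- upper.tri(th)
    nEdges <- sum(th[up] != 0)
    if (nEdges != nrow(object@edges))
      msg <- c(msg, "edge list does not match non-zero support of theta")
  }
  if (length(object@kinds) && length(object@kinds) != nrow(th))
    msg <- c(msg, "kinds length must match theta dimension")
  if (length(msg)) msg else TRUE
})

#' StabilityPath: StARS subsampling summary along a regularization path
#'
#' Per-lambda edge selection frequencies over subsamples, the resulting
#' graph instability D(lambda) (mean over feature pairs of
#' \eqn{2\hat\theta(1-\hat\theta)}), its monotonized version, and the
#' selected lambda.
#'
#' @slot lambdas decreasing regularization path
#' @slot frequency matrix (feature pairs x lambdas) of selection frequencies
#' @slot instability raw D per lambda
#' @slot monotone monotonized D (non-decreasing toward small lambda)
#' @slot rep number of subsamples
#' @slot b subsample size
#' @slot beta instability threshold
#' @slot optIndex index of the selected lambda in the path
#' @slot seed master seed used for subsampling
#' @aliases StabilityPath-class
#' @exportClass StabilityPath
setClass("StabilityPath",
         representation(lambdas = "numeric", frequency = "matrix",
                        instability = "numeric", monotone = "numeric",
                        rep = "integer", b = "integer", beta = "numeric",
                        optIndex = "integer", seed = "integer"))

setValidity("StabilityPath", function(object) {
  msg <- character()
  if (is.unsorted(rev(object@lambdas), strictly = TRUE))
    msg <- c(msg, "lambdas must be strictly decreasing")
  if (any(object@lambdas <= 0)) msg <- c(msg, "lambdas must be > 0")
  if (length(object@instability) != length(object@lambdas))
    msg <- c(msg, "instability length mismatch")
  if (any(object@frequency < 0 | object@frequency > 1))
    msg <- c(msg, "selection frequencies must lie in [0, 1]")
  if (any(object@instability < 0 | object@instability > 0.5 + 1e-12))
    msg <- c(msg, "instability must lie in [0, 0.5]")
  if (is.unsorted(object@monotone))
    msg <- c(msg, "monotonized instability must be non-decreasing")
  if (length(msg)) msg else TRUE
})
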