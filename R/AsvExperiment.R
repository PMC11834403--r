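#' Build an AsvExperiment from a count matrix, sample metadata and taxonomy
#'
#' @param counts numeric matrix of non-negative counts (or relative
#'   abundances), ASVs in rows, samples in columns. A samples-by-ASVs
#'   matrix read from disk should be transposed first (the TSV readers do
#'   this for you).
#' @param dates per-sample collection dates (\code{Date} or ISO-8601
#'   strings)
#' @param depth per-sample depth label (e.g. \code{"surface"}, \code{"DCM"})
#' @param taxonomy named character vector (or data.frame with columns
#'   \code{asv_id}, \code{lineage}) of semicolon-delimited 8- or 9-rank
#'   lineages (domain;supergroup;division;subdivision;class;order;family;
#'   genus[;species]); one entry per ASV in \code{counts}
#'
#' @details Matching keys for interaction-database lookup (genus,
#'   Syndiniales group, MAST clade, radiolarian host class) are derived
#'   from the lineage at construction time and stored in \code{rowData};
#'   see \code{\link{deriveTaxonKeys}}.
#'
#' @return an \linkS4class{AsvExperiment}
#' @examples
#' cts <- matrix(rpois(20, 50), nrow = 4,
#'               dimnames = list(paste0("asv", 1:4), paste0("s", 1:5)))
#' tax <- setNames(rep(paste(c("Eukaryota", "TSAR", "Alveolata",
#'   "Dinoflagellata", "Dinophyceae", "Gonyaulacales", "Gonyaulacaceae",
#'   "Tripos"), collapse = ";"), 4), rownames(cts))
#' ae <- AsvExperiment(cts, dates = as.Date("2003-09-01") + 30 * (0:4),
#'                     depth = "surface", taxonomy = tax)
#' @export
AsvExperiment <- function(counts, dates, depth, taxonomy) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have ASV rownames and sample colnames")
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("unparseable sample dates")
  if (length(dates) != ncol(counts))
    stop("'dates' must have one entry per sample")
  depth <- rep_len(as.character(depth), ncol(counts))
  if (is.data.frame(taxonomy)) {
    taxonomy <- setNames(as.character(taxonomy$lineage),
                         as.character(taxonomy$asv_id))
  }
  missTax <- setdiff(rownames(counts), names(taxonomy))
  if (length(missTax))
    stop("ASVs absent from taxonomy: ", paste(missTax, collapse = ", "))
  lineage <- unname(taxonomy[rownames(counts)])
  keys <- deriveTaxonKeys(lineage)
  rd <- S4Vectors::DataFrame(lineage = lineage, keys)
  rownames(rd) <- rownames(counts)
  cd <- S4Vectors::DataFrame(date = dates, depth = depth,
                             row.names = colnames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd)
  methods::new("AsvExperiment", se)
}

#' Derive interaction-matching keys from lineage strings
#'
#' Four keys drive taxonomy-aware database matching:
#' \describe{
#'   \item{genus}{8th rank (or the lowest resolved rank token) unless it is
#'     a placeholder (empty, \code{sp.}, \code{unclassified} or a
#'     \code{_X}/\code{_XX}-style stub), normalized case/whitespace, species
#'     epithets stripped.}
#'   \item{syndiniales_group}{\code{"group i"}, \code{"group ii"}, ... when
#'     any rank mentions Syndiniales; sub-genus taxonomy of these parasites
#'     is unresolved so matching happens at the group level.}
#'   \item{mast_clade}{the most specific \code{MAST-n[letter]} token found
#'     (uncultured marine stramenopile clades).}
#'   \item{radiolarian_class}{\code{"acantharea clade f"} for Clade F
#'     acantharians, \code{"polycystinea"} for polycystines; these
#'     photosymbiotic hosts are matched at class/clade level.}
#' }
#'
#' @param lineage character vector of semicolon-delimited lineages
#' @return data.frame with columns \code{genus}, \code{syndiniales_group},
#'   \code{mast_clade}, \code{radiolarian_class} (NA where underivable)
#' @export
deriveTaxonKeys <- function(lineage) {
  n <- length(lineage)
  genus <- rep(NA_character_, n)
  synd <- rep(NA_character_, n)
  mast <- rep(NA_character_, n)
  radio <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ranks <- trimws(strsplit(lineage[i], ";", fixed = TRUE)[[1]])
    if (length(ranks) < 8) next
    g <- ranks[8]
    placeholder <- !nzchar(g) || grepl("_X+$", g) ||
      grepl("^(unclassified|unknown|sp\\.?)$", g, ignore.case = TRUE) ||
      grepl("(MAST-[0-9]+[A-Z]?|Group[ _-]*[IVX]+)", g, ignore.case = TRUE)
    if (!placeholder) genus[i] <- normalizeKey(g, genus = TRUE)
    joined <- paste(ranks, collapse = ";")
    if (grepl("Syndiniales", joined, ignore.case = TRUE)) {
      m <- regmatches(joined,
                      regexpr("Group[ _-]*[IVX]+", joined, ignore.case = TRUE))
      if (length(m))
        synd[i] <- paste("group", tolower(gsub("Group[ _-]*", "", m,
                                               ignore.case = TRUE)))
      genus[i] <- NA_character_ # genus unreliable for Syndiniales
    }
    mm <- regmatches(joined, gregexpr("MAST-[0-9]+[A-Z]?", joined,
                                      ignore.case = TRUE))[[1]]
    if (length(mm)) {
      mast[i] <- toupper(mm[which.max(nchar(mm))])
      genus[i] <- NA_character_
    }
    if (any(grepl("^Acantharea$", ranks, ignore.case = TRUE)) &&
        grepl("Clade[ _-]*F", joined, ignore.case = TRUE)) {
      radio[i] <- "acantharea clade f"
      genus[i] <- NA_character_
    } else if (any(grepl("^Polycystin(ea|es)$", ranks, ignore.case = TRUE))) {
      radio[i] <- "polycystinea"
      genus[i] <- NA_character_
    }
  }
  data.frame(genus = genus, syndiniales_group = synd, mast_clade = mast,
             radiolarian_class = radio, stringsAsFactors = FALSE)
}

#' @describeIn AsvExperiment count matrix (ASVs x samples)
#' @param x an \code{AsvExperiment}
#' @export
setMethod("asvCounts", "AsvExperiment", function(x)
  SummarizedExperiment::assay(x, "counts"))

#' @describeIn AsvExperiment per-sample collection dates
#' @export
setMethod("sampleDates", "AsvExperiment", function(x)
  SummarizedExperiment::colData(x)$date)

#' @describeIn AsvExperiment per-sample depth labels
#' @export
setMethod("sampleDepths", "AsvExperiment", function(x)
  SummarizedExperiment::colData(x)$depth)

#' @describeIn AsvExperiment taxonomy matching keys (data.frame with
#'   genus, syndiniales_group, mast_clade, radiolarian_class)
#' @export
setMethod("taxonomyKeys", "AsvExperiment", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  out <- as.data.frame(rd[, c("genus", "syndiniales_group", "mast_clade",
                              "radiolarian_class")])
  rownames(out) <- rownames(x)
  out
})

setMethod("show", "AsvExperiment", function(object) {
  cat("AsvExperiment with", nrow(object), "ASVs x", ncol(object),
      "samples\n")
  d <- sampleDates(object)
  if (length(d))
    cat("  dates:", format(min(d)), "to", format(max(d)), "| depths:",
        paste(unique(sampleDepths(object)), collapse = ", "), "\n")
  methods::callNextMethod()
})
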