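#' Parse an interaction-database TSV
#'
#' Expected columns: \code{record_id}, \code{taxon_a_key},
#' \code{taxon_a_rank}, \code{taxon_b_key}, \code{taxon_b_rank},
#' \code{interaction_type}. Ranks must be one of \code{genus},
#' \code{syndiniales_group}, \code{radiolarian_class}, \code{mast_clade};
#' types one of \code{parasitism}, \code{predation}, \code{symbiosis},
#' \code{unresolved}. Duplicate records (same keys, ranks and type,
#' orientation-insensitive) are collapsed with their multiplicity
#' retained.
#'
#' @param path TSV file path
#' @param provenance short description stored with the database
#' @return an \linkS4class{InteractionDB}
#' @export
parseInteractionDB <- function(path, provenance = path) {
  rec <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("record_id", "taxon_a_key", "taxon_a_rank", "taxon_b_key",
            "taxon_b_rank", "interaction_type")
  if (!all(need %in% colnames(rec)))
    stop("interaction DB must have columns: ", paste(need, collapse = ", "))
  badType <- which(!rec$interaction_type %in% DB_TYPES)
  if (length(badType))
    stop(sprintf("unknown interaction_type '%s' at line %d",
                 rec$interaction_type[badType[1]], badType[1] + 1L))
  badRank <- which(!(rec$taxon_a_rank %in% DB_RANKS &
                       rec$taxon_b_rank %in% DB_RANKS))
  if (length(badRank))
    stop(sprintf("unknown taxon rank at line %d", badRank[1] + 1L))

  normA <- normalizeKey(rec$taxon_a_key, genus = rec$taxon_a_rank == "genus")
  normB <- normalizeKey(rec$taxon_b_key, genus = rec$taxon_b_rank == "genus")
  ka <- paste(normA, rec$taxon_a_rank, sep = "|")
  kb <- paste(normB, rec$taxon_b_rank, sep = "|")
  dup <- paste(pmin(ka, kb), pmax(ka, kb), rec$interaction_type, sep = "##")
  first <- !duplicated(dup)
  mult <- as.integer(table(dup)[dup[first]])
  out <- data.frame(record_id = rec$record_id[first],
                    taxon_a_key = normA[first],
                    taxon_a_rank = rec$taxon_a_rank[first],
                    taxon_b_key = normB[first],
                    taxon_b_rank = rec$taxon_b_rank[first],
                    interaction_type = rec$interaction_type[first],
                    multiplicity = mult, stringsAsFactors = FALSE)
  methods::new("InteractionDB", records = out, provenance = provenance)
}

## candidate (key, rank) descriptors for one ASV given its derived keys;
## special ranks come before the genus fallback (rule precedence)
.candidateKeys <- function(keys, id) {
  out <- list()
  if (!is.na(keys[id, "syndiniales_group"]))
    out[[length(out) + 1L]] <- c(key = keys[id, "syndiniales_group"],
                                 rank = "syndiniales_group")
  if (!is.na(keys[id, "radiolarian_class"]))
    out[[length(out) + 1L]] <- c(key = keys[id, "radiolarian_class"],
                                 rank = "radiolarian_class")
  if (!is.na(keys[id, "mast_clade"]))
    out[[length(out) + 1L]] <- c(key = keys[id, "mast_clade"],
                                 rank = "mast_clade")
  if (!is.na(keys[id, "genus"]))
    out[[length(out) + 1L]] <- c(key = keys[id, "genus"], rank = "genus")
  out
}

## does (key, rank) match one side of a record? MAST clades match on
## prefix so a record at "MAST-3" supports a "MAST-3E" ASV
.sideMatches <- function(key, rank, recKey, recRank) {
  if (rank != recRank) return(FALSE)
  k <- normalizeKey(key, genus = rank == "genus")
  rk <- normalizeKey(recKey, genus = rank == "genus")
  if (rank == "mast_clade")
    return(toupper(k) == toupper(rk) || startsWith(toupper(k), toupper(rk)))
  identical(k, rk)
}

MATCH_RULES <- c(syndiniales_group = "syndiniales_group_host_genus",
                 radiolarian_class = "radiolarian_class_symbiont_genus",
                 mast_clade = "mast_clade_symbiont_genus",
                 genus = "genus_genus")

.foldType <- function(type)
  ifelse(type %in% c("symbiosis", "unresolved"), "other_symbioses", type)

#' Match network edges against an interaction database
#'
#' For each ASV-ASV edge, matching keys are derived from both lineages
#' and tested against every database record in both orientations under
#' four taxonomy-aware rules, in precedence order: (1) Syndiniales group
#' + host genus, (2) radiolarian host class (Clade F acantharians or
#' polycystines) + symbiont genus, (3) MAST clade + symbiont genus, (4)
#' genus + genus. An edge with at least one matching record is
#' \code{"supported"}; all matching records are recorded and their types
#' folded for reporting (\code{symbiosis} and \code{unresolved} both
#' report as \code{other_symbioses}). Edges with no match are
#' \code{"novel"}; edges whose taxonomy yields no usable key on one side
#' are \code{"novel"} with reason \code{"rank-unresolvable"}. Matching is
#' symmetric in edge orientation, and one database record may support
#' many ASV-level edges.
#'
#' @param edges data.frame with columns \code{asv_a}, \code{asv_b} (and
#'   optionally \code{partial_cor}), or a \linkS4class{PrecisionGraph}
#'   (its ASV-ASV edges are used)
#' @param taxonomy an \linkS4class{AsvExperiment}, or a data.frame as
#'   returned by \code{\link{deriveTaxonKeys}} with ASV ids as rownames
#' @param db an \linkS4class{InteractionDB}
#' @param clr optional samples x ASVs CLR matrix; if given, the Spearman
#'   correlation (SCC) of each edge's CLR abundances is added
#' @return data.frame, one row per edge: \code{asv_a}, \code{asv_b},
#'   \code{status} ("supported"/"novel"), \code{match_rule},
#'   \code{matched_records}, \code{reported_type} (comma-joined set),
#'   \code{scc}, \code{partial_cor}, \code{reason}
#' @export
matchEdges <- function(edges, taxonomy, db, clr = NULL) {
  if (is(edges, "PrecisionGraph")) {
    e <- edges(edges, kind = "asv-asv")
    edges <- data.frame(asv_a = e$feature_a, asv_b = e$feature_b,
                        partial_cor = e$partial_cor,
                        stringsAsFactors = FALSE)
  }
  keys <- if (is(taxonomy, "AsvExperiment")) taxonomyKeys(taxonomy)
          else as.data.frame(taxonomy)
  missing <- setdiff(unique(c(edges$asv_a, edges$asv_b)), rownames(keys))
  if (length(missing))
    stop("ASVs missing from taxonomy: ", paste(missing, collapse = ", "))
  rec <- dbRecords(db)
  n <- nrow(edges)
  status <- rep("novel", n)
  rule <- rep(NA_character_, n)
  matched <- rep(NA_character_, n)
  rtype <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  scc <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    a <- edges$asv_a[i]; b <- edges$asv_b[i]
    ca <- .candidateKeys(keys, a)
    cb <- .candidateKeys(keys, b)
    if (!length(ca) || !length(cb)) {
      reason[i] <- "rank-unresolvable"
      next
    }
    hits <- integer(0)
    hitRule <- character(0)
    for (ka in ca) for (kb in cb) {
      for (r in seq_len(nrow(rec))) {
        fwd <- .sideMatches(ka["key"], ka["rank"], rec$taxon_a_key[r],
                            rec$taxon_a_rank[r]) &&
               .sideMatches(kb["key"], kb["rank"], rec$taxon_b_key[r],
                            rec$taxon_b_rank[r])
        rev <- .sideMatches(ka["key"], ka["rank"], rec$taxon_b_key[r],
                            rec$taxon_b_rank[r]) &&
               .sideMatches(kb["key"], kb["rank"], rec$taxon_a_key[r],
                            rec$taxon_a_rank[r])
        if (fwd || rev) {
          hits <- c(hits, r)
          sp <- setdiff(unique(c(ka["rank"], kb["rank"])), "genus")
          hitRule <- c(hitRule,
                       MATCH_RULES[[if (length(sp)) sp[1] else "genus"]])
        }
      }
    }
    if (length(hits)) {
      keepFirst <- !duplicated(hits)
      hits <- hits[keepFirst]
      hitRule <- hitRule[keepFirst]
      status[i] <- "supported"
      rule[i] <- hitRule[1] # highest-precedence rule that fired
      matched[i] <- paste(rec$record_id[hits], collapse = ",")
      rtype[i] <- paste(sort(unique(.foldType(rec$interaction_type[hits]))),
                        collapse = ",")
    }
    if (!is.null(clr)) {
      xa <- clr[, a]; xb <- clr[, b]
      if (sd(xa) > 0 && sd(xb) > 0)
        scc[i] <- cor(xa, xb, method = "spearman")
    }
  }
  out <- data.frame(asv_a = edges$asv_a, asv_b = edges$asv_b,
                    status = status, match_rule = rule,
                    matched_records = matched, reported_type = rtype,
                    scc = scc,
                    partial_cor = if ("partial_cor" %in% colnames(edges))
                      edges$partial_cor else NA_real_,
                    reason = reason, stringsAsFactors = FALSE)
  out
}

#' Summarize database recall per interaction type
#'
#' For each reported type (parasitism, predation, other_symbioses):
#' the number of database records of that type; the number whose both
#' taxon keys are realizable by at least one ASV in the network input;
#' and the number of supported edges of that type found in the network.
#'
#' @param annotations output of \code{\link{matchEdges}}
#' @param db the \linkS4class{InteractionDB}
#' @param taxonomy as in \code{\link{matchEdges}} — keys of the ASVs that
#'   entered the network (post prevalence filter)
#' @param network_input_asvs character vector of ASV ids that entered the
#'   network input (defaults to all rows of \code{taxonomy})
#' @return data.frame with one row per reported type and columns
#'   \code{type}, \code{db_records}, \code{db_records_realizable},
#'   \code{supported_edges}
#' @export
summarizeRecall <- function(annotations, db, taxonomy,
                            network_input_asvs = NULL) {
  keys <- if (is(taxonomy, "AsvExperiment")) taxonomyKeys(taxonomy)
          else as.data.frame(taxonomy)
  if (is.null(network_input_asvs)) network_input_asvs <- rownames(keys)
  keys <- keys[rownames(keys) %in% network_input_asvs, , drop = FALSE]
  rec <- dbRecords(db)
  recFold <- .foldType(rec$interaction_type)

  realizableSide <- function(key, rank) {
    any(vapply(rownames(keys), function(id)
      any(vapply(.candidateKeys(keys, id), function(k)
        .sideMatches(k["key"], k["rank"], key, rank), TRUE)), TRUE))
  }
  realizable <- vapply(seq_len(nrow(rec)), function(r)
    realizableSide(rec$taxon_a_key[r], rec$taxon_a_rank[r]) &&
      realizableSide(rec$taxon_b_key[r], rec$taxon_b_rank[r]), TRUE)

  types <- c("parasitism", "predation", "other_symbioses")
  sup <- annotations[annotations$status == "supported", , drop = FALSE]
  supTypes <- strsplit(sup$reported_type, ",", fixed = TRUE)
  data.frame(
    type = types,
    db_records = vapply(types, function(tp) sum(recFold == tp), 0L),
    db_records_realizable = vapply(types, function(tp)
      sum(recFold == tp & realizable), 0L),
    supported_edges = vapply(types, function(tp)
      sum(vapply(supTypes, function(s) tp %in% s, TRUE)), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank unmatched (novel) edges by Spearman correlation
#'
#' Computes (or reuses) the Spearman correlation coefficient of the CLR
#' abundances of each novel edge, sorts by |SCC| descending, and flags
#' rows with \code{|SCC| >= threshold} as \code{"strong"} (inclusive
#' bound). Edges with a constant CLR series are excluded from the
#' ranking and returned in the \code{excluded} attribute.
#'
#' @param annotations output of \code{\link{matchEdges}}
#' @param clr samples x ASVs CLR matrix covering all edge members
#' @param report_threshold |SCC| at or above which an edge is flagged
#'   strong (default 0.64)
#' @return data.frame of novel edges sorted by |SCC| descending with an
#'   added logical column \code{strong}
#' @export
novelEdgeScc <- function(annotations, clr, report_threshold = 0.64) {
  nov <- annotations[annotations$status == "novel", , drop = FALSE]
  if (nrow(nov)) {
    for (i in seq_len(nrow(nov))) {
      if (is.na(nov$scc[i])) {
        xa <- clr[, nov$asv_a[i]]
        xb <- clr[, nov$asv_b[i]]
        if (sd(xa) > 0 && sd(xb) > 0)
          nov$scc[i] <- cor(xa, xb, method = "spearman")
      }
    }
  }
  excluded <- nov[is.na(nov$scc), , drop = FALSE]
  nov <- nov[!is.na(nov$scc), , drop = FALSE]
  nov <- nov[order(-abs(nov$scc)), , drop = FALSE]
  # inclusive bound; tolerance so rank-exact values at the threshold
  # (e.g. 0.64) are not lost to floating-point representation
  nov$strong <- abs(nov$scc) >= report_threshold - 1e-12
  attr(nov, "excluded") <- excluded
  nov
}
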