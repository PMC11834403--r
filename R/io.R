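#' Read and cross-validate the tabular inputs
#'
#' Reads the ASV count table (rows = samples, first column
#' \code{sample_id}), the sample metadata (\code{sample_id}, ISO-8601
#' \code{date}, \code{depth}), the taxonomy table (\code{asv_id},
#' \code{lineage}) and optionally the environmental table
#' (\code{sample_id} plus one numeric column per variable; empty string =
#' missing). All tables are UTF-8, tab-separated with '.' decimals.
#' Samples are aligned across tables by \code{sample_id}; validation
#' failures are hard errors naming the offending entries.
#'
#' @param counts,meta,tax,env file paths (\code{env} optional)
#' @return list with \code{asv} (an \linkS4class{AsvExperiment}) and
#'   \code{env} (numeric matrix with NA for missing, or NULL)
#' @export
readProtistTables <- function(counts, meta, tax, env = NULL) {
  cts <- read.delim(counts, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(cts)[1] != "sample_id")
    stop("counts table must have 'sample_id' as its first column")
  sampleIds <- as.character(cts$sample_id)
  if (anyDuplicated(sampleIds))
    stop("duplicate sample ids in counts table: ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  m <- as.matrix(cts[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- sampleIds
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at sample '%s', ASV '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))

  md <- read.delim(meta, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "date", "depth") %in% colnames(md)))
    stop("metadata must have columns sample_id, date, depth")
  missingMeta <- setdiff(sampleIds, md$sample_id)
  if (length(missingMeta))
    stop("samples missing from metadata: ",
         paste(missingMeta, collapse = ", "))
  md <- md[match(sampleIds, md$sample_id), ]
  dt <- as.Date(md$date, format = "%Y-%m-%d")
  if (anyNA(dt))
    stop("unparseable dates for samples: ",
         paste(md$sample_id[is.na(dt)], collapse = ", "))

  tx <- read.delim(tax, stringsAsFactors = FALSE)
  if (!all(c("asv_id", "lineage") %in% colnames(tx)))
    stop("taxonomy must have columns asv_id, lineage")
  missingTax <- setdiff(colnames(m), tx$asv_id)
  if (length(missingTax))
    stop("ASVs missing from taxonomy: ",
         paste(missingTax, collapse = ", "))

  asv <- AsvExperiment(t(m), dates = dt, depth = md$depth,
                       taxonomy = setNames(tx$lineage, tx$asv_id))

  envMat <- NULL
  if (!is.null(env)) {
    ev <- read.delim(env, check.names = FALSE, stringsAsFactors = FALSE,
                     na.strings = c("NA", ""))
    if (colnames(ev)[1] != "sample_id")
      stop("env table must have 'sample_id' as its first column")
    missingEnv <- setdiff(sampleIds, ev$sample_id)
    if (length(missingEnv))
      stop("samples missing from env table: ",
           paste(missingEnv, collapse = ", "))
    ev <- ev[match(sampleIds, ev$sample_id), ]
    envMat <- as.matrix(ev[, -1, drop = FALSE])
    storage.mode(envMat) <- "double"
    rownames(envMat) <- sampleIds
  }
  list(asv = asv, env = envMat)
}

#' Write an AsvExperiment (and optional env table / interaction DB) as TSV
#'
#' Counterpart of \code{\link{readProtistTables}}; reading the written
#' files reproduces the objects (round-trip identity, up to numeric
#' formatting of the env table).
#'
#' @param asv an \linkS4class{AsvExperiment}
#' @param dir output directory (created if needed)
#' @param env optional samples x variables matrix
#' @param db optional \linkS4class{InteractionDB}
#' @param truth optional \code{SyntheticTruth}; written as JSON
#' @return invisibly, the named vector of written paths
#' @export
writeProtistTables <- function(asv, dir, env = NULL, db = NULL,
                               truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "asv_counts.tsv"),
             meta = file.path(dir, "sample_metadata.tsv"),
             tax = file.path(dir, "taxonomy.tsv"))
  cts <- t(asvCounts(asv))
  df <- data.frame(sample_id = rownames(cts), cts, check.names = FALSE)
  write.table(df, paths["counts"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample_id = colnames(asv),
                         date = format(sampleDates(asv), "%Y-%m-%d"),
                         depth = sampleDepths(asv)),
              paths["meta"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(asv_id = rownames(asv),
                         lineage = SummarizedExperiment::rowData(asv)$lineage),
              paths["tax"], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(env)) {
    paths["env"] <- file.path(dir, "env.tsv")
    write.table(data.frame(sample_id = rownames(env), env,
                           check.names = FALSE),
                paths["env"], sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
  }
  if (!is.null(db)) {
    paths["db"] <- file.path(dir, "interaction_db.tsv")
    write.table(dbRecords(db), paths["db"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(truth)) {
    paths["truth"] <- file.path(dir, "truth.json")
    jsonlite::write_json(
      list(planted_edges = truth$planted_edges,
           seasonal_ids = truth$seasonal_ids,
           sample_dates = format(truth$sample_dates, "%Y-%m-%d")),
      paths["truth"], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}
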