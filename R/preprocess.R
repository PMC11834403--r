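#' Prevalence filter for network input
#'
#' Retains ASVs that are present (non-zero) in at least
#' \code{threshold} of the samples of the table — the "at least 20%" rule
#' used to keep the network input computationally tractable while
#' retaining as many ASVs as possible. Surface and DCM tables should be
#' filtered independently (subset by depth first).
#'
#' @param x an \linkS4class{AsvExperiment}
#' @param threshold prevalence threshold in (0, 1]; default 0.20
#' @param verbose report retained/dropped counts as a message
#' @return the filtered \code{AsvExperiment}; the prevalence per retained
#'   ASV is available in \code{rowData(x)$prevalence}
#' @export
prevalenceFilter <- function(x, threshold = 0.20, verbose = TRUE) {
  stopifnot(is(x, "AsvExperiment"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("'threshold' must lie in (0, 1]")
  prev <- rowMeans(asvCounts(x) > 0)
  keep <- prev >= threshold
  if (!any(keep))
    stop("prevalence filter dropped all ASVs (empty network input)")
  out <- x[keep, ]
  SummarizedExperiment::rowData(out)$prevalence <- prev[keep]
  if (verbose)
    message(sum(keep), " ASVs retained, ", sum(!keep),
            " dropped at prevalence >= ", threshold)
  out
}

#' Centered log-ratio transform of compositional ASV abundances
#'
#' Per sample \eqn{i}: \eqn{clr(x)_j = \ln(x_{ij} / g(x_i))} with \eqn{g}
#' the geometric mean over ASVs after zero handling. Output rows sum to
#' zero, and the transform is invariant to per-sample scaling of the
#' input.
#'
#' Zero handling (the literature rarely states its choice, so it is
#' explicit here): \code{"pseudocount"} adds \code{pseudocount} to every
#' entry (default 1 for counts; for relative-abundance rows that sum to 1
#' the default becomes half the smallest non-zero value);
#' \code{"multiplicative"} replaces zeros by delta = 0.5 * (smallest
#' non-zero proportion) and rescales the non-zero proportions so each row
#' still sums to one.
#'
#' @param x an \linkS4class{AsvExperiment} or non-negative matrix with
#'   samples in rows
#' @param zero_policy \code{"pseudocount"} or \code{"multiplicative"}
#' @param pseudocount the pseudocount c (NULL = automatic, see Details)
#' @return samples x ASVs real matrix, tagged as stage \code{"clr"}
#' @examples
#' clrTransform(matrix(c(1, 2, 4), 1, dimnames = list("s1", letters[1:3])))
#' @export
clrTransform <- function(x, zero_policy = c("pseudocount", "multiplicative"),
                         pseudocount = NULL) {
  zero_policy <- match.arg(zero_policy)
  m <- if (is(x, "AsvExperiment")) t(asvCounts(x)) else as.matrix(x)
  if (any(!is.finite(m)) || any(m < 0))
    stop("abundances must be finite and >= 0")
  allZero <- rowSums(m) == 0
  if (any(allZero))
    stop("sample(s) with all-zero counts (geometric mean undefined): ",
         paste(rownames(m)[allZero], collapse = ", "))
  relAbund <- all(abs(rowSums(m) - 1) < 1e-6)
  if (zero_policy == "pseudocount") {
    if (is.null(pseudocount)) {
      pseudocount <- if (relAbund) min(m[m > 0]) / 2 else 1
    }
    if (any(m == 0)) m <- m + pseudocount
  } else {
    pm <- m / rowSums(m)
    delta <- min(pm[pm > 0]) / 2
    for (i in seq_len(nrow(pm))) {
      z <- pm[i, ] == 0
      if (any(z)) {
        pm[i, z] <- delta
        pm[i, !z] <- pm[i, !z] * (1 - sum(z) * delta)
      }
    }
    m <- pm
  }
  lg <- log(m)
  out <- lg - rowMeans(lg)
  setStage(out, "clr")
}

#' Impute and standardize an environmental table
#'
#' Missing entries are imputed by iterative chained imputation — each
#' incomplete variable is regressed on all others (random-forest or
#' linear regressor), sweeping until the imputations stabilize — then
#' every column is centered to mean 0 and scaled to variance 1, the
#' standardization used before ordination and distance analyses.
#'
#' @param env samples x variables numeric matrix (NA = missing)
#' @param impute_method \code{"forest"} (default; same model family as
#'   random-forest imputation), \code{"linear"} (chained least squares,
#'   exact for linearly dependent columns) or \code{"mean"}
#' @param seed integer seed for the forest imputer
#' @param max_sweeps maximum chained-imputation sweeps
#' @param standardize center/scale the result (TRUE for all downstream
#'   uses)
#' @return numeric matrix with no missing values, tagged as stage
#'   \code{"env"}
#' @export
prepareEnv <- function(env, impute_method = c("forest", "linear", "mean"),
                       seed = 1L, max_sweeps = 10L, standardize = TRUE) {
  impute_method <- match.arg(impute_method)
  env <- as.matrix(env)
  storage.mode(env) <- "double"
  nMissCol <- colSums(is.na(env))
  if (any(nMissCol == nrow(env)))
    stop("all-missing variable(s): ",
         paste(colnames(env)[nMissCol == nrow(env)], collapse = ", "))
  if (any(nrow(env) - nMissCol < 2))
    stop("variable(s) with fewer than 2 observed values: ",
         paste(colnames(env)[nrow(env) - nMissCol < 2], collapse = ", "))

  missIdx <- which(is.na(env), arr.ind = TRUE)
  if (nrow(missIdx)) {
    filled <- env
    for (j in seq_len(ncol(env))) # mean initialization
      filled[is.na(env[, j]), j] <- mean(env[, j], na.rm = TRUE)
    if (impute_method != "mean") {
      set.seed(seed)
      incomplete <- sort(unique(missIdx[, 2]))
      for (sweep in seq_len(max_sweeps)) {
        delta <- 0
        for (j in incomplete) {
          obs <- !is.na(env[, j])
          dfAll <- as.data.frame(filled[, -j, drop = FALSE])
          colnames(dfAll) <- paste0("v", seq_len(ncol(dfAll)))
          fit <- if (impute_method == "forest")
            randomForest::randomForest(dfAll[obs, , drop = FALSE],
                                       env[obs, j], ntree = 100)
          else lm(y ~ ., data = cbind(y = env[obs, j],
                                      dfAll[obs, , drop = FALSE]))
          pred <- predict(fit, dfAll[!obs, , drop = FALSE])
          delta <- max(delta, max(abs(pred - filled[!obs, j])))
          filled[!obs, j] <- pred
        }
        if (delta < 1e-8) break
      }
    }
    env <- filled
  }
  if (standardize) env <- scale(env)[, , drop = FALSE]
  setStage(env, "env")
}
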