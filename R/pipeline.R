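#' Full network-inference pipeline for one depth
#'
#' Runs the pre-network conditioning chain in its fixed order —
#' prevalence filter, CLR normalization, seasonal GAM detrending,
#' nonparanormal transform — optionally appends standardized
#' environmental variables (detrended with the same settings), and
#' estimates the co-occurrence network by graphical lasso with StARS
#' stability selection.
#'
#' @param asv an \linkS4class{AsvExperiment} (one depth)
#' @param env optional samples x variables environmental matrix aligned
#'   with the samples of \code{asv}; imputed/standardized via
#'   \code{\link{prepareEnv}} if it contains missing values
#' @param prevalence prevalence threshold (default 0.20)
#' @param zero_policy CLR zero handling, see \code{\link{clrTransform}}
#' @param detrend detrend the series before the network (default TRUE)
#' @param n_lambda,ratio,rep,beta,b StARS/glasso controls, see
#'   \code{\link{starsSelect}}
#' @param seed integer seed
#' @param verbose print stage messages
#' @return list: \code{network} (\linkS4class{PrecisionGraph}),
#'   \code{stability} (\linkS4class{StabilityPath}), \code{clr},
#'   \code{detrended}, \code{npn} matrices, and \code{input_asvs}
#' @examples
#' sim <- generateCommunity(syntheticConfig(n_asvs = 12, n_months = 60,
#'                                          missing_month_fraction = 0,
#'                                          n_planted_edges = 4, seed = 7))
#' \donttest{
#' res <- inferCooccurrenceNetwork(sim$asv, rep = 20, seed = 7,
#'                                 verbose = FALSE)
#' res$network
#' }
#' @export
inferCooccurrenceNetwork <- function(asv, env = NULL, prevalence = 0.20,
                                     zero_policy = "pseudocount",
                                     detrend = TRUE, n_lambda = 30L,
                                     ratio = 0.1, rep = 50L, beta = 0.05,
                                     b = NULL, seed = 1L, verbose = TRUE) {
  filt <- prevalenceFilter(asv, threshold = prevalence, verbose = verbose)
  clr <- clrTransform(filt, zero_policy = zero_policy)
  dates <- sampleDates(filt)
  feat <- clr
  kinds <- setNames(rep("asv", ncol(clr)), colnames(clr))
  if (!is.null(env)) {
    env <- as.matrix(env)
    if (anyNA(env)) env <- prepareEnv(env, seed = seed)
    else env <- scale(env)[, , drop = FALSE]
    if (nrow(env) != nrow(clr))
      stop("env rows must align with the samples of 'asv'")
    feat <- cbind(clr, env)
    kinds <- c(kinds, setNames(rep("env", ncol(env)), colnames(env)))
    feat <- setStage(feat, "clr")
  }
  det <- if (detrend) gamDetrend(feat, dates) else setStage(feat,
                                                           "detrended")
  npn <- nonparanormal(det)
  if (verbose) message("StARS over ", n_lambda, " lambdas, ", rep,
                       " subsamples")
  fit <- starsSelect(npn, n_lambda = n_lambda, ratio = ratio, rep = rep,
                     beta = beta, b = b, seed = seed, kinds = kinds)
  list(network = fit$network, stability = fit$stability, clr = clr,
       detrended = det, npn = npn, input_asvs = colnames(clr))
}

#' Edge-recovery F1 against a set of true edges
#'
#' Precision/recall/F1 of an estimated edge list against planted truth,
#' plus (optionally) the expected F1 of a density-matched random graph —
#' the baseline an informative network must beat.
#'
#' @param est data.frame of estimated edges (\code{feature_a}/\code{asv_a},
#'   \code{feature_b}/\code{asv_b}) or a \linkS4class{PrecisionGraph}
#' @param truthEdges data.frame with \code{asv_a}, \code{asv_b}
#' @param nodes character vector of all node ids (defines the pair
#'   universe for the random baseline)
#' @param random_reps random-graph draws for the baseline (0 = skip)
#' @param seed seed for the baseline draws
#' @return list: \code{precision}, \code{recall}, \code{f1},
#'   \code{n_estimated}, \code{n_true}, \code{random_f1}
#' @export
edgeRecoveryF1 <- function(est, truthEdges, nodes, random_reps = 100L,
                           seed = 1L) {
  if (is(est, "PrecisionGraph")) {
    e <- edges(est, kind = "asv-asv")
    est <- data.frame(asv_a = e$feature_a, asv_b = e$feature_b)
  }
  nm <- intersect(c("asv_a", "feature_a"), colnames(est))[1]
  nm2 <- intersect(c("asv_b", "feature_b"), colnames(est))[1]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  estK <- unique(key(est[[nm]], est[[nm2]]))
  truK <- key(truthEdges$asv_a, truthEdges$asv_b)
  f1of <- function(kEst) {
    tp <- length(intersect(kEst, truK))
    prec <- if (length(kEst)) tp / length(kEst) else 0
    rec <- if (length(truK)) tp / length(truK) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1)
  }
  obs <- f1of(estK)
  randomF1 <- NA_real_
  if (random_reps > 0 && length(estK)) {
    pairs <- combn(sort(nodes), 2)
    allK <- key(pairs[1, ], pairs[2, ])
    set.seed(seed)
    randomF1 <- mean(vapply(seq_len(random_reps), function(i)
      f1of(sample(allK, length(estK)))[3], 0))
  }
  list(precision = obs[1], recall = obs[2], f1 = obs[3],
       n_estimated = length(estK), n_true = length(truK),
       random_f1 = randomF1)
}
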