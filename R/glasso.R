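#' Build the regularization path for the graphical lasso
#'
#' Computes the empirical Pearson correlation matrix S of the
#' (nonparanormal-transformed) data and a log-spaced, strictly decreasing
#' path of \code{n_lambda} penalty values from \eqn{\lambda_{max} = \max_{i
#' \ne j} |S_{ij}|} (at which the solved graph has no edges) down to
#' \code{ratio * lambda_max}.
#'
#' @param X samples x features matrix
#' @param n_lambda path length (default 30)
#' @param ratio lower bound as a fraction of lambda_max, in (0, 1)
#'   (default 0.1)
#' @return list with \code{S} (correlation matrix) and \code{lambdas}
#' @export
buildLambdaPath <- function(X, n_lambda = 30L, ratio = 0.1) {
  X <- as.matrix(X)
  if (nrow(X) < 4) stop("need n >= 4 samples")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("constant feature(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio <= 0 || ratio >= 1)
    stop("'ratio' must lie strictly inside (0, 1)")
  if (n_lambda < 2) stop("'n_lambda' must be >= 2")
  S <- cor(X)
  lmax <- max(abs(S[upper.tri(S)]))
  if (lmax == 0) lmax <- 1e-8
  lambdas <- exp(seq(log(lmax), log(ratio * lmax), length.out = n_lambda))
  list(S = S, lambdas = lambdas)
}

## edge list + partial correlations from a precision matrix
.edgesFromTheta <- function(theta, kinds) {
  p <- nrow(theta)
  nm <- colnames(theta) %||% paste0("f", seq_len(p))
  ut <- which(upper.tri(theta) & theta != 0, arr.ind = TRUE)
  if (!nrow(ut))
    return(data.frame(feature_a = character(0), feature_b = character(0),
                      theta = numeric(0), partial_cor = numeric(0),
                      kind_pair = character(0), stringsAsFactors = FALSE))
  pc <- -theta[ut] / sqrt(diag(theta)[ut[, 1]] * diag(theta)[ut[, 2]])
  kp <- if (length(kinds))
    paste(pmin(kinds[ut[, 1]], kinds[ut[, 2]]),
          pmax(kinds[ut[, 1]], kinds[ut[, 2]]), sep = "-")
  else rep("asv-asv", nrow(ut))
  data.frame(feature_a = nm[ut[, 1]], feature_b = nm[ut[, 2]],
             theta = theta[ut], partial_cor = pc, kind_pair = kp,
             stringsAsFactors = FALSE)
}

#' Solve the graphical lasso at a single penalty
#'
#' Maximizes \eqn{\log\det\Theta - tr(S\Theta) - \lambda \sum_{i \ne j}
#' |\Theta_{ij}|} (diagonal unpenalized) by block coordinate descent over
#' lasso subproblems (compiled). At \eqn{\lambda = 0} the unpenalized
#' maximum-likelihood estimate \eqn{S^{-1}} is returned directly via
#' Cholesky inversion. Off-diagonal zeros of the estimate are exact, so
#' the edge list is the non-zero support without thresholding.
#'
#' @param S symmetric correlation (or covariance) matrix
#' @param lambda penalty, >= 0
#' @param kinds optional named character vector ("asv"/"env") per feature
#' @param tol relative convergence tolerance on the working covariance
#'   (default 1e-9; KKT residuals track this)
#' @param max_iter maximum outer sweeps (default 1000); exceeding it is
#'   an error carrying the last gap
#' @param warm optional warm start: a previous fit's \code{list(W, B)}
#' @return a \linkS4class{PrecisionGraph}
#' @export
glassoSolve <- function(S, lambda, kinds = character(0), tol = 1e-9,
                        max_iter = 1000L, warm = NULL) {
  S <- as.matrix(S)
  p <- nrow(S)
  if (p != ncol(S) || max(abs(S - t(S))) > 1e-8)
    stop("S must be square and symmetric")
  if (lambda < 0) stop("'lambda' must be >= 0")
  if (is.null(colnames(S))) dimnames(S) <- list(paste0("f", seq_len(p)),
                                                paste0("f", seq_len(p)))
  if (lambda == 0) {
    theta <- chol2inv(chol(S))
    dimnames(theta) <- dimnames(S)
    fit <- list(Theta = theta, W = S, B = NULL, converged = TRUE)
  } else {
    fit <- .glassoCpp(S, lambda, tol, as.integer(max_iter),
                      warm$W, warm$B)
    if (!fit$converged)
      stop(sprintf(
        "glasso did not converge in %d sweeps (last gap %.3e > tol)",
        max_iter, fit$gap))
    dimnames(fit$Theta) <- dimnames(S)
  }
  theta <- (fit$Theta + t(fit$Theta)) / 2
  theta[fit$Theta == 0] <- 0 # keep support exact through symmetrization
  methods::new("PrecisionGraph", theta = theta, lambda = lambda,
               edges = .edgesFromTheta(theta, kinds), kinds = kinds,
               converged = TRUE)
}

#' Penalized negative log-likelihood objective of a glasso solution
#'
#' \eqn{-\log\det\Theta + tr(S\Theta) + \lambda\sum_{i\ne j}|\Theta_{ij}|}
#' (the minimized form; smaller is better).
#'
#' @param theta precision matrix (or a \linkS4class{PrecisionGraph})
#' @param S the input correlation matrix
#' @param lambda the penalty
#' @return numeric scalar
#' @export
glassoObjective <- function(theta, S, lambda) {
  if (is(theta, "PrecisionGraph")) theta <- precisionMatrix(theta)
  -determinant(theta, logarithm = TRUE)$modulus[1] + sum(S * theta) +
    lambda * sum(abs(theta[upper.tri(theta)])) * 2
}

#' Karush-Kuhn-Tucker residual of a glasso solution
#'
#' With \eqn{W = \Theta^{-1}}: off-diagonal entries must satisfy
#' \eqn{S_{ij} - W_{ij} = -\lambda\,sign(\Theta_{ij})} where
#' \eqn{\Theta_{ij} \ne 0} and \eqn{|S_{ij} - W_{ij}| \le \lambda} where
#' \eqn{\Theta_{ij} = 0}; the diagonal must satisfy \eqn{W_{jj} = S_{jj}}
#' (unpenalized). Returns the largest violation.
#'
#' @inheritParams glassoObjective
#' @return numeric scalar (max violation; ~0 at an exact solution)
#' @export
kktResidual <- function(theta, S, lambda) {
  if (is(theta, "PrecisionGraph")) theta <- precisionMatrix(theta)
  W <- solve(theta)
  G <- S - W
  off <- upper.tri(theta)
  nz <- off & theta != 0
  z <- off & theta == 0
  resid <- abs(diag(G))
  if (any(nz)) resid <- c(resid, abs(G[nz] + lambda * sign(theta[nz])))
  if (any(z)) resid <- c(resid, pmax(0, abs(G[z]) - lambda))
  max(resid)
}

#' StARS stability selection along the regularization path
#'
#' Draws \code{rep} subsamples of size \code{b} without replacement,
#' solves the whole path on each (warm-started), and records per-edge
#' selection frequencies. The graph instability at each lambda is the
#' mean over feature pairs of \eqn{2\hat\theta(1-\hat\theta)}; it is
#' monotonized to be non-decreasing toward small lambda, and the selected
#' penalty is the smallest lambda whose monotonized instability is still
#' at most \code{beta} — the densest graph whose edge set is reproducible
#' across subsamples. The final model is refit on the full data at that
#' penalty. If even the sparsest end of the path is unstable, the
#' lambda_max (empty-graph) fit is returned with a warning.
#'
#' @param X samples x features matrix (nonparanormal-transformed)
#' @param n_lambda,ratio path construction, see
#'   \code{\link{buildLambdaPath}}
#' @param rep number of subsamples (default 50)
#' @param beta instability threshold (default 0.05)
#' @param b subsample size; default \code{floor(10 * sqrt(n))} for n >
#'   144, else \code{floor(0.8 * n)}
#' @param seed integer seed (subsampling is bit-reproducible under it)
#' @param kinds optional feature kind labels ("asv"/"env")
#' @param tol,max_iter solver controls passed to
#'   \code{\link{glassoSolve}}
#' @return list with \code{network} (the refit
#'   \linkS4class{PrecisionGraph}) and \code{stability} (a
#'   \linkS4class{StabilityPath})
#' @export
starsSelect <- function(X, n_lambda = 30L, ratio = 0.1, rep = 50L,
                        beta = 0.05, b = NULL, seed = 1L,
                        kinds = character(0), tol = 1e-7,
                        max_iter = 1000L) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (rep < 2) stop("'rep' must be >= 2")
  if (is.null(b))
    b <- if (n > 144) floor(10 * sqrt(n)) else floor(0.8 * n)
  b <- as.integer(b)
  if (b >= n || b < 4) stop("subsample size b must satisfy 4 <= b < n")
  path <- buildLambdaPath(X, n_lambda = n_lambda, ratio = ratio)
  lambdas <- path$lambdas
  L <- length(lambdas)
  nPairs <- p * (p - 1) / 2
  counts <- matrix(0, nPairs, L)

  set.seed(seed)
  for (r in seq_len(rep)) {
    idx <- sample(n, b)
    Ssub <- cor(X[idx, , drop = FALSE])
    warm <- NULL
    for (l in seq_len(L)) {
      fitRaw <- .glassoCpp(Ssub, lambdas[l], tol, as.integer(max_iter),
                           warm$W, warm$B)
      if (!fitRaw$converged)
        stop("glasso did not converge during StARS subsampling")
      warm <- fitRaw
      th <- fitRaw$Theta
      counts[, l] <- counts[, l] + (th[upper.tri(th)] != 0)
    }
  }
  freq <- counts / rep
  instab <- colMeans(2 * freq * (1 - freq))
  mono <- cummax(instab)
  okay <- which(mono <= beta)
  if (length(okay)) {
    optIdx <- max(okay) # smallest stable lambda = densest stable graph
  } else {
    warning("no lambda met the instability threshold; ",
            "returning the maximally sparse (lambda_max) graph")
    optIdx <- 1L
  }
  stab <- methods::new("StabilityPath", lambdas = lambdas,
                       frequency = freq, instability = instab,
                       monotone = mono, rep = as.integer(rep), b = b,
                       beta = beta, optIndex = as.integer(optIdx),
                       seed = as.integer(seed))
  net <- glassoSolve(path$S, lambdas[optIdx], kinds = kinds, tol = tol,
                     max_iter = max_iter)
  list(network = net, stability = stab)
}

#' Merge two networks: associations detected in both
#'
#' Returns the unordered feature pairs present as edges in both graphs
#' (e.g. the surface and DCM networks), with the partial correlation each
#' graph assigned.
#'
#' @param netA,netB \linkS4class{PrecisionGraph} objects with comparable
#'   feature id spaces
#' @return data.frame: \code{feature_a}, \code{feature_b},
#'   \code{partial_cor_a}, \code{partial_cor_b}, \code{kind_pair}
#' @export
mergeNetworks <- function(netA, netB) {
  ea <- edges(netA)
  eb <- edges(netB)
  keyA <- paste(pmin(ea$feature_a, ea$feature_b),
                pmax(ea$feature_a, ea$feature_b), sep = "\r")
  keyB <- paste(pmin(eb$feature_a, eb$feature_b),
                pmax(eb$feature_a, eb$feature_b), sep = "\r")
  shared <- intersect(keyA, keyB)
  ia <- match(shared, keyA)
  ib <- match(shared, keyB)
  data.frame(feature_a = ea$feature_a[ia], feature_b = ea$feature_b[ia],
             partial_cor_a = ea$partial_cor[ia],
             partial_cor_b = eb$partial_cor[ib],
             kind_pair = ea$kind_pair[ia], stringsAsFactors = FALSE)
}

#' Count edges by feature-kind pair
#'
#' Networks built over ASVs plus environmental variables are reported
#' separately as ASV-ASV and ASV-environment associations.
#'
#' @param net a \linkS4class{PrecisionGraph}
#' @return named integer vector over the kind pairs present
#' @export
edgePartition <- function(net) {
  e <- edges(net)
  if (!nrow(e)) return(setNames(integer(0), character(0)))
  tt <- table(e$kind_pair)
  setNames(as.integer(tt), names(tt))
}

#' Export a network as GraphML
#'
#' @param net a \linkS4class{PrecisionGraph}
#' @param file output path
#' @return invisibly, the igraph object written
#' @export
writeGraphML <- function(net, file) {
  e <- edges(net)
  g <- igraph::graph_from_data_frame(
    e[, c("feature_a", "feature_b", "partial_cor", "kind_pair")],
    directed = FALSE,
    vertices = data.frame(name = colnames(precisionMatrix(net)),
                          kind = if (length(featureKinds(net)))
                            featureKinds(net) else "asv"))
  igraph::write_graph(g, file, format = "graphml")
  invisible(g)
}
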