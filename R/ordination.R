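#' Redundancy analysis (RDA) of community data on environmental constraints
#'
#' Column-centers the (CLR-transformed) community matrix Y, projects it
#' onto the column space of the centered constraint matrix X, and
#' eigen-decomposes the fitted part via SVD. The constrained proportion
#' of variance is \eqn{R^2 = tr(\hat Y' \hat Y)/tr(Y'Y)}; the adjusted
#' value is \eqn{R^2_{adj} = 1 - (1 - R^2)(n - 1)/(n - m - 1)} with m
#' constraints.
#'
#' @param Y samples x features response matrix (CLR abundances)
#' @param X samples x m standardized constraint matrix, full column rank
#' @return list of class \code{"rda_model"}: \code{eig_constrained},
#'   \code{eig_unconstrained}, \code{site_scores}, \code{r_squared},
#'   \code{adj_r_squared}, \code{total_variance}, \code{variables},
#'   \code{n}, \code{m}
#' @export
rdaFit <- function(Y, X) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  n <- nrow(Y)
  if (nrow(X) != n) stop("Y and X must have the same number of samples")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qx <- qr(Xc)
  if (qx$rank < ncol(Xc))
    stop("constraint matrix is rank-deficient; remove collinear variables")
  Yhat <- qr.fitted(qx, Yc)
  Yres <- Yc - Yhat
  totSS <- sum(Yc^2)
  fitSS <- sum(Yhat^2)
  r2 <- fitSS / totSS
  m <- ncol(X)
  adj <- 1 - (1 - r2) * (n - 1) / (n - m - 1)
  svf <- svd(Yhat)
  nAxes <- min(qx$rank, sum(svf$d > max(svf$d) * 1e-10))
  eigC <- (svf$d^2 / (n - 1))[seq_len(nAxes)]
  scores <- svf$u[, seq_len(nAxes), drop = FALSE] %*%
    diag(svf$d[seq_len(nAxes)], nAxes)
  rownames(scores) <- rownames(Y)
  colnames(scores) <- paste0("RDA", seq_len(nAxes))
  svr <- svd(Yres, nu = 0, nv = 0)
  eigU <- (svr$d^2 / (n - 1))
  eigU <- eigU[eigU > max(svr$d^2 / (n - 1), 0) * 1e-12]
  structure(list(eig_constrained = eigC, eig_unconstrained = eigU,
                 site_scores = scores, r_squared = r2,
                 adj_r_squared = adj, total_variance = totSS / (n - 1),
                 variables = colnames(X), n = n, m = m),
            class = "rda_model")
}

#' @export
print.rda_model <- function(x, ...) {
  cat("RDA:", x$m, "constraints on", x$n, "samples\n")
  cat("  R2 =", signif(x$r_squared, 4), "; adjusted R2 =",
      signif(x$adj_r_squared, 4), "\n")
  cat("  constrained axes:", length(x$eig_constrained), "\n")
  invisible(x)
}

## pseudo-F for adding 'add' to the model 'sel' (possibly empty)
.partialF <- function(Yc, Xc, sel, add) {
  if (length(sel)) {
    qr_red <- qr(Xc[, sel, drop = FALSE])
    Yhat_red <- qr.fitted(qr_red, Yc)
  } else Yhat_red <- matrix(0, nrow(Yc), ncol(Yc))
  rssR <- sum((Yc - Yhat_red)^2)
  qr_full <- qr(Xc[, c(sel, add), drop = FALSE])
  rssF <- sum((Yc - qr.fitted(qr_full, Yc))^2)
  n <- nrow(Yc)
  mf <- length(sel) + 1L
  list(F = ((rssR - rssF) / 1) / (rssF / (n - mf - 1)),
       Yhat_red = Yhat_red, resid_red = Yc - Yhat_red)
}

#' Forward selection of RDA constraints with the double-stopping rule
#'
#' Iteratively adds the candidate variable that maximizes the adjusted
#' R-squared of the partial model. Each added term is tested by residual
#' permutation (residuals of the reduced model are permuted, \code{n_perm}
#' shuffles, add-one p-value); the Bonferroni correction factor is the
#' number of candidates still in play at that step. Selection stops when
#' (a) the Bonferroni-adjusted p-value of the best candidate is not below
#' \code{alpha}, or (b) the cumulative adjusted R-squared would exceed
#' that of the global model containing all candidates — the guard that
#' keeps forward selection from overfitting past the global fit.
#'
#' @param Y samples x features response matrix (CLR abundances)
#' @param X samples x candidates standardized matrix of candidate
#'   constraints
#' @param alpha significance level for the adjusted p-value (default
#'   0.05)
#' @param n_perm permutations per step (default 999)
#' @param seed integer seed
#' @return list of class \code{"rda_forward"}: \code{model} (final
#'   \code{rda_model}, or NULL if nothing was selected), \code{selected},
#'   \code{trace} (one row per tested step), \code{global_adj_r2}
#' @export
forwardSelect <- function(Y, X, alpha = 0.05, n_perm = 999L, seed = 1L) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) < 1) stop("need at least one candidate variable")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  globalAdj <- rdaFit(Y, X)$adj_r_squared
  n <- nrow(Yc)

  selected <- character(0)
  remaining <- colnames(X)
  trace <- list()
  set.seed(seed)
  step <- 0L
  repeat {
    if (!length(remaining)) break
    step <- step + 1L
    adjs <- vapply(remaining, function(v)
      rdaFit(Y, X[, c(selected, v), drop = FALSE])$adj_r_squared, 0)
    best <- remaining[which.max(adjs)]
    bestAdj <- max(adjs)

    pf <- .partialF(Yc, Xc, selected, best)
    Fobs <- pf$F
    exc <- 0L
    for (b in seq_len(n_perm)) {
      Yperm <- pf$Yhat_red + pf$resid_red[sample(n), , drop = FALSE]
      if (.partialF(Yperm, Xc, selected, best)$F >= Fobs - 1e-12)
        exc <- exc + 1L
    }
    p <- (1 + exc) / (1 + n_perm)
    pAdj <- min(1, p * length(remaining))
    trace[[step]] <- data.frame(step = step, variable = best,
                                adj_r2 = bestAdj, p = p, p_adj = pAdj,
                                n_candidates = length(remaining),
                                selected = FALSE)
    if (pAdj >= alpha) break
    if (bestAdj > globalAdj) break # global adjusted-R2 guard
    selected <- c(selected, best)
    trace[[step]]$selected <- TRUE
    remaining <- setdiff(remaining, best)
  }
  model <- if (length(selected))
    rdaFit(Y, X[, selected, drop = FALSE]) else NULL
  structure(list(model = model, selected = selected,
                 trace = do.call(rbind, trace),
                 global_adj_r2 = globalAdj,
                 empty = !length(selected)),
            class = "rda_forward")
}

#' @export
print.rda_forward <- function(x, ...) {
  if (x$empty) cat("Forward selection: no variable passed (empty model)\n")
  else {
    cat("Forward selection:", length(x$selected), "variables:",
        paste(x$selected, collapse = ", "), "\n")
    cat("  adjusted R2 =", signif(x$model$adj_r_squared, 4),
        "(global:", signif(x$global_adj_r2, 4), ")\n")
  }
  invisible(x)
}
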