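#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{BC(i,k) = \sum_j |x_{ij} - x_{kj}| / \sum_j (x_{ij} + x_{kj})},
#' computed on relative (or raw) abundances with samples in rows.
#' Similarity is \code{1 - BC}.
#'
#' @param abundance samples x ASVs non-negative matrix, or an
#'   \linkS4class{AsvExperiment}
#' @return a \code{dist} object (method \code{"bray"}) with sample labels
#' @examples
#' brayCurtis(rbind(a = c(1, 2, 3), b = c(3, 2, 1))) # 4/12
#' @export
brayCurtis <- function(abundance) {
  m <- if (is(abundance, "AsvExperiment")) t(asvCounts(abundance))
       else as.matrix(abundance)
  if (any(m < 0)) stop("abundances must be non-negative")
  zero <- rowSums(m) == 0
  if (sum(zero) >= 2)
    stop("Bray-Curtis undefined between all-zero samples: ",
         paste(rownames(m)[zero], collapse = ", "))
  vegan::vegdist(m, method = "bray")
}

#' Similarity view of a distance matrix
#'
#' @param d a \code{dist} or square dissimilarity matrix with entries in
#'   [0, 1]
#' @return square matrix of \code{1 - d}
#' @export
asSimilarity <- function(d) 1 - as.matrix(d)

#' Month-lag similarity profile
#'
#' For every unordered sample pair the lag in months is
#' \code{|days apart| / 30.4} (the average month length); pairs are
#' binned to the nearest integer month (half-lags round up) and the mean
#' and standard error of the Bray-Curtis \emph{similarity} (1 -
#' dissimilarity) are computed per bin. Pairs collected 0 days apart are
#' excluded.
#'
#' @param d \code{dist} (or square matrix) of dissimilarities between
#'   samples
#' @param dates per-sample \code{Date} vector aligned with \code{d}
#' @return data.frame with columns \code{lag_months}, \code{mean_sim},
#'   \code{se}, \code{n_pairs}; attribute \code{n_pairs_total} carries the
#'   total (pre-exclusion) pair count
#' @export
lagProfile <- function(d, dates) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  dates <- as.Date(dates)
  if (length(dates) != n) stop("need one date per sample")
  ut <- which(upper.tri(dm), arr.ind = TRUE)
  dayLag <- abs(as.numeric(dates[ut[, 1]] - dates[ut[, 2]]))
  sim <- 1 - dm[ut]
  keep <- dayLag > 0
  bins <- roundHalfUp(dayLag[keep] / MONTH_DAYS)
  sims <- sim[keep]
  agg <- tapply(sims, bins, function(v)
    c(mean = mean(v), se = sd(v) / sqrt(length(v)), n = length(v)))
  lag <- as.integer(names(agg))
  out <- data.frame(lag_months = lag,
                    mean_sim = vapply(agg, `[`, 0, "mean"),
                    se = vapply(agg, `[`, 0, "se"),
                    n_pairs = as.integer(vapply(agg, `[`, 0, "n")),
                    row.names = NULL)
  out <- out[order(out$lag_months), ]
  attr(out, "n_pairs_total") <- n * (n - 1) / 2
  out
}

## Spearman correlation of the upper triangles of two square matrices
.mantelStat <- function(m1, m2) {
  ut <- upper.tri(m1)
  cor(m1[ut], m2[ut], method = "spearman")
}

#' Mantel test between two distance matrices
#'
#' Statistic: Spearman rank correlation of the vectorized upper
#' triangles. Significance by joint row/column permutation of the second
#' matrix; the p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{r^* \ge r\}) / (1 + n_{perm})} (one-sided, positive
#' association; \code{alternative = "two.sided"} doubles the smaller
#' tail). With \code{exhaustive = TRUE} all \eqn{n!} permutations are
#' enumerated and \eqn{p = \#\{r^* \ge r\}/n!} (identity included).
#'
#' @param d1,d2 \code{dist} objects or square symmetric matrices over the
#'   same samples in the same order
#' @param n_perm number of permutations (ignored when exhaustive)
#' @param seed integer seed
#' @param alternative \code{"greater"} (default) or \code{"two.sided"}
#' @param exhaustive enumerate all permutations (only sensible for n <= 8)
#' @return list of class \code{"mantel_result"}: \code{statistic},
#'   \code{p_value}, \code{n_perm}, \code{seed}, \code{alternative}
#' @export
mantelTest <- function(d1, d2, n_perm = 999L, seed = 1L,
                       alternative = c("greater", "two.sided"),
                       exhaustive = FALSE) {
  alternative <- match.arg(alternative)
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2))) stop("distance matrices must be conformable")
  n <- nrow(m1)
  ut <- upper.tri(m1)
  if (sd(m1[ut]) == 0 || sd(m2[ut]) == 0)
    stop("constant distance matrix: Mantel statistic undefined")
  r <- .mantelStat(m1, m2)
  if (exhaustive) {
    perms <- .allPermutations(n)
    rs <- vapply(perms, function(p) .mantelStat(m1, m2[p, p]), 0)
    pGreater <- mean(rs >= r - 1e-12)
    pLess <- mean(rs <= r + 1e-12)
    np <- length(perms)
  } else {
    if (n_perm < 1) stop("'n_perm' must be >= 1")
    set.seed(seed)
    rs <- vapply(seq_len(n_perm), function(i) {
      p <- sample(n)
      .mantelStat(m1, m2[p, p])
    }, 0)
    pGreater <- (1 + sum(rs >= r - 1e-12)) / (1 + n_perm)
    pLess <- (1 + sum(rs <= r + 1e-12)) / (1 + n_perm)
    np <- n_perm
  }
  p <- if (alternative == "greater") pGreater else min(1, 2 * min(pGreater,
                                                                  pLess))
  structure(list(statistic = r, p_value = p, n_perm = np, seed = seed,
                 alternative = alternative, exhaustive = exhaustive),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat("Mantel test (Spearman): r =", signif(x$statistic, 4),
      ", p =", signif(x$p_value, 4),
      sprintf("(%s, %d permutations%s)\n", x$alternative, x$n_perm,
              if (x$exhaustive) ", exhaustive" else ""))
  invisible(x)
}

## all permutations of 1..n (n! of them) — used by the exhaustive modes
.allPermutations <- function(n) {
  if (n > 8) stop("exhaustive enumeration limited to n <= 8")
  rec <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(rec(v[-i]), function(p) c(v[i], p)))
    out
  }
  rec(seq_len(n))
}

#' Analysis of similarities (ANOSIM)
#'
#' \eqn{R = (\bar r_B - \bar r_W) / (M/2)} with \eqn{M = n(n-1)/2}, where
#' \eqn{\bar r_B} and \eqn{\bar r_W} are the mean ranks (average-tie
#' ranks over all pairwise dissimilarities) of between- and within-group
#' pairs. Significance by permutation of group labels with the add-one
#' estimator, or exhaustively.
#'
#' @param d \code{dist} or square dissimilarity matrix
#' @param groups group labels, one per sample; at least 2 groups with >= 2
#'   members
#' @param n_perm,seed,exhaustive as in \code{\link{mantelTest}}
#' @return list of class \code{"anosim_result"}: \code{statistic} (R),
#'   \code{p_value}, \code{n_perm}, \code{seed}
#' @export
anosimTest <- function(d, groups, n_perm = 999L, seed = 1L,
                       exhaustive = FALSE) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  groups <- as.character(groups)
  if (length(groups) != n) stop("need one group label per sample")
  tab <- table(groups)
  if (length(tab) < 2) stop("ANOSIM needs at least 2 groups")
  if (any(tab < 2)) stop("every group needs at least 2 members")
  ut <- which(upper.tri(dm), arr.ind = TRUE)
  rk <- rank(dm[upper.tri(dm)]) # average ranks for ties
  M <- n * (n - 1) / 2
  statFor <- function(g) {
    within <- g[ut[, 1]] == g[ut[, 2]]
    (mean(rk[!within]) - mean(rk[within])) / (M / 2)
  }
  R <- statFor(groups)
  if (exhaustive) {
    perms <- .allPermutations(n)
    rs <- vapply(perms, function(p) statFor(groups[p]), 0)
    p <- mean(rs >= R - 1e-12)
    np <- length(perms)
  } else {
    set.seed(seed)
    rs <- vapply(seq_len(n_perm), function(i) statFor(sample(groups)), 0)
    p <- (1 + sum(rs >= R - 1e-12)) / (1 + n_perm)
    np <- n_perm
  }
  structure(list(statistic = R, p_value = p, n_perm = np, seed = seed,
                 exhaustive = exhaustive),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat("ANOSIM: R =", signif(x$statistic, 4), ", p =",
      signif(x$p_value, 4), sprintf("(%d permutations%s)\n", x$n_perm,
      if (x$exhaustive) ", exhaustive" else ""))
  invisible(x)
}

#' Regression of community similarity on environmental PC1 distance
#'
#' PCA (correlation-matrix, i.e. on standardized variables) of the
#' environmental table; the absolute difference in PC1 scores between
#' every sample pair is regressed against the Bray-Curtis similarity of
#' that pair by ordinary least squares. A negative slope means
#' communities are less similar when the environment differs more. The
#' sign of PC1 is fixed by making its largest-magnitude loading positive
#' (pair distances are sign-invariant).
#'
#' @param env standardized samples x variables matrix (no missing values;
#'   see \code{\link{prepareEnv}})
#' @param sim square similarity matrix (e.g.
#'   \code{\link{asSimilarity}} of \code{\link{brayCurtis}}), samples
#'   aligned with \code{env}
#' @return list: \code{slope}, \code{intercept}, \code{p_value} (slope
#'   t-test), \code{r_squared}, \code{pc1_var_explained}, \code{n_pairs}
#' @export
pc1DistanceRegression <- function(env, sim) {
  env <- as.matrix(env)
  if (ncol(env) < 2) stop("PCA needs at least 2 environmental variables")
  if (anyNA(env)) stop("env contains missing values; impute first")
  sim <- as.matrix(sim)
  if (nrow(sim) != nrow(env)) stop("'sim' and 'env' sample counts differ")
  pca <- prcomp(env, center = TRUE, scale. = FALSE)
  pc1 <- pca$x[, 1]
  if (pca$rotation[which.max(abs(pca$rotation[, 1])), 1] < 0) pc1 <- -pc1
  ut <- upper.tri(sim)
  pairIdx <- which(ut, arr.ind = TRUE)
  dPc1 <- abs(pc1[pairIdx[, 1]] - pc1[pairIdx[, 2]])
  y <- sim[ut]
  fit <- lm(y ~ dPc1)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       p_value = sm$coefficients[2, 4], r_squared = sm$r.squared,
       pc1_var_explained = unname(pca$sdev[1]^2 / sum(pca$sdev^2)),
       n_pairs = length(y))
}
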