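#' Remove seasonal and long-term temporal signal by GAM residualization
#'
#' Fits, per feature, a Gaussian additive model with (i) a cyclic cubic
#' spline of the annual phase (day within the 365.25-day year) and (ii) a
#' thin-plate smooth of elapsed time (long-term trend), and returns the
#' residuals. Co-occurrence estimated on these residuals reflects more
#' than shared seasonality or drift. Smoothing parameters are selected by
#' restricted maximum likelihood with shrinkage (\code{select = TRUE}), so
#' features without temporal signal are left essentially untouched.
#' A feature whose fit fails falls back to linear harmonic regression
#' (annual sine/cosine pair + linear trend) with a warning.
#'
#' @param X samples x features matrix (CLR abundances and/or standardized
#'   environmental variables), rows aligned with \code{dates}
#' @param dates per-sample \code{Date} vector
#' @param k_season basis dimension of the cyclic seasonal smooth (default
#'   6)
#' @param k_trend basis dimension of the long-term trend smooth (default
#'   5)
#' @param force skip the pipeline-stage check (e.g. to detrend residuals
#'   a second time when probing for leftover temporal signal)
#' @return samples x features matrix of residuals, tagged as stage
#'   \code{"detrended"}, with attributes \code{edf} (effective degrees of
#'   freedom), \code{deviance_explained} and \code{fallback} (logical per
#'   feature)
#' @export
gamDetrend <- function(X, dates, k_season = 6, k_trend = 5,
                       force = FALSE) {
  X <- as.matrix(X)
  st <- stageOf(X)
  if (!force && !is.null(st) && st %in% c("detrended", "npn"))
    stop("input is already stage '", st,
         "'; the pipeline order is clr -> detrend -> npn")
  dates <- as.Date(dates)
  n <- nrow(X)
  if (length(dates) != n) stop("need one date per row of X")
  spanDays <- as.numeric(max(dates) - min(dates))
  if (n < 12 || spanDays <= 365.25)
    stop("need >= 12 samples spanning more than one year ",
         "for the cyclic seasonal term to be identifiable")
  elapsed <- as.numeric(dates - min(dates))
  doy <- elapsed %% 365.25
  tt <- elapsed / 365.25

  res <- X
  edf <- deva <- numeric(ncol(X))
  fallback <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    y <- X[, j]
    fit <- tryCatch(
      mgcv::gam(y ~ s(doy, bs = "cc", k = k_season) +
                  s(tt, bs = "tp", k = k_trend),
                knots = list(doy = c(0, 365.25)),
                method = "REML", select = TRUE),
      error = function(e) NULL)
    if (is.null(fit)) {
      fallback[j] <- TRUE
      warning("GAM fit failed for feature ",
              colnames(X)[j] %||% j,
              "; falling back to harmonic regression")
      hfit <- lm(y ~ sin(2 * pi * doy / 365.25) +
                   cos(2 * pi * doy / 365.25) + tt)
      res[, j] <- residuals(hfit)
      edf[j] <- length(na.omit(coef(hfit)))
      deva[j] <- summary(hfit)$r.squared
    } else {
      res[, j] <- residuals(fit)
      edf[j] <- sum(fit$edf)
      deva[j] <- summary(fit)$dev.expl
    }
  }
  attr(res, "edf") <- edf
  attr(res, "deviance_explained") <- deva
  attr(res, "fallback") <- fallback
  setStage(res, "detrended")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Nonparanormal (Gaussian copula) transform
#'
#' Per feature: average-tie ranks are mapped through the Winsorized
#' empirical CDF, truncated at
#' \eqn{\delta = 1/(4 n^{1/4} \sqrt{\pi \ln n})}, through the standard
#' normal quantile function, and rescaled to unit variance. Because only
#' ranks enter, the transform is exactly invariant under monotone
#' marginal transformations, and the output margins are as close to
#' Gaussian as ranks allow — the assumption the graphical lasso needs.
#'
#' @param X samples x features matrix of GAM residuals (stage
#'   \code{"detrended"}); set \code{force = TRUE} to transform matrices
#'   from other stages
#' @param force skip the pipeline-stage check
#' @return samples x features matrix, tagged as stage \code{"npn"}
#' @export
nonparanormal <- function(X, force = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("nonparanormal transform needs n >= 4")
  st <- stageOf(X)
  if (!force && !is.null(st) && st != "detrended")
    stop("input is stage '", st, "', expected 'detrended' ",
         "(pipeline order clr -> detrend -> npn); use force = TRUE ",
         "to override")
  if (!force && is.null(st))
    stop("untagged input; run gamDetrend() first or use force = TRUE")
  delta <- 1 / (4 * n^0.25 * sqrt(pi * log(n)))
  out <- apply(X, 2, function(x) {
    if (sd(x) == 0) return(rep(NA_real_, n))
    u <- rank(x, ties.method = "average") / n
    qnorm(pmin(pmax(u, delta), 1 - delta))
  })
  const <- apply(X, 2, sd) == 0
  if (any(const))
    stop("constant feature(s), rank-degenerate: ",
         paste(colnames(X)[const], collapse = ", "))
  out <- scale(out, center = FALSE,
               scale = apply(out, 2, sd))[, , drop = FALSE]
  dimnames(out) <- dimnames(X)
  setStage(out, "npn")
}
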