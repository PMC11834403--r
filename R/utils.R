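#' Round half away from zero
#'
#' Lag bins are symmetric around integer month lags, so 11.5 months belongs
#' to bin 12. Base \code{round()} rounds half to even, which would split
#' borderline pairs inconsistently between bins.
#'
#' @param x numeric vector
#' @return integer vector
#' @keywords internal
#' @noRd
roundHalfUp <- function(x) as.integer(floor(x + 0.5))

#' Derive a child seed from a master seed
#'
#' All stochastic sub-generators draw their own seed deterministically from
#' the master seed plus a purpose tag, so whole artifact sets are
#' bit-reproducible and individual draws can be replayed in isolation.
#'
#' @param seed master integer seed
#' @param tag short character tag naming the consumer
#' @return integer seed in [0, 2^31 - 1)
#' @keywords internal
childSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(as.numeric(seed)) * 2654435.0 + h * 97.0) %% 2147483647)
}

## stage tags keep the conditioning pipeline in its intended order
## (clr -> detrended -> npn); each stage checks and rewrites the tag.
stageOf <- function(x) attr(x, "protnet_stage", exact = TRUE)

setStage <- function(x, stage) {
  attr(x, "protnet_stage") <- stage
  x
}

#' Normalize a taxon key for database matching
#'
#' Lower-cases, collapses whitespace/underscores, and (for genus keys)
#' drops species/strain suffixes so that e.g. "Teleaulax_amphioxeia" and
#' "Teleaulax" compare equal at the genus level.
#'
#' @param key character vector
#' @param genus logical (recycled): keep only the leading token
#' @return normalized character vector (NA preserved)
#' @keywords internal
normalizeKey <- function(key, genus = FALSE) {
  out <- tolower(trimws(gsub("[_[:space:]]+", " ", as.character(key))))
  out[!nzchar(out)] <- NA_character_
  g <- which(rep_len(genus, length(out)))
  if (length(g)) {
    out[g] <- sub("^cf\\.? ", "", out[g])
    out[g] <- sub(" .*$", "", out[g])
  }
  out
}

## average month length (days) used to convert day lags to month lags
MONTH_DAYS <- 30.4

isWholeNumber <- function(x, tol = 1e-8) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && abs(x - round(x)) < tol
}

stopifnotScalarProp <- function(x, name, lo = 0, hi = 1,
                                 lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) stop(sprintf("'%s' must be a proportion in %s%g, %g%s", name,
                        if (lo_open) "(" else "[", lo, hi,
                        if (hi_open) ")" else "]"), call. = FALSE)
  invisible(TRUE)
}
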