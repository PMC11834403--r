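#' Configuration for the synthetic monthly ASV time series
#'
#' Defaults mirror the sampling design of a ~15-year monthly ocean
#' time-series: 177 calendar months with roughly 31% of months lost to
#' weather/equipment (leaving ~122 samples), multinomial read depth of
#' 50,000 per sample, half of the ASVs carrying an annual abundance cycle,
#' a weak long-term random-walk drift, and 20 planted pairwise
#' dependencies of partial correlation 0.6 among 30 ASVs together with a
#' toy interaction database covering all of them.
#'
#' @param n_asvs number of ASVs
#' @param n_months number of calendar months in the sampling grid
#' @param missing_month_fraction fraction of months dropped (in [0,1))
#' @param library_size multinomial read depth per sample
#' @param seasonal_fraction fraction of ASVs with an annual cycle
#' @param seasonal_amplitude amplitude of the annual cycle (log-abundance
#'   units)
#' @param drift_sd step SD of the per-ASV random-walk drift (log units per
#'   month)
#' @param n_planted_edges number of planted pairwise dependencies
#' @param partial_corr_strength |partial correlation| of planted edges,
#'   in (0,1)
#' @param db_coverage fraction of planted edges emitted into the toy
#'   interaction database
#' @param n_decoy_records decoy database records involving absent taxa
#' @param n_env_vars number of environmental/biological variables
#' @param n_driver_vars how many env variables are linear functions of ASV
#'   latent abundances
#' @param driver_noise_sd noise SD added to driver variables
#' @param env_missing_fraction fraction of missing env cells
#' @param copy_number_sd SD of an optional per-ASV multiplicative
#'   (log-normal) factor emulating rRNA copy-number variation; 0 disables
#' @param seed master seed; all sub-generators derive child seeds from it
#' @return a validated list of class \code{SyntheticConfig}
#' @export
syntheticConfig <- function(n_asvs = 30L, n_months = 177L,
                            missing_month_fraction = 0.31,
                            library_size = 50000L,
                            seasonal_fraction = 0.5,
                            seasonal_amplitude = 1,
                            drift_sd = 0.02,
                            n_planted_edges = 20L,
                            partial_corr_strength = 0.6,
                            db_coverage = 1,
                            n_decoy_records = 5L,
                            n_env_vars = 24L,
                            n_driver_vars = 2L,
                            driver_noise_sd = 0.2,
                            env_missing_fraction = 0.05,
                            copy_number_sd = 0,
                            seed = 1L) {
  cfg <- list(n_asvs = as.integer(n_asvs), n_months = as.integer(n_months),
              missing_month_fraction = missing_month_fraction,
              library_size = as.integer(library_size),
              seasonal_fraction = seasonal_fraction,
              seasonal_amplitude = seasonal_amplitude, drift_sd = drift_sd,
              n_planted_edges = as.integer(n_planted_edges),
              partial_corr_strength = partial_corr_strength,
              db_coverage = db_coverage,
              n_decoy_records = as.integer(n_decoy_records),
              n_env_vars = as.integer(n_env_vars),
              n_driver_vars = as.integer(n_driver_vars),
              driver_noise_sd = driver_noise_sd,
              env_missing_fraction = env_missing_fraction,
              copy_number_sd = copy_number_sd, seed = as.integer(seed))
  if (cfg$n_asvs < 2L) stop("'n_asvs' must be >= 2")
  if (cfg$n_months < 1L) stop("'n_months' must be >= 1")
  if (cfg$library_size < 1L) stop("'library_size' must be positive")
  stopifnotScalarProp(cfg$missing_month_fraction, "missing_month_fraction",
                      hi_open = TRUE)
  stopifnotScalarProp(cfg$seasonal_fraction, "seasonal_fraction")
  stopifnotScalarProp(cfg$db_coverage, "db_coverage")
  stopifnotScalarProp(cfg$env_missing_fraction, "env_missing_fraction",
                      hi_open = TRUE)
  if (cfg$seasonal_amplitude < 0) stop("'seasonal_amplitude' must be >= 0")
  if (cfg$drift_sd < 0) stop("'drift_sd' must be >= 0")
  if (cfg$n_planted_edges < 0) stop("'n_planted_edges' must be >= 0")
  maxEdges <- cfg$n_asvs * (cfg$n_asvs - 1L) / 2L
  if (cfg$n_planted_edges > maxEdges)
    stop("'n_planted_edges' exceeds n_asvs*(n_asvs-1)/2 = ", maxEdges)
  if (cfg$n_planted_edges > 0 &&
      (cfg$partial_corr_strength <= 0 || cfg$partial_corr_strength >= 1))
    stop("'partial_corr_strength' must lie in (0, 1)")
  class(cfg) <- "SyntheticConfig"
  cfg
}

## Gaussian residuals with covariance = inverse of 'precision';
## precision = U'U (Cholesky) so x = U^{-1} z has the right covariance.
.sampleResiduals <- function(precision, n, seed) {
  U <- chol(precision)
  set.seed(seed)
  z <- matrix(rnorm(n * nrow(precision)), nrow = n)
  t(backsolve(U, t(z)))
}

## Construct a positive-definite precision matrix with off-diagonal support
## exactly at the planted edges. If the first attempt is not PD the
## diagonal is inflated (shrinking realized partial correlations) until
## Cholesky succeeds.
.buildPrecision <- function(n_asvs, edgeIdx, strength, signs) {
  theta <- diag(n_asvs)
  if (nrow(edgeIdx)) {
    for (r in seq_len(nrow(edgeIdx))) {
      i <- edgeIdx[r, 1]; j <- edgeIdx[r, 2]
      theta[i, j] <- theta[j, i] <- -signs[r] * strength
    }
  }
  dfac <- 1
  for (tries in 1:40) {
    ok <- !inherits(try(chol(theta), silent = TRUE), "try-error")
    if (ok) break
    dfac <- dfac * 1.15
    diag(theta) <- dfac
    if (tries == 40)
      stop("constructed precision matrix is not positive definite; ",
           "reduce 'partial_corr_strength' or 'n_planted_edges'")
  }
  theta
}

.genusLineage <- function(genus, group = c("dino", "diatom", "ciliate",
                                           "crypto", "hapto", "chloro",
                                           "cerco")) {
  group <- match.arg(group)
  switch(group,
    dino = paste("Eukaryota;TSAR;Alveolata;Dinoflagellata;Dinophyceae;",
                 "Gymnodiniales;Gymnodiniaceae;", sep = ""),
    diatom = paste("Eukaryota;TSAR;Stramenopiles;Gyrista;Bacillariophyceae;",
                   "Bacillariales;Bacillariaceae;", sep = ""),
    ciliate = paste("Eukaryota;TSAR;Alveolata;Ciliophora;Spirotrichea;",
                    "Tintinnida;Tintinnidae;", sep = ""),
    crypto = paste("Eukaryota;Cryptista;Cryptophyta;Cryptophyceae;",
                   "Cryptomonadales;Pyrenomonadales;Geminigeraceae;",
                   sep = ""),
    hapto = paste("Eukaryota;Haptista;Haptophyta;Prymnesiophyceae;",
                  "Prymnesiales;Prymnesiales;Chrysochromulinaceae;",
                  sep = ""),
    chloro = paste("Eukaryota;Archaeplastida;Chlorophyta;Mamiellophyceae;",
                   "Mamiellales;Mamiellales;Mamiellaceae;", sep = ""),
    cerco = paste("Eukaryota;TSAR;Rhizaria;Cercozoa;Filosa-Thecofilosea;",
                  "Cryomonadida;Protaspidae;", sep = "")) |>
    paste0(genus)
}

.syndinialesLineage <- function(groupRoman) {
  sprintf(paste0("Eukaryota;TSAR;Alveolata;Dinoflagellata;Syndiniales;",
                 "Syndiniales Group %s;Dino-Group-%s;Dino-Group-%s_XX"),
          groupRoman, groupRoman, groupRoman)
}

.acanthareaLineage <- function()
  paste0("Eukaryota;TSAR;Rhizaria;Radiolaria;Acantharea;Chaunacanthida;",
         "Acantharea Clade F;Acantharea_X")

.polycystineLineage <- function()
  paste0("Eukaryota;TSAR;Rhizaria;Radiolaria;Polycystinea;Nassellaria;",
         "Nassellaria_X;Nassellaria_XX")

.mastLineage <- function(clade)
  sprintf(paste0("Eukaryota;TSAR;Stramenopiles;Bigyra;Sagenista;MAST-%s;",
                 "MAST-%s;MAST-%s_X"),
          sub("([0-9]+).*", "\\1", clade), clade, clade)

.placeholderLineage <- function()
  paste0("Eukaryota;TSAR;Alveolata;Dinoflagellata;Dinophyceae;",
         "Dinophyceae_X;Dinophyceae_XX;Dinophyceae_XXX")

GENUS_POOL <- data.frame(
  genus = c("Tripos", "Dinophysis", "Gymnodinium", "Heterocapsa",
            "Scrippsiella", "Pelagodinium", "Prorocentrum", "Alexandrium",
            "Chaetoceros", "Leptocylindrus", "Pseudo-nitzschia",
            "Thalassiosira", "Eutintinnus", "Strombidium", "Laboea",
            "Teleaulax", "Plagioselmis", "Phaeocystis", "Chrysochromulina",
            "Micromonas", "Ostreococcus", "Cryothecomonas", "Protaspis"),
  group = c(rep("dino", 8), rep("diatom", 4), rep("ciliate", 3),
            rep("crypto", 2), rep("hapto", 2), rep("chloro", 2),
            rep("cerco", 2)),
  stringsAsFactors = FALSE)

## Assign lineages so that every database matching rule is exercisable:
## parasitism edges get a Syndiniales endpoint + genus-resolved host,
## symbiosis edges alternate Acantharea/Polycystinea/MAST hosts with a
## genus-resolved symbiont, remaining edge endpoints and background ASVs
## get genus-resolved lineages (with a few unresolved placeholders).
.assignTaxonomy <- function(n_asvs, edgeIdx, types, seed) {
  set.seed(seed)
  lineage <- rep(NA_character_, n_asvs)
  genusCursor <- sample(nrow(GENUS_POOL)) # shuffled genus order
  gi <- 0L
  nextGenus <- function() {
    gi <<- gi + 1L
    row <- GENUS_POOL[genusCursor[(gi - 1L) %% nrow(GENUS_POOL) + 1L], ]
    .genusLineage(row$genus, row$group)
  }
  syndGroups <- c("I", "II", "III")
  mastClades <- c("3E", "3F", "3I", "3L")
  symCursor <- 0L
  if (nrow(edgeIdx)) {
    for (r in seq_len(nrow(edgeIdx))) {
      a <- edgeIdx[r, 1]; b <- edgeIdx[r, 2]
      if (types[r] == "parasitism" && is.na(lineage[a])) {
        lineage[a] <- .syndinialesLineage(
          syndGroups[(r - 1L) %% length(syndGroups) + 1L])
      } else if (types[r] == "symbiosis" && is.na(lineage[a])) {
        symCursor <- symCursor + 1L
        lineage[a] <- switch((symCursor - 1L) %% 3L + 1L,
                             .acanthareaLineage(), .polycystineLineage(),
                             .mastLineage(mastClades[(symCursor - 1L) %%
                                                      length(mastClades) + 1L]))
      }
      if (is.na(lineage[a])) lineage[a] <- nextGenus()
      if (is.na(lineage[b])) lineage[b] <- nextGenus()
    }
  }
  free <- which(is.na(lineage))
  nPlaceholder <- min(length(free), max(0L, round(0.1 * n_asvs)))
  if (nPlaceholder > 0) {
    ph <- free[seq_len(nPlaceholder)]
    lineage[ph] <- .placeholderLineage()
    free <- setdiff(free, ph)
  }
  for (i in free) lineage[i] <- nextGenus()
  lineage
}

#' Generate a synthetic ASV community with planted pairwise dependencies
#'
#' Latent log-abundance per ASV is baseline + annual sinusoid (period
#' 365.25 days, seasonal ASVs only) + random-walk drift + a multivariate
#' Gaussian residual whose covariance is the inverse of a constructed
#' sparse precision matrix (non-zero off-diagonals exactly at the planted
#' edges). Counts are multinomial draws of \code{library_size} reads over
#' the softmax of the latent log-abundances, inducing the compositional
#' coupling that CLR normalization is meant to address. A configurable
#' fraction of months is dropped to emulate missed cruises.
#'
#' @param config a \code{\link{syntheticConfig}}
#' @param depth depth label stamped on all samples (default
#'   \code{"surface"})
#' @return a list with elements \code{asv} (an
#'   \linkS4class{AsvExperiment}), \code{taxonomy} (named lineage vector)
#'   and \code{truth} (planted edges with realized partial correlations,
#'   the latent precision matrix, seasonal ASV ids, the retained latent
#'   matrix and the emitted sample dates)
#' @examples
#' sim <- generateCommunity(syntheticConfig(n_asvs = 10, n_months = 24,
#'                                          n_planted_edges = 3, seed = 42))
#' sim$asv
#' sim$truth$planted_edges
#' @export
generateCommunity <- function(config, depth = "surface") {
  stopifnot(inherits(config, "SyntheticConfig"))
  p <- config$n_asvs
  asvIds <- sprintf("asv_%03d", seq_len(p))

  ## structural draws: edges, signs, types, seasonal ids, phases, baselines
  set.seed(childSeed(config$seed, "structure"))
  allPairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
  eSel <- if (config$n_planted_edges > 0)
    sort(sample(nrow(allPairs), config$n_planted_edges)) else integer(0)
  edgeIdx <- allPairs[eSel, , drop = FALSE]
  signs <- if (length(eSel)) sample(c(-1, 1), length(eSel), replace = TRUE)
           else numeric(0)
  types <- if (length(eSel))
    sample(rep_len(DB_TYPES, length(eSel))) else character(0)
  nSeason <- round(config$seasonal_fraction * p)
  seasonalIds <- sort(sample(p, nSeason))
  phases <- runif(p, 0, 2 * pi)
  baselines <- rnorm(p, mean = 0, sd = 1)
  copyFactor <- if (config$copy_number_sd > 0)
    rnorm(p, 0, config$copy_number_sd) else rep(0, p)

  theta <- .buildPrecision(p, edgeIdx, config$partial_corr_strength, signs)
  dimnames(theta) <- list(asvIds, asvIds)

  ## calendar: samples on the 1st of each month; date arithmetic in days
  allDates <- seq(as.Date("2003-09-01"), by = "month",
                  length.out = config$n_months)
  nDrop <- floor(config$missing_month_fraction * config$n_months)
  set.seed(childSeed(config$seed, "dates"))
  dropIdx <- if (nDrop > 0) sort(sample(config$n_months, nDrop)) else integer(0)
  keep <- setdiff(seq_len(config$n_months), dropIdx)
  dates <- allDates[keep]

  dayNum <- as.numeric(allDates - allDates[1])
  seasonal <- matrix(0, config$n_months, p)
  for (i in seasonalIds)
    seasonal[, i] <- config$seasonal_amplitude *
      sin(2 * pi * dayNum / 365.25 + phases[i])

  set.seed(childSeed(config$seed, "drift"))
  drift <- apply(matrix(rnorm(config$n_months * p, 0, config$drift_sd),
                        config$n_months, p), 2, cumsum)
  drift <- matrix(drift, config$n_months, p)

  resid <- .sampleResiduals(theta, config$n_months,
                            childSeed(config$seed, "residuals"))
  latentAll <- sweep(seasonal + drift + resid, 2, baselines, "+")
  latent <- latentAll[keep, , drop = FALSE]
  rownames(latent) <- format(dates)
  colnames(latent) <- asvIds

  set.seed(childSeed(config$seed, "counts"))
  counts <- matrix(0L, nrow = p, ncol = length(keep),
                   dimnames = list(asvIds, sprintf("s_%s", format(dates))))
  for (s in seq_along(keep)) {
    lat <- latent[s, ] + copyFactor
    pr <- exp(lat - max(lat))
    counts[, s] <- rmultinom(1, config$library_size, pr / sum(pr))[, 1]
  }

  lineage <- .assignTaxonomy(p, edgeIdx, types,
                             childSeed(config$seed, "taxonomy"))
  taxonomy <- setNames(lineage, asvIds)

  realized <- if (length(eSel))
    -theta[cbind(edgeIdx[, 1], edgeIdx[, 2])] /
      sqrt(diag(theta)[edgeIdx[, 1]] * diag(theta)[edgeIdx[, 2]])
  else numeric(0)
  plantedEdges <- data.frame(
    asv_a = asvIds[edgeIdx[, 1]], asv_b = asvIds[edgeIdx[, 2]],
    type = types, sign = signs, partial_cor = realized,
    stringsAsFactors = FALSE)

  truth <- structure(list(planted_edges = plantedEdges,
                          latent_precision = theta,
                          seasonal_ids = asvIds[seasonalIds],
                          sample_dates = dates,
                          dropped_dates = allDates[dropIdx],
                          latent = latent, baselines = baselines,
                          config = config),
                     class = "SyntheticTruth")
  asv <- AsvExperiment(counts, dates = dates, depth = depth,
                       taxonomy = taxonomy)
  list(asv = asv, taxonomy = taxonomy, truth = truth)
}

#' Generate a synthetic environmental/biological variable table
#'
#' Emits a samples x variables matrix containing (i) "driver" variables
#' that are linear functions of designated ASVs' latent abundances plus
#' noise, (ii) purely seasonal variables (annual sinusoid + noise), and
#' (iii) white-noise variables, with a configurable fraction of cells set
#' missing. The number of variables defaults to 24, the size of a typical
#' time-series environmental panel.
#'
#' @param config a \code{\link{syntheticConfig}}
#' @param truth the \code{truth} element returned by
#'   \code{\link{generateCommunity}}
#' @return numeric matrix (samples x variables, NA = missing) with
#'   attributes \code{driver_map} (variable -> ASV id) and
#'   \code{driver_noise_sd}
#' @export
generateEnv <- function(config, truth) {
  stopifnot(inherits(config, "SyntheticConfig"),
            inherits(truth, "SyntheticTruth"))
  dates <- truth$sample_dates
  if (!length(dates)) stop("truth contains no sample dates")
  n <- length(dates)
  nv <- config$n_env_vars
  nd <- min(config$n_driver_vars, nv)
  vars <- sprintf("env_%02d", seq_len(nv))
  env <- matrix(NA_real_, n, nv,
                dimnames = list(sprintf("s_%s", format(dates)), vars))

  set.seed(childSeed(config$seed, "env"))
  driverAsv <- sample(ncol(truth$latent), nd)
  dayNum <- as.numeric(dates - dates[1])
  nSeasonal <- max(0L, floor((nv - nd) / 2))
  for (v in seq_len(nv)) {
    if (v <= nd) {
      env[, v] <- truth$latent[, driverAsv[v]] +
        rnorm(n, 0, config$driver_noise_sd)
    } else if (v <= nd + nSeasonal) {
      env[, v] <- sin(2 * pi * dayNum / 365.25 + runif(1, 0, 2 * pi)) +
        rnorm(n, 0, 0.5)
    } else {
      env[, v] <- rnorm(n)
    }
  }

  set.seed(childSeed(config$seed, "env_missing"))
  mask <- runif(n * nv) < config$env_missing_fraction
  env[matrix(mask, n, nv)] <- NA_real_

  attr(env, "driver_map") <- setNames(colnames(truth$latent)[driverAsv],
                                      vars[seq_len(nd)])
  attr(env, "driver_noise_sd") <- config$driver_noise_sd
  env
}

## endpoint database key for an ASV, by rule precedence:
## Syndiniales group > radiolarian class > MAST clade > genus
.endpointKey <- function(keys, i) {
  if (!is.na(keys$syndiniales_group[i]))
    c(key = keys$syndiniales_group[i], rank = "syndiniales_group")
  else if (!is.na(keys$radiolarian_class[i]))
    c(key = keys$radiolarian_class[i], rank = "radiolarian_class")
  else if (!is.na(keys$mast_clade[i]))
    c(key = keys$mast_clade[i], rank = "mast_clade")
  else if (!is.na(keys$genus[i]))
    c(key = keys$genus[i], rank = "genus")
  else c(key = NA_character_, rank = NA_character_)
}

#' Emit a toy interaction database covering a subset of the planted edges
#'
#' A seeded sampler selects \code{db_coverage} of the planted edges (the
#' selection is replayable from the master seed) and writes one record per
#' selected edge, keyed at the granularity its taxa require: Syndiniales
#' group + host genus, radiolarian host class + symbiont genus, MAST clade
#' + symbiont genus, or genus + genus. Edges whose taxonomy lacks any
#' usable rank are skipped with a warning. Decoy records reference genera
#' absent from the community.
#'
#' @param truth \code{truth} from \code{\link{generateCommunity}}
#' @param taxonomy named lineage vector (as returned alongside the
#'   community)
#' @param config the \code{\link{syntheticConfig}} used
#' @return an \linkS4class{InteractionDB}
#' @export
generateInteractionDB <- function(truth, taxonomy, config) {
  stopifnot(inherits(truth, "SyntheticTruth"),
            inherits(config, "SyntheticConfig"))
  pe <- truth$planted_edges
  keys <- deriveTaxonKeys(unname(taxonomy))
  rownames(keys) <- names(taxonomy)

  nCov <- round(config$db_coverage * nrow(pe))
  set.seed(childSeed(config$seed, "db"))
  covIdx <- if (nCov > 0) sort(sample(nrow(pe), nCov)) else integer(0)

  rows <- list()
  for (r in covIdx) {
    ia <- match(pe$asv_a[r], rownames(keys))
    ib <- match(pe$asv_b[r], rownames(keys))
    ka <- .endpointKey(keys, ia)
    kb <- .endpointKey(keys, ib)
    if (is.na(ka["key"]) || is.na(kb["key"])) {
      warning("skipping planted edge ", pe$asv_a[r], "-", pe$asv_b[r],
              ": taxonomy lacks a usable matching rank")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      taxon_a_key = unname(ka["key"]), taxon_a_rank = unname(ka["rank"]),
      taxon_b_key = unname(kb["key"]), taxon_b_rank = unname(kb["rank"]),
      interaction_type = pe$type[r], stringsAsFactors = FALSE)
  }

  decoyPool <- c("Absentia", "Nullomonas", "Vacuopsis", "Phantomella",
                 "Inanis", "Nemomonas", "Vanuella", "Latetia")
  set.seed(childSeed(config$seed, "decoys"))
  for (d in seq_len(config$n_decoy_records)) {
    gg <- sample(decoyPool, 2)
    rows[[length(rows) + 1L]] <- data.frame(
      taxon_a_key = normalizeKey(gg[1], genus = TRUE),
      taxon_a_rank = "genus",
      taxon_b_key = normalizeKey(gg[2], genus = TRUE),
      taxon_b_rank = "genus",
      interaction_type = sample(DB_TYPES, 1), stringsAsFactors = FALSE)
  }

  rec <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon_a_key = character(0), taxon_a_rank = character(0),
               taxon_b_key = character(0), taxon_b_rank = character(0),
               interaction_type = character(0), stringsAsFactors = FALSE)
  rec <- cbind(record_id = sprintf("R%04d", seq_len(nrow(rec))), rec,
               multiplicity = rep(1L, nrow(rec)))
  methods::new("InteractionDB", records = rec,
               provenance = "synthetic toy interaction database")
}
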