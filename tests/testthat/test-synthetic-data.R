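test_that("config validation rejects out-of-range settings", {
  expect_error(syntheticConfig(n_planted_edges = 500, n_asvs = 10),
               "exceeds")
  expect_error(syntheticConfig(missing_month_fraction = 1), "proportion")
  expect_error(syntheticConfig(partial_corr_strength = 1.2), "\\(0, 1\\)")
  expect_error(syntheticConfig(drift_sd = -1), ">= 0")
})

test_that("no planted edges gives a diagonal precision and empty truth", {
  sim <- generateCommunity(syntheticConfig(n_asvs = 8, n_months = 30,
                                           n_planted_edges = 0, seed = 5))
  expect_equal(nrow(sim$truth$planted_edges), 0L)
  th <- sim$truth$latent_precision
  expect_equal(th, diag(nrow(th)), ignore_attr = TRUE)
})

test_that("every sample's counts sum to the library size; months dropped as configured", {
  cfg <- syntheticConfig(n_asvs = 12, n_months = 48,
                         missing_month_fraction = 0.25,
                         library_size = 7000, n_planted_edges = 4,
                         seed = 11)
  sim <- generateCommunity(cfg)
  cts <- asvCounts(sim$asv)
  expect_true(all(colSums(cts) == 7000))
  expect_true(all(cts >= 0))
  expect_identical(ncol(cts), 48L - as.integer(floor(0.25 * 48)))
  expect_identical(length(sim$truth$sample_dates), ncol(cts))
  # dropped months never exceed the configured fraction by more than one
  expect_lte(length(sim$truth$dropped_dates), floor(0.25 * 48) + 1)
})

test_that("precision off-diagonal support matches planted edges exactly", {
  cfg <- syntheticConfig(n_asvs = 10, n_months = 24, n_planted_edges = 6,
                         seed = 2)
  sim <- generateCommunity(cfg)
  th <- sim$truth$latent_precision
  expect_true(!inherits(try(chol(th), silent = TRUE), "try-error"))
  nz <- which(upper.tri(th) & th != 0, arr.ind = TRUE)
  got <- paste(rownames(th)[nz[, 1]], colnames(th)[nz[, 2]])
  want <- paste(sim$truth$planted_edges$asv_a, sim$truth$planted_edges$asv_b)
  expect_setequal(got, want)
})

test_that("seasonal ASVs show stronger 12-month than 6-month latent autocorrelation", {
  cfg <- syntheticConfig(n_asvs = 10, n_months = 120,
                         missing_month_fraction = 0,
                         seasonal_fraction = 1, seasonal_amplitude = 2,
                         drift_sd = 0, n_planted_edges = 0, seed = 21)
  sim <- generateCommunity(cfg)
  lat <- sim$truth$latent
  acAt <- function(x, l) cor(x[seq_len(length(x) - l)],
                             x[seq_len(length(x) - l) + l])
  ac6 <- mean(apply(lat, 2, acAt, l = 6))
  ac12 <- mean(apply(lat, 2, acAt, l = 12))
  expect_gt(ac12, ac6)
  expect_gt(ac12, 0.5)
})

test_that("latent residual partial correlations converge to the constructed precision", {
  cfg <- syntheticConfig(n_asvs = 8, n_months = 24, n_planted_edges = 5,
                         partial_corr_strength = 0.4, seed = 13)
  sim <- generateCommunity(cfg)
  th <- sim$truth$latent_precision
  E <- ProtNet:::.sampleResiduals(th, n = 5000, seed = 777)
  thHat <- solve(cov(E))
  pcor <- function(m) -m / sqrt(outer(diag(m), diag(m)))
  expect_lt(max(abs(pcor(thHat) - pcor(th))[upper.tri(th)]), 0.05)
})

test_that("env table: drivers, missingness replay, and zero-noise exactness", {
  cfg <- syntheticConfig(n_asvs = 10, n_months = 100,
                         missing_month_fraction = 0, n_planted_edges = 0,
                         n_env_vars = 10, env_missing_fraction = 0.1,
                         seed = 31)
  sim <- generateCommunity(cfg)
  env <- generateEnv(cfg, sim$truth)
  expect_identical(dim(env), c(100L, 10L))
  # replay the seeded missingness draw
  set.seed(ProtNet:::childSeed(31, "env_missing"))
  expect_identical(sum(is.na(env)), sum(runif(100 * 10) < 0.1))

  cfg0 <- syntheticConfig(n_asvs = 10, n_months = 60,
                          missing_month_fraction = 0, n_planted_edges = 0,
                          env_missing_fraction = 0, driver_noise_sd = 0,
                          seed = 32)
  sim0 <- generateCommunity(cfg0)
  env0 <- generateEnv(cfg0, sim0$truth)
  expect_false(anyNA(env0))
  dm <- attr(env0, "driver_map")
  for (v in names(dm))
    expect_equal(cor(env0[, v], sim0$truth$latent[, dm[[v]]]), 1,
                 tolerance = 1e-12)
})

test_that("interaction DB coverage is exact and replayable; decoys fill the rest", {
  cfg <- syntheticConfig(n_asvs = 30, n_months = 24, n_planted_edges = 20,
                         db_coverage = 0.5, n_decoy_records = 3, seed = 41)
  sim <- generateCommunity(cfg)
  db <- generateInteractionDB(sim$truth, sim$taxonomy, cfg)
  rec <- dbRecords(db)
  expect_identical(nrow(rec), 10L + 3L)
  # replay the seeded edge subset and check the emitted types line up
  set.seed(ProtNet:::childSeed(41, "db"))
  idx <- sort(sample(20, 10))
  expect_identical(rec$interaction_type[1:10],
                   sim$truth$planted_edges$type[idx])

  cfgFull <- syntheticConfig(n_asvs = 30, n_months = 24,
                             n_planted_edges = 20, db_coverage = 1,
                             n_decoy_records = 0, seed = 41)
  dbFull <- generateInteractionDB(sim$truth, sim$taxonomy, cfgFull)
  expect_identical(nrow(dbRecords(dbFull)), 20L)

  cfgNone <- syntheticConfig(n_asvs = 30, n_months = 24,
                             n_planted_edges = 20, db_coverage = 0,
                             n_decoy_records = 4, seed = 41)
  dbNone <- generateInteractionDB(sim$truth, sim$taxonomy, cfgNone)
  expect_identical(nrow(dbRecords(dbNone)), 4L)
  expect_true(all(dbRecords(dbNone)$taxon_a_rank == "genus"))
})

test_that("taxonomy synthesis exercises the special matching lineages", {
  cfg <- syntheticConfig(n_asvs = 40, n_months = 24, n_planted_edges = 24,
                         seed = 51)
  sim <- generateCommunity(cfg)
  keys <- taxonomyKeys(sim$asv)
  expect_true(any(!is.na(keys$syndiniales_group)))
  expect_true(any(!is.na(keys$genus)))
  # parasitism edges carry a Syndiniales endpoint by construction
  pe <- sim$truth$planted_edges
  para <- pe[pe$type == "parasitism", ]
  firstSeen <- !duplicated(c(rbind(pe$asv_a, pe$asv_b)))
  expect_gt(sum(!is.na(keys[para$asv_a, "syndiniales_group"]) |
                  !is.na(keys[para$asv_b, "syndiniales_group"])), 0)
})
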