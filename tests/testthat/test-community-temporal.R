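test_that("Bray-Curtis matches hand values and the raw-formula oracle", {
  m <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, 2, 3),
             d = c(0, 0, 7))
  d <- as.matrix(brayCurtis(m))
  expect_equal(d["a", "b"], (2 + 0 + 2) / 12, tolerance = 1e-12)
  expect_equal(d["a", "c"], 0, tolerance = 1e-12)
  # disjoint support
  expect_equal(as.matrix(brayCurtis(rbind(c(1, 2, 0), c(0, 0, 5))))[1, 2],
               1, tolerance = 1e-12)
  set.seed(12)
  r <- matrix(rexp(40), 5, 8)
  dr <- as.matrix(brayCurtis(r))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(dr[i, j], oracleBrayCurtis(r[i, ], r[j, ]),
                 tolerance = 1e-12)
  expect_true(all(dr >= 0 & dr <= 1))
  expect_error(brayCurtis(rbind(c(0, 0), c(0, 0), c(1, 2))), "all-zero")
})

test_that("lag profile bins use the 30.4-day month and round-half-up", {
  dates <- as.Date("2005-01-01") + c(0, 30, 365)
  m <- matrix(rexp(9), 3, 3)
  prof <- lagProfile(brayCurtis(m), dates)
  # lags: 30/30.4 = 0.987 -> 1; 335/30.4 = 11.02 -> 11; 365/30.4 = 12.007 -> 12
  expect_identical(prof$lag_months, c(1L, 11L, 12L))
  expect_identical(prof$n_pairs, c(1L, 1L, 1L))
  expect_identical(attr(prof, "n_pairs_total"), 3)

  # zero-lag pairs (duplicate dates) are excluded
  dates2 <- as.Date("2005-01-01") + c(0, 0, 61)
  prof2 <- lagProfile(brayCurtis(m), dates2)
  expect_identical(sum(prof2$n_pairs), 2L)
  expect_identical(prof2$lag_months, 2L) # 61/30.4 = 2.007
  # profile means match direct averaging
  sim <- 1 - as.matrix(brayCurtis(m))
  expect_equal(prof2$mean_sim, mean(c(sim[1, 3], sim[2, 3])),
               tolerance = 1e-12)
})

test_that("Mantel statistic agrees with vegan and p matches exhaustive enumeration", {
  set.seed(3)
  x <- matrix(rnorm(24), 6, 4)
  y <- matrix(rnorm(24), 6, 4)
  d1 <- dist(x)
  d2 <- dist(y)
  res <- mantelTest(d1, d2, n_perm = 99, seed = 7)
  vg <- vegan::mantel(d1, d2, method = "spearman", permutations = 99)
  expect_equal(res$statistic, unname(vg$statistic), tolerance = 1e-12)

  # self-comparison: r = 1, add-one p floor (n large enough that no
  # random permutation reproduces the observed ordering)
  dBig <- dist(matrix(rnorm(40), 10, 4))
  self <- mantelTest(dBig, dBig, n_perm = 199, seed = 1)
  expect_equal(self$statistic, 1)
  expect_equal(self$p_value, 1 / 200)

  # exhaustive enumeration on 4 samples vs an independent oracle
  d1s <- as.matrix(dist(x[1:4, ]))
  d2s <- as.matrix(dist(y[1:4, ]))
  ex <- mantelTest(d1s, d2s, exhaustive = TRUE)
  ut <- upper.tri(d1s)
  rObs <- oracleSpearman(d1s[ut], d2s[ut])
  rsAll <- vapply(oraclePermutations(4), function(p)
    oracleSpearman(d1s[ut], d2s[p, p][ut]), 0)
  expect_equal(ex$statistic, rObs, tolerance = 1e-12)
  expect_equal(ex$p_value, mean(rsAll >= rObs - 1e-12))
  expect_identical(ex$n_perm, 24L)

  expect_error(mantelTest(matrix(1, 4, 4) - diag(4), d1s), "constant")
})

test_that("ANOSIM: maximal separation gives R = 1, null is centered, exhaustive p exact", {
  # two tight clusters far apart
  pts <- rbind(matrix(rnorm(8, 0, .01), 4), matrix(rnorm(8, 50, .01), 4))
  d <- dist(pts)
  g <- rep(c("a", "b"), each = 4)
  res <- anosimTest(d, g, n_perm = 199, seed = 2)
  expect_equal(res$statistic, 1)
  vg <- vegan::anosim(d, g, permutations = 49)
  expect_equal(res$statistic, unname(vg$statistic), tolerance = 1e-12)

  # shuffled labels: R distribution centered near 0
  set.seed(9)
  dd <- dist(matrix(rnorm(40), 10, 4))
  rs <- vapply(1:50, function(i)
    anosimTest(dd, sample(rep(c("a", "b"), 5)), n_perm = 1,
               seed = i)$statistic, 0)
  expect_lt(abs(mean(rs)), 0.1)

  # exhaustive p on 6 samples matches brute-force enumeration
  set.seed(17)
  pts6 <- matrix(rnorm(18), 6, 3)
  d6 <- as.matrix(dist(pts6))
  g6 <- c("a", "a", "a", "b", "b", "b")
  ex <- anosimTest(d6, g6, exhaustive = TRUE)
  rk <- rank(d6[upper.tri(d6)])
  ut6 <- which(upper.tri(d6), arr.ind = TRUE)
  statOracle <- function(g) {
    w <- g[ut6[, 1]] == g[ut6[, 2]]
    (mean(rk[!w]) - mean(rk[w])) / (15 / 2)
  }
  rsAll <- vapply(oraclePermutations(6), function(p) statOracle(g6[p]), 0)
  expect_equal(ex$p_value, mean(rsAll >= ex$statistic - 1e-12))

  expect_error(anosimTest(d6, rep("a", 6)), "2 groups")
  expect_error(anosimTest(d6, c("a", rep("b", 5))), "2 members")
})

test_that("PC1-distance regression matches the closed-form least squares", {
  # single varying variable: PC1 explains everything
  v <- c(0, 1, 2, 4, 7)
  env <- cbind(v = v, w = rep(2, 5))
  sim <- matrix(0.5, 5, 5)
  diag(sim) <- 1
  res <- pc1DistanceRegression(env, sim)
  expect_equal(res$pc1_var_explained, 1)

  # constructed exact negative linear dependence: slope recovered, r2 = 1
  set.seed(5)
  env2 <- matrix(rnorm(12), 6, 2)
  pc1 <- prcomp(env2, center = TRUE)$x[, 1]
  simM <- 1 - 0.3 * abs(outer(pc1, pc1, "-"))
  res2 <- pc1DistanceRegression(env2, simM)
  expect_equal(res2$slope, -0.3, tolerance = 1e-10)
  expect_equal(res2$r_squared, 1, tolerance = 1e-10)
  expect_equal(res2$intercept, 1, tolerance = 1e-10)

  # normal-equations oracle on a noisy fixture
  simN <- simM + 0.01 * (m <- matrix(runif(36), 6, 6) + t(matrix(runif(36), 6, 6)))
  simN <- (simN + t(simN)) / 2
  resN <- pc1DistanceRegression(env2, simN)
  ut <- upper.tri(simN)
  idx <- which(ut, arr.ind = TRUE)
  xv <- abs(pc1[idx[, 1]] - pc1[idx[, 2]])
  yv <- simN[ut]
  betas <- solve(crossprod(cbind(1, xv)), crossprod(cbind(1, xv), yv))
  expect_equal(resN$intercept, betas[1], tolerance = 1e-10)
  expect_equal(resN$slope, betas[2], tolerance = 1e-10)

  expect_error(pc1DistanceRegression(env2[, 1, drop = FALSE], simM),
               "at least 2")
})
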