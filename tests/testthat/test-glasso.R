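test_that("lambda path is log-spaced, decreasing, and guarded", {
  set.seed(1)
  X <- matrix(rnorm(40 * 6), 40, 6)
  bp <- buildLambdaPath(X)
  expect_length(bp$lambdas, 30L)
  expect_true(all(diff(bp$lambdas) < 0))
  expect_equal(bp$lambdas[1], max(abs(bp$S[upper.tri(bp$S)])),
               tolerance = 1e-12)
  expect_equal(bp$lambdas[30], 0.1 * bp$lambdas[1], tolerance = 1e-10)
  expect_error(buildLambdaPath(X, ratio = 1), "strictly inside")
  Xc <- cbind(X, const = 1)
  expect_error(buildLambdaPath(Xc), "constant feature.*const")
})

test_that("solver hits the unpenalized and fully-shrunk limits", {
  set.seed(2)
  S <- cor(matrix(rnorm(60 * 3), 60, 3))
  expect_lt(max(abs(precisionMatrix(glassoSolve(S, 0)) - solve(S))), 1e-8)
  lmax <- max(abs(S[upper.tri(S)]))
  g <- glassoSolve(S, lmax)
  expect_identical(nrow(edges(g)), 0L)
  expect_equal(precisionMatrix(g), diag(1 / diag(S), 3),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_error(glassoSolve(S, -0.1), ">= 0")
})

test_that("solution matches the projected-gradient oracle and satisfies KKT", {
  set.seed(3)
  S <- cor(matrix(rnorm(50 * 5), 50, 5))
  lam <- 0.3 * max(abs(S[upper.tri(S)]))
  fit <- glassoSolve(S, lam, tol = 1e-10)
  oracle <- oracleGlassoPG(S, lam)
  expect_lt(abs(glassoObjective(fit, S, lam) - oracle$objective), 1e-6)
  expect_lt(kktResidual(fit, S, lam), 1e-6)
  # edge support of the oracle agrees (both exact-zero patterns)
  expect_identical(unname(precisionMatrix(fit) != 0),
                   unname(abs(oracle$Theta) > 1e-7))
})

test_that("edge counts are non-increasing in lambda on a fixture path", {
  set.seed(4)
  X <- matrix(rnorm(80 * 8), 80, 8)
  X[, 2] <- X[, 1] + rnorm(80, 0, 0.4)
  X[, 5] <- X[, 4] - X[, 3] + rnorm(80, 0, 0.4)
  bp <- buildLambdaPath(X, n_lambda = 12)
  ne <- vapply(bp$lambdas, function(l)
    nrow(edges(glassoSolve(bp$S, l))), 0L)
  expect_true(all(diff(ne) >= -1)) # tolerance for borderline entries
  expect_identical(ne[1], 0L)
})

test_that("StARS: instability bounded, monotone, reproducible, sparse at lambda_max", {
  set.seed(5)
  n <- 60
  z <- matrix(rnorm(n * 4), n, 4)
  X <- cbind(z, z[, 1:2] + matrix(rnorm(n * 2, 0, 0.6), n, 2),
             matrix(rnorm(n * 2), n, 2))
  colnames(X) <- paste0("f", 1:8)
  r1 <- starsSelect(X, n_lambda = 15, rep = 10, seed = 42)
  r2 <- starsSelect(X, n_lambda = 15, rep = 10, seed = 42)
  st <- r1$stability
  expect_true(all(instability(st) >= 0 & instability(st) <= 0.5))
  expect_true(!is.unsorted(instability(st, monotone = TRUE)))
  expect_identical(instability(st), instability(r2$stability))
  expect_identical(precisionMatrix(r1$network),
                   precisionMatrix(r2$network))
  # instability is exactly the 2*theta*(1-theta) average of the
  # recorded selection frequencies, and it vanishes wherever every
  # subsample agreed (frequency 0 or 1 for all pairs)
  expect_equal(instability(st),
               colMeans(2 * st@frequency * (1 - st@frequency)))
  agree <- apply(st@frequency, 2, function(f) all(f %in% c(0, 1)))
  expect_true(all(instability(st)[agree] == 0))
  expect_equal(optimalLambda(st), lambdaPath(st)[st@optIndex])
  expect_error(starsSelect(X, rep = 1), "rep")
})

test_that("network merge is the edge-set intersection", {
  set.seed(6)
  mk <- function(pairs, p = 6) {
    th <- diag(p)
    for (pr in pairs) th[pr[1], pr[2]] <- th[pr[2], pr[1]] <- -0.2
    dimnames(th) <- list(paste0("f", 1:p), paste0("f", 1:p))
    methods::new("PrecisionGraph", theta = th, lambda = 0.1,
                 edges = ProtNet:::.edgesFromTheta(th, character(0)),
                 kinds = character(0), converged = TRUE)
  }
  gA <- mk(list(c(1, 2), c(1, 3), c(2, 4), c(3, 5), c(4, 6)))
  gB <- mk(list(c(1, 2), c(2, 4), c(3, 5), c(2, 6), c(5, 6), c(1, 6)))
  shared <- mergeNetworks(gA, gB)
  expect_identical(nrow(shared), 3L)
  expect_setequal(paste(shared$feature_a, shared$feature_b),
                  c("f1 f2", "f2 f4", "f3 f5"))
  # idempotence and disjointness
  expect_identical(nrow(mergeNetworks(gA, gA)), nrow(edges(gA)))
  expect_identical(nrow(mergeNetworks(mk(list(c(1, 2))),
                                      mk(list(c(3, 4))))), 0L)
})

test_that("feature kinds partition edges and survive GraphML export", {
  set.seed(7)
  n <- 80
  a <- rnorm(n)
  X <- cbind(asv1 = a + rnorm(n, 0, .4), asv2 = a + rnorm(n, 0, .4),
             env1 = a + rnorm(n, 0, .4), env2 = rnorm(n))
  kinds <- c(asv1 = "asv", asv2 = "asv", env1 = "env", env2 = "env")
  bp <- buildLambdaPath(X, n_lambda = 5)
  g <- glassoSolve(bp$S, bp$lambdas[5], kinds = kinds)
  part <- edgePartition(g)
  expect_identical(sum(part), nrow(edges(g)))
  expect_true(all(names(part) %in% c("asv-asv", "asv-env", "env-env")))
  f <- withr::local_tempfile(fileext = ".graphml")
  ig <- writeGraphML(g, f)
  expect_true(file.exists(f))
  back <- igraph::read_graph(f, format = "graphml")
  expect_identical(igraph::ecount(back), as.numeric(nrow(edges(g))))
})
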