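test_that("RDA recovers exact and orthogonal limits", {
  set.seed(1)
  X <- matrix(rnorm(16), 8, 2)
  B <- matrix(rnorm(6), 2, 3)
  fit <- rdaFit(X %*% B, X) # Y exactly in the span of X
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_lt(sum(fit$eig_unconstrained), 1e-16)

  Yraw <- matrix(rnorm(8 * 3), 8, 3)
  Yorth <- residuals(lm(Yraw ~ X)) # orthogonal to X by construction
  expect_lt(rdaFit(Yorth, X)$r_squared, 1e-10)
})

test_that("RDA R2 matches the hat-matrix trace oracle and vegan", {
  set.seed(2)
  Y <- matrix(rnorm(8 * 3), 8, 3)
  X <- matrix(rnorm(8 * 2), 8, 2, dimnames = list(NULL, c("a", "b")))
  fit <- rdaFit(Y, X)
  Yc <- scale(Y, scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  H <- Xc %*% solve(crossprod(Xc)) %*% t(Xc)
  expect_equal(fit$r_squared, sum(diag(H %*% Yc %*% t(Yc))) / sum(Yc^2),
               tolerance = 1e-10)
  vg <- vegan::rda(Y ~ a + b, data = as.data.frame(X))
  expect_equal(fit$r_squared, vg$CCA$tot.chi / vg$tot.chi,
               tolerance = 1e-10)
  expect_equal(fit$adj_r_squared,
               vegan::RsquareAdj(vg)$adj.r.squared, tolerance = 1e-10)
  # variance partition and axis eigenvalues
  expect_equal(sum(fit$eig_constrained) + sum(fit$eig_unconstrained),
               fit$total_variance, tolerance = 1e-8)
  expect_equal(unname(fit$eig_constrained), unname(vg$CCA$eig),
               tolerance = 1e-8)
  # invariance to constraint column order
  expect_equal(rdaFit(Y, X[, c(2, 1)])$r_squared, fit$r_squared,
               tolerance = 1e-12)
  expect_error(rdaFit(Y, cbind(X, a2 = X[, 1])), "rank-deficient")
})

test_that("forward selection takes a perfect predictor at the p floor", {
  set.seed(3)
  Y <- matrix(rnorm(30 * 4), 30, 4)
  X <- cbind(perfect = Y[, 1])
  fs <- forwardSelect(Y, X, n_perm = 199, seed = 5)
  expect_identical(fs$selected, "perfect")
  expect_equal(fs$trace$p[1], 1 / 200)
})

test_that("collinear duplicate candidates are never co-selected and the scope guard holds", {
  set.seed(4)
  n <- 50
  x <- rnorm(n)
  X <- cbind(x = x, x_dup = x, n1 = rnorm(n), n2 = rnorm(n))
  Y <- cbind(2 * x, -x, x) + matrix(rnorm(n * 3, 0, 0.5), n, 3)
  # global model is rank-deficient with the exact duplicate; perturb a hair
  X[, "x_dup"] <- x + rnorm(n, 0, 1e-6)
  fs <- forwardSelect(Y, X, n_perm = 199, seed = 6)
  expect_lte(sum(c("x", "x_dup") %in% fs$selected), 1)
  if (!fs$empty)
    expect_lte(fs$model$adj_r_squared, fs$global_adj_r2 + 1e-10)
  # adding the twin after its partner cannot raise adjusted R2 materially
  a1 <- rdaFit(Y, X[, "x", drop = FALSE])$adj_r_squared
  a2 <- rdaFit(Y, X[, c("x", "x_dup")])$adj_r_squared
  expect_lt(a2 - a1, 1e-3)
})
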