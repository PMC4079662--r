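test_that("propensity transform and inverse are consistent", {
  p <- c(0, 0.04, 0.25, 1)
  expect_equal(prop_inverse(prop_transform(p)), p)
  expect_equal(prop_inverse(-0.2), -0.04)  # signed square admits small negatives
  expect_error(prop_transform(1.2), "0, 1")
})

test_that("z-scoring drops constant columns with a warning and round-trips", {
  X <- cbind(a = rnorm(10), b = rep(2, 10), c = runif(10))
  expect_warning(z <- zscore_fit_apply(X), "constant")
  expect_equal(z$scaler$kept, c("a", "c"))
  expect_equal(colMeans(z$scaled), c(a = 0, c = 0), tolerance = 1e-12)
  expect_equal(apply(z$scaled, 2, sd), c(a = 1, c = 1))
  expect_equal(zscore_apply(X, z$scaler), z$scaled)
})

test_that("SE kernel has unit-diagonal structure and ARD anisotropy", {
  X <- matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)
  K <- se_kernel(X, X, sf2 = 2, ls = c(1, 10))
  expect_equal(diag(K), rep(2, 3))
  expect_equal(K[1, 2], 2 * exp(-0.5))          # moves along the short axis
  expect_equal(K[1, 3], 2 * exp(-0.5 / 100))    # long axis barely matters
  expect_true(isSymmetric(K))
  expect_error(se_kernel(X, X[, 1, drop = FALSE], 1, c(1, 1)), "dimension")
})

test_that("analytic LML gradient matches finite differences", {
  set.seed(5)
  X <- matrix(rnorm(36), 12, 3)
  y <- sin(X[, 1]) + rnorm(12, 0, 0.1)
  ls <- c(0.7, 1.3, 4); sf2 <- 1.5; sn2 <- 0.04
  got <- log_marginal_likelihood(X, y, ls, sf2, sn2)
  f <- function(th) log_marginal_likelihood(X, y, exp(th[1:3]), exp(th[4]),
                                            exp(th[5]))$lml
  fd <- fd_gradient(f, c(log(ls), log(sf2), log(sn2)))
  expect_equal(got$grad, fd, tolerance = 1e-5)
})

test_that("predictions match a dense-solve oracle", {
  set.seed(6)
  X <- matrix(rnorm(30), 15, 2)
  y <- X[, 1]^2 + rnorm(15, 0, 0.05)
  m <- gpr_train(X, y, n_restarts = 4, seed = 1, maxit = 80, scale = FALSE)
  newX <- matrix(rnorm(10), 5, 2)
  got <- gpr_predict(m, newX)
  want <- oracle_gpr_predict(X, y, newX, m$ls, m$sf2, m$sn2)
  expect_lt(max(abs(got$mean - want$mean)), 1e-10)
  expect_lt(max(abs(got$var - want$var)), 1e-10)
})

test_that("closed-form LOO equals the refit oracle", {
  set.seed(8)
  n <- 20
  X <- matrix(rnorm(n * 2), n, 2)
  y <- cos(X[, 1]) + rnorm(n, 0, 0.1)
  m <- gpr_train(X, y, n_restarts = 4, seed = 2, maxit = 80, scale = FALSE)
  got <- gpr_loo(m)
  want <- oracle_loo(X, y, m$ls, m$sf2, m$sn2)
  expect_equal(got$mean, want$mean, tolerance = 1e-8)
  expect_equal(got$var, want$var, tolerance = 1e-8)
})

test_that("training is deterministic given the seed", {
  set.seed(9)
  X <- matrix(rnorm(40), 20, 2)
  y <- X[, 1] + rnorm(20, 0, 0.2)
  m1 <- gpr_train(X, y, n_restarts = 3, seed = 7, maxit = 50)
  m2 <- gpr_train(X, y, n_restarts = 3, seed = 7, maxit = 50)
  expect_identical(m1$ls, m2$ls)
  expect_identical(m1$lml, m2$lml)
})

test_that("irrelevant dimensions get long length scales", {
  set.seed(10)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3)
  y <- sin(2 * X[, 1]) + rnorm(n, 0, 0.05)
  m <- gpr_train(X, y, n_restarts = 6, seed = 3, maxit = 150)
  sig <- significant_variables(m)
  expect_true(sig$significant[sig$feature == "x1"])
  expect_equal(sig$feature[1], "x1")  # shortest length scale first
  expect_false(sig$significant[sig$feature == "x3"])
  lc <- pmin(pmax(m$ls, m$ls_range[1]), m$ls_range[2])
  expect_equal(attr(sig, "threshold"), sqrt(min(lc) * max(lc)))
})

test_that("relative relevance is anchored at 1 for the top feature", {
  set.seed(12)
  X <- matrix(rnorm(60), 30, 2)
  y <- X[, 1] + rnorm(30, 0.1)
  m <- gpr_train(X, y, n_restarts = 3, seed = 1, maxit = 60)
  sig <- significant_variables(m)
  expect_equal(sig$relative[1], 1)
  expect_true(all(diff(sig$relative) >= 0))
})

test_that("GPR beats the linear baseline on a curved response", {
  set.seed(13)
  n <- 80
  X <- matrix(runif(n * 2, -2, 2), n, 2)
  pii <- pmin(pmax(0.1 + 0.6 * exp(-rowSums(X^2)), 0), 1)
  cmp <- compare_with_linear(X, pii, seed = 1, n_restarts = 4, maxit = 100)
  expect_gt(cmp$fraction, 0.6)
})

test_that("restart log-likelihoods are recorded and the best is kept", {
  set.seed(14)
  X <- matrix(rnorm(30), 15, 2)
  y <- rnorm(15)
  m <- gpr_train(X, y, n_restarts = 5, seed = 4, maxit = 40)
  expect_length(m$restart_lmls, 5)
  # the model LML is recomputed at the winning parameters; optim's reported
  # value can differ in the last CG step, so compare loosely
  expect_equal(m$lml, max(m$restart_lmls, na.rm = TRUE), tolerance = 1e-4)
})
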