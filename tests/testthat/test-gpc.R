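make_toy_classification <- function(n = 60, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 2), n, 2)
  y <- as.integer(X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, 0.3) > 0)
  list(X = X, y = y)
}

test_that("input validation catches bad labels", {
  toy <- make_toy_classification()
  expect_error(ivm_fit(toy$X, toy$y + 1), "0/1")
  expect_error(ivm_fit(toy$X, rep(1, nrow(toy$X))), "degenerate")
})

test_that("sparse fit with full active set matches the dense EP oracle", {
  toy <- make_toy_classification(60, seed = 2)
  ls <- c(1, 1); sf2 <- 1
  fit <- ivm_fit(toy$X, toy$y, fixed_lengths = c(x1 = 1, x2 = 1),
                 d_active = 60, seed = 1, sf2 = sf2, refine_sweeps = 30,
                 scale = FALSE)
  set.seed(3)
  newX <- matrix(rnorm(40), 20, 2)
  colnames(newX) <- c("x1", "x2")
  got <- predict_probability(fit, newX)
  ep <- oracle_dense_ep(toy$X, toy$y, ls, sf2)
  want <- oracle_ep_predict(ep, toy$X, newX, ls, sf2)
  expect_lt(max(abs(got - want)), 0.02)
})

test_that("label flip mirrors the predictions", {
  toy <- make_toy_classification(50, seed = 4)
  fit_a <- ivm_fit(toy$X, toy$y, d_active = 25, seed = 1)
  fit_b <- ivm_fit(toy$X, 1L - toy$y, d_active = 25, seed = 1)
  p_a <- predict_probability(fit_a, toy$X)
  p_b <- predict_probability(fit_b, toy$X)
  expect_lt(max(abs(p_a + p_b - 1)), 0.02)
})

test_that("active set size follows the requested sparsity", {
  toy <- make_toy_classification(80, seed = 5)
  fit <- ivm_fit(toy$X, toy$y, d_active = 15, seed = 1)
  expect_length(fit$active, 15)
  expect_false(any(duplicated(fit$active)))
  # default rule: min(n, min(500, max(ceiling(n/10), 20)))
  fit2 <- ivm_fit(toy$X, toy$y, seed = 1)
  expect_length(fit2$active, 20)
})

test_that("sparse classification separates an easy problem", {
  set.seed(6)
  n <- 80
  X <- rbind(matrix(rnorm(n, -2, 0.5), n / 2, 2),
             matrix(rnorm(n, 2, 0.5), n / 2, 2))
  y <- rep(c(0L, 1L), each = n / 2)
  fit <- ivm_fit(X, y, d_active = 20, seed = 1)
  p <- predict_probability(fit, X)
  expect_gt(mean((p > 0.5) == y), 0.95)
  expect_true(all(p > 0 & p < 1))
})

test_that("fixed protein length scales are honoured", {
  toy <- make_toy_classification(40, seed = 7)
  colnames(toy$X) <- c("f1", "f2")
  fit <- ivm_fit(toy$X, toy$y, fixed_lengths = c(f1 = 3.3), seed = 1,
                 optimize = TRUE, n_restarts = 2, maxit = 10, d_active = 20)
  expect_equal(unname(fit$ls["f1"]), 3.3)
  expect_error(ivm_fit(toy$X, toy$y, fixed_lengths = c(nope = 1)), "name")
})

test_that("quadratic fit recovers exact quadratic curves", {
  cc <- seq(0, 2, length.out = 15)
  for (coef in list(c(0.1, 0.6, -0.25), c(0.5, -0.4, 0.12), c(0.1, 0.2, 0))) {
    P <- coef[1] + coef[2] * cc + coef[3] * cc^2
    qf <- fit_quadratic(data.frame(conc = cc, prob = P))
    expect_equal(c(qf$p0, qf$p1, qf$p2), coef, tolerance = 1e-10)
  }
})

test_that("quadratic shape classification matches the vertex rule", {
  cc <- seq(0, 2, length.out = 15)
  shapes <- list(
    list(P = 0.2 + 0.5 * cc - 0.25 * cc^2, cls = "interior-max", exc = FALSE),
    list(P = 0.6 - 0.5 * cc + 0.25 * cc^2, cls = "interior-min", exc = FALSE),
    list(P = 0.1 + 0.2 * cc, cls = "monotone-increasing", exc = FALSE),
    list(P = 0.8 - 0.2 * cc, cls = "monotone-decreasing", exc = TRUE))
  for (s in shapes) {
    qf <- fit_quadratic(data.frame(conc = cc, prob = s$P))
    expect_equal(qf$class, s$cls)
    expect_equal(qf$excluded, s$exc)
  }
})

test_that("optimal condition finds a planted interior optimum", {
  # build a model whose response in IS peaks at a moderate salt level
  reg <- build_registry()
  set.seed(8)
  conc <- runif(120, 0, 2.5)
  feats <- t(vapply(conc, function(cc) {
    cocktail_feature_vector(c(sodium = cc, chloride = cc), Rg = 18, registry = reg)
  }, numeric(61)))
  is_star <- 1.2
  prob_true <- pnorm(1.5 - 4 * (feats[, "IS"] - is_star)^2)
  y <- rbinom(length(conc), 1, prob_true)
  # most species never occur in these single-salt cocktails; the constant
  # columns are dropped by the scaler, which is exactly what we want here
  fit <- suppressWarnings(ivm_fit(feats, y, d_active = 60, seed = 1))
  pf <- c(Rg = 18)
  grid <- seq(0.05, 1.2, length.out = 25)
  opt <- optimal_condition(fit, pf, "sodium", grid, registry = reg)
  # IS of the c(sodium=c, chloride=0) probe cocktail is c/2... the curve probes
  # single-species cocktails, so the optimum concentration satisfies c/2 ~ near
  # the planted IS peak within the grid resolution where the model can see it
  expect_s3_class(opt$curve, "response_curve")
  expect_true(opt$c_star %in% c(0, grid))
  expect_true(is.finite(opt$p0) && opt$p0 >= 0 && opt$p0 <= 1)
})

test_that("concentration grids start at zero and stay within training range", {
  tr <- c(rep(0, 5), runif(50, 0.1, 2))
  g <- make_conc_grid(tr, n = 25)
  expect_equal(g[1], 0)
  expect_length(g, 25)
  expect_true(!is.unsorted(g))
  expect_lte(max(g), max(tr))
  expect_error(make_conc_grid(rep(0, 4)), "never occurs")
})
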