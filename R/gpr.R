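#' Propensity transform
#'
#' The regression target is f = sqrt(pi), whose inverse pi = sign(f) * f^2
#' permits small non-physical negative predicted propensities while staying
#' nearly linear at small pi and emphasizing high-propensity proteins.
#'
#' @param pi Crystallization propensity in 0..1.
#' @return Transformed response f.
#' @export
prop_transform <- function(pi) {
  if (any(pi < 0 | pi > 1, na.rm = TRUE)) stop("propensity must lie in [0, 1]")
  sqrt(pi)
}

#' @param f Transformed response (any real).
#' @rdname prop_transform
#' @export
prop_inverse <- function(f) sign(f) * f^2

#' Z-score a feature table
#'
#' Centres and scales every column by its mean and standard deviation.
#' Constant columns have undefined z-scores and are dropped with a warning.
#'
#' @param x Data frame or matrix of numeric features (>= 2 rows).
#' @return List: `scaled` (matrix), `scaler` (list with `center`, `scale`,
#'   `kept` column names).
#' @export
zscore_fit_apply <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to z-score")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  if (any(!keep)) {
    warning("dropping constant column(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
  }
  scaled <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2, sds[keep], "/")
  list(scaled = scaled,
       scaler = list(center = ctr[keep], scale = sds[keep],
                     kept = colnames(x)[keep]))
}

#' Apply a fitted scaler to new data
#' @param x New data (matrix/data.frame) with at least the scaler's columns.
#' @param scaler A scaler from [zscore_fit_apply()].
#' @return Scaled matrix over the scaler's kept columns.
#' @export
zscore_apply <- function(x, scaler) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    if (ncol(x) != length(scaler$kept)) stop("dimension mismatch")
    colnames(x) <- scaler$kept
  }
  x <- x[, scaler$kept, drop = FALSE]
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}

#' ARD squared-exponential kernel
#'
#' k(x, x') = sigma_f^2 exp(-1/2 sum_d (x_d - x'_d)^2 / l_d^2). The per-
#' dimension length scales implement automatic relevance determination: a
#' small l_d marks a variable whose variation strongly moves the response.
#'
#' @param X1,X2 Row matrices of inputs (same number of columns).
#' @param sf2 Signal variance.
#' @param ls Positive length scales, one per column.
#' @return Kernel matrix nrow(X1) x nrow(X2).
#' @export
se_kernel <- function(X1, X2, sf2, ls) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (ncol(X1) != ncol(X2) || ncol(X1) != length(ls)) {
    stop("dimension mismatch between inputs and length scales")
  }
  S1 <- sweep(X1, 2, ls, "/")
  S2 <- sweep(X2, 2, ls, "/")
  d2 <- outer(rowSums(S1^2), rowSums(S2^2), "+") - 2 * tcrossprod(S1, S2)
  sf2 * exp(-0.5 * pmax(d2, 0))
}

# squared-difference arrays per dimension, reused across LML evaluations
sqdiff_list <- function(X) {
  lapply(seq_len(ncol(X)), function(d) outer(X[, d], X[, d], "-")^2)
}

# Cholesky with a jitter ladder 1e-10 .. 1e-6 * mean diag
chol_jitter <- function(K) {
  sc <- mean(diag(K))
  for (j in c(0, 10^(-10:-6) * sc)) {
    L <- tryCatch(chol(K + diag(j, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  stop("kernel matrix is not positive definite even after jitter")
}

# log marginal likelihood and gradient w.r.t. log-hyperparameters
# theta = c(log ls (d), log sf2, log sn2); y is the raw response (centred
# internally by its training mean)
lml_core <- function(theta, D, yc, grad = TRUE) {
  d <- length(D)
  ls <- exp(theta[seq_len(d)])
  sf2 <- exp(theta[d + 1L])
  sn2 <- exp(theta[d + 2L])
  n <- length(yc)
  r2 <- matrix(0, n, n)
  for (k in seq_len(d)) r2 <- r2 + D[[k]] / ls[k]^2
  K <- sf2 * exp(-0.5 * r2)
  L <- chol_jitter(K + diag(sn2, n))
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  lml <- -0.5 * sum(yc * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)
  if (!grad) return(list(lml = lml, alpha = alpha, L = L, K = K))
  Kinv <- chol2inv(L)
  W <- tcrossprod(alpha) - Kinv
  g <- numeric(d + 2L)
  for (k in seq_len(d)) g[k] <- 0.5 * sum(W * (K * (D[[k]] / ls[k]^2)))
  g[d + 1L] <- 0.5 * sum(W * K)
  g[d + 2L] <- 0.5 * sn2 * sum(diag(W))
  list(lml = lml, grad = g, alpha = alpha, L = L, K = K)
}

#' Log marginal likelihood of a GPR model
#'
#' -1/2 (y - ybar)' Ky^-1 (y - ybar) - 1/2 log|Ky| - n/2 log 2pi with
#' Ky = K + sigma_n^2 I, plus its analytic gradient with respect to the
#' log-hyperparameters (log length scales, log signal variance, log noise
#' variance).
#'
#' @param X Scaled input matrix.
#' @param y Response vector.
#' @param ls,sf2,sn2 Hyperparameters.
#' @return List with `lml` and `grad`.
#' @export
log_marginal_likelihood <- function(X, y, ls, sf2, sn2) {
  X <- as.matrix(X)
  D <- sqdiff_list(X)
  r <- lml_core(c(log(ls), log(sf2), log(sn2)), D, y - mean(y))
  list(lml = r$lml, grad = r$grad)
}

#' Train an ARD GPR model with random restarts
#'
#' Maximizes the marginal log-likelihood by conjugate-gradient search from
#' multiple random initial hyperparameters; length-scale initial values are
#' Beta(0.5, 0.5) samples stretched onto log-space bounds, mirroring the
#' bimodal restart sampling used to explore the many local maxima. The best
#' restart (highest LML) is returned; all restart LMLs are kept for
#' diagnostics.
#'
#' @param X Feature matrix or data frame (raw units; z-scored internally).
#' @param y Response vector (e.g. transformed propensity).
#' @param n_restarts Number of restarts (>= 1).
#' @param seed Integer seed controlling the restart draws.
#' @param maxit Conjugate-gradient iteration cap per restart.
#' @param ls_log_range Log-space range for length-scale initialization
#'   (z-scored units).
#' @param scale If TRUE (default) z-score X and keep the scaler in the model.
#' @return An object of class `gpr_model`.
#' @export
gpr_train <- function(X, y, n_restarts = 100, seed = 1, maxit = 200,
                      ls_log_range = c(log(0.05), log(20)), scale = TRUE) {
  if (n_restarts < 1L) stop("n_restarts must be >= 1")
  if (length(y) < 2L) stop("need at least 2 training rows")
  if (is.data.frame(X)) X <- as.matrix(X)
  scaler <- NULL
  if (scale) {
    z <- zscore_fit_apply(X)
    X <- z$scaled
    scaler <- z$scaler
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  d <- ncol(X)
  D <- sqdiff_list(X)
  ybar <- mean(y)
  yc <- y - ybar
  vy <- max(stats::var(y), 1e-12)

  best <- NULL
  lmls <- rep(NA_real_, n_restarts)
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      u <- stats::rbeta(d, 0.5, 0.5)
      th0 <- c(ls_log_range[1] + u * diff(ls_log_range),
               log(vy) + stats::rnorm(1, 0, 0.3),
               log(vy) + log(stats::runif(1, 0.01, 0.5)))
      fit <- tryCatch(
        stats::optim(th0,
                     fn = function(th) lml_core(th, D, yc, grad = FALSE)$lml,
                     gr = function(th) lml_core(th, D, yc)$grad,
                     method = "CG",
                     control = list(fnscale = -1, maxit = maxit)),
        error = function(e) NULL)
      if (is.null(fit)) next
      lmls[r] <- fit$value
      if (is.null(best) || fit$value > best$value) best <- fit
    }
  })
  if (is.null(best)) stop("all restarts failed")

  th <- best$par
  fin <- lml_core(th, D, yc)
  model <- list(
    ls = stats::setNames(exp(th[seq_len(d)]), colnames(X)),
    sf2 = exp(th[d + 1L]),
    sn2 = exp(th[d + 2L]),
    X = X, y = y, y_mean = ybar,
    scaler = scaler,
    alpha = fin$alpha, L = fin$L,
    lml = fin$lml, restart_lmls = lmls,
    ls_range = exp(ls_log_range)
  )
  class(model) <- "gpr_model"
  model
}

#' @export
print.gpr_model <- function(x, ...) {
  cat(sprintf("<gpr_model> n = %d, d = %d, LML = %.3f, sf2 = %.3g, sn2 = %.3g\n",
              nrow(x$X), ncol(x$X), x$lml, x$sf2, x$sn2))
  invisible(x)
}

#' GPR predictive mean and variance
#'
#' mean = ybar + k*' Ky^-1 (y - ybar); variance = k** - k*' Ky^-1 k* +
#' sigma_n^2 (predictive, i.e. including observation noise).
#'
#' @param model A `gpr_model`.
#' @param newX New inputs in the units the model was trained on (raw if the
#'   model carries a scaler, which is then applied).
#' @return Data frame with `mean` and `var`.
#' @export
gpr_predict <- function(model, newX) {
  newX <- as.matrix(newX)
  if (!is.null(model$scaler)) newX <- zscore_apply(newX, model$scaler)
  if (ncol(newX) != ncol(model$X)) stop("dimension mismatch")
  Ks <- se_kernel(model$X, newX, model$sf2, model$ls)
  mu <- model$y_mean + drop(crossprod(Ks, model$alpha))
  V <- forwardsolve(t(model$L), Ks)
  var <- model$sf2 - colSums(V^2) + model$sn2
  data.frame(mean = mu, var = pmax(var, .Machine$double.eps))
}

#' Closed-form leave-one-out cross-validation
#'
#' LOO predictive means and variances at fixed hyperparameters from the
#' full-data inverse: mu_i = y_i - alpha_i / Kinv_ii, var_i = 1 / Kinv_ii.
#'
#' @param model A `gpr_model` with at least 3 training points.
#' @param level Confidence level for the intervals.
#' @return Data frame with `mean`, `var`, `lower`, `upper` per training row.
#' @export
gpr_loo <- function(model, level = 0.95) {
  if (length(model$y) < 3L) stop("LOO needs n >= 3")
  Kinv <- chol2inv(model$L)
  dKi <- diag(Kinv)
  mu <- model$y - model$alpha / dKi
  var <- 1 / dKi
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(mean = mu, var = var,
             lower = mu - zq * sqrt(var), upper = mu + zq * sqrt(var))
}

#' Relevance report from learned length scales
#'
#' A feature is significant when its length scale does not exceed the
#' geometric midpoint sqrt(l_min * l_max) of the learned scales ("roughly the
#' half point between the largest and the smallest length measured in
#' logarithmic scale"). Length scales are clipped to the hyperparameter search
#' box before the midpoint is taken: on z-scored inputs, any scale beyond the
#' box ceiling is indistinguishable from an inert dimension, and letting such
#' runaway values inflate l_max would drag the midpoint up and admit false
#' positives. Also reports l / l_min so the most relevant feature maps
#' to 1.00.
#'
#' @param model A `gpr_model`.
#' @return Data frame ordered by length scale: `feature`, `length_scale`,
#'   `relative`, `significant`; threshold in attribute `threshold`.
#' @export
significant_variables <- function(model) {
  ls <- model$ls
  rng <- if (!is.null(model$ls_range)) model$ls_range else range(ls)
  lc <- pmin(pmax(ls, rng[1]), rng[2])
  thr <- sqrt(min(lc) * max(lc))
  out <- data.frame(feature = names(ls), length_scale = unname(ls),
                    relative = unname(ls / min(ls)),
                    significant = unname(lc <= thr),
                    stringsAsFactors = FALSE)
  out <- out[order(out$length_scale), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Compare GPR with a linear baseline under LOO
#'
#' Fits both models to the same transformed propensity target and compares
#' per-protein absolute LOO residuals. Linear-regression LOO residuals use
#' the hat-matrix identity e_i / (1 - h_ii). Ties count 0.5 to each model.
#'
#' @param X Feature table (raw units).
#' @param pi Observed propensities in 0..1.
#' @param seed Seed for the GPR restarts.
#' @param n_restarts,maxit Passed to [gpr_train()].
#' @return List: `fraction` (share of proteins where GPR has the smaller
#'   absolute residual), `table` (per-protein residuals), `gpr` (the model).
#' @export
compare_with_linear <- function(X, pi, seed = 1, n_restarts = 10, maxit = 200) {
  f <- prop_transform(pi)
  z <- zscore_fit_apply(X)
  gpr <- gpr_train(z$scaled, f, n_restarts = n_restarts, seed = seed,
                   maxit = maxit, scale = FALSE)
  gpr$scaler <- z$scaler
  res_gpr <- f - gpr_loo(gpr)$mean

  Xd <- cbind(1, z$scaled)
  fit <- stats::lm.fit(Xd, f)
  h <- rowSums((Xd %*% chol2inv(chol(crossprod(Xd)))) * Xd)
  res_lr <- fit$residuals / (1 - h)

  d <- abs(res_lr) - abs(res_gpr)
  wins <- ifelse(abs(d) < 1e-12, 0.5, as.numeric(d > 0))
  list(fraction = mean(wins),
       table = data.frame(f_obs = f, resid_gpr = res_gpr, resid_lr = res_lr,
                          gpr_wins = wins),
       gpr = gpr)
}

# evaluate a function with a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
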