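# Independent reference implementations used as oracles. These deliberately
# take the slow, obvious route and share no code with the package internals.

# central finite-difference gradient of a scalar function
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + h
    xm[k] <- xm[k] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}

# dense GPR prediction by direct solve (no Cholesky reuse)
oracle_gpr_predict <- function(X, y, newX, ls, sf2, sn2) {
  K <- se_kernel(X, X, sf2, ls) + diag(sn2, nrow(X))
  Ks <- se_kernel(X, newX, sf2, ls)
  Ki <- solve(K)
  mu <- mean(y) + drop(t(Ks) %*% Ki %*% (y - mean(y)))
  var <- sf2 - diag(t(Ks) %*% Ki %*% Ks) + sn2
  list(mean = mu, var = var)
}

# leave-one-out by literally refitting without point i
oracle_loo <- function(X, y, ls, sf2, sn2) {
  n <- nrow(X)
  mu <- numeric(n); var <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    Ktr <- se_kernel(X[tr, , drop = FALSE], X[tr, , drop = FALSE], sf2, ls) +
      diag(sn2, n - 1L)
    Ks <- se_kernel(X[tr, , drop = FALSE], X[i, , drop = FALSE], sf2, ls)
    Ki <- solve(Ktr)
    # same centring convention as the model: full-data training mean
    mu[i] <- mean(y) + drop(t(Ks) %*% Ki %*% (y[tr] - mean(y)))
    var[i] <- sf2 + sn2 - drop(t(Ks) %*% Ki %*% Ks)
  }
  list(mean = mu, var = var)
}

# dense EP for probit GP classification, textbook sequential form without
# rank-one shortcuts: posterior recomputed from scratch at every site update
oracle_dense_ep <- function(X, y01, ls, sf2, sweeps = 30, tol = 1e-8) {
  y <- 2 * y01 - 1
  n <- nrow(X)
  K <- se_kernel(X, X, sf2, ls)
  ttau <- numeric(n); tnu <- numeric(n)
  posterior <- function() {
    S <- diag(ttau, n)
    Sigma <- solve(solve(K + diag(1e-10, n)) + S)
    list(Sigma = Sigma, mu = drop(Sigma %*% tnu))
  }
  for (sw in seq_len(sweeps)) {
    delta <- 0
    for (i in seq_len(n)) {
      post <- posterior()
      vi <- post$Sigma[i, i]
      mi <- post$mu[i]
      tau_c <- 1 / vi - ttau[i]
      nu_c <- mi / vi - tnu[i]
      if (tau_c <= 0) next
      mc <- nu_c / tau_c; vc <- 1 / tau_c
      z <- y[i] * mc / sqrt(1 + vc)
      ratio <- exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
      dmu <- y[i] * ratio / sqrt(1 + vc)
      dbeta <- ratio * (z + ratio) / (1 + vc)
      denom <- 1 - vc * dbeta
      if (denom <= 1e-12) next
      tt_new <- max(dbeta / denom, 0)
      tn_new <- (dmu + mc * dbeta) / denom
      delta <- max(delta, abs(tt_new - ttau[i]), abs(tn_new - tnu[i]))
      ttau[i] <- tt_new
      tnu[i] <- tn_new
    }
    if (delta < tol) break
  }
  post <- posterior()
  list(ttau = ttau, tnu = tnu, Sigma = post$Sigma, mu = post$mu, K = K)
}

# predictive probabilities from the dense EP site parameters by direct algebra
oracle_ep_predict <- function(ep, X, newX, ls, sf2) {
  S <- diag(ep$ttau, nrow(X)) + diag(1e-12, nrow(X))
  A <- solve(ep$K + solve(S))
  Ks <- se_kernel(X, newX, sf2, ls)
  # mu* = k*' (K + S^-1)^-1 (S^-1 tnu), var* = k** - k*' (K + S^-1)^-1 k*
  mu_s <- drop(t(Ks) %*% A %*% solve(S) %*% ep$tnu)
  var_s <- sf2 - diag(t(Ks) %*% A %*% Ks)
  pnorm(mu_s / sqrt(1 + pmax(var_s, 1e-12)))
}

# brute-force two-sample KS statistic: evaluate both ECDFs at every sample
# point of either sample
oracle_ks_D <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(t) abs(mean(a <= t) - mean(b <= t)), 0))
}

# sphere SASA of an isolated atom is exactly 4 pi (r + probe)^2
oracle_isolated_sasa <- function(r, probe = 1.4) 4 * pi * (r + probe)^2
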