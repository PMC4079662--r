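#' Sparse probit Gaussian-process classification (informative vector machine)
#'
#' Binary crystallization outcomes are modelled with a probit link,
#' P(success | x) = Phi(f(x)), with a GP prior on the latent f using the same
#' ARD squared-exponential kernel as the regression model. The posterior is
#' approximated by Gaussian sites: an active subset of training points is
#' chosen greedily by entropy reduction with assumed-density-filtering (ADF)
#' site updates, and the site parameters on the active set are then refined
#' by expectation-propagation sweeps. Length scales of protein features are
#' typically frozen to their GPR values; remaining (solution-condition)
#' hyperparameters can be optimized on the approximate marginal likelihood by
#' conjugate-gradient search from Beta(0.5, 0.5)-stretched restarts.
#'
#' @param X Feature matrix or data frame (raw units; z-scored internally).
#' @param y01 Outcomes in {0, 1}.
#' @param fixed_lengths Named vector of length scales (z-scored units) to
#'   freeze, e.g. protein-feature scales from a trained GPR model. Features
#'   not named here are free.
#' @param d_active Active-set size; default `min(500, max(ceiling(n/10), 20))`,
#'   capped at n.
#' @param seed Integer seed (restart draws, tie-breaking).
#' @param sf2 Signal variance (fixed unless `optimize`).
#' @param free_ls Initial length scale for free features.
#' @param optimize Optimize free log length scales and log sf2 on the sparse
#'   marginal-likelihood approximation.
#' @param n_restarts,maxit Restart count and CG iteration cap when optimizing.
#' @param refine_sweeps EP refinement sweeps over the active set.
#' @param scale Z-score the features (default TRUE).
#' @return An object of class `gpc_model`.
#' @export
ivm_fit <- function(X, y01, fixed_lengths = NULL, d_active = NULL, seed = 1,
                    sf2 = 1, free_ls = 1, optimize = FALSE, n_restarts = 3,
                    maxit = 25, refine_sweeps = 10, scale = TRUE) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!all(y01 %in% c(0, 1))) stop("outcomes must be 0/1")
  if (all(y01 == 0) || all(y01 == 1)) stop("degenerate labels: all outcomes identical")
  n <- nrow(X)
  scaler <- NULL
  if (scale) {
    z <- zscore_fit_apply(X)
    X <- z$scaled
    scaler <- z$scaler
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(d_active)) d_active <- min(n, min(500, max(ceiling(n / 10), 20)))
  d_active <- min(d_active, n)
  y <- 2 * y01 - 1

  ls <- stats::setNames(rep(free_ls, ncol(X)), colnames(X))
  fixed_mask <- rep(FALSE, ncol(X))
  if (!is.null(fixed_lengths)) {
    idx <- match(names(fixed_lengths), colnames(X))
    if (any(is.na(idx))) stop("fixed_lengths name not in features")
    ls[idx] <- fixed_lengths
    fixed_mask[idx] <- TRUE
  }

  fit_once <- function(ls, sf2, seed_r) {
    act <- with_seed(seed_r, ivm_select(X, y, ls, sf2, d_active))
    ep <- ep_refine(X[act, , drop = FALSE], y[act], ls, sf2, refine_sweeps)
    list(active = act, ep = ep)
  }

  if (optimize && any(!fixed_mask)) {
    free <- which(!fixed_mask)
    base <- fit_once(ls, sf2, seed)
    act <- base$active
    Xa <- X[act, , drop = FALSE]
    ya <- y[act]
    obj <- function(th) {
      l2 <- ls
      l2[free] <- exp(th[seq_along(free)])
      s2 <- exp(th[length(free) + 1L])
      ep <- tryCatch(ep_refine(Xa, ya, l2, s2, refine_sweeps),
                     error = function(e) NULL)
      if (is.null(ep)) return(-1e10)
      ep$evidence
    }
    best <- NULL
    with_seed(seed, {
      for (r in seq_len(n_restarts)) {
        u <- stats::rbeta(length(free) + 1L, 0.5, 0.5)
        th0 <- c(log(0.05) + u[seq_along(free)] * (log(20) - log(0.05)),
                 log(0.2) + u[length(free) + 1L] * (log(5) - log(0.2)))
        fit <- tryCatch(stats::optim(th0, obj, method = "CG",
                                     control = list(fnscale = -1, maxit = maxit)),
                        error = function(e) NULL)
        if (!is.null(fit) && (is.null(best) || fit$value > best$value)) best <- fit
      }
    })
    if (!is.null(best)) {
      ls[free] <- exp(best$par[seq_along(free)])
      sf2 <- exp(best$par[length(free) + 1L])
    }
  }

  fin <- fit_once(ls, sf2, seed)
  model <- list(ls = ls, sf2 = sf2, fixed_mask = fixed_mask,
                X = X, y = y, scaler = scaler,
                active = fin$active, ttau = fin$ep$ttau, tnu = fin$ep$tnu,
                evidence = fin$ep$evidence, d_active = d_active, seed = seed)
  class(model) <- "gpc_model"
  model
}

#' @export
print.gpc_model <- function(x, ...) {
  cat(sprintf("<gpc_model> n = %d, d = %d, active = %d, evidence = %.3f\n",
              nrow(x$X), ncol(x$X), length(x$active), x$evidence))
  invisible(x)
}

# probit ADF moments at a Gaussian marginal (m, v) with label y in {-1, +1}
probit_moments <- function(y, m, v) {
  z <- y * m / sqrt(1 + v)
  lZ <- stats::pnorm(z, log.p = TRUE)
  ratio <- exp(stats::dnorm(z, log = TRUE) - lZ)
  alpha <- y * ratio / sqrt(1 + v)
  beta <- ratio * (z + ratio) / (1 + v)
  list(logZ = lZ, alpha = alpha, beta = beta)
}

# greedy entropy-reduction selection with ADF updates (full-covariance
# bookkeeping; adequate for the training sizes used here)
ivm_select <- function(X, y, ls, sf2, d_active) {
  n <- nrow(X)
  K <- se_kernel(X, X, sf2, ls)
  mu <- numeric(n)
  Sigma <- K
  remaining <- rep(TRUE, n)
  active <- integer(0)
  for (step in seq_len(d_active)) {
    idx <- which(remaining)
    mm <- probit_moments(y[idx], mu[idx], diag(Sigma)[idx])
    dH <- -0.5 * log1p(-pmin(mm$beta * diag(Sigma)[idx], 1 - 1e-12))
    pick <- idx[which.max(dH)]
    mmi <- probit_moments(y[pick], mu[pick], Sigma[pick, pick])
    s <- Sigma[, pick]
    mu <- mu + mmi$alpha * s
    Sigma <- Sigma - mmi$beta * tcrossprod(s)
    remaining[pick] <- FALSE
    active <- c(active, pick)
  }
  active
}

# EP refinement of site parameters on a (sub)set of points; returns site
# precisions/means and the EP approximate log marginal likelihood
ep_refine <- function(X, y, ls, sf2, sweeps = 10, tol = 1e-6) {
  n <- nrow(X)
  K <- se_kernel(X, X, sf2, ls)
  ttau <- numeric(n)
  tnu <- numeric(n)
  # sequential sweeps with rank-one posterior updates, full recompute between
  Sigma <- K
  mu <- numeric(n)
  for (sw in seq_len(max(sweeps, 1L))) {
    max_delta <- 0
    for (i in seq_len(n)) {
      vi <- Sigma[i, i]
      tau_c <- 1 / vi - ttau[i]
      nu_c <- mu[i] / vi - tnu[i]
      if (tau_c <= 0) next
      m_c <- nu_c / tau_c
      v_c <- 1 / tau_c
      mm <- probit_moments(y[i], m_c, v_c)
      denom <- 1 - v_c * mm$beta
      if (denom <= 1e-12) next
      ttau_new <- max(mm$beta / denom, 0)
      tnu_new <- (mm$alpha + m_c * mm$beta) / denom
      dtau <- ttau_new - ttau[i]
      dnu <- tnu_new - tnu[i]
      max_delta <- max(max_delta, abs(dtau), abs(dnu))
      r <- 1 + dtau * vi
      si <- Sigma[, i]
      mu <- mu + ((dnu - dtau * mu[i]) / r) * si
      Sigma <- Sigma - (dtau / r) * tcrossprod(si)
      ttau[i] <- ttau_new
      tnu[i] <- tnu_new
    }
    # stabilise: recompute posterior from the site parameters
    sr <- sqrt(ttau)
    B <- diag(n) + (sr %o% sr) * K
    LB <- chol(B)
    tmp <- backsolve(LB, forwardsolve(t(LB), sr * K))
    Sigma <- K - K %*% (sr * tmp)
    mu <- drop(Sigma %*% tnu)
    if (max_delta < tol) break
  }
  list(ttau = ttau, tnu = tnu,
       evidence = ep_evidence(K, y, ttau, tnu, Sigma, mu))
}

# EP approximate log marginal likelihood (Gaussian-integral identity plus
# per-site normalizers from the cavity distributions)
ep_evidence <- function(K, y, ttau, tnu, Sigma, mu) {
  n <- length(y)
  sr <- sqrt(ttau)
  B <- diag(n) + (sr %o% sr) * K
  LB <- chol(B)
  gauss <- -sum(log(diag(LB))) + 0.5 * sum(tnu * (Sigma %*% tnu))
  site <- 0
  for (i in seq_len(n)) {
    vi <- Sigma[i, i]
    tau_c <- 1 / vi - ttau[i]
    if (tau_c <= 0) next
    nu_c <- mu[i] / vi - tnu[i]
    m_c <- nu_c / tau_c
    v_c <- 1 / tau_c
    mm <- probit_moments(y[i], m_c, v_c)
    a <- 1 + ttau[i] * v_c
    site <- site + mm$logZ + 0.5 * log(a) -
      (2 * tnu[i] * m_c + tnu[i]^2 * v_c - ttau[i] * m_c^2) / (2 * a)
  }
  gauss + site
}

#' Predictive success probability
#'
#' Probit-link expectation under the approximate latent posterior:
#' P = Phi(mean / sqrt(1 + var)).
#'
#' @param model A `gpc_model`.
#' @param newX New inputs (raw units if the model carries a scaler). A named
#'   vector is treated as a single row.
#' @return Numeric vector of success probabilities in (0, 1).
#' @export
predict_probability <- function(model, newX) {
  if (is.null(dim(newX))) newX <- matrix(newX, nrow = 1, dimnames = list(NULL, names(newX)))
  newX <- as.matrix(newX)
  if (!is.null(model$scaler)) newX <- zscore_apply(newX, model$scaler)
  if (ncol(newX) != ncol(model$X)) stop("dimension mismatch")
  Xa <- model$X[model$active, , drop = FALSE]
  K <- se_kernel(Xa, Xa, model$sf2, model$ls)
  sr <- sqrt(model$ttau)
  n <- length(model$active)
  B <- diag(n) + (sr %o% sr) * K
  LB <- chol(B)
  zvec <- sr * backsolve(LB, forwardsolve(t(LB), sr * (K %*% model$tnu)))
  Ks <- se_kernel(Xa, newX, model$sf2, model$ls)
  fmu <- drop(crossprod(Ks, model$tnu - zvec))
  v <- forwardsolve(t(LB), sr * Ks)
  fvar <- pmax(model$sf2 - colSums(v^2), 1e-12)
  stats::pnorm(fmu / sqrt(1 + fvar))
}

#' Crystallization probability versus additive concentration
#'
#' For each concentration on the grid, builds the solution feature vector of
#' a cocktail at neutral pH containing only the given additive (IS, HS+/-,
#' DEP recomputed from the registry) and evaluates the model's predicted
#' success probability for the given protein.
#'
#' @param model A `gpc_model` trained on the joint protein + cocktail space.
#' @param protein_features Named vector of the protein's features (must cover
#'   the protein features the model uses; its `Rg` entry feeds DEP).
#' @param additive Registry species name.
#' @param grid Increasing concentration grid in molar; should stay within the
#'   training range (a warning is issued otherwise, since far-from-data
#'   predictions are essentially meaningless).
#' @param pH Solution pH for the probe cocktails (default 7, neutral).
#' @param registry Species registry.
#' @param train_max Largest training concentration of the additive, used for
#'   the out-of-range warning (optional).
#' @return Object of class `response_curve`: data.frame (`conc`, `prob`) with
#'   the quadratic fit attached (see [fit_quadratic()]).
#' @export
additive_response_curve <- function(model, protein_features, additive, grid,
                                    pH = 7, registry = build_registry(),
                                    train_max = NULL) {
  if (!additive %in% registry$name) stop("unknown additive: ", additive)
  if (is.unsorted(grid)) grid <- sort(grid)
  if (!is.null(train_max) && any(grid > train_max)) {
    warning("grid exceeds the training concentration range for ", additive,
            "; predictions out there are essentially meaningless")
  }
  if (is.data.frame(protein_features)) {
    num <- vapply(protein_features, is.numeric, TRUE)
    protein_features <- unlist(protein_features[1, num, drop = FALSE])
  }
  Rg <- unname(protein_features[["Rg"]])
  model_cols <- if (!is.null(model$scaler)) model$scaler$kept else colnames(model$X)
  probs <- vapply(grid, function(cc) {
    ck <- cocktail_feature_vector(stats::setNames(cc, additive), Rg = Rg,
                                  pH = pH, registry = registry)
    full <- c(protein_features[setdiff(names(protein_features), names(ck))], ck)
    missing_cols <- setdiff(model_cols, names(full))
    if (length(missing_cols)) {
      stop("protein features do not cover model inputs: ",
           paste(utils::head(missing_cols, 5), collapse = ", "))
    }
    predict_probability(model, full[model_cols])
  }, 0)
  curve <- data.frame(conc = grid, prob = probs)
  attr(curve, "additive") <- additive
  class(curve) <- c("response_curve", "data.frame")
  qfit <- fit_quadratic(curve)
  attr(curve, "quadratic") <- qfit
  curve
}

#' Quadratic characterization of a response curve
#'
#' Ordinary least squares of P on (1, c, c^2). p0 is the crystallization
#' probability without the additive; the (p1, p2) pair classifies the trend:
#' interior-max (crystallizes best at intermediate concentration),
#' interior-min (best at very low or very high concentration), or monotone.
#' Monotone-decreasing curves are flagged excluded, mirroring how purely
#' suppressive additives are dropped from the trend analysis.
#'
#' @param curve A `response_curve` or data.frame with `conc` and `prob`.
#' @return List: `p0`, `p1`, `p2`, `class`, `excluded`.
#' @export
fit_quadratic <- function(curve) {
  cc <- curve$conc
  P <- curve$prob
  if (length(unique(cc)) < 3L) stop("need >= 3 distinct grid points")
  Xd <- cbind(1, cc, cc^2)
  co <- drop(solve(crossprod(Xd), crossprod(Xd, P)))
  p0 <- co[1]; p1 <- co[2]; p2 <- co[3]
  eps <- 1e-12
  rng <- range(cc)
  cls <- NULL
  if (abs(p2) > eps) {
    vert <- -p1 / (2 * p2)
    if (vert > rng[1] && vert < rng[2]) {
      cls <- if (p2 < 0) "interior-max" else "interior-min"
    }
  }
  if (is.null(cls)) {
    slope <- (p1 + p2 * (rng[1] + rng[2]))  # mean slope over the range
    cls <- if (slope > eps) "monotone-increasing" else "monotone-decreasing"
  }
  list(p0 = unname(p0), p1 = unname(p1), p2 = unname(p2), class = cls,
       excluded = cls == "monotone-decreasing")
}

#' Optimal additive concentration
#'
#' Argmax of the response curve over the grid; `improves` flags whether the
#' best concentration beats the no-additive probability by more than the
#' tolerance.
#'
#' @inheritParams additive_response_curve
#' @param tolerance Minimum absolute probability gain to count as improvement.
#' @return List: `c_star`, `p_star`, `p0`, `improves`, `curve`.
#' @export
optimal_condition <- function(model, protein_features, additive, grid,
                              tolerance = 0.01, pH = 7,
                              registry = build_registry(), train_max = NULL) {
  if (!0 %in% grid) grid <- sort(c(0, grid))
  curve <- additive_response_curve(model, protein_features, additive, grid,
                                   pH = pH, registry = registry,
                                   train_max = train_max)
  i <- which.max(curve$prob)
  p0 <- curve$prob[curve$conc == 0][1]
  list(c_star = curve$conc[i], p_star = curve$prob[i], p0 = p0,
       improves = curve$prob[i] > p0 + tolerance, curve = curve)
}

#' Concentration grid for an additive
#'
#' 25 points from 0 to the 95th percentile of the positive training
#' concentrations, log-spaced above a small floor.
#'
#' @param train_conc Training concentrations of the additive (M).
#' @param n Grid size.
#' @return Increasing numeric grid starting at 0.
#' @export
make_conc_grid <- function(train_conc, n = 25) {
  pos <- train_conc[train_conc > 0]
  if (!length(pos)) stop("additive never occurs in the training set")
  hi <- stats::quantile(pos, 0.95, names = FALSE)
  lo <- hi / 100
  c(0, exp(seq(log(lo), log(hi), length.out = n - 1L)))
}

#' Split proteins by mean observed propensity
#'
#' @param pi Observed propensities.
#' @return Character vector "high"/"low" relative to the arithmetic mean.
#' @export
split_by_propensity <- function(pi) ifelse(pi >= mean(pi), "high", "low")
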