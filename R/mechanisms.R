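#' Assign proteins to sGRAVY-sSCE quadrants
#'
#' The sGRAVY-sSCE plane is split at the reference means. With the default
#' orientation, Q1 is the low-sGRAVY / high-sSCE quadrant (electrostatic
#' mechanism side), Q2 high/high, Q3 high-sGRAVY / low-sSCE (entropic /
#' hydrophobic side), Q4 low/low. The orientation is a single config constant
#' because the field's quadrant labelling conventions differ; every report
#' should carry it. Points exactly on a boundary take the lowest matching
#' quadrant index.
#'
#' @param features Data frame with `sGRAVY` and `sSCE` (and optionally
#'   `protein_id`).
#' @param reference_means Named vector `c(sGRAVY = ..., sSCE = ...)`; defaults
#'   to the dataset means.
#' @param orientation Either "Q1_high_sSCE" (default) or "Q1_low_sSCE"
#'   (swaps Q1<->Q3 and Q2<->Q4).
#' @return Data frame: `protein_id`, `quadrant`, `sGRAVY`, `sSCE`, with the
#'   reference means and orientation as attributes.
#' @export
assign_quadrants <- function(features, reference_means = NULL,
                             orientation = c("Q1_high_sSCE", "Q1_low_sSCE")) {
  orientation <- match.arg(orientation)
  if (is.null(reference_means)) {
    reference_means <- c(sGRAVY = mean(features$sGRAVY), sSCE = mean(features$sSCE))
  }
  if (!all(is.finite(reference_means))) stop("reference means must be finite")
  dx <- sign(features$sGRAVY - reference_means[["sGRAVY"]])
  dy <- sign(features$sSCE - reference_means[["sSCE"]])
  # quadrant index per (dx, dy); boundary (0) matches both sides -> min index
  quad_of <- function(dx, dy) {
    cand <- c(
      if (dx <= 0 && dy >= 0) 1L,
      if (dx >= 0 && dy >= 0) 2L,
      if (dx >= 0 && dy <= 0) 3L,
      if (dx <= 0 && dy <= 0) 4L
    )
    min(cand)
  }
  q <- mapply(quad_of, dx, dy)
  if (orientation == "Q1_low_sSCE") q <- c(3L, 4L, 1L, 2L)[q]
  ids <- if ("protein_id" %in% names(features)) features$protein_id else seq_len(nrow(features))
  out <- data.frame(protein_id = ids, quadrant = paste0("Q", q),
                    sGRAVY = features$sGRAVY, sSCE = features$sSCE,
                    stringsAsFactors = FALSE)
  attr(out, "reference_means") <- reference_means
  attr(out, "orientation") <- orientation
  out
}

# recompute composition-dependent features after a grid move: renormalize the
# 20 coverage fractions onto the simplex and rederive category fractions and
# the surface scale means
enforce_composition <- function(x) {
  aas <- amino_acids()
  fcols <- paste0("frac_", aas)
  if (!all(fcols %in% names(x))) return(x)
  fr <- pmax(as.numeric(x[fcols]), 0)
  tot <- sum(fr)
  if (tot <= 0) fr <- rep(1 / 20, 20) else fr <- fr / tot
  x[fcols] <- fr
  tab <- residue_scales()
  sc_g <- stats::setNames(tab$gravy, tab$aa)[aas]
  sc_s <- stats::setNames(tab$sce, tab$aa)[aas]
  sc_p <- stats::setNames(tab$pol, tab$aa)[aas]
  cats <- residue_categories()[aas]
  for (cc in .categories) {
    nm <- paste0("cat_", cc)
    if (nm %in% names(x)) x[nm] <- sum(fr[cats == cc])
  }
  if ("sGRAVY" %in% names(x)) x["sGRAVY"] <- sum(fr * sc_g)
  if ("sSCE" %in% names(x)) x["sSCE"] <- sum(fr * sc_s)
  if ("sPOL" %in% names(x)) x["sPOL"] <- sum(fr * sc_p)
  x
}

#' Hot-spot search over constrained feature space
#'
#' Starting from the observed proteins in the top propensity percentile, lays
#' a grid over feature space: features deemed significant by the length-scale
#' rule take four equidistant values across their observed (physical) range,
#' all other features sit at the mid value of their range. Surface residue
#' composition is kept on the 20-simplex by renormalization and the dependent
#' features (category fractions, sGRAVY, sSCE, sPOL) are recomputed after each
#' move. For each start, grid points whose predicted propensity is at least
#' the start's are returned, ranked by predicted propensity.
#'
#' @param model A trained `gpr_model` (carrying its scaler).
#' @param features Feature data frame in raw units (training proteins).
#' @param observed_pi Observed propensities aligned with `features`.
#' @param percentile Top percentile (0..100, exclusive) defining the starts.
#' @param n_grid Values per significant dimension (default 4).
#' @param max_significant Cap on gridded dimensions (most relevant first), to
#'   keep the enumeration tractable.
#' @return Data.frame: `start_id`, predicted propensity `pred_pi`, and the
#'   grid-point features; ranked by predicted propensity within each start.
#' @export
hotspot_search <- function(model, features, observed_pi, percentile = 5,
                           n_grid = 4, max_significant = 6) {
  if (percentile <= 0 || percentile >= 100) stop("percentile must be in (0, 100)")
  thr <- stats::quantile(observed_pi, 1 - percentile / 100, names = FALSE)
  starts <- which(observed_pi >= thr)
  if (!length(starts)) stop("no protein above the percentile threshold")

  feats <- as.data.frame(features)[, model$scaler$kept, drop = FALSE]
  sig <- significant_variables(model)
  sig_feats <- utils::head(sig$feature[sig$significant], max_significant)
  rng <- lapply(feats, range)

  axis <- lapply(names(feats), function(nm) {
    r <- rng[[nm]]
    if (nm %in% sig_feats) seq(r[1], r[2], length.out = n_grid) else mean(r)
  })
  names(axis) <- names(feats)
  grid <- expand.grid(axis, KEEP.OUT.ATTRS = FALSE)
  grid <- as.data.frame(t(apply(grid, 1, enforce_composition)))
  names(grid) <- names(feats)

  pred <- prop_inverse(gpr_predict(model, grid)$mean)
  out <- NULL
  for (s in starts) {
    start_row <- enforce_composition(unlist(feats[s, , drop = TRUE]))
    p_start <- prop_inverse(gpr_predict(model, matrix(start_row, nrow = 1,
                                                      dimnames = list(NULL, names(feats))))$mean)
    keep <- which(pred >= p_start)
    if (!length(keep)) next
    ord <- keep[order(pred[keep], decreasing = TRUE)]
    out <- rbind(out, cbind(data.frame(start_id = s, pred_pi = pred[ord]),
                            grid[ord, , drop = FALSE]))
  }
  if (is.null(out)) {
    out <- cbind(data.frame(start_id = integer(0), pred_pi = numeric(0)),
                 grid[0, , drop = FALSE])
  }
  rownames(out) <- NULL
  attr(out, "significant") <- sig_feats
  out
}

#' Project predicted propensity onto the sGRAVY-sSCE plane
#'
#' Bin-wise arithmetic mean of the predicted propensity over a regular 2-D
#' binning of (sGRAVY, sSCE).
#'
#' @param points Data frame with `sGRAVY`, `sSCE` and `pred_pi` (e.g. from
#'   [hotspot_search()]).
#' @param bins Number of bins per axis.
#' @return Data frame: `bin_x`, `bin_y` (bin centres), `mean`, `count`.
#' @export
project_propensity <- function(points, bins = 20) {
  if (!nrow(points)) stop("no points to project")
  bx <- seq(min(points$sGRAVY), max(points$sGRAVY), length.out = bins + 1L)
  by <- seq(min(points$sSCE), max(points$sSCE), length.out = bins + 1L)
  ix <- pmin(findInterval(points$sGRAVY, bx, rightmost.closed = TRUE), bins)
  iy <- pmin(findInterval(points$sSCE, by, rightmost.closed = TRUE), bins)
  key <- paste(ix, iy)
  agg <- tapply(points$pred_pi, key, mean)
  cnt <- tapply(points$pred_pi, key, length)
  ij <- do.call(rbind, strsplit(names(agg), " "))
  data.frame(bin_x = (bx[as.integer(ij[, 1])] + bx[as.integer(ij[, 1]) + 1L]) / 2,
             bin_y = (by[as.integer(ij[, 2])] + by[as.integer(ij[, 2]) + 1L]) / 2,
             mean = as.numeric(agg), count = as.integer(cnt))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum of the absolute difference between the two empirical
#' CDFs; the p-value uses the asymptotic Kolmogorov distribution with the
#' standard effective-sample-size correction.
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs >= 2 values")
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(t) mean(a <= t), 0)
  Fb <- vapply(pts, function(t) mean(b <= t), 0)
  D <- max(abs(Fa - Fb))
  ne <- length(a) * length(b) / (length(a) + length(b))
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(D = D, p = min(max(p, .Machine$double.xmin), 1))
}

#' Kolmogorov-Smirnov enrichment tables
#'
#' Within each quadrant, compares easy- versus hard-to-crystallize proteins
#' (by default the top and bottom quartiles of predicted propensity over the
#' whole set) feature by feature with two-sample KS tests; rows with p below
#' alpha are reported with the direction given by the group medians. Quadrants
#' with a group below the minimum size are skipped with a notice.
#'
#' @param assignments Quadrant assignments from [assign_quadrants()].
#' @param predicted_pi Predicted propensities aligned with `assignments`.
#' @param feature_table Data frame of features to compare (aligned rows).
#' @param easy_hard_rule Quantile pair `c(hard_below, easy_above)` on the
#'   predicted-propensity distribution (default quartiles).
#' @param alpha Significance threshold (default 0.05).
#' @param min_group Minimum group size per comparison (default 10).
#' @param adjust Optional p-value adjustment method (e.g. "BH"); default
#'   "none", mirroring per-feature reporting.
#' @return Data frame: `quadrant`, `feature`, `D`, `p`, `direction`; skipped
#'   quadrants are listed in attribute `skipped`.
#' @export
enrichment_tables <- function(assignments, predicted_pi, feature_table,
                              easy_hard_rule = c(0.25, 0.75), alpha = 0.05,
                              min_group = 10, adjust = "none") {
  qs <- stats::quantile(predicted_pi, easy_hard_rule, names = FALSE)
  grp <- rep(NA_character_, length(predicted_pi))
  grp[predicted_pi <= qs[1]] <- "hard"
  grp[predicted_pi >= qs[2]] <- "easy"
  out <- NULL
  skipped <- character(0)
  for (qd in sort(unique(assignments$quadrant))) {
    in_q <- assignments$quadrant == qd
    easy <- which(in_q & grp == "easy")
    hard <- which(in_q & grp == "hard")
    if (length(easy) < min_group || length(hard) < min_group) {
      skipped <- c(skipped, qd)
      message("quadrant ", qd, " below the minimum group size; skipped")
      next
    }
    rows <- lapply(names(feature_table), function(ft) {
      ks <- ks_two_sample(feature_table[[ft]][easy], feature_table[[ft]][hard])
      dir <- if (stats::median(feature_table[[ft]][easy]) >
                 stats::median(feature_table[[ft]][hard])) "enriched" else "depleted"
      data.frame(quadrant = qd, feature = ft, D = ks$D, p = ks$p,
                 direction = dir, stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    rows$p <- stats::p.adjust(rows$p, method = adjust)
    out <- rbind(out, rows[rows$p < alpha, , drop = FALSE])
  }
  if (is.null(out)) {
    out <- data.frame(quadrant = character(0), feature = character(0),
                      D = numeric(0), p = numeric(0), direction = character(0))
  }
  attr(out, "skipped") <- skipped
  out
}
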