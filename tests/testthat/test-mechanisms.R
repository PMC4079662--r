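test_that("quadrant assignment splits the plane at the reference means", {
  f <- data.frame(protein_id = paste0("P", 1:4),
                  sGRAVY = c(-1, 1, 1, -1), sSCE = c(1, 1, -1, -1))
  q <- assign_quadrants(f, reference_means = c(sGRAVY = 0, sSCE = 0))
  expect_equal(q$quadrant, c("Q1", "Q2", "Q3", "Q4"))
  expect_equal(attr(q, "orientation"), "Q1_high_sSCE")
})

test_that("boundary points take the lowest quadrant index", {
  f <- data.frame(sGRAVY = c(0, 0, -1, 1), sSCE = c(0, 1, 0, 0))
  q <- assign_quadrants(f, reference_means = c(sGRAVY = 0, sSCE = 0))
  expect_equal(q$quadrant, c("Q1", "Q1", "Q1", "Q2"))
})

test_that("the orientation constant swaps opposite quadrants", {
  f <- data.frame(sGRAVY = c(-1, 1, 1, -1), sSCE = c(1, 1, -1, -1))
  q1 <- assign_quadrants(f, reference_means = c(sGRAVY = 0, sSCE = 0))
  q2 <- assign_quadrants(f, reference_means = c(sGRAVY = 0, sSCE = 0),
                         orientation = "Q1_low_sSCE")
  expect_equal(q2$quadrant, c("Q3", "Q4", "Q1", "Q2"))
  expect_equal(q1$quadrant, c("Q1", "Q2", "Q3", "Q4"))
})

test_that("KS statistic equals the brute-force oracle on small samples", {
  set.seed(21)
  for (rep in 1:200) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    a <- round(rnorm(na), 1)  # rounding forces ties across samples
    b <- round(rnorm(nb), 1)
    got <- ks_two_sample(a, b)
    expect_equal(got$D, oracle_ks_D(a, b))
  }
})

test_that("KS p-values match stats::ks.test in the tie-free case", {
  set.seed(22)
  a <- rnorm(40); b <- rnorm(35, 0.5)
  got <- ks_two_sample(a, b)
  ref <- suppressWarnings(stats::ks.test(a, b))
  expect_equal(got$D, unname(ref$statistic))
  # asymptotic-with-correction vs exact: same order of magnitude is enough
  expect_lt(abs(log10(got$p) - log10(ref$p.value)), 0.5)
  expect_error(ks_two_sample(1, c(1, 2)), ">= 2")
})

test_that("enrichment tables flag planted distributional shifts", {
  set.seed(23)
  n <- 120
  quads <- data.frame(protein_id = seq_len(n),
                      quadrant = rep(c("Q1", "Q3"), each = n / 2),
                      sGRAVY = rnorm(n), sSCE = rnorm(n))
  pred <- runif(n)
  ft <- data.frame(shifted = rnorm(n) + 3 * (pred >= 0.75),
                   null_feature = rnorm(n))
  out <- enrichment_tables(quads, pred, ft, min_group = 5)
  expect_true("shifted" %in% out$feature)
  expect_true(all(out$direction[out$feature == "shifted"] == "enriched"))
  expect_false(any(out$feature == "null_feature" & out$p < 1e-4))
})

test_that("small quadrants are skipped with a notice", {
  set.seed(24)
  n <- 40
  quads <- data.frame(protein_id = seq_len(n),
                      quadrant = c(rep("Q1", 38), "Q2", "Q2"),
                      sGRAVY = rnorm(n), sSCE = rnorm(n))
  pred <- runif(n)
  ft <- data.frame(x = rnorm(n))
  expect_message(out <- enrichment_tables(quads, pred, ft, min_group = 3),
                 "skipped")
  expect_true("Q2" %in% attr(out, "skipped"))
})

test_that("composition is re-normalized after grid moves", {
  spec <- synthetic_screen_spec(n_proteins = 10, n_cocktails = 8, seed = 2)
  pr <- generate_protein_table(spec)$proteins
  x <- unlist(pr[1, -1])
  x["frac_A"] <- x["frac_A"] + 0.5  # knock the composition off the simplex
  y <- xtalgp:::enforce_composition(x)
  aas <- amino_acids()
  expect_equal(sum(y[paste0("frac_", aas)]), 1, tolerance = 1e-12)
  tab <- residue_scales()
  sc <- stats::setNames(tab$sce, tab$aa)[aas]
  expect_equal(unname(y["sSCE"]), sum(y[paste0("frac_", aas)] * sc),
               tolerance = 1e-12)
})

test_that("hotspot search returns simplex-valid points above the start", {
  set.seed(25)
  spec <- synthetic_screen_spec(n_proteins = 50, n_cocktails = 8, seed = 3)
  pr <- generate_protein_table(spec)$proteins
  pi_obs <- gp_truth <- generate_protein_table(spec)$truth$true_propensity
  cols <- c("sSCE", "sGRAVY", "cat_S", "pI", "Rg")
  m <- gpr_train(as.matrix(pr[, cols]), prop_transform(pi_obs),
                 n_restarts = 4, seed = 1, maxit = 80)
  hs <- hotspot_search(m, pr[, cols], pi_obs, percentile = 10, n_grid = 4)
  expect_true(all(c("start_id", "pred_pi") %in% names(hs)))
  if (nrow(hs)) {
    # ranked by predicted propensity within each start
    for (s in unique(hs$start_id)) {
      expect_false(is.unsorted(rev(hs$pred_pi[hs$start_id == s])))
    }
  }
  expect_lte(length(attr(hs, "significant")), 6)
})

test_that("propensity projection averages within bins", {
  pts <- data.frame(sGRAVY = c(0.1, 0.1, 0.9), sSCE = c(0.1, 0.1, 0.9),
                    pred_pi = c(0.2, 0.4, 0.8))
  pj <- project_propensity(pts, bins = 2)
  expect_equal(nrow(pj), 2)
  expect_equal(sort(pj$mean), c(0.3, 0.8))
  expect_equal(sum(pj$count), 3)
})
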