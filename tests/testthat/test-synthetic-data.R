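test_that("spec validation names the offending field", {
  expect_error(synthetic_screen_spec(n_proteins = 1), "n_proteins")
  expect_error(synthetic_screen_spec(n_cocktails = 0), "n_cocktails")
  expect_error(synthetic_screen_spec(mechanism_weights = c(0, 0)), "mechanism_weights")
  expect_error(synthetic_screen_spec(noise_sd = -1), "noise_sd")
})

spec <- synthetic_screen_spec(n_proteins = 60, n_cocktails = 128, seed = 5)
gp <- generate_protein_table(spec)
ck <- generate_cocktail_table(spec)

test_that("protein table covers the schema with valid compositions", {
  pr <- gp$proteins
  expect_equal(names(pr), c("protein_id", protein_feature_schema()))
  expect_equal(nrow(pr), 60)
  fr <- as.matrix(pr[, paste0("frac_", amino_acids())])
  expect_lt(max(abs(rowSums(fr) - 1)), 1e-12)
  expect_true(all(fr >= 0))
  cat_cols <- paste0("cat_", c("S", "pos", "neg", "P", "H"))
  expect_lt(max(abs(rowSums(as.matrix(pr[, cat_cols])) - 1)), 1e-12)
  pair_cols <- paste0("pair_", xtalgp:::category_pairs())
  expect_lt(max(abs(rowSums(as.matrix(pr[, pair_cols])) - 1)), 1e-12)
  # surface scale means are recomputed from the composition, never sampled
  tab <- residue_scales()
  sc <- stats::setNames(tab$sce, tab$aa)[amino_acids()]
  expect_lt(max(abs(pr$sSCE - drop(fr %*% sc))), 1e-10)
  expect_true(all(pr$pI >= 3 & pr$pI <= 12))
  expect_true(all(pr$Rg > 0 & pr$SASA > 0))
})

test_that("planted truth covers every protein with sane propensities", {
  tr <- gp$truth
  expect_s3_class(tr, "planted_truth")
  expect_equal(names(tr$true_propensity), gp$proteins$protein_id)
  expect_true(all(tr$true_propensity > 0 & tr$true_propensity < 1))
  expect_setequal(tr$relevant_features, planted_relevant_features())
  expect_equal(names(tr$true_length_scales), tr$relevant_features)
  # recovery panel: the 5 planted plus 15 others, all in the protein schema
  panel <- recovery_feature_set()
  expect_length(panel, 20)
  expect_true(all(panel %in% protein_feature_schema()))
  expect_true(all(planted_relevant_features() %in% panel))
})

test_that("generators are deterministic in the spec seed", {
  gp2 <- generate_protein_table(spec)
  expect_identical(gp$proteins, gp2$proteins)
  ck2 <- generate_cocktail_table(spec)
  expect_identical(ck, ck2)
  spec2 <- synthetic_screen_spec(n_proteins = 60, n_cocktails = 128, seed = 6)
  expect_false(identical(generate_protein_table(spec2)$proteins, gp$proteins))
})

test_that("cocktail table has two families with expected chemistry", {
  reg <- build_registry()
  expect_equal(nrow(ck), 128)
  expect_setequal(unique(ck$family), c("salt", "peg"))
  conc <- as.matrix(ck[, reg$name])
  expect_true(all(conc >= 0))
  peg_cols <- reg$name[reg$kind == "PEG"]
  # salt-only family has no PEG; peg family has exactly one PEG
  expect_true(all(rowSums(conc[ck$family == "salt", peg_cols] > 0) == 0))
  expect_true(all(rowSums(conc[ck$family == "peg", peg_cols] > 0) == 1))
  # at most 4 species per cocktail
  expect_lte(max(rowSums(conc > 0)), 4)
  expect_true(all(ck$pH >= 3 & ck$pH <= 11))
  # acid-leaning truncated normal: mean near 6.8
  expect_lt(abs(mean(ck$pH) - 6.8), 0.5)
})

test_that("outcome marginals honour the planted propensity", {
  oc <- generate_outcomes(gp$proteins, ck, gp$truth, seed = 5)
  expect_equal(nrow(oc), 60 * 128)
  expect_true(all(oc$outcome %in% c(0L, 1L)))
  obs <- observed_propensity(oc)[gp$proteins$protein_id]
  tp <- gp$truth$true_propensity
  # the tilt is centred and amplitude-capped, so each observed propensity sits
  # within 4 binomial standard errors of its planted value
  band <- 4 * sqrt(tp * (1 - tp) / 128)
  expect_true(all(abs(obs - tp) <= pmax(band, 1e-12)))
  expect_gt(cor(obs, tp), 0.9)
})

test_that("outcomes are reproducible and reject mismatched truth", {
  oc1 <- generate_outcomes(gp$proteins, ck, gp$truth, seed = 9)
  oc2 <- generate_outcomes(gp$proteins, ck, gp$truth, seed = 9)
  expect_identical(oc1, oc2)
  bad <- gp$truth
  bad$true_propensity <- bad$true_propensity[-1]
  expect_error(generate_outcomes(gp$proteins, ck, bad, seed = 1), "mismatch")
  expect_error(generate_outcomes(gp$proteins[0, ], ck, gp$truth), "empty")
})

test_that("linear latent option produces a distinct truth surface", {
  spl <- synthetic_screen_spec(n_proteins = 60, n_cocktails = 16, seed = 5,
                               latent = "linear")
  gpl <- generate_protein_table(spl)
  expect_equal(gpl$truth$latent, "linear")
  # same seed, same features, different propensity surface
  expect_identical(gpl$proteins, gp$proteins)
  expect_false(isTRUE(all.equal(gpl$truth$true_propensity,
                                gp$truth$true_propensity)))
})
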