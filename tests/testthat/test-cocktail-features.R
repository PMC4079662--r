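reg <- build_registry()

test_that("ionic strength follows the half-sum of c z^2", {
  expect_equal(ionic_strength(c(sodium = 0.1, chloride = 0.1), reg), 0.1)
  # 0.05 M MgCl2: 0.5 * (0.05*4 + 0.10*1) = 0.15
  expect_equal(ionic_strength(c(magnesium = 0.05, chloride = 0.10), reg), 0.15)
  # PEGs are uncharged and contribute nothing
  expect_equal(ionic_strength(c(peg_4000 = 0.1), reg), 0)
  expect_equal(ionic_strength(numeric(0), reg), 0)
})

test_that("hofmeister index maps the rank extremes onto +1 and -1", {
  h_cat <- xtalgp:::hofmeister_index(reg, "cation")
  expect_equal(unname(h_cat[which(reg$hofmeister_rank[reg$kind == "cation"] == 1)]), 1)
  expect_equal(unname(h_cat[which(reg$hofmeister_rank[reg$kind == "cation"] == 19)]), -1)
  expect_equal(sort(unique(h_cat)), seq(-1, 1, length.out = 19), tolerance = 1e-12)
})

test_that("unranked anions receive the median rank with a message", {
  expect_message(h_an <- xtalgp:::hofmeister_index(reg, "anion", warn = TRUE))
  ranked <- !is.na(reg$hofmeister_rank[reg$kind == "anion"])
  h_med <- 1 - 2 * (stats::median(1:18) - 1) / (18 - 1)
  expect_true(all(abs(h_an[!ranked] - h_med) < 1e-12))
})

test_that("hofmeister sums split by ion sign", {
  hs <- hofmeister_coefficients(c(ammonium = 0.2, chloride = 0.3), reg)
  h_cat <- xtalgp:::hofmeister_index(reg, "cation")
  h_an <- xtalgp:::hofmeister_index(reg, "anion")
  expect_equal(unname(hs["HSpos"]), unname(0.2 * h_cat["ammonium"]))
  expect_equal(unname(hs["HSneg"]), unname(0.3 * h_an["chloride"]))
})

test_that("depletion coefficient follows the excluded-volume form", {
  Rg <- 20
  conc <- 0.01
  for (peg in c("peg_1000", "peg_8000")) {
    M <- reg$peg_mass[reg$name == peg]
    rdep <- 12.1 * (M / 1000)^0.588
    want <- conc * (1 + rdep / Rg)^3
    expect_equal(depletion_coefficient(stats::setNames(conc, peg), Rg, reg), want)
  }
  # PEG-1000 has depletion radius exactly r0
  expect_equal(depletion_coefficient(c(peg_1000 = 1), Rg, reg), (1 + 12.1 / 20)^3)
  # salts contribute nothing
  expect_equal(depletion_coefficient(c(sodium = 2, chloride = 2), Rg, reg), 0)
})

test_that("depletion grows with PEG mass at fixed molarity", {
  Rg <- 18
  pegs <- reg$name[reg$kind == "PEG"]
  dep <- vapply(pegs, function(p) depletion_coefficient(stats::setNames(0.01, p), Rg, reg), 0)
  expect_true(all(diff(dep) > 0))
})

test_that("cocktail feature vector has schema order and correct summaries", {
  cv <- cocktail_feature_vector(c(sodium = 1, chloride = 1, peg_4000 = 0.002),
                                Rg = 18, pH = 6.5, registry = reg)
  expect_equal(names(cv), cocktail_feature_schema())
  expect_equal(unname(cv["pH"]), 6.5)
  expect_equal(unname(cv["IS"]), 1)
  expect_equal(unname(cv["sodium"]), 1)
  expect_equal(unname(cv["peg_4000"]), 0.002)
  expect_equal(sum(cv[reg$name] != 0), 3)
})

test_that("unknown species and negative concentrations are rejected", {
  expect_error(cocktail_feature_vector(c(unobtainium = 1), Rg = 18, registry = reg),
               "unknown")
  expect_error(cocktail_feature_vector(c(sodium = -0.1), Rg = 18, registry = reg),
               "negative")
})

test_that("featurization is additive in ionic strength over mixtures", {
  a <- cocktail_feature_vector(c(sodium = 0.5, chloride = 0.5), Rg = 18, registry = reg)
  b <- cocktail_feature_vector(c(potassium = 0.2, sulfate = 0.1), Rg = 18, registry = reg)
  ab <- cocktail_feature_vector(c(sodium = 0.5, chloride = 0.5,
                                  potassium = 0.2, sulfate = 0.1),
                                Rg = 18, registry = reg)
  expect_equal(unname(ab["IS"]), unname(a["IS"] + b["IS"]))
  expect_equal(unname(ab["HSpos"]), unname(a["HSpos"] + b["HSpos"]))
  expect_equal(unname(ab["HSneg"]), unname(a["HSneg"] + b["HSneg"]))
})
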