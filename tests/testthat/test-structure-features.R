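test_that("toy PDB text round-trips through the parser", {
  pdb <- generate_toy_structure(c("LYS", "GLY", "TRP"), cell = c(30, 30, 30, 90, 90, 90))
  st <- parse_structure(pdb)
  expect_s3_class(st, "xtal_structure")
  expect_equal(nrow(st$residues), 3)
  expect_equal(st$residues$resname, c("LYS", "GLY", "TRP"))
  expect_equal(st$residues$aa, c("K", "G", "W"))
  # 4 backbone atoms per residue + side-chain heavy atoms 5/0/10
  expect_equal(nrow(st$atoms), 12 + 15)
  expect_equal(unname(st$cell), c(30, 30, 30, 90, 90, 90))
  expect_length(st$symmetry_ops, 1)
  expect_equal(st$symmetry_ops[[1]], cbind(diag(3), 0), ignore_attr = TRUE)
})

test_that("unknown residue codes are rejected by the generator", {
  expect_error(generate_toy_structure(c("ALA", "XYZ")), "unknown residue")
})

test_that("altloc policy keeps the highest-occupancy conformer", {
  txt <- paste(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    sep = "\n")
  st <- parse_structure(txt)
  expect_equal(nrow(st$atoms), 2)
  expect_equal(st$atoms$x[1], 1.0)  # conformer B wins on occupancy
})

test_that("isolated-atom SASA equals the analytic sphere area", {
  txt <- "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C"
  st <- parse_structure(txt)
  s <- compute_sasa(st, n_sphere_points = 960)
  want <- oracle_isolated_sasa(1.70)
  expect_equal(as.numeric(s), want, tolerance = 1e-6)
})

test_that("a buried atom has zero SASA and burial reduces exposure", {
  # central atom enclosed by an octahedral cage of 6 atoms at 2.2 A
  mk <- function(i, xyz) sprintf(
    "ATOM  %5d  C%s  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    i, LETTERS[(i %% 26) + 1], i, xyz[1], xyz[2], xyz[3])
  pts <- rbind(c(0, 0, 0), 2.2 * rbind(diag(3), -diag(3)))
  txt <- paste(vapply(seq_len(nrow(pts)), function(i) mk(i, pts[i, ]), ""), collapse = "\n")
  st <- parse_structure(txt)
  s <- compute_sasa(st)
  expect_equal(unname(s["A|1"]), 0)
  expect_true(all(s[-1] < oracle_isolated_sasa(1.70)))
})

test_that("SASA of two atoms is symmetric and pairwise-occluded", {
  txt <- paste(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.000   0.000   0.000  1.00  0.00           C",
    sep = "\n")
  s <- compute_sasa(parse_structure(txt))
  # the fixed quadrature directions are not mirror-symmetric, so allow ~1%
  expect_equal(as.numeric(s[1]), as.numeric(s[2]), tolerance = 0.02)
  expect_lt(as.numeric(s[1]), oracle_isolated_sasa(1.70))
  expect_lt(as.numeric(s[2]), oracle_isolated_sasa(1.70))
})

test_that("surface_residues applies an inclusive threshold", {
  s <- c("A|1" = 2.5, "A|2" = 2.4999, "A|3" = 100)
  expect_equal(surface_residues(s, 2.5), c("A|1", "A|3"))
  expect_error(surface_residues(s, 0), "threshold")
})

test_that("isoelectric point matches hand-computed references", {
  # no ionizable side chains: pI at the midpoint of the termini pKas
  expect_equal(isoelectric_point("GGG"), (8.6 + 3.6) / 2, tolerance = 1e-3)
  # net charge at the reported pI is ~0
  for (seqn in c("KRKRK", "DEDED", "ACDEFGHIKLMNPQRSTVWY")) {
    pI <- isoelectric_point(seqn)
    counts <- table(strsplit(seqn, "")[[1]])
    expect_lt(abs(xtalgp:::net_charge(counts, pI)), 1e-3)
  }
  # more basic sequence has higher pI
  expect_gt(isoelectric_point("KKKK"), isoelectric_point("DDDD"))
})

test_that("radius of gyration matches the direct formula", {
  st <- parse_structure(generate_toy_structure(c("ALA", "LYS", "TRP", "GLY")))
  xyz <- xtalgp:::atom_coords(st, polymer_only = TRUE)
  ctr <- colMeans(xyz)
  want <- sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
  expect_equal(radius_of_gyration(st), want)
})

test_that("scale averages reproduce direct dot products", {
  tab <- residue_scales()
  aa <- c("A", "A", "W", "D")
  want <- mean(stats::setNames(tab$gravy, tab$aa)[aa])
  expect_equal(scale_average(aa, "gravy"), want)
})

test_that("protein feature vector obeys the schema and composition identities", {
  pdb <- generate_toy_structure(
    c("LYS", "GLU", "SER", "ALA", "GLY", "ARG", "ASP", "THR", "LEU", "ASN"))
  st <- parse_structure(pdb)
  fv <- protein_feature_vector(st)
  expect_equal(names(fv), protein_feature_schema())
  aas <- amino_acids()
  expect_equal(sum(fv[paste0("frac_", aas)]), 1, tolerance = 1e-12)
  expect_equal(sum(fv[paste0("wfrac_", aas)]), 1, tolerance = 1e-12)
  expect_equal(sum(fv[paste0("cat_", c("S", "pos", "neg", "P", "H"))]), 1,
               tolerance = 1e-12)
  # surface scale means are exactly composition-weighted scale sums
  tab <- residue_scales()
  for (pair in list(c("sGRAVY", "gravy"), c("sSCE", "sce"), c("sPOL", "pol"))) {
    sc <- stats::setNames(tab[[pair[2]]], tab$aa)[aas]
    expect_equal(unname(fv[pair[1]]), sum(fv[paste0("frac_", aas)] * sc),
                 tolerance = 1e-10)
  }
  # pair fractions live on the simplex when any pairs exist
  psum <- sum(fv[paste0("pair_", xtalgp:::category_pairs())])
  expect_true(abs(psum - 1) < 1e-12 || psum == 0)
})

test_that("neighbor pairs are symmetric in category order", {
  expect_equal(xtalgp:::pair_name("pos", "S"), xtalgp:::pair_name("S", "pos"))
  expect_equal(xtalgp:::pair_name("H", "H"), "H_H")
})
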