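#' Residue physico-chemical scales and categories
#'
#' Loads the versioned per-residue scale table shipped with the package:
#' Kyte-Doolittle hydropathy (GRAVY), side-chain conformational entropy (SCE,
#' oriented so flexible residues score high), Grantham polarity (POL), and the
#' five-way residue category used throughout the analysis: small (G, A),
#' positively charged (H, R, K), negatively charged (D, E), polar
#' (C, S, T, N, Q) and hydrophobic (L, I, V, F, Y, M, W, P).
#'
#' @param path Optional path to an alternative scale CSV with the same columns.
#' @return A data.frame with columns `aa`, `aa3`, `gravy`, `sce`, `pol`,
#'   `category`, one row per standard residue (20 rows).
#' @export
residue_scales <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "residue_scales.csv", package = "xtalgp")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 20L, all(c("aa", "aa3", "gravy", "sce", "pol", "category") %in% names(tab)))
  tab[order(tab$aa), , drop = FALSE]
}

#' @return Character vector of the 20 one-letter residue codes in the stable
#'   order used for feature columns.
#' @rdname residue_scales
#' @export
amino_acids <- function() sort(residue_scales()$aa)

# category codes in stable order; "pos"/"neg" are the +/- categories
.categories <- c("S", "pos", "neg", "P", "H")

#' Residue category labels
#'
#' @return Named character vector mapping one-letter residue codes to the
#'   category codes `S`, `pos`, `neg`, `P`, `H`.
#' @export
residue_categories <- function() {
  sc <- residue_scales()
  stats::setNames(sc$category, sc$aa)
}

# unordered category pairs in stable order (upper triangle incl. diagonal)
category_pairs <- function() {
  cats <- .categories
  out <- character(0)
  for (i in seq_along(cats)) {
    for (j in i:length(cats)) out <- c(out, paste(cats[i], cats[j], sep = "_"))
  }
  out
}

pair_name <- function(cat_a, cat_b) {
  cats <- .categories
  ia <- match(cat_a, cats)
  ib <- match(cat_b, cats)
  i <- pmin(ia, ib)
  j <- pmax(ia, ib)
  paste(cats[i], cats[j], sep = "_")
}

#' Protein feature schema
#'
#' The 89 protein-level predictive variables: 20 surface residue coverage
#' fractions, 5 surface category fractions, 15 neighbouring-pair fractions,
#' the same 40 weighted by solvent-accessible area (prefix `w`), and 9 global
#' properties (pI, SASA, Rg, GRAVY, sGRAVY, SCE, sSCE, POL, sPOL).
#'
#' @return Character vector of the 89 feature names in stable column order.
#' @export
protein_feature_schema <- function() {
  aas <- amino_acids()
  comp <- c(paste0("frac_", aas),
            paste0("cat_", .categories),
            paste0("pair_", category_pairs()))
  c(comp, paste0("w", comp),
    "pI", "SASA", "Rg", "GRAVY", "sGRAVY", "SCE", "sSCE", "POL", "sPOL")
}

#' Cocktail feature schema
#'
#' The 61 solution-condition variables: 56 species molarities in registry
#' order, then pH, ionic strength (IS), Hofmeister coefficients for cations
#' (HSpos) and anions (HSneg), and the depletion coefficient (DEP).
#'
#' @return Character vector of the 61 feature names in stable column order.
#' @export
cocktail_feature_schema <- function() {
  c(build_registry()$name, "pH", "IS", "HSpos", "HSneg", "DEP")
}

#' Joint feature schema for per-experiment classification
#'
#' @return Character vector of the 150 feature names (89 protein + 61 cocktail).
#' @export
joint_feature_schema <- function() c(protein_feature_schema(), cocktail_feature_schema())

# 3-letter -> 1-letter lookup
aa3_to_aa1 <- function(codes) {
  sc <- residue_scales()
  map <- stats::setNames(sc$aa, sc$aa3)
  map[toupper(codes)]
}
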