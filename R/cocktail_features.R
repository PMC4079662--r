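#' Chemical species registry
#'
#' The 56 chemical species tracked in the screen featurization: 19 cations,
#' 24 anions and 13 polyethylene glycols. Each entry carries a formal charge,
#' a Hofmeister rank (1 = most kosmotropic within its kind; NA for species
#' absent from the printed ranking, which receive the median rank when the
#' Hofmeister coefficients are computed) and, for PEGs, the molecular mass in
#' g/mol.
#'
#' @param path Optional path to an alternative registry CSV.
#' @return A data.frame with columns `name`, `kind` (cation/anion/PEG),
#'   `charge`, `hofmeister_rank`, `peg_mass`.
#' @export
build_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "species_registry.csv", package = "xtalgp")
  }
  reg <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  stopifnot(all(c("name", "kind", "charge", "hofmeister_rank", "peg_mass") %in% names(reg)))
  reg
}

# validate a cocktail: named numeric vector/list of molarities over registry
# species (missing species treated as 0), plus a pH
as_cocktail_conc <- function(cocktail, registry) {
  conc <- stats::setNames(numeric(nrow(registry)), registry$name)
  if (length(cocktail)) {
    nm <- names(cocktail)
    if (is.null(nm)) stop("cocktail concentrations must be named by species")
    unknown <- setdiff(nm, c(registry$name, "pH"))
    if (length(unknown)) {
      stop("unknown species in cocktail: ", paste(unknown, collapse = ", "))
    }
    nm <- setdiff(nm, "pH")
    vals <- unlist(cocktail[nm], use.names = FALSE)
    if (any(vals < 0)) stop("negative species concentration")
    conc[nm] <- vals
  }
  conc
}

#' Ionic strength of a cocktail
#'
#' IS = 1/2 * sum_i c_i z_i^2 over ionic species; PEGs are excluded.
#'
#' @param cocktail Named numeric vector of species molarities (M).
#' @param registry Species registry, see [build_registry()].
#' @return Ionic strength in molar units.
#' @export
ionic_strength <- function(cocktail, registry = build_registry()) {
  conc <- as_cocktail_conc(cocktail, registry)
  ion <- registry$kind %in% c("cation", "anion")
  0.5 * sum(conc[ion] * registry$charge[ion]^2)
}

# linear map of Hofmeister rank onto [+1, -1]; NA ranks get the median of
# the printed ranks for that kind (logged once per call)
hofmeister_index <- function(registry, kind, warn = TRUE) {
  sel <- registry$kind == kind
  ranks <- registry$hofmeister_rank[sel]
  printed <- ranks[!is.na(ranks)]
  r_max <- max(printed)
  if (any(is.na(ranks))) {
    if (warn) {
      message("species without a printed Hofmeister rank assigned the median rank: ",
              paste(registry$name[sel][is.na(ranks)], collapse = ", "))
    }
    ranks[is.na(ranks)] <- stats::median(printed)
  }
  h <- 1 - 2 * (ranks - 1) / (r_max - 1)
  stats::setNames(h, registry$name[sel])
}

#' Hofmeister series coefficients
#'
#' HS+ (cations) and HS- (anions) are concentration-weighted sums of a
#' Hofmeister index h_i that maps the printed kosmotropic-to-chaotropic rank
#' linearly onto [+1, -1].
#'
#' @inheritParams ionic_strength
#' @param warn Message about species lacking a printed rank.
#' @return Named numeric vector `c(HSpos = ..., HSneg = ...)`.
#' @export
hofmeister_coefficients <- function(cocktail, registry = build_registry(), warn = FALSE) {
  conc <- as_cocktail_conc(cocktail, registry)
  h_cat <- hofmeister_index(registry, "cation", warn = warn)
  h_an <- hofmeister_index(registry, "anion", warn = warn)
  c(HSpos = sum(conc[names(h_cat)] * h_cat),
    HSneg = sum(conc[names(h_an)] * h_an))
}

#' Depletion coefficient
#'
#' Asakura-Oosawa overlap-volume form: DEP = sum over PEGs of
#' c_a * (1 + R_dep,a / Rg)^3 with depletant radius
#' R_dep,a = r0 * (M_a / M0)^0.588 (Flory scaling of the polymer coil size).
#'
#' @inheritParams ionic_strength
#' @param Rg Solvated protein radius of gyration in angstrom (> 0).
#' @param r0,M0,flory_exp Depletant-radius scaling constants: coil radius r0
#'   (angstrom) at reference mass M0 (g/mol), Flory exponent.
#' @return Dimensionless depletion coefficient (>= 0).
#' @export
depletion_coefficient <- function(cocktail, Rg, registry = build_registry(),
                                  r0 = 12.1, M0 = 1000, flory_exp = 0.588) {
  if (!is.numeric(Rg) || length(Rg) != 1L || is.na(Rg) || Rg <= 0) {
    stop("Rg must be a positive scalar")
  }
  conc <- as_cocktail_conc(cocktail, registry)
  peg <- registry$kind == "PEG"
  r_dep <- r0 * (registry$peg_mass[peg] / M0)^flory_exp
  sum(conc[registry$name[peg]] * (1 + r_dep / Rg)^3)
}

#' Full 61-dimensional cocktail feature vector
#'
#' 56 species molarities (registry order), pH, and the derived descriptors
#' IS, HS+, HS- and DEP (the last needs the protein's radius of gyration).
#'
#' @param cocktail Named numeric vector of species molarities; may include a
#'   `pH` element, otherwise supply `pH`.
#' @param Rg Protein radius of gyration in angstrom, used by DEP.
#' @param pH Solution pH (overridden by a `pH` element of `cocktail`).
#' @param registry Species registry.
#' @return Named numeric vector of length 61 following
#'   [cocktail_feature_schema()].
#' @export
cocktail_feature_vector <- function(cocktail, Rg, pH = 7, registry = build_registry()) {
  conc <- as_cocktail_conc(cocktail, registry)
  if ("pH" %in% names(cocktail)) pH <- unname(unlist(cocktail["pH"]))
  hs <- hofmeister_coefficients(cocktail, registry)
  out <- c(conc,
           pH = pH,
           IS = ionic_strength(cocktail, registry),
           hs,
           DEP = depletion_coefficient(cocktail, Rg, registry))
  out[c(registry$name, "pH", "IS", "HSpos", "HSneg", "DEP")]
}

#' Featurize a table of raw cocktails
#'
#' @param cocktails Data frame with `cocktail_id`, `pH` and one column per
#'   registry species (molarity; absent species are 0).
#' @param Rg Protein radius of gyration used for DEP (a scalar; DEP is
#'   protein-specific, so call per protein when that matters).
#' @param registry Species registry.
#' @return Data frame: `cocktail_id` plus the 61 feature columns.
#' @export
featurize_cocktails <- function(cocktails, Rg, registry = build_registry()) {
  stopifnot("cocktail_id" %in% names(cocktails))
  species_cols <- intersect(names(cocktails), registry$name)
  feats <- t(vapply(seq_len(nrow(cocktails)), function(i) {
    conc <- unlist(cocktails[i, species_cols, drop = TRUE])
    cocktail_feature_vector(conc, Rg = Rg, pH = cocktails$pH[i], registry = registry)
  }, numeric(nrow(registry) + 5L)))
  cbind(data.frame(cocktail_id = cocktails$cocktail_id), as.data.frame(feats))
}
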