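#' Mean of a residue scale over a set of residues
#'
#' Unweighted arithmetic mean of a per-residue scale (hydropathy, side-chain
#' entropy or polarity) over the supplied residues. Surface-restricted values
#' (sGRAVY, sSCE, sPOL) are obtained by passing only exposed residues.
#'
#' @param aa Character vector of one-letter residue codes (the selection).
#' @param scale One of "gravy", "sce", "pol", or a named numeric vector over
#'   the 20 residues.
#' @return The mean scale value.
#' @export
scale_average <- function(aa, scale = c("gravy", "sce", "pol")) {
  if (is.character(scale)) {
    scale <- match.arg(scale)
    tab <- residue_scales()
    scale <- stats::setNames(tab[[scale]], tab$aa)
  }
  aa <- aa[!is.na(aa)]
  if (!length(aa)) stop("empty residue selection")
  vals <- scale[aa]
  if (any(is.na(vals))) stop("non-standard residue code: ",
                             paste(unique(aa[is.na(vals)]), collapse = ", "))
  mean(vals)
}

#' Isoelectric point by bisection
#'
#' pH at which the Henderson-Hasselbalch net charge of the sequence (EMBOSS
#' pKa set, termini included) vanishes; bisection on pH 0..14 to
#' |charge| < tol.
#'
#' @param sequence Character vector of one-letter codes, or a single string.
#' @param tol Convergence tolerance on the net charge.
#' @return Isoelectric point in pH units.
#' @export
isoelectric_point <- function(sequence, tol = 1e-4) {
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  sequence <- sequence[!is.na(sequence)]
  if (!length(sequence)) stop("empty sequence")
  counts <- table(sequence)
  nq <- function(pH) net_charge(counts, pH)
  lo <- 0; hi <- 14
  # charge is monotone decreasing in pH
  if (nq(lo) < 0) return(lo)
  if (nq(hi) > 0) return(hi)
  while (TRUE) {
    mid <- (lo + hi) / 2
    q <- nq(mid)
    if (abs(q) < tol || (hi - lo) < 1e-12) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

# EMBOSS pKa values
.pka_pos <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
.pka_neg <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

net_charge <- function(counts, pH) {
  n_of <- function(aa) if (aa %in% names(counts)) as.numeric(counts[[aa]]) else 0
  pos <- sum(vapply(names(.pka_pos), function(g) {
    n <- if (g == "Nterm") 1 else n_of(g)
    n / (1 + 10^(pH - .pka_pos[[g]]))
  }, 0))
  neg <- sum(vapply(names(.pka_neg), function(g) {
    n <- if (g == "Cterm") 1 else n_of(g)
    n / (1 + 10^(.pka_neg[[g]] - pH))
  }, 0))
  pos - neg
}

#' Radius of gyration
#'
#' Mass-unweighted root-mean-square distance of polymer atoms from their
#' centroid.
#'
#' @param structure An `xtal_structure`.
#' @return Radius of gyration in angstrom.
#' @export
radius_of_gyration <- function(structure) {
  xyz <- atom_coords(structure, polymer_only = TRUE)
  if (!nrow(xyz)) stop("structure has no polymer atoms")
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Neighbouring surface residue-pair category fractions
#'
#' Counts each unordered pair of exposed residues on the same chain whose
#' minimal heavy-atom distance is at most `cutoff` once, maps the pair to its
#' category pair (15 possibilities over S, +, -, P, H), and normalizes over
#' the total number of neighbouring pairs. The SASA-weighted variant weights
#' each pair by the mean exposed area of its two residues before normalizing.
#'
#' @param structure An `xtal_structure`.
#' @param surface_set Residue keys (`chain|resseq`) considered exposed.
#' @param cutoff Neighbour distance cutoff in angstrom (default 5).
#' @param sasa_map Per-residue SASA (required for the weighted variant).
#' @return List with `fractions` and `weighted` (named length-15 vectors) and
#'   `n_pairs`; when no pair exists both vectors are all zero and the
#'   `no_pairs` flag is TRUE.
#' @export
neighbor_pair_fractions <- function(structure, surface_set, cutoff = 5,
                                    sasa_map = NULL) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  a <- structure$atoms[!structure$atoms$hetatm & structure$atoms$element != "H", , drop = FALSE]
  a$key <- paste(a$chain, a$resseq, sep = "|")
  a <- a[a$key %in% surface_set, , drop = FALSE]
  cats <- residue_categories()
  res <- structure$residues
  res$key <- paste(res$chain, res$resseq, sep = "|")
  res <- res[res$key %in% surface_set & !is.na(res$aa), , drop = FALSE]

  pnames <- paste0("pair_", category_pairs())
  counts <- stats::setNames(numeric(15), pnames)
  wcounts <- counts
  n_pairs <- 0L
  if (nrow(res) >= 2L) {
    for (ch in unique(res$chain)) {
      rch <- res[res$chain == ch, , drop = FALSE]
      if (nrow(rch) < 2L) next
      coords <- lapply(rch$key, function(k) as.matrix(a[a$key == k, c("x", "y", "z")]))
      for (i in seq_len(nrow(rch) - 1L)) {
        for (j in (i + 1L):nrow(rch)) {
          if (min_pair_dist(coords[[i]], coords[[j]]) <= cutoff) {
            pn <- paste0("pair_", pair_name(cats[rch$aa[i]], cats[rch$aa[j]]))
            counts[pn] <- counts[pn] + 1
            if (!is.null(sasa_map)) {
              w <- mean(c(sasa_map[rch$key[i]], sasa_map[rch$key[j]]))
              wcounts[pn] <- wcounts[pn] + w
            }
            n_pairs <- n_pairs + 1L
          }
        }
      }
    }
  }
  no_pairs <- n_pairs == 0L
  list(fractions = if (no_pairs) counts else counts / sum(counts),
       weighted = if (no_pairs || is.null(sasa_map)) wcounts else wcounts / sum(wcounts),
       n_pairs = n_pairs, no_pairs = no_pairs)
}

min_pair_dist <- function(c1, c2) {
  if (!nrow(c1) || !nrow(c2)) return(Inf)
  d2 <- outer(rowSums(c1^2), rowSums(c2^2), "+") - 2 * tcrossprod(c1, c2)
  sqrt(max(0, min(d2)))
}

#' The 89 protein-level predictive variables from a structure
#'
#' Surface residue coverage fractions (20), surface category fractions (5),
#' neighbouring-pair category fractions (15), the same 40 weighted by
#' solvent-accessible area, and 9 global properties: pI, total SASA, radius
#' of gyration, GRAVY/sGRAVY, SCE/sSCE, POL/sPOL. Surface values average the
#' scales over exposed residues only; by construction sGRAVY, sSCE and sPOL
#' equal the coverage-weighted means of the per-residue scales.
#'
#' @param structure An `xtal_structure`.
#' @param exposure_threshold Residue exposure threshold in square angstrom.
#' @param pair_cutoff Neighbour-pair distance cutoff in angstrom.
#' @param probe_radius,n_sphere_points SASA parameters.
#' @return Named numeric vector of length 89 following
#'   [protein_feature_schema()].
#' @export
protein_feature_vector <- function(structure, exposure_threshold = 2.5,
                                   pair_cutoff = 5, probe_radius = 1.4,
                                   n_sphere_points = 960) {
  sasa <- compute_sasa(structure, probe_radius, n_sphere_points)
  surf <- surface_residues(sasa, exposure_threshold)
  res <- structure$residues
  res$key <- paste(res$chain, res$resseq, sep = "|")
  res <- res[!is.na(res$aa), , drop = FALSE]
  s_res <- res[res$key %in% surf, , drop = FALSE]
  if (!nrow(s_res)) stop("no exposed residues above the threshold")

  aas <- amino_acids()
  tab <- residue_scales()
  cats <- residue_categories()

  counts <- table(factor(s_res$aa, levels = aas))
  frac <- as.numeric(counts) / nrow(s_res)
  names(frac) <- paste0("frac_", aas)
  w_by_aa <- tapply(sasa[s_res$key], factor(s_res$aa, levels = aas), sum)
  w_by_aa[is.na(w_by_aa)] <- 0
  wfrac <- as.numeric(w_by_aa) / sum(sasa[s_res$key])
  names(wfrac) <- paste0("wfrac_", aas)

  cat_of_aa <- cats[aas]
  cat_frac <- vapply(.categories, function(cc) sum(frac[cat_of_aa == cc]), 0)
  names(cat_frac) <- paste0("cat_", .categories)
  wcat_frac <- vapply(.categories, function(cc) sum(wfrac[cat_of_aa == cc]), 0)
  names(wcat_frac) <- paste0("wcat_", .categories)

  pr <- neighbor_pair_fractions(structure, surf, pair_cutoff, sasa_map = sasa)
  wpair <- pr$weighted
  names(wpair) <- paste0("w", names(pr$fractions))

  gravy <- stats::setNames(tab$gravy, tab$aa)
  sce <- stats::setNames(tab$sce, tab$aa)
  pol <- stats::setNames(tab$pol, tab$aa)
  globals <- c(
    pI = isoelectric_point(res$aa),
    SASA = sum(sasa),
    Rg = radius_of_gyration(structure),
    GRAVY = scale_average(res$aa, gravy),
    sGRAVY = sum(frac * gravy[aas]),
    SCE = scale_average(res$aa, sce),
    sSCE = sum(frac * sce[aas]),
    POL = scale_average(res$aa, pol),
    sPOL = sum(frac * pol[aas])
  )
  out <- c(frac, cat_frac, pr$fractions, wfrac, wcat_frac, wpair, globals)
  out <- out[protein_feature_schema()]
  if (pr$no_pairs) attr(out, "no_pairs") <- TRUE
  out
}
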