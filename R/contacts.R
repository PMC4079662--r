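#' Symmetry expansion of a crystal structure
#'
#' Applies every REMARK 290 symmetry operator (Cartesian convention: rotated
#' coordinates plus an angstrom translation) combined with lattice
#' translations within +/- `shell` unit cells, and keeps the copies whose
#' bounding box comes within `cutoff + margin` of the asymmetric unit's
#' bounding box. The identity operator with zero lattice translation (the
#' central copy itself) is excluded.
#'
#' @param structure An `xtal_structure` with `cell` and `symmetry_ops`.
#' @param shell Lattice translation range (default 1 -> 3^3 cells).
#' @param cutoff Contact distance the pruning must preserve (angstrom).
#' @param margin Extra bounding-box margin (angstrom).
#' @param prune Set FALSE to keep all candidate copies.
#' @return List of neighbour copies; each has `coords` (heavy polymer atoms),
#'   `residue_key`, `aa`, `op` and `translation`.
#' @export
expand_symmetry <- function(structure, shell = 1, cutoff = 5, margin = 0.5,
                            prune = TRUE) {
  if (is.null(structure$cell)) stop("structure lacks CRYST1; cannot expand symmetry")
  if (is.null(structure$symmetry_ops) || !length(structure$symmetry_ops)) {
    stop("structure lacks REMARK 290 symmetry operators; cannot expand symmetry")
  }
  cellv <- cell_vectors(structure$cell)
  a <- structure$atoms[!structure$atoms$hetatm & structure$atoms$element != "H", , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  key <- paste(a$chain, a$resseq, sep = "|")
  aa <- aa3_to_aa1(a$resname)
  bb_lo <- apply(xyz, 2, min) - (cutoff + margin)
  bb_hi <- apply(xyz, 2, max) + (cutoff + margin)

  shifts <- as.matrix(expand.grid(i = -shell:shell, j = -shell:shell, k = -shell:shell))
  out <- list()
  for (op_i in seq_along(structure$symmetry_ops)) {
    op <- structure$symmetry_ops[[op_i]]
    base <- xyz %*% t(op[, 1:3]) + matrix(op[, 4], nrow(xyz), 3, byrow = TRUE)
    identity_op <- all(abs(op[, 1:3] - diag(3)) < 1e-9) && all(abs(op[, 4]) < 1e-9)
    for (s in seq_len(nrow(shifts))) {
      tr <- drop(shifts[s, ] %*% cellv)
      if (identity_op && all(shifts[s, ] == 0)) next
      cp <- sweep(base, 2, tr, "+")
      if (prune) {
        inside <- cp[, 1] >= bb_lo[1] & cp[, 1] <= bb_hi[1] &
          cp[, 2] >= bb_lo[2] & cp[, 2] <= bb_hi[2] &
          cp[, 3] >= bb_lo[3] & cp[, 3] <= bb_hi[3]
        if (!any(inside)) next
      }
      out[[length(out) + 1L]] <- list(coords = cp, residue_key = key, aa = aa,
                                      op = op_i, translation = shifts[s, ])
    }
  }
  out
}

# cell vectors (rows) from a, b, c, alpha, beta, gamma
cell_vectors <- function(cell) {
  d2r <- pi / 180
  al <- cell[4] * d2r; be <- cell[5] * d2r; ga <- cell[6] * d2r
  av <- c(cell[1], 0, 0)
  bv <- c(cell[2] * cos(ga), cell[2] * sin(ga), 0)
  cx <- cell[3] * cos(be)
  cy <- cell[3] * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- sqrt(max(cell[3]^2 - cx^2 - cy^2, 0))
  rbind(av, bv, c(cx, cy, cz))
}

#' Crystal-contact residues
#'
#' Surface residues of the central copy with any heavy atom within `cutoff`
#' of any atom of a symmetry neighbour.
#'
#' @param structure An `xtal_structure`.
#' @param neighbors Neighbour copies from [expand_symmetry()].
#' @param cutoff Contact distance in angstrom (default 5).
#' @param surface_set Exposed residue keys; computed from SASA (threshold
#'   `exposure_threshold`) when NULL.
#' @param exposure_threshold Passed to [surface_residues()] when needed.
#' @return Character vector of contact residue keys (`chain|resseq`), possibly
#'   empty.
#' @export
contact_residues <- function(structure, neighbors, cutoff = 5,
                             surface_set = NULL, exposure_threshold = 2.5) {
  if (!length(neighbors)) stop("no neighbour copies supplied")
  if (cutoff <= 0) return(character(0))
  if (is.null(surface_set)) {
    surface_set <- surface_residues(compute_sasa(structure), exposure_threshold)
  }
  a <- structure$atoms[!structure$atoms$hetatm & structure$atoms$element != "H", , drop = FALSE]
  key <- paste(a$chain, a$resseq, sep = "|")
  keep <- key %in% surface_set
  a <- a[keep, , drop = FALSE]
  key <- key[keep]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  hit <- rep(FALSE, nrow(xyz))
  for (nb in neighbors) {
    d2 <- outer(rowSums(xyz^2), rowSums(nb$coords^2), "+") - 2 * tcrossprod(xyz, nb$coords)
    hit <- hit | (apply(d2, 1, min) <= cutoff^2 + 1e-12)
  }
  sort(unique(key[hit]))
}

#' Residue and cross-chain pair composition of crystal contacts
#'
#' Category fractions over the contact residues, and cross-chain pair
#' category fractions over (contact residue, neighbour residue) pairs within
#' the cutoff -- pairs here are interactions between residues on different
#' chains in the lattice, not intra-chain neighbours.
#'
#' @param structure An `xtal_structure`.
#' @param contacts Contact residue keys from [contact_residues()].
#' @param neighbors Neighbour copies from [expand_symmetry()].
#' @param cutoff Contact distance in angstrom.
#' @return List: `contact_residues`, `category_fractions` (5),
#'   `pair_fractions` (15), `n_contacts`, `n_pairs`.
#' @export
contact_profile <- function(structure, contacts, neighbors, cutoff = 5) {
  res <- structure$residues
  res$key <- paste(res$chain, res$resseq, sep = "|")
  cats <- residue_categories()
  cres <- res[res$key %in% contacts & !is.na(res$aa), , drop = FALSE]

  cat_frac <- stats::setNames(numeric(5), paste0("cat_", .categories))
  if (nrow(cres)) {
    tab <- table(factor(cats[cres$aa], levels = .categories))
    cat_frac[] <- as.numeric(tab) / nrow(cres)
  }

  pnames <- paste0("pair_", category_pairs())
  pair_counts <- stats::setNames(numeric(15), pnames)
  n_pairs <- 0L
  if (nrow(cres)) {
    a <- structure$atoms[!structure$atoms$hetatm & structure$atoms$element != "H", , drop = FALSE]
    akey <- paste(a$chain, a$resseq, sep = "|")
    for (i in seq_len(nrow(cres))) {
      ci <- as.matrix(a[akey == cres$key[i], c("x", "y", "z")])
      for (nb in neighbors) {
        d2 <- outer(rowSums(ci^2), rowSums(nb$coords^2), "+") - 2 * tcrossprod(ci, nb$coords)
        near <- apply(d2, 2, min) <= cutoff^2 + 1e-12
        if (!any(near)) next
        partner_keys <- unique(nb$residue_key[near])
        for (pk in partner_keys) {
          paa <- nb$aa[match(pk, nb$residue_key)]
          if (is.na(paa)) next
          pn <- paste0("pair_", pair_name(cats[cres$aa[i]], cats[paa]))
          pair_counts[pn] <- pair_counts[pn] + 1
          n_pairs <- n_pairs + 1L
        }
      }
    }
  }
  pair_frac <- if (n_pairs > 0L) pair_counts / sum(pair_counts) else pair_counts
  list(contact_residues = contacts, category_fractions = cat_frac,
       pair_fractions = pair_frac, n_contacts = length(contacts),
       n_pairs = n_pairs)
}

#' Between-quadrant enrichment of contact composition
#'
#' Pairwise quadrant comparisons of the contact residue-category and
#' cross-chain pair fractions with two-sample KS tests; direction by medians.
#'
#' @param profiles List of [contact_profile()] results, or a data frame with
#'   the 20 fraction columns; one row/entry per protein.
#' @param quadrant_assignments Data frame with `quadrant` aligned to profiles.
#' @param alpha Significance threshold.
#' @param min_group Minimum proteins per quadrant.
#' @return Data frame: `quadrant_a`, `quadrant_b`, `feature`, `D`, `p`,
#'   `direction` (enrichment of `quadrant_a` relative to `quadrant_b`).
#' @export
contact_enrichment <- function(profiles, quadrant_assignments, alpha = 0.05,
                               min_group = 10) {
  if (!is.data.frame(profiles)) {
    profiles <- as.data.frame(t(vapply(profiles, function(p) {
      c(p$category_fractions, p$pair_fractions)
    }, numeric(20))))
  }
  qd <- quadrant_assignments$quadrant
  keep_q <- names(which(table(qd) >= min_group))
  out <- NULL
  if (length(keep_q) < 2L) {
    message("fewer than two quadrants reach the minimum group size")
  } else {
    combos <- utils::combn(sort(keep_q), 2)
    for (k in seq_len(ncol(combos))) {
      qa <- combos[1, k]; qb <- combos[2, k]
      ia <- which(qd == qa); ib <- which(qd == qb)
      for (ft in names(profiles)) {
        ks <- ks_two_sample(profiles[[ft]][ia], profiles[[ft]][ib])
        if (ks$p < alpha) {
          dir <- if (stats::median(profiles[[ft]][ia]) >
                     stats::median(profiles[[ft]][ib])) "enriched" else "depleted"
          out <- rbind(out, data.frame(quadrant_a = qa, quadrant_b = qb,
                                       feature = ft, D = ks$D, p = ks$p,
                                       direction = dir, stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(quadrant_a = character(0), quadrant_b = character(0),
                      feature = character(0), D = numeric(0), p = numeric(0),
                      direction = character(0))
  }
  out
}
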