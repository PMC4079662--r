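#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA by rolling a probe sphere over van der Waals spheres: each
#' atom's extended sphere (r_vdw + probe) is sampled with a deterministic
#' Fibonacci point set and a point counts as accessible when it lies outside
#' every other atom's extended sphere. Hydrogens are typically absent from
#' X-ray structures; when present they are included like any other atom.
#' HETATM records are excluded.
#'
#' @param structure An `xtal_structure` from [parse_structure()].
#' @param probe_radius Probe (water) radius in angstrom.
#' @param n_sphere_points Quadrature points per atom.
#' @return Named numeric vector: SASA in square angstrom per residue, names
#'   `chain|resseq`. The per-atom breakdown is attached as attribute `atoms`.
#' @export
compute_sasa <- function(structure, probe_radius = 1.4, n_sphere_points = 960) {
  a <- structure$atoms[!structure$atoms$hetatm, , drop = FALSE]
  if (!nrow(a)) stop("structure has no polymer atoms")
  sub <- structure
  sub$atoms <- a
  radii <- atom_radii(sub) + probe_radius
  xyz <- as.matrix(a[, c("x", "y", "z")])
  pts <- fibonacci_sphere(n_sphere_points)

  n <- nrow(xyz)
  area <- numeric(n)
  # pairwise distances once; neighbours are atoms whose extended spheres
  # can intersect this atom's extended sphere
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (radii[i] + radii)^2 & seq_len(n) != i)
    p <- sweep(pts * radii[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, nrow(p))
      for (j in nb) {
        if (!any(acc)) break
        dx <- p[acc, 1] - xyz[j, 1]
        dy <- p[acc, 2] - xyz[j, 2]
        dz <- p[acc, 3] - xyz[j, 3]
        acc[acc] <- (dx * dx + dy * dy + dz * dz) >= radii[j]^2
      }
      n_acc <- sum(acc)
    } else {
      n_acc <- nrow(p)
    }
    area[i] <- 4 * pi * radii[i]^2 * n_acc / n_sphere_points
  }
  res_key <- paste(a$chain, a$resseq, sep = "|")
  out <- tapply(area, res_key, sum)
  keys <- paste(structure$residues$chain, structure$residues$resseq, sep = "|")
  res <- stats::setNames(numeric(length(keys)), keys)
  res[names(out)] <- as.numeric(out)
  attr(res, "atoms") <- data.frame(chain = a$chain, resseq = a$resseq,
                                   name = a$name, area = area,
                                   stringsAsFactors = FALSE)
  res
}

# deterministic quasi-uniform points on the unit sphere (golden-angle spiral)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Exposed (surface) residues
#'
#' A residue is exposed when its solvent-accessible area is at least the
#' threshold (boundary inclusive).
#'
#' @param sasa_map Named per-residue SASA from [compute_sasa()].
#' @param threshold Exposure threshold in square angstrom (default 2.5).
#' @return Character vector of residue keys (`chain|resseq`).
#' @export
surface_residues <- function(sasa_map, threshold = 2.5) {
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  names(sasa_map)[sasa_map >= threshold]
}
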