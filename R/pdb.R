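#' Parse a PDB-format text into a Structure
#'
#' Reads ATOM/HETATM records (fixed columns), CRYST1 and REMARK 290 SMTRY
#' symmetry operators. Alternate locations are resolved per atom by keeping
#' the highest-occupancy record, ties going to altloc 'A' (then alphabetical).
#' HETATM records and waters are retained in the structure but flagged, and
#' excluded from feature computation downstream.
#'
#' @param pdb_text Character scalar (whole file) or character vector of lines.
#' @return An object of class `xtal_structure`: list with `atoms` (data.frame:
#'   serial, name, altloc, resname, chain, resseq, x, y, z, occupancy,
#'   element, hetatm), `residues` (data.frame: chain, resseq, resname, aa),
#'   `cell` (length-6 numeric or NULL) and `symmetry_ops` (list of 3x4
#'   matrices in Cartesian angstrom convention, or NULL).
#' @export
parse_structure <- function(pdb_text) {
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text, fixed = TRUE)) {
    strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  } else {
    pdb_text
  }
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("no ATOM records found")

  al <- lines[is_atom]
  lineno <- which(is_atom)
  num <- function(from, to, what) {
    x <- suppressWarnings(as.numeric(substr(al, from, to)))
    bad <- which(is.na(x))
    if (length(bad)) {
      stop(sprintf("malformed %s field at line %d", what, lineno[bad[1]]))
    }
    x
  }
  atoms <- data.frame(
    serial = suppressWarnings(as.integer(substr(al, 7, 11))),
    name = trimws(substr(al, 13, 16)),
    altloc = substr(al, 17, 17),
    resname = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    resseq = suppressWarnings(as.integer(substr(al, 23, 26))),
    x = num(31, 38, "x coordinate"),
    y = num(39, 46, "y coordinate"),
    z = num(47, 54, "z coordinate"),
    occupancy = suppressWarnings(as.numeric(substr(al, 55, 60))),
    element = trimws(substr(al, 77, 78)),
    hetatm = substr(al, 1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  # fall back to first letter of atom name when the element column is blank
  blank <- atoms$element == ""
  atoms$element[blank] <- substr(gsub("[^A-Za-z].*$", "", atoms$name[blank]), 1, 1)
  atoms$element <- toupper(atoms$element)

  # altloc policy: per (chain, resseq, atom name) keep highest occupancy,
  # ties resolved by altloc order (' ' < 'A' < 'B' ...)
  if (any(atoms$altloc != " ")) {
    key <- paste(atoms$chain, atoms$resseq, atoms$name, sep = "|")
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
      if (length(idx) == 1L) return(idx)
      occ <- atoms$occupancy[idx]
      best <- idx[occ == max(occ)]
      best[order(atoms$altloc[best])][1]
    }), use.names = FALSE)
    atoms <- atoms[sort(keep), , drop = FALSE]
  }
  if (any(!is.finite(atoms$x + atoms$y + atoms$z))) stop("non-finite coordinates")

  cell <- NULL
  cl <- lines[rec == "CRYST1"]
  if (length(cl)) {
    cl <- cl[1]
    cell <- as.numeric(c(substr(cl, 7, 15), substr(cl, 16, 24), substr(cl, 25, 33),
                         substr(cl, 34, 40), substr(cl, 41, 47), substr(cl, 48, 54)))
    names(cell) <- c("a", "b", "c", "alpha", "beta", "gamma")
  }

  sym <- NULL
  sm <- grep("^REMARK 290   SMTRY", lines, value = TRUE)
  if (length(sm)) {
    tok <- lapply(strsplit(trimws(sm), "\\s+"), identity)
    row_idx <- as.integer(substr(vapply(tok, `[`, "", 3), 6, 6))
    op_idx <- as.integer(vapply(tok, `[`, "", 4))
    vals <- t(vapply(tok, function(t) as.numeric(t[5:8]), numeric(4)))
    sym <- lapply(sort(unique(op_idx)), function(k) {
      m <- matrix(NA_real_, 3, 4)
      sel <- which(op_idx == k)
      m[row_idx[sel], ] <- vals[sel, , drop = FALSE]
      if (any(is.na(m))) stop("incomplete SMTRY operator ", k)
      m
    })
  }

  res_key <- !duplicated(paste(atoms$chain, atoms$resseq, sep = "|"))
  residues <- data.frame(
    chain = atoms$chain[res_key],
    resseq = atoms$resseq[res_key],
    resname = atoms$resname[res_key],
    stringsAsFactors = FALSE
  )
  residues$aa <- unname(aa3_to_aa1(residues$resname))

  structure(list(atoms = atoms, residues = residues, cell = cell,
                 symmetry_ops = sym),
            class = "xtal_structure")
}

#' @export
print.xtal_structure <- function(x, ...) {
  cat(sprintf("<xtal_structure> %d atoms, %d residues, %d chain(s)%s%s\n",
              nrow(x$atoms), nrow(x$residues), length(unique(x$atoms$chain)),
              if (is.null(x$cell)) "" else ", with cell",
              if (is.null(x$symmetry_ops)) "" else sprintf(", %d symmetry ops", length(x$symmetry_ops))))
  invisible(x)
}

# van der Waals radii (Bondi), angstrom
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)
}

atom_radii <- function(structure) {
  r <- vdw_radii()[structure$atoms$element]
  if (any(is.na(r))) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(structure$atoms$element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

# coordinates matrix (n x 3) of (optionally non-HETATM) atoms
atom_coords <- function(structure, heavy_only = FALSE, polymer_only = FALSE) {
  a <- structure$atoms
  sel <- rep(TRUE, nrow(a))
  if (heavy_only) sel <- sel & a$element != "H"
  if (polymer_only) sel <- sel & !a$hetatm
  as.matrix(a[sel, c("x", "y", "z")])
}

format_atom_line <- function(serial, name, resname, chain, resseq, xyz, element) {
  name_fmt <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_fmt, resname, chain, resseq, xyz[1], xyz[2], xyz[3], 1, 0, element)
}

format_cryst1 <- function(cell) {
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
          cell[1], cell[2], cell[3], cell[4], cell[5], cell[6])
}

format_smtry <- function(ops) {
  unlist(lapply(seq_along(ops), function(k) {
    vapply(1:3, function(r) {
      sprintf("REMARK 290   SMTRY%d %3d%10.6f%10.6f%10.6f%15.5f",
              r, k, ops[[k]][r, 1], ops[[k]][r, 2], ops[[k]][r, 3], ops[[k]][r, 4])
    }, "")
  }))
}
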