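#' Specification of a synthetic crystallization screen
#'
#' Bundles the generator settings emulating a high-throughput screen: a panel
#' of proteins, a cocktail array (two condition families: moderate-to-high
#' salt alone, and low salt with PEG), and Bernoulli outcomes driven by a
#' planted latent propensity surface built from two mechanism "bumps" --
#' an entropic hot-spot (low surface side-chain entropy, moderate
#' hydropathy, many small residues) and an electrostatic hot-spot (high
#' sSCE, polar-rich surfaces with charge-complementary neighbour pairs).
#'
#' @param n_proteins Number of proteins (>= 2).
#' @param n_cocktails Number of cocktails (>= 1); the emulated screen uses
#'   1536.
#' @param seed Integer seed; identical specs give bit-identical outputs.
#' @param mechanism_weights Nonnegative weights (entropic, electrostatic) of
#'   the two planted hot-spots; not both zero.
#' @param noise_sd White-noise standard deviation added to the latent surface.
#' @param ph_mean,ph_sd Truncated-normal pH distribution on 3..11; the screen
#'   is slightly acid-biased, default mean 6.8, sd 1.3.
#' @param latent "bumps" (default) for the two-mechanism surface, or "linear"
#'   for a purely linear latent in the same relevant features (null case for
#'   nonlinearity tests).
#' @return Object of class `screen_spec`.
#' @export
synthetic_screen_spec <- function(n_proteins = 182, n_cocktails = 1536,
                                  seed = 1, mechanism_weights = c(1, 1),
                                  noise_sd = 0.05, ph_mean = 6.8, ph_sd = 1.3,
                                  latent = c("bumps", "linear")) {
  latent <- match.arg(latent)
  chk <- function(ok, field, msg) if (!ok) stop("invalid spec field '", field, "': ", msg)
  chk(is.numeric(n_proteins) && n_proteins >= 2, "n_proteins", "need at least 2 proteins")
  chk(is.numeric(n_cocktails) && n_cocktails >= 1, "n_cocktails", "need at least 1 cocktail")
  chk(is.numeric(seed) && length(seed) == 1, "seed", "must be a scalar integer")
  chk(is.numeric(mechanism_weights) && length(mechanism_weights) == 2 &&
        all(mechanism_weights >= 0) && any(mechanism_weights > 0),
      "mechanism_weights", "two nonnegative reals, not both zero")
  chk(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(is.numeric(ph_sd) && ph_sd >= 0, "ph_sd", "must be >= 0")
  structure(list(n_proteins = as.integer(n_proteins),
                 n_cocktails = as.integer(n_cocktails),
                 seed = as.integer(seed),
                 mechanism_weights = mechanism_weights,
                 noise_sd = noise_sd, ph_mean = ph_mean, ph_sd = ph_sd,
                 latent = latent),
            class = "screen_spec")
}

# typical surface residue frequencies used as the Dirichlet base measure
.surface_base_freq <- c(
  A = 0.08, C = 0.01, D = 0.07, E = 0.10, F = 0.03, G = 0.07, H = 0.02,
  I = 0.03, K = 0.10, L = 0.06, M = 0.01, N = 0.05, P = 0.05, Q = 0.05,
  R = 0.06, S = 0.07, T = 0.06, V = 0.05, W = 0.01, Y = 0.02)

#' The planted relevant features and the recovery feature panel
#'
#' The two planted hot-spots involve exactly five features: sSCE, sGRAVY and
#' the small-residue category fraction (entropic bump) and sSCE, the polar
#' category fraction and the positive-negative neighbour-pair fraction
#' (electrostatic bump). `recovery_feature_set()` returns these five plus
#' fifteen generator-independent features, the panel used for
#' parameter-recovery experiments.
#'
#' @return Character vector of feature names.
#' @export
planted_relevant_features <- function() {
  c("sSCE", "sGRAVY", "cat_S", "cat_P", "pair_pos_neg")
}

#' @rdname planted_relevant_features
#' @export
recovery_feature_set <- function() {
  c(planted_relevant_features(),
    "frac_L", "frac_I", "frac_V", "frac_F", "frac_M", "frac_W", "frac_Y",
    "pair_H_H", "pair_pos_pos", "pair_neg_neg", "pair_pos_H", "pair_neg_H",
    "pI", "Rg", "SASA")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic protein feature table with planted truth
#'
#' Samples the full 89-feature schema for `n_proteins` proteins: surface
#' composition from a Dirichlet over the 20-simplex, neighbour-pair fractions
#' from a noisy random-contact model proportional to category products,
#' SASA-weighted variants as noisy reweightings, and global properties from
#' plausible marginals. sGRAVY, sSCE and sPOL are recomputed from the sampled
#' composition (never sampled independently). The planted propensity is the
#' probit squash of the weighted sum of the two mechanism bumps (defined in
#' z-scored coordinates of the relevant features) plus white noise.
#'
#' @param spec A `screen_spec`.
#' @return List: `proteins` (data.frame `protein_id` + 89 features), `truth`
#'   (class `planted_truth`: relevant feature names, true length scales,
#'   latent description, per-protein `true_propensity` and bump memberships).
#' @export
generate_protein_table <- function(spec) {
  stopifnot(inherits(spec, "screen_spec"))
  n <- spec$n_proteins
  aas <- amino_acids()
  tab <- residue_scales()
  sc_g <- stats::setNames(tab$gravy, tab$aa)[aas]
  sc_s <- stats::setNames(tab$sce, tab$aa)[aas]
  sc_p <- stats::setNames(tab$pol, tab$aa)[aas]
  cats <- residue_categories()[aas]
  pnames <- paste0("pair_", category_pairs())

  with_seed(spec$seed, {
    comp <- t(vapply(seq_len(n), function(i) rdirichlet1(40 * .surface_base_freq[aas]),
                     numeric(20)))
    colnames(comp) <- paste0("frac_", aas)

    cat_frac <- vapply(.categories, function(cc) rowSums(comp[, cats == cc, drop = FALSE]), numeric(n))
    colnames(cat_frac) <- paste0("cat_", .categories)

    # pair fractions: category-product contact model with gamma noise
    pair <- matrix(0, n, 15, dimnames = list(NULL, pnames))
    idx <- 0L
    pw <- matrix(0, n, 15)
    for (i in seq_along(.categories)) {
      for (j in i:length(.categories)) {
        idx <- idx + 1L
        mult <- if (i == j) 1 else 2
        pw[, idx] <- mult * cat_frac[, i] * cat_frac[, j] *
          stats::rgamma(n, shape = 8, rate = 8)
      }
    }
    pair[] <- pw / rowSums(pw)

    renorm_noise <- function(m, sd) {
      m2 <- m * matrix(exp(stats::rnorm(length(m), 0, sd)), nrow(m))
      m2 / rowSums(m2)
    }
    wcomp <- renorm_noise(comp, 0.15)
    colnames(wcomp) <- paste0("wfrac_", aas)
    wcat <- vapply(.categories, function(cc) rowSums(wcomp[, cats == cc, drop = FALSE]), numeric(n))
    colnames(wcat) <- paste0("wcat_", .categories)
    wpair <- renorm_noise(pair, 0.15)
    colnames(wpair) <- paste0("w", pnames)

    sGRAVY <- drop(comp %*% sc_g)
    sSCE <- drop(comp %*% sc_s)
    sPOL <- drop(comp %*% sc_p)
    globals <- data.frame(
      pI = pmin(pmax(stats::rnorm(n, 6.5, 1.5), 3.5), 11.5),
      SASA = stats::rlnorm(n, log(9000), 0.25),
      Rg = pmax(stats::rnorm(n, 18, 2.5), 8),
      GRAVY = sGRAVY + 0.4 + stats::rnorm(n, 0, 0.1),
      sGRAVY = sGRAVY,
      SCE = sSCE + stats::rnorm(n, 0.05, 0.05),
      sSCE = sSCE,
      POL = sPOL - 0.3 + stats::rnorm(n, 0, 0.2),
      sPOL = sPOL
    )

    proteins <- cbind(
      data.frame(protein_id = sprintf("P%04d", seq_len(n))),
      as.data.frame(comp), as.data.frame(cat_frac), as.data.frame(pair),
      as.data.frame(wcomp), as.data.frame(wcat), as.data.frame(wpair),
      globals
    )

    zs <- function(v) (v - mean(v)) / stats::sd(v)
    z_sSCE <- zs(sSCE); z_sGRAVY <- zs(sGRAVY)
    z_catS <- zs(cat_frac[, "cat_S"]); z_catP <- zs(cat_frac[, "cat_P"])
    z_ppn <- zs(pair[, "pair_pos_neg"])

    w <- spec$mechanism_weights
    if (spec$latent == "bumps") {
      bump_ent <- exp(-0.5 * (((z_sSCE + 1) / 0.9)^2 + (z_sGRAVY / 0.9)^2 +
                                ((z_catS - 1) / 1.2)^2))
      bump_elec <- exp(-0.5 * (((z_sSCE - 1) / 0.9)^2 + ((z_catP - 1) / 1.1)^2 +
                                 ((z_ppn - 1) / 1.1)^2))
      latent_desc <- "probit(-1.75 + 2.2*(w1*bump_ent + w2*bump_elec) + noise)"
    } else {
      # null case for nonlinearity tests: the truth is linear in the
      # regression target sqrt(pi), so a linear model is correctly specified
      bump_ent <- 0.25 * (-z_sSCE + 0.5 * z_catS - 0.3 * z_sGRAVY)
      bump_elec <- 0.25 * (0.5 * z_catP + 0.5 * z_ppn)
      latent_desc <- "sqrt(pi) = 0.45 + 0.35*(w1*lin_ent + w2*lin_elec) + noise, clipped"
    }
    zl <- w[1] * bump_ent + w[2] * bump_elec +
      stats::rnorm(n, 0, spec$noise_sd)
    true_prop <- if (spec$latent == "bumps") {
      stats::pnorm(-1.75 + 2.2 * zl)
    } else {
      pmin(pmax(0.45 + 0.35 * zl, 0.05), 0.95)^2
    }

    truth <- structure(list(
      relevant_features = planted_relevant_features(),
      true_length_scales = c(sSCE = 0.9, sGRAVY = 0.9, cat_S = 1.2,
                             cat_P = 1.1, pair_pos_neg = 1.1),
      latent_fn = latent_desc,
      true_propensity = stats::setNames(true_prop, proteins$protein_id),
      mech_entropic = stats::setNames(w[1] * bump_ent, proteins$protein_id),
      mech_electrostatic = stats::setNames(w[2] * bump_elec, proteins$protein_id),
      latent = spec$latent
    ), class = "planted_truth")

    list(proteins = proteins, truth = truth)
  })
}

#' Generate a synthetic raw cocktail table
#'
#' Two condition families: "salt" (moderate-to-high salt alone: one or two
#' cation/anion pairs at 0.3..2.5 M) and "peg" (one PEG at 5..30 % w/v,
#' usually with low salt below 0.4 M). pH is truncated normal on 3..11.
#'
#' @param spec A `screen_spec`.
#' @param registry Species registry.
#' @param max_species Maximum nonzero species per cocktail.
#' @return Data frame: `cocktail_id`, `family`, `pH`, and the 56 species
#'   molarity columns.
#' @export
generate_cocktail_table <- function(spec, registry = build_registry(),
                                    max_species = 4) {
  stopifnot(inherits(spec, "screen_spec"))
  n <- spec$n_cocktails
  cations <- registry$name[registry$kind == "cation"]
  anions <- registry$name[registry$kind == "anion"]
  pegs <- registry$name[registry$kind == "PEG"]
  peg_mass <- stats::setNames(registry$peg_mass[registry$kind == "PEG"], pegs)

  with_seed(spec$seed + 1L, {
    conc <- matrix(0, n, nrow(registry), dimnames = list(NULL, registry$name))
    family <- ifelse(stats::runif(n) < 0.55, "salt", "peg")
    for (i in seq_len(n)) {
      budget <- max_species
      if (family[i] == "salt") {
        n_salt <- min(sample(1:2, 1), budget %/% 2)
        for (k in seq_len(n_salt)) {
          cc <- stats::runif(1, 0.3, 2.5)
          ca <- sample(cations, 1); an <- sample(anions, 1)
          conc[i, ca] <- conc[i, ca] + cc
          conc[i, an] <- conc[i, an] + cc
        }
      } else {
        pg <- sample(pegs, 1)
        pct <- stats::runif(1, 5, 30)              # % w/v
        conc[i, pg] <- pct * 10 / peg_mass[[pg]]   # g/L over g/mol
        if (stats::runif(1) < 0.7) {
          cc <- stats::runif(1, 0.01, 0.4)
          ca <- sample(cations, 1); an <- sample(anions, 1)
          conc[i, ca] <- conc[i, ca] + cc
          conc[i, an] <- conc[i, an] + cc
        }
      }
    }
    # truncated normal pH on [3, 11]
    pH <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        v <- stats::rnorm(1, spec$ph_mean, max(spec$ph_sd, 1e-12))
        if (v >= 3 && v <= 11) { pH[i] <- v; break }
      }
    }
    cbind(data.frame(cocktail_id = sprintf("C%05d", seq_len(n)),
                     family = family, pH = pH),
          as.data.frame(conc))
  })
}

#' Generate Bernoulli screen outcomes
#'
#' Each experiment succeeds with probability Phi(latent(p, c)); the latent is
#' the probit of the planted per-protein propensity shifted by a cocktail
#' tilt: proteins in the electrostatic regime respond positively to ionic
#' strength, proteins in the entropic regime to PEG depletant strength. The
#' tilt is centred over the realized cocktail table and amplitude-bounded, so
#' each protein's marginal success probability equals its planted propensity
#' exactly and empirical success fractions converge to the planted truth as
#' the cocktail count grows.
#'
#' @param protein_table Data frame from [generate_protein_table()].
#' @param cocktail_table Data frame from [generate_cocktail_table()].
#' @param truth A `planted_truth`.
#' @param seed Integer seed for the Bernoulli draws.
#' @param tilt_strength Fraction (0..1) of the feasible tilt amplitude used.
#' @param registry Species registry.
#' @return Long data frame: `protein_id`, `cocktail_id`, `outcome` (0/1).
#' @export
generate_outcomes <- function(protein_table, cocktail_table, truth, seed = 1,
                              tilt_strength = 0.8, registry = build_registry()) {
  if (!nrow(protein_table) || !nrow(cocktail_table)) stop("empty input table")
  ids <- protein_table$protein_id
  if (!all(ids %in% names(truth$true_propensity))) {
    stop("shape mismatch: truth does not cover all proteins")
  }
  conc <- as.matrix(cocktail_table[, registry$name, drop = FALSE])
  ion <- registry$kind %in% c("cation", "anion")
  IS <- 0.5 * drop(conc[, ion, drop = FALSE] %*% (registry$charge[ion]^2))
  peg <- registry$kind == "PEG"
  peg_str <- drop(conc[, peg, drop = FALSE] %*% ((registry$peg_mass[peg] / 1000)^0.588))
  ctr <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v - mean(v)
  s_salt <- ctr(pmin(IS, stats::quantile(IS, 0.99, names = FALSE)))
  s_peg <- ctr(pmin(peg_str, stats::quantile(peg_str, 0.99, names = FALSE)))

  pi_p <- truth$true_propensity[ids]
  w_e <- truth$mech_electrostatic[ids]
  w_n <- truth$mech_entropic[ids]

  with_seed(seed, {
    out <- vector("list", length(ids))
    for (p in seq_along(ids)) {
      tilt <- w_e[p] * s_salt + w_n[p] * s_peg
      tilt <- tilt - mean(tilt)
      mx <- max(abs(tilt))
      amp <- if (mx > 0) tilt_strength * min(pi_p[p], 1 - pi_p[p]) / mx else 0
      prob <- pmin(pmax(pi_p[p] + amp * tilt, 0), 1)
      out[[p]] <- data.frame(protein_id = ids[p],
                             cocktail_id = cocktail_table$cocktail_id,
                             outcome = stats::rbinom(length(prob), 1, prob))
    }
    do.call(rbind, out)
  })
}

#' Observed crystallization propensity per protein
#'
#' @param outcomes Long outcome table from [generate_outcomes()].
#' @return Named numeric vector: fraction of successful cocktails per protein.
#' @export
observed_propensity <- function(outcomes) {
  v <- tapply(outcomes$outcome, outcomes$protein_id, mean)
  stats::setNames(as.numeric(v), names(v))
}

# side-chain heavy atom counts of the standard residues
.sc_atoms <- c(ALA = 1, ARG = 7, ASN = 4, ASP = 4, CYS = 2, GLN = 5, GLU = 5,
               GLY = 0, HIS = 6, ILE = 4, LEU = 4, LYS = 5, MET = 4, PHE = 7,
               PRO = 3, SER = 2, THR = 3, TRP = 10, TYR = 8, VAL = 3)

#' Generate a toy PDB structure
#'
#' Emits a small, valid PDB text (ATOM records, optional CRYST1 and REMARK
#' 290 SMTRY rows) for fixture purposes: an idealized backbone (N, CA, C, O)
#' with generic carbon side-chain atoms matching each residue's heavy-atom
#' count, laid out as an extended strand or an alpha-helix-like spiral. These
#' fixtures carry no crystallographic realism beyond what the parsers and
#' geometry code require.
#'
#' @param residues Character vector of 3-letter residue codes.
#' @param mode "extended" (CA every 3.8 A along x) or "helix" (2.3 A radius,
#'   1.5 A rise, 100 degrees per residue).
#' @param chain Chain identifier.
#' @param cell Optional unit cell `c(a, b, c, alpha, beta, gamma)`.
#' @param sym_ops Optional list of 3x4 Cartesian symmetry operators; an
#'   identity operator is written when a cell is given without operators.
#' @param ca_coords Optional explicit n x 3 matrix of CA positions
#'   (overrides `mode`).
#' @return Character scalar: the PDB file text.
#' @export
generate_toy_structure <- function(residues, mode = c("extended", "helix"),
                                   chain = "A", cell = NULL, sym_ops = NULL,
                                   ca_coords = NULL) {
  mode <- match.arg(mode)
  residues <- toupper(residues)
  unknown <- setdiff(residues, names(.sc_atoms))
  if (length(unknown)) stop("unknown residue code(s): ", paste(unknown, collapse = ", "))
  n <- length(residues)
  if (is.null(ca_coords)) {
    ca_coords <- if (mode == "extended") {
      cbind(3.8 * (seq_len(n) - 1), 0, 0)
    } else {
      ang <- (seq_len(n) - 1) * 100 * pi / 180
      cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * (seq_len(n) - 1))
    }
  }
  stopifnot(nrow(ca_coords) == n)

  lines <- character(0)
  if (!is.null(cell)) {
    lines <- c(lines, format_cryst1(cell))
    if (is.null(sym_ops)) sym_ops <- list(cbind(diag(3), 0))
  }
  if (!is.null(sym_ops)) lines <- c(lines, format_smtry(sym_ops))

  sc_names <- c("CB", "CG", "CD", "CE", "CZ", "CH", "CI", "CJ", "CK", "CL")
  serial <- 0L
  for (i in seq_len(n)) {
    ca <- ca_coords[i, ]
    # side chains point away from the strand/helix axis
    u <- if (mode == "helix" && is.null(dim(ca_coords)) == FALSE) {
      v <- c(ca[1], ca[2], 0)
      if (sum(v^2) < 1e-9) c(0, 1, 0) else v / sqrt(sum(v^2))
    } else c(0, 1, 0)
    atoms <- list(N = c(ca + c(-0.8, -1.0, 0), el = "N"),
                  CA = c(ca, el = "C"),
                  C = c(ca + c(0.8, -1.0, 0), el = "C"),
                  O = c(ca + c(1.2, -2.1, 0), el = "O"))
    for (nm in names(atoms)) {
      serial <- serial + 1L
      xyz <- as.numeric(atoms[[nm]][1:3])
      lines <- c(lines, format_atom_line(serial, nm, residues[i], chain, i,
                                         xyz, atoms[[nm]][["el"]]))
    }
    for (k in seq_len(.sc_atoms[[residues[i]]])) {
      serial <- serial + 1L
      xyz <- ca + u * (1.5 * k)
      lines <- c(lines, format_atom_line(serial, sc_names[k], residues[i],
                                         chain, i, xyz, "C"))
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}
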