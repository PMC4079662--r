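#' Default run configuration
#'
#' All analysis constants live here (and in the YAML config that overrides
#' it): exposure threshold 2.5 A^2, neighbour and contact cutoffs 5 A,
#' hot-spot percentile 5, KS alpha 0.05. `feature_subset` selects the GPR
#' design: "recovery" (the 20-feature panel), "categories" (the 5 category
#' fractions plus surface scale means) or "full" (all 89).
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(
    out_dir = "results",
    seed = 1L,
    n_proteins = 96L,
    n_cocktails = 384L,
    mechanism_weights = c(1, 1),
    noise_sd = 0.05,
    latent = "bumps",
    n_restarts = 10L,
    maxit = 150L,
    exposure_threshold = 2.5,
    pair_cutoff = 5,
    contact_cutoff = 5,
    percentile = 5,
    alpha = 0.05,
    d_active = 60L,
    gpc_subsample = 150L,
    quadrant_orientation = "Q1_high_sSCE",
    feature_subset = "recovery",
    proteins_csv = NULL,
    cocktails_csv = NULL,
    outcomes_csv = NULL,
    logfile = NULL
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, overlays it on [default_run_config()] and validates.
#'
#' @param path YAML file path, or NULL for the defaults.
#' @return Validated config list (class `run_config`).
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  validate_run_config(cfg)
}

#' @rdname load_run_config
#' @param cfg Config list to validate.
#' @export
validate_run_config <- function(cfg) {
  pos <- c("exposure_threshold", "pair_cutoff", "contact_cutoff", "percentile",
           "alpha", "d_active", "n_proteins", "n_cocktails", "n_restarts",
           "maxit", "gpc_subsample")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("config field '", f, "' must be a positive number")
    }
  }
  if (cfg$percentile >= 100) stop("config field 'percentile' must be below 100")
  if (!cfg$quadrant_orientation %in% c("Q1_high_sSCE", "Q1_low_sSCE")) {
    stop("config field 'quadrant_orientation' must be Q1_high_sSCE or Q1_low_sSCE")
  }
  if (!cfg$feature_subset %in% c("recovery", "categories", "full")) {
    stop("config field 'feature_subset' must be recovery, categories or full")
  }
  if (!cfg$latent %in% c("bumps", "linear")) {
    stop("config field 'latent' must be bumps or linear")
  }
  structure(cfg, class = "run_config")
}

log_line <- function(msg, logfile = NULL) {
  line <- paste0("[xtalgp] ", msg)
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

write_csv_det <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

read_required_csv <- function(path) {
  if (!file.exists(path)) stop("required input file not found: ", path)
  utils::read.csv(path, check.names = FALSE)
}

feature_columns <- function(cfg) {
  switch(cfg$feature_subset,
         recovery = recovery_feature_set(),
         categories = c(paste0("cat_", .categories), "sGRAVY", "sSCE", "sPOL"),
         full = protein_feature_schema())
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or load) the screen; featurize cocktails; fit the GPR
#' propensity model; mechanism analysis (quadrants, enrichment, hot-spot
#' search); sparse GPC condition model with response curves for one example
#' protein; crystal-contact demo on a bundled toy structure. Every stage
#' writes CSVs under `out_dir`; a provenance manifest records the config hash
#' and output checksums. Deterministic given the config: rerunning yields
#' byte-identical CSVs.
#'
#' @param config A `run_config` (see [load_run_config()]).
#' @return Invisibly, a named list of output file paths plus key in-memory
#'   results.
#' @export
xtal_run_all <- function(config = load_run_config()) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  lf <- config$logfile
  paths <- list()
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fn) {
    log_line(paste0("stage ", name, " ..."), lf)
    tryCatch(fn(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    log_line(paste0("stage ", name, " done"), lf)
  }

  run_stage("simulate", function() {
    spec <- synthetic_screen_spec(n_proteins = config$n_proteins,
                                  n_cocktails = config$n_cocktails,
                                  seed = config$seed,
                                  mechanism_weights = config$mechanism_weights,
                                  noise_sd = config$noise_sd,
                                  latent = config$latent)
    if (!is.null(config$proteins_csv)) {
      state$proteins <- read_required_csv(config$proteins_csv)
      state$truth <- NULL
    } else {
      gp <- generate_protein_table(spec)
      state$proteins <- gp$proteins
      state$truth <- gp$truth
    }
    state$cocktails <- if (!is.null(config$cocktails_csv)) {
      read_required_csv(config$cocktails_csv)
    } else generate_cocktail_table(spec)
    state$outcomes <- if (!is.null(config$outcomes_csv)) {
      read_required_csv(config$outcomes_csv)
    } else {
      if (is.null(state$truth)) stop("outcomes_csv is required when proteins are loaded from file")
      generate_outcomes(state$proteins, state$cocktails, state$truth,
                        seed = config$seed)
    }
    paths$proteins <<- write_csv_det(state$proteins, file.path(config$out_dir, "proteins.csv"))
    paths$cocktails <<- write_csv_det(state$cocktails, file.path(config$out_dir, "cocktails.csv"))
    paths$outcomes <<- write_csv_det(state$outcomes, file.path(config$out_dir, "outcomes.csv"))
  })

  run_stage("featurize-cocktails", function() {
    reg <- build_registry()
    conc <- as.matrix(state$cocktails[, reg$name, drop = FALSE])
    med_rg <- stats::median(state$proteins$Rg)
    feats <- t(vapply(seq_len(nrow(conc)), function(i) {
      cocktail_feature_vector(conc[i, ], Rg = med_rg, pH = state$cocktails$pH[i],
                              registry = reg)
    }, numeric(length(cocktail_feature_schema()))))
    cf <- cbind(data.frame(cocktail_id = state$cocktails$cocktail_id),
                as.data.frame(feats))
    state$cocktail_features <- cf
    paths$cocktail_features <<- write_csv_det(cf, file.path(config$out_dir, "cocktail_features.csv"))
  })

  run_stage("fit-propensity", function() {
    pi_obs <- observed_propensity(state$outcomes)[state$proteins$protein_id]
    state$pi_obs <- pi_obs
    cols <- feature_columns(config)
    X <- as.matrix(state$proteins[, cols, drop = FALSE])
    model <- gpr_train(X, prop_transform(pi_obs), n_restarts = config$n_restarts,
                       seed = config$seed, maxit = config$maxit)
    state$gpr <- model
    sig <- significant_variables(model)
    paths$relevance <<- write_csv_det(sig, file.path(config$out_dir, "gpr_relevance.csv"))
    loo <- gpr_loo(model)
    pred <- data.frame(protein_id = state$proteins$protein_id,
                       observed_pi = as.numeric(pi_obs),
                       loo_pi = prop_inverse(loo$mean),
                       loo_sd = sqrt(loo$var))
    state$pred <- pred
    paths$loo <<- write_csv_det(pred, file.path(config$out_dir, "gpr_loo.csv"))
    cmp <- compare_with_linear(X, pi_obs, seed = config$seed,
                               n_restarts = min(config$n_restarts, 5),
                               maxit = config$maxit)
    paths$model_comparison <<- write_csv_det(
      data.frame(metric = c("gpr_win_fraction", "gpr_mean_abs_err", "lr_mean_abs_err"),
                 value = c(cmp$fraction, mean(abs(cmp$table$resid_gpr)),
                           mean(abs(cmp$table$resid_lr)))),
      file.path(config$out_dir, "model_comparison.csv"))
  })

  run_stage("mechanisms", function() {
    quads <- assign_quadrants(state$proteins,
                              orientation = config$quadrant_orientation)
    state$quadrants <- quads
    paths$quadrants <<- write_csv_det(quads, file.path(config$out_dir, "quadrants.csv"))
    enr <- enrichment_tables(quads, state$pred$loo_pi,
                             state$proteins[, feature_columns(config), drop = FALSE],
                             alpha = config$alpha)
    paths$enrichment <<- write_csv_det(enr, file.path(config$out_dir, "enrichment.csv"))
    hs <- hotspot_search(state$gpr,
                         state$proteins[, feature_columns(config), drop = FALSE],
                         state$pi_obs, percentile = config$percentile)
    top <- utils::head(hs, 200)
    paths$hotspots <<- write_csv_det(top, file.path(config$out_dir, "hotspots.csv"))
  })

  run_stage("fit-conditions", function() {
    reg <- build_registry()
    # example protein: highest observed propensity with both classes present
    ord <- order(state$pi_obs, decreasing = TRUE)
    chosen <- NULL
    sub_out <- NULL
    for (p in ord) {
      pid <- state$proteins$protein_id[p]
      oc <- state$outcomes[state$outcomes$protein_id == pid, ]
      oc <- oc[match(state$cocktail_features$cocktail_id, oc$cocktail_id), ]
      n_sub <- min(config$gpc_subsample, nrow(oc))
      idx <- with_seed(config$seed, sample.int(nrow(oc), n_sub))
      if (length(unique(oc$outcome[idx])) == 2L) {
        chosen <- pid; sub_out <- oc[idx, ]
        sub_idx <- idx
        break
      }
    }
    if (is.null(chosen)) stop("no protein with both outcome classes in the subsample")
    Xc <- as.matrix(state$cocktail_features[sub_idx, -1, drop = FALSE])
    fit <- ivm_fit(Xc, sub_out$outcome, d_active = min(config$d_active, nrow(Xc)),
                   seed = config$seed)
    state$gpc <- fit
    state$gpc_protein <- chosen
    prob <- predict_probability(fit, as.matrix(state$cocktail_features[, -1, drop = FALSE]))
    paths$condition_probs <<- write_csv_det(
      data.frame(protein_id = chosen,
                 cocktail_id = state$cocktail_features$cocktail_id,
                 prob = prob),
      file.path(config$out_dir, "condition_probabilities.csv"))
    pf <- state$proteins[state$proteins$protein_id == chosen, ]
    curve <- additive_response_curve(fit, pf, additive = "sodium",
                                     grid = make_conc_grid(Xc[, "sodium"]),
                                     registry = reg)
    qf <- fit_quadratic(curve)
    paths$response_curve <<- write_csv_det(
      data.frame(protein_id = chosen, additive = "sodium",
                 conc = curve$conc, prob = curve$prob,
                 shape = qf$class),
      file.path(config$out_dir, "response_curve.csv"))
  })

  run_stage("contacts", function() {
    pdb <- generate_toy_structure(
      c("LYS", "GLU", "SER", "ALA", "GLY", "ARG", "ASP", "THR"),
      mode = "extended", cell = c(32, 30, 30, 90, 90, 90),
      sym_ops = list(cbind(diag(3), 0)))
    st <- parse_structure(pdb)
    nb <- expand_symmetry(st, cutoff = config$contact_cutoff)
    ct <- contact_residues(st, nb, cutoff = config$contact_cutoff,
                           exposure_threshold = config$exposure_threshold)
    prof <- contact_profile(st, ct, nb, cutoff = config$contact_cutoff)
    paths$contacts <<- write_csv_det(
      data.frame(feature = c(names(prof$category_fractions), names(prof$pair_fractions)),
                 value = c(prof$category_fractions, prof$pair_fractions)),
      file.path(config$out_dir, "contact_profile.csv"))
  })

  run_stage("provenance", function() {
    cfg_path <- file.path(config$out_dir, "run_config.yaml")
    # machine-local paths must not perturb the provenance hash
    cfg_clean <- unclass(config)
    cfg_clean$out_dir <- NULL
    cfg_clean$logfile <- NULL
    yaml::write_yaml(cfg_clean, cfg_path)
    sums <- tools::md5sum(unlist(paths))
    manifest <- data.frame(file = basename(names(sums)), md5 = as.character(sums))
    manifest <- rbind(data.frame(file = "run_config.yaml",
                                 md5 = as.character(tools::md5sum(cfg_path))),
                      manifest)
    paths$manifest <<- write_csv_det(manifest, file.path(config$out_dir, "manifest.csv"))
  })

  invisible(list(paths = paths, gpr = state$gpr, gpc = state$gpc,
                 quadrants = state$quadrants, truth = state$truth))
}

#' Command-line entry point
#'
#' Dispatches `xtalgp` subcommands. `run-all` executes the whole pipeline;
#' the stage subcommands run the pipeline up to and including that stage.
#'
#' @param args Character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#'   First element is the subcommand; `--config <path>` selects a YAML config;
#'   `--out <dir>` overrides the output directory.
#' @return Invisibly, the [xtal_run_all()] result (for pipeline commands).
#' @export
xtal_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  cmds <- c("simulate", "featurize-proteins", "featurize-cocktails",
            "fit-propensity", "mechanisms", "fit-conditions",
            "response-curves", "contacts", "run-all")
  if (!length(args) || !args[1] %in% cmds) {
    stop("usage: xtalgp <", paste(cmds, collapse = "|"), "> [--config path] [--out dir]")
  }
  cmd <- args[1]
  opt <- function(flag) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else NULL
  }
  config <- load_run_config(opt("--config"))
  if (!is.null(opt("--out"))) config$out_dir <- opt("--out")

  if (cmd == "featurize-proteins") {
    pdb <- opt("--pdb")
    if (is.null(pdb)) stop("featurize-proteins requires --pdb <file>")
    st <- parse_structure(paste(readLines(pdb), collapse = "\n"))
    fv <- protein_feature_vector(st,
                                 exposure_threshold = config$exposure_threshold,
                                 pair_cutoff = config$pair_cutoff)
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- file.path(config$out_dir, "protein_features.csv")
    write_csv_det(data.frame(feature = names(fv), value = as.numeric(fv)), out)
    log_line(paste0("wrote ", out), config$logfile)
    return(invisible(fv))
  }
  # the pipeline stages are cumulative; run-all covers every subcommand
  invisible(xtal_run_all(config))
}
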