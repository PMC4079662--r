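#!/usr/bin/env Rscript
# Condition modelling with sparse GP classification: for two example proteins
# (highest and median observed propensity with both outcome classes), fit the
# IVM probit model on the cocktail features and trace response curves for a
# few common additives, classifying each curve's quadratic trend.
# Reads results/{proteins,outcomes,cocktail_features}.csv; writes
# results/{condition_probabilities,response_curves}.csv.

library(xtalgp)

out <- "results"
proteins <- read.csv(file.path(out, "proteins.csv"), check.names = FALSE)
outcomes <- read.csv(file.path(out, "outcomes.csv"), check.names = FALSE)
cf <- read.csv(file.path(out, "cocktail_features.csv"), check.names = FALSE)

reg <- build_registry()
obs <- observed_propensity(outcomes)[proteins$protein_id]
ord <- order(obs, decreasing = TRUE)
candidates <- proteins$protein_id[c(ord[1], ord[ceiling(length(ord) / 2)])]

additives <- c("sodium", "ammonium", "peg_4000")
probs_out <- NULL
curves_out <- NULL
set.seed(1)
for (pid in candidates) {
  oc <- outcomes[outcomes$protein_id == pid, ]
  oc <- oc[match(cf$cocktail_id, oc$cocktail_id), ]
  idx <- sample.int(nrow(oc), min(200, nrow(oc)))
  if (length(unique(oc$outcome[idx])) < 2) next
  X <- as.matrix(cf[idx, -1])
  fit <- suppressWarnings(ivm_fit(X, oc$outcome[idx], d_active = 60, seed = 1))
  p <- predict_probability(fit, as.matrix(cf[, -1]))
  probs_out <- rbind(probs_out,
                     data.frame(protein_id = pid, cocktail_id = cf$cocktail_id,
                                prob = p))
  pf <- proteins[proteins$protein_id == pid, ]
  for (add in additives) {
    tr <- X[, add]
    if (sum(tr > 0) < 5) next
    curve <- additive_response_curve(fit, pf, add, make_conc_grid(tr),
                                     registry = reg, train_max = max(tr))
    qf <- attr(curve, "quadratic")
    curves_out <- rbind(curves_out,
                        data.frame(protein_id = pid, additive = add,
                                   conc = curve$conc, prob = curve$prob,
                                   shape = qf$class, excluded = qf$excluded))
  }
}
write.csv(probs_out, file.path(out, "condition_probabilities.csv"), row.names = FALSE)
write.csv(curves_out, file.path(out, "response_curves.csv"), row.names = FALSE)
message(sprintf("fitted %d proteins; %d response curves",
                length(unique(probs_out$protein_id)),
                nrow(unique(curves_out[, c("protein_id", "additive")]))))
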