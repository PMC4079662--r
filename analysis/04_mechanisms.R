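#!/usr/bin/env Rscript
# Mechanism analysis: quadrant assignment on the sGRAVY-sSCE plane, KS
# enrichment of features between easy- and hard-to-crystallize proteins
# within each quadrant, and the constrained hot-spot search around the most
# crystallizable proteins.
# Reads results/{proteins,outcomes}.csv and gpr_loo.csv; writes
# results/{quadrants,enrichment,hotspots}.csv.

library(xtalgp)

out <- "results"
proteins <- read.csv(file.path(out, "proteins.csv"), check.names = FALSE)
outcomes <- read.csv(file.path(out, "outcomes.csv"), check.names = FALSE)
loo <- read.csv(file.path(out, "gpr_loo.csv"), check.names = FALSE)

obs <- observed_propensity(outcomes)[proteins$protein_id]

quads <- assign_quadrants(proteins)
write.csv(quads, file.path(out, "quadrants.csv"), row.names = FALSE)
message(paste(capture.output(print(table(quads$quadrant))), collapse = "\n"))

panel <- proteins[, recovery_feature_set()]
enr <- enrichment_tables(quads, loo$loo_pi, panel)
write.csv(enr, file.path(out, "enrichment.csv"), row.names = FALSE)

# hot-spot search needs the fitted GPR model; refit with the same settings as
# the propensity driver (deterministic, so the model is identical)
model <- gpr_train(as.matrix(panel), prop_transform(obs), n_restarts = 20,
                   seed = 1, maxit = 200)
hs <- hotspot_search(model, panel, obs, percentile = 5, n_grid = 4)
write.csv(head(hs, 500), file.path(out, "hotspots.csv"), row.names = FALSE)
message(sprintf("%d enrichment rows; hot-spot grid over: %s",
                nrow(enr), paste(attr(hs, "significant"), collapse = ", ")))
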