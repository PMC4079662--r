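#!/usr/bin/env Rscript
# Simulate the full-size synthetic crystallization screen: 182 proteins
# against 1,536 cocktails, with the planted two-mechanism truth retained for
# later validation. Writes results/{proteins,cocktails,outcomes,truth}.csv.

library(xtalgp)

out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- synthetic_screen_spec(n_proteins = 182, n_cocktails = 1536,
                              seed = 20260101)
gp <- generate_protein_table(spec)
ck <- generate_cocktail_table(spec)
oc <- generate_outcomes(gp$proteins, ck, gp$truth, seed = spec$seed)

write.csv(gp$proteins, file.path(out, "proteins.csv"), row.names = FALSE)
write.csv(ck, file.path(out, "cocktails.csv"), row.names = FALSE)
write.csv(oc, file.path(out, "outcomes.csv"), row.names = FALSE)
write.csv(data.frame(protein_id = names(gp$truth$true_propensity),
                     true_propensity = as.numeric(gp$truth$true_propensity),
                     mech_entropic = as.numeric(gp$truth$mech_entropic),
                     mech_electrostatic = as.numeric(gp$truth$mech_electrostatic)),
          file.path(out, "truth.csv"), row.names = FALSE)

obs <- observed_propensity(oc)[gp$proteins$protein_id]
message(sprintf("simulated %d proteins x %d cocktails; observed propensity %.3f (mean), %.3f-%.3f (range)",
                spec$n_proteins, spec$n_cocktails, mean(obs), min(obs), max(obs)))
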