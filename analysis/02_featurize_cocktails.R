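#!/usr/bin/env Rscript
# Convert the raw cocktail table into the 61-dimensional solution feature
# vectors (56 species molarities + pH, ionic strength, Hofmeister sums and
# the PEG depletion coefficient at the panel's median radius of gyration).
# Reads results/{proteins,cocktails}.csv, writes results/cocktail_features.csv.

library(xtalgp)

out <- "results"
proteins <- read.csv(file.path(out, "proteins.csv"), check.names = FALSE)
cocktails <- read.csv(file.path(out, "cocktails.csv"), check.names = FALSE)

reg <- build_registry()
med_rg <- median(proteins$Rg)
conc <- as.matrix(cocktails[, reg$name])
feats <- t(vapply(seq_len(nrow(conc)), function(i) {
  cocktail_feature_vector(conc[i, ], Rg = med_rg, pH = cocktails$pH[i],
                          registry = reg)
}, numeric(length(cocktail_feature_schema()))))

write.csv(cbind(data.frame(cocktail_id = cocktails$cocktail_id),
                as.data.frame(feats)),
          file.path(out, "cocktail_features.csv"), row.names = FALSE)
message(sprintf("featurized %d cocktails (median Rg %.1f A)", nrow(conc), med_rg))
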