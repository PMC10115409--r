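#!/usr/bin/env Rscript
## Preprocess the bundle the way the real dataset is prepared:
## merge dialects (keep the least-missing variety under its parent id),
## crop features then taxa above 25% missing, and impute the remainder
## with the chained random-forest imputer.

suppressMessages(library(lingdiv))

b_matrix <- read_trait_matrix("results/bundle/traits.tsv")
meta <- read.csv("results/bundle/taxa.csv", stringsAsFactors = FALSE)

merged <- merge_dialects(b_matrix, meta)
cat(sprintf("full matrix missing fraction: %.3f\n",
            missing_fraction(merged$matrix)))

cropped <- crop_missing(merged$matrix, threshold = 0.25)
cat(sprintf("after crop: %d taxa x %d features, %.3f missing\n",
            nrow(cropped$values), ncol(cropped$values),
            missing_fraction(cropped)))

imp <- impute(cropped, seed = 42, n_trees = 100)
cat(sprintf("imputation: %d sweeps, OOB error %.3f\n",
            imp$n_iterations, imp$oob_error))

write_trait_matrix(cropped, "results/cropped.tsv")
write_trait_matrix(imp$completed, "results/imputed.tsv")
meta_out <- merged$meta[match(taxon_ids(cropped), merged$meta$taxon_id), ]
write.csv(meta_out, "results/taxa_cropped.csv", row.names = FALSE)
write.csv(data.frame(feature = names(imp$oob_by_feature),
                     oob = imp$oob_by_feature),
          "results/imputation_oob.csv", row.names = FALSE)
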