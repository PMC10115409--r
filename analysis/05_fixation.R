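#!/usr/bin/env Rscript
## Between-area cultural fixation scores on the cropped (non-imputed)
## matrix, the similarity network over areas, and the modularity of a
## two-way split of the areas.

suppressMessages(library(lingdiv))

cropped <- read_trait_matrix("results/cropped.tsv")
meta <- read.csv("results/taxa_cropped.csv", stringsAsFactors = FALSE)

grouping <- setNames(meta$cultural_area, meta$taxon_id)
ft <- pairwise_fst(cropped, grouping)
write.csv(ft$scores, "results/fst_areas.csv")
cat(sprintf("%d areas; fixation scores in [%.3f, %.3f], mean %.3f\n",
            nrow(ft$scores), min(ft$scores[lower.tri(ft$scores)]),
            max(ft$scores), mean(ft$scores[lower.tri(ft$scores)])))

## edge list of the similarity network (max(F) - F transform)
W <- max(ft$scores) - ft$scores; diag(W) <- 0
el <- which(upper.tri(W), arr.ind = TRUE)
write.csv(data.frame(from = rownames(W)[el[, 1]], to = colnames(W)[el[, 2]],
                     weight = W[el]),
          "results/fst_network_edges.csv", row.names = FALSE)

## does a geographic half-split form a community?
groups <- rownames(ft$scores)
half <- setNames(ifelse(seq_along(groups) <= length(groups) / 2, "A", "B"),
                 groups)
q <- partition_modularity(ft, half)
cat(sprintf("modularity of an arbitrary half-split: %.3f\n", q))
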