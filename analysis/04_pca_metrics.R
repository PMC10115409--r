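#!/usr/bin/env Rscript
## Dimensionality of the grammar design space: PCA on the imputed matrix,
## nongraphical scree component count, typological consistency metrics,
## and PGLS correlations of components with metric scores.

suppressMessages(library(lingdiv))
suppressMessages(library(ape))

imputed <- read_trait_matrix("results/imputed.tsv")
weights <- read.csv("results/bundle/metric_weights.csv", stringsAsFactors = FALSE)
sets <- read.csv("results/bundle/function_sets.csv", stringsAsFactors = FALSE)
tree <- read.tree("results/bundle/tree.nwk")

pca <- run_pca(imputed)
k <- optimal_components(pca$sdev^2)
cat(sprintf("optimal components: %d (capture %.1f%% of variance)\n",
            k, 100 * sum(pca$variance_fractions[1:k])))
cat(sprintf("first three components capture %.1f%% (%s)\n",
            100 * sum(pca$variance_fractions[1:3]),
            paste(sprintf("%.1f%%", 100 * pca$variance_fractions[1:3]),
                  collapse = ", ")))

scores <- consistency_scores(imputed, weights)
scores$informativity <- informativity_scores(imputed, sets)$informativity
write.csv(scores, "results/metric_scores.csv", row.names = FALSE)

## Pearson matrix (scores vs first three components)
pcs <- pca$scores[, 1:3]
cormat <- cor(cbind(pcs, scores[, -1]), use = "pairwise.complete.obs")
write.csv(round(cormat, 3), "results/metric_pc_correlations.csv")

## PGLS of each of the first three components on each metric
common <- intersect(scores$taxon_id, tree$tip.label)
V <- brownian_vcv(keep.tip(tree, common), taxa_order = common)$vcv
rows <- list()
for (pcn in colnames(pcs)) for (m in setdiff(names(scores), "taxon_id")) {
  x <- scores[[m]][match(common, scores$taxon_id)]
  y <- pcs[match(common, rownames(pcs)), pcn]
  if (anyNA(x) || sd(x) == 0) next
  g <- pgls_corr(x, y, V)
  rows[[paste(pcn, m)]] <- data.frame(component = pcn, metric = m,
                                      coef = g$coef, se = g$se,
                                      corr = g$corr)
}
pgls <- do.call(rbind, rows)
write.csv(pgls, "results/pgls_metric_pcs.csv", row.names = FALSE)
print(pgls[order(-abs(pgls$coef)), ][1:5, ], row.names = FALSE)

## RGB projection of the first three components (for map plotting)
write.csv(data.frame(taxon_id = rownames(pca$scores), pc_rgb(pca$scores)),
          "results/pc_rgb.csv", row.names = FALSE)
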