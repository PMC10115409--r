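#!/usr/bin/env Rscript
## Grammar unusualness: kernel-density and latent-class surprisal on the
## imputed matrix, estimator selection by skewness, Manhattan distances,
## and the Bayesian regression of unusualness on family and area with
## phylogenetic and spatial random effects.

suppressMessages(library(lingdiv))
suppressMessages(library(ape))

imputed <- read_trait_matrix("results/imputed.tsv")
cropped <- read_trait_matrix("results/cropped.tsv")
meta <- read.csv("results/taxa_cropped.csv", stringsAsFactors = FALSE)
tree <- read.tree("results/bundle/tree.nwk")

us <- surprisal_scores(imputed, kernels = c(1, 5, 10, 15, 20, 25, 30, 40),
                       lca = TRUE, seed = 42)
write.csv(us$scores, "results/unusualness.csv", row.names = FALSE)
cat("skewness by estimator:\n")
print(round(us$selection$skewness, 3))
cat(sprintf("selected estimator: %s\n", us$selection$chosen))

u <- us$scores[[us$selection$chosen]]
names(u) <- us$scores$taxon_id
top <- names(sort(u, decreasing = TRUE))[1:10]
cat("most unusual taxa:", paste(top[1:5], collapse = ", "), "...\n")

## Manhattan distances (skip rule) on the non-imputed matrix
mh <- manhattan_matrix(cropped)
cat(sprintf("Manhattan distances: max %d of %d features, mean %.1f, %d identical pairs\n",
            max(mh), ncol(as.matrix(cropped)), mean(mh[lower.tri(mh)]),
            sum(mh[lower.tri(mh)] == 0)))
write.csv(mh, "results/manhattan.csv")

## regression of unusualness on family + area with correlated effects
common <- intersect(names(u), tree$tip.label)
trs <- keep.tip(tree, common)
m2 <- meta[match(common, meta$taxon_id), ]
## singleton families are unidentifiable against the phylogenetic random
## effect (their coefficient and their tip effect are confounded): lump
## families below 4 members, as is standard for fixed-effect coding
small <- names(which(table(m2$family) < 4))
m2$family[m2$family %in% small] <- "smallfam"
pcv <- brownian_vcv(trs, taxa_order = common)
scv <- matern_cov(data.frame(lat = m2$lat, lon = m2$lon,
                             row.names = common))
fit <- unusualness_regression(u[common], m2$family, m2$cultural_area,
                              pcv, scv, chains = 4, iterations = 6000,
                              burnin = 1000, seed = 42)
write.csv(fit$coefficients, "results/unusualness_regression.csv",
          row.names = FALSE)
cat(sprintf("Bayesian R2 (family/area component): %.2f (sd %.2f), max Rhat %.3f\n",
            fit$bayes_r2["mean"], fit$bayes_r2["sd"], fit$rhat_max))
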