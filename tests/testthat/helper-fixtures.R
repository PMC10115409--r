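## Shared fixture builders; everything is generated in code.

## tiny raw-code trait matrix with a multistate word-order feature
tiny_raw_matrix <- function() {
  v <- rbind(
    taxA = c("1", "0", "XY"),
    taxB = c("0", NA, "both"),
    taxC = c("1", "1", "YX")
  )
  colnames(v) <- c("F1", "F2", "WO1")
  trait_matrix(v)
}

tiny_feature_meta <- function() {
  data.frame(feature_id = c("F1", "F2", "WO1"),
             description = c("f1", "f2", "order"),
             multistate = c(FALSE, FALSE, TRUE),
             grammar_domain = c("nominal", "verbal", "clausal"),
             stringsAsFactors = FALSE)
}

tiny_meta <- function(taxa, level = "language", parent = NA_character_) {
  data.frame(taxon_id = taxa, level = level, parent_id = parent,
             lat = seq(-10, 10, length.out = length(taxa)),
             lon = seq(0, 30, length.out = length(taxa)),
             family = "famX", macroarea = "macro1",
             cultural_area = "areaA", endangerment = "not endangered",
             stringsAsFactors = FALSE)
}

## small ultrametric tree with depth 1 and named tips
fixture_tree <- function(n, seed = 42) {
  set.seed(seed)
  tr <- ape::rphylo(n, birth = 1, death = 0.5)
  tr$tip.label <- sprintf("t%03d", seq_len(n))
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr
}

fixture_coords <- function(tree, seed = 43) {
  set.seed(seed)
  n <- ape::Ntip(tree)
  data.frame(lat = stats::runif(n, -50, 60),
             lon = stats::runif(n, -180, 180),
             row.names = tree$tip.label)
}

## random binary matrix with optional missingness
random_binary_matrix <- function(n, p, miss = 0, prob = 0.5, seed = 1) {
  set.seed(seed)
  v <- matrix(rbinom(n * p, 1, prob), n, p,
              dimnames = list(sprintf("tx%03d", seq_len(n)),
                              sprintf("f%03d", seq_len(p))))
  if (miss > 0) v[matrix(runif(n * p) < miss, n, p)] <- NA
  trait_matrix(v, binarized = TRUE)
}

## write a tiny CLDF-style fixture into a temp dir; returns the paths
write_cldf_fixture <- function(dir = tempfile("cldf")) {
  dir.create(dir)
  vals <- data.frame(
    Language_ID = rep(c("taxA", "taxB", "taxC"), each = 2),
    Parameter_ID = rep(c("F1", "F2"), 3),
    Value = c("1", "0", "?", "1", "0", "1"))
  langs <- data.frame(ID = c("taxA", "taxB", "taxC"),
                      Level = "language", Parent_ID = NA,
                      Latitude = c(1, 2, 3), Longitude = c(10, 20, 30),
                      Family = "famX", Macroarea = "m1",
                      Cultural_Area = "a1", AES = "not endangered")
  feats <- data.frame(ID = c("F1", "F2"), Name = c("feat one", "feat two"),
                      Multistate = FALSE, Domain = c("nominal", "verbal"))
  p <- list(values = file.path(dir, "values.csv"),
            taxa = file.path(dir, "languages.csv"),
            features = file.path(dir, "parameters.csv"))
  write.csv(vals, p$values, row.names = FALSE)
  write.csv(langs, p$taxa, row.names = FALSE)
  write.csv(feats, p$features, row.names = FALSE)
  p
}
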