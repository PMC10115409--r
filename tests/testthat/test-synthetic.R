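test_that("generated bundles have the requested shape and are seeded", {
  cfg <- synth_config(n_taxa = 50, n_features = 20, n_spatial_features = 4,
                      n_noise_features = 4, n_dialect_pairs = 0,
                      missing_rate = 0.2, seed = 81)
  b1 <- generate_dataset(cfg)
  expect_equal(dim(b1$matrix), c(50, 20))
  expect_equal(length(b1$tree$tip.label), 50)
  expect_equal(nrow(b1$meta), 50)
  b2 <- generate_dataset(cfg)
  expect_identical(b1$matrix$values, b2$matrix$values)
  expect_identical(b1$meta, b2$meta)
  expect_identical(ape::write.tree(b1$tree), ape::write.tree(b2$tree))
  expect_error(synth_config(n_taxa = 0), "n_taxa")
  expect_error(synth_config(n_features = 4, n_spatial_features = 10),
               "exceed")
})

test_that("realized missingness concentrates near the requested rate", {
  cfg <- synth_config(n_taxa = 150, n_features = 70, n_spatial_features = 10,
                      n_noise_features = 10, n_dialect_pairs = 0,
                      missing_rate = 0.24, seed = 82)
  b <- generate_dataset(cfg)
  expect_lt(abs(missing_fraction(b$matrix) - 0.24), 0.02)
  ## clustered mode also hits the target on average
  cfgc <- synth_config(n_taxa = 150, n_features = 70, n_spatial_features = 10,
                       n_noise_features = 10, n_dialect_pairs = 0,
                       missing_rate = 0.24, missing_mode = "clustered",
                       seed = 83)
  bc <- generate_dataset(cfgc)
  expect_lt(abs(missing_fraction(bc$matrix) - 0.24), 0.06)
})

test_that("dialect injection creates mergeable near-duplicates", {
  cfg <- synth_config(n_taxa = 40, n_features = 16, n_spatial_features = 3,
                      n_noise_features = 3, n_dialect_pairs = 5,
                      missing_rate = 0.1, seed = 84)
  b <- generate_dataset(cfg)
  expect_equal(nrow(b$matrix$values), 45)
  expect_equal(sum(b$meta$level == "dialect"), 10)
  expect_true(all(!is.na(b$meta$parent_id[b$meta$level == "dialect"])))
  m <- suppressMessages(merge_dialects(b$matrix, b$meta))
  expect_equal(nrow(m$matrix$values), 40)
  expect_setequal(taxon_ids(m$matrix), b$tree$tip.label)
})

test_that("truth record reproduces the generating conditions", {
  cfg <- synth_config(n_taxa = 60, n_features = 30, n_spatial_features = 6,
                      n_noise_features = 6, n_dialect_pairs = 0,
                      missing_rate = 0, seed = 85)
  b <- generate_dataset(cfg)
  tf <- b$truth$features
  expect_equal(length(tf), 30)
  kinds <- vapply(tf, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "phylo"), 18)
  expect_equal(sum(kinds == "spatial"), 6)
  expect_equal(sum(kinds == "noise"), 6)
  ## realized prevalence matches the recorded value on the complete matrix
  v <- b$matrix$values
  for (fid in names(tf)[kinds == "phylo"][1:3])
    expect_equal(mean(v[, fid]), tf[[fid]]$realized)
  ## phylogenetic features are more heritable than noise features:
  ## closest-relative pairs agree more often
  D <- ape::cophenetic.phylo(b$tree); diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  agree <- function(fid) mean(v[, fid] == v[nn, fid])
  a_ph <- mean(vapply(names(tf)[kinds == "phylo"], agree, numeric(1)))
  a_ns <- mean(vapply(names(tf)[kinds == "noise"], agree, numeric(1)))
  expect_gt(a_ph, a_ns)
})

test_that("the simulation grid covers every condition with valid prevalences", {
  tr <- fixture_tree(40, seed = 86)
  bat <- replicate_simulation_grid(tr, seed = 87, n_reps = 2)
  expect_equal(ncol(bat), 4 * 3 * 2)
  conds <- attr(bat, "conditions")
  expect_equal(nrow(conds), 24)
  for (i in seq_len(ncol(bat)))
    expect_lte(abs(mean(bat[, i]) - conds$prevalence[i]), 0.05)
  ## replicates within a condition are not degenerate copies
  same <- which(conds$lambda == 0.9 & conds$prevalence == 0.25)
  expect_false(identical(bat[, same[1]], bat[, same[2]]))
})

test_that("multistate generation feeds the binarization path", {
  cfg <- synth_config(n_taxa = 30, n_features = 12, n_spatial_features = 2,
                      n_noise_features = 2, n_multistate = 2,
                      n_dialect_pairs = 0, missing_rate = 0.1, seed = 88)
  b <- generate_dataset(cfg)
  expect_false(b$matrix$binarized)
  expect_equal(sum(b$feature_meta$multistate), 2)
  bb <- binarize(b$matrix, b$feature_meta)
  expect_equal(ncol(bb$matrix$values), 14)
  expect_true(bb$matrix$binarized)
})
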