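test_that("PCoA embeds exact Euclidean configurations", {
  ## collinear points: one dimension carries everything
  x <- c(0, 3, 7)
  D <- as.matrix(dist(x)); dimnames(D) <- list(letters[1:3], letters[1:3])
  e <- pcoa_embed(D, dims = 2)
  expect_equal(e$variance_fractions[1], 1, tolerance = 1e-10)
  expect_equal(unname(as.matrix(dist(e$coords[, 1]))), unname(D),
               tolerance = 1e-8)
  ## planar points: pairwise distances reproduced
  set.seed(61)
  pts <- matrix(rnorm(20), 10, 2)
  D2 <- as.matrix(dist(pts))
  e2 <- pcoa_embed(D2, dims = 2)
  expect_lt(max(abs(as.matrix(dist(e2$coords)) - D2)), 1e-8)
  expect_error(pcoa_embed(matrix(1:9, 3)), "symmetric")
})

test_that("PCoA eigenvalues match a hand eigendecomposition of the Gram matrix", {
  v <- rbind(a = c(0, 0, 1, 1), b = c(1, 0, 1, 0),
             c = c(1, 1, 0, 0), d = c(0, 1, 0, 1))
  D <- as.matrix(dist(v, method = "manhattan"))
  ## brute-force double centring
  D2 <- D^2
  J <- diag(4) - matrix(1 / 4, 4, 4)
  B <- -0.5 * J %*% D2 %*% J
  ev_oracle <- sort(eigen(B, symmetric = TRUE, only.values = TRUE)$values,
                    decreasing = TRUE)
  e <- pcoa_embed(D, dims = 2)
  expect_equal(sort(e$eig, decreasing = TRUE)[1:3], ev_oracle[1:3],
               tolerance = 1e-8)
})

test_that("PCoA is an involution up to rigid motion", {
  tm <- random_binary_matrix(20, 10, seed = 62)
  e1 <- pcoa_embed(gower_matrix(tm), dims = 2)
  D2 <- as.matrix(dist(e1$coords))
  e2 <- pcoa_embed(D2, dims = 2)
  ## rigid motions preserve all pairwise distances, so re-embedding the
  ## embedded configuration must reproduce them exactly
  expect_lt(max(abs(as.matrix(dist(e2$coords)) - D2)), 1e-6)
  ## and the agreement holds configuration-wise after alignment
  pr <- vegan::procrustes(e1$coords, e2$coords)
  expect_lt(max(abs(pr$Yrot - e1$coords)), 1e-6)
})

test_that("hull areas match known geometry and are monotone", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  rownames(sq) <- paste0("p", 1:4)
  expect_equal(hull_richness(sq), 1)
  expect_equal(hull_richness(sq, c("p1", "p2")), 0)
  expect_warning(expect_equal(hull_richness(sq, character(0)), 0), "empty")
  ## subsets never exceed their superset; random deletions are monotone
  set.seed(63)
  pts <- matrix(rnorm(60), 30, 2, dimnames = list(paste0("q", 1:30), NULL))
  a_full <- hull_richness(pts)
  for (r in 1:10) {
    keep <- sample(rownames(pts), sample(3:29, 1))
    a_sub <- hull_richness(pts, keep)
    expect_lte(a_sub, a_full + 1e-12)
    a_sub2 <- hull_richness(pts, sample(keep, max(3, length(keep) - 4)))
    expect_lte(a_sub2, a_sub + 1e-12)
  }
  ## collinear subsets have zero area
  col3 <- rbind(c(0, 0), c(1, 1), c(2, 2)); rownames(col3) <- paste0("c", 1:3)
  expect_equal(hull_richness(col3), 0)
})

test_that("endangerment split is a partition with AES semantics", {
  meta <- data.frame(
    taxon_id = paste0("t", 1:6),
    endangerment = c("not endangered", "threatened", "shifting",
                     "nearly extinct", NA, "moribund"))
  sp <- endangerment_split(meta)
  expect_equal(sp$nonthreatened, "t1")
  expect_equal(sort(sp$threatened), c("t2", "t3", "t4", "t6"))
  expect_equal(sp$excluded, "t5")
  expect_setequal(c(sp$nonthreatened, sp$threatened, sp$excluded),
                  meta$taxon_id)
  meta$endangerment[2] <- "mystery label"
  expect_error(endangerment_split(meta), "unknown endangerment.*mystery")
})

test_that("richness report handles all-threatened, none-threatened and interior loss", {
  set.seed(64)
  b <- generate_dataset(synth_config(n_taxa = 60, n_features = 24,
                                     n_spatial_features = 4,
                                     n_noise_features = 4,
                                     missing_rate = 0, n_dialect_pairs = 0,
                                     n_regions = 3, seed = 65))
  meta <- b$meta
  ## force one region fully threatened and one fully safe
  r <- sort(unique(meta$cultural_area))
  meta$endangerment[meta$cultural_area == r[1]] <- "moribund"
  meta$endangerment[meta$cultural_area == r[2]] <- "not endangered"
  meta$endangerment[is.na(meta$endangerment)] <- "not endangered"
  rep <- suppressMessages(richness_report(b$matrix, meta))
  tab <- rep$table
  expect_equal(tab$ratio[tab$region == r[1]], 0)
  expect_equal(tab$ratio[tab$region == r[2]], 1)
  expect_true(all(tab$area_nonthreatened <= tab$area_all + 1e-12))
  expect_true(all(tab$ratio >= 0 & tab$ratio <= 1))
  ## the global area dominates every regional area
  g <- tab$area_all[tab$region == "GLOBAL"]
  expect_true(all(tab$area_all[tab$region != "GLOBAL"] <= g + 1e-12))
  ## threatened taxa strictly inside the hull do not reduce the area
  pts <- rbind(matrix(c(0, 0, 4, 0, 4, 4, 0, 4), 4, 2, byrow = TRUE),
               matrix(runif(10, 1, 3), 5, 2))
  rownames(pts) <- paste0("z", 1:9)
  a_all <- hull_richness(pts)
  a_corners <- hull_richness(pts, paste0("z", 1:4))
  expect_equal(a_all, a_corners)
})
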