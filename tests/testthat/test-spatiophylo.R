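## shared fixtures for the model tests (built once per file)
tr60 <- fixture_tree(60, seed = 71)
co60 <- fixture_coords(tr60, seed = 72)
pc60 <- brownian_vcv(tr60)
sc60 <- matern_cov(co60)

test_that("pc_prior validates and encodes the exponential rate", {
  p <- pc_prior(1, 0.1)
  expect_equal(p$rate, -log(0.1))
  expect_error(pc_prior(0, 0.1), "u must be")
  expect_error(pc_prior(1, 1.2), "alpha")
})

test_that("a strongly phylogenetic trait loads on the phylogenetic component", {
  y <- simulate_binary_trait(tr60, 0.9, 0.3, seed = 73)
  f <- fit_feature(y, pc60, sc60)
  expect_gt(f$prop_phylo["mean"], f$prop_spatial["mean"])
  vp <- variance_partition(f)
  expect_equal(unname(vp["prop_phylo"]), unname(f$prop_phylo["mean"]))
  expect_lte(vp["prop_phylo"] + vp["prop_spatial"], 1)
  expect_true(all(vp >= 0 & vp <= 1))
  ## raw ratios drop the logistic residual and grow accordingly
  expect_gte(variance_partition(f, raw = TRUE)["prop_phylo"],
             vp["prop_phylo"])
})

test_that("missing responses are tolerated and degenerate traits flagged", {
  y <- simulate_binary_trait(tr60, 0.6, 0.3, seed = 74)
  y[sample(60, 12)] <- NA
  f <- fit_feature(y, pc60, sc60)
  expect_equal(f$n_obs, 48)
  expect_false(f$degenerate)
  y1 <- setNames(rep(1L, 60), tr60$tip.label)
  expect_warning(f1 <- fit_feature(y1, pc60, sc60), "degenerate")
  expect_true(f1$degenerate)
  expect_error(fit_feature(y[1:10], pc60, sc60), "cover|length")
})

test_that("duplicated features give identical fits and summaries skip degenerates", {
  y <- simulate_binary_trait(tr60, 0.6, 0.25, seed = 75)
  v <- cbind(fA = y, fB = y, fC = rep(1L, 60))
  rownames(v) <- tr60$tip.label
  fits <- run_all_features(trait_matrix(v, binarized = TRUE), pc60, sc60)
  expect_equal(fits$prop_phylo[1], fits$prop_phylo[2], tolerance = 1e-10)
  expect_true(fits$degenerate[3])
  s <- attr(fits, "summary")
  expect_equal(s$n_features, 2)
  expect_equal(s$mean_prop_phylo, mean(fits$prop_phylo[1:2]))
})

test_that("simulated traits hit their target prevalence and are seeded", {
  y1 <- simulate_binary_trait(tr60, 0.6, 0.25, seed = 76, tol = 0.05)
  y2 <- simulate_binary_trait(tr60, 0.6, 0.25, seed = 76, tol = 0.05)
  expect_identical(y1, y2)
  expect_true(abs(mean(y1) - 0.25) <= 0.05)
  expect_error(simulate_binary_trait(tr60, 0.6, 1.2), "prevalence")
  expect_error(
    simulate_binary_trait(tr60, 0.6, 0.25, seed = 1, tol = 1e-6,
                          max_tries = 5),
    "could not reach")
})

test_that("ancestral probabilities respect consensus and clade structure", {
  y1 <- setNames(rep(1L, 60), tr60$tip.label)
  ar <- suppressWarnings(ancestral_reconstruction(y1, tr60, sc60))
  expect_true(all(ar$prob > 0.5))
  expect_true(all(ar$prob >= 0 & ar$prob <= 1))

  ## trait split perfectly by the two root clades of a balanced tree:
  ## the root is torn between the clades while each clade's ancestor
  ## leans towards its own state
  bt <- ape::stree(16, "balanced")
  bt <- ape::compute.brlen(bt, 1)
  bt$edge.length <- bt$edge.length / max(ape::node.depth.edgelength(bt))
  set.seed(70)
  bco <- data.frame(lat = runif(16, -40, 40), lon = runif(16, -150, 150),
                    row.names = bt$tip.label)
  bsc <- matern_cov(bco)
  left <- ape::extract.clade(bt, 18)$tip.label  # first child of the root
  y <- setNames(as.integer(bt$tip.label %in% left), bt$tip.label)
  ar2 <- ancestral_reconstruction(y, bt, bsc)
  p_root <- ar2$prob[ar2$node == 17]
  expect_gt(p_root, 0.25); expect_lt(p_root, 0.75)
  kids <- bt$edge[bt$edge[, 1] == 17, 2]
  p_left <- ar2$prob[ar2$node == kids[1]]
  p_right <- ar2$prob[ar2$node == kids[2]]
  expect_gt(p_left, p_root)
  expect_lt(p_right, p_root)
  ## direction agrees with a two-state ML reconstruction
  ml <- ape::ace(factor(y[bt$tip.label]), bt, type = "discrete",
                 model = "ER")
  ml_p1 <- ml$lik.anc[, "1"]
  agree <- mean((ar2$prob > 0.5) == (ml_p1 > 0.5))
  expect_gt(agree, 0.8)
  expect_error(ancestral_reconstruction(y + 0.5, bt, bsc), "binary")
})

test_that("domain effect test separates null from shifted domains", {
  set.seed(77)
  dom <- rep(c("clausal", "nominal", "verbal"), each = 25)
  null_props <- rbeta(75, 2, 3)
  r0 <- domain_effect_test(null_props, dom, n_iter = 1200, n_burn = 400,
                           seed = 2)
  expect_false(r0$improvement)
  expect_lt(abs(r0$delta_waic), r0$se_delta + 1e-9)
  shifted <- null_props
  shifted[dom == "verbal"] <- pmin(shifted[dom == "verbal"] + 0.3, 0.999)
  r1 <- domain_effect_test(shifted, dom, n_iter = 1200, n_burn = 400,
                           seed = 2)
  expect_true(r1$improvement)
  expect_error(domain_effect_test(null_props, rep("one", 75)), "two domains")
  ## boundary proportions are nudged, not fatal
  bp <- c(0, null_props[-1])
  expect_message(domain_effect_test(bp, dom, n_iter = 400, n_burn = 200),
                 "nudged")
})

test_that("unusualness regression recovers planted family effects", {
  set.seed(78)
  n <- 60
  fam <- sample(c("famA", "famB", "famC"), n, replace = TRUE)
  area <- sample(c("east", "west"), n, replace = TRUE)
  hits <- 0; total <- 0
  betaB <- 1.2; betaC <- -0.8
  for (rep_i in 1:6) {
    u <- 2 + betaB * (fam == "famB") + betaC * (fam == "famC") +
      rnorm(n, 0, 0.5)
    fit <- suppressWarnings(
      unusualness_regression(u, fam, area, pc60, sc60, chains = 2,
                             iterations = 1500, burnin = 700, seed = rep_i))
    co <- fit$coefficients
    for (tb in list(c("famB", betaB), c("famC", betaC))) {
      row <- co[grepl(tb[1], co$term), ]
      total <- total + 1
      if (row$lower <= as.numeric(tb[2]) && as.numeric(tb[2]) <= row$upper)
        hits <- hits + 1
    }
    expect_true(all(fit$bayes_r2 >= 0 & fit$bayes_r2 <= 1))
  }
  expect_gte(hits / total, 0.8)
})

test_that("pure-noise unusualness yields a small Bayesian R-squared", {
  set.seed(79)
  n <- 60
  fam <- sample(c("famA", "famB"), n, replace = TRUE)
  area <- sample(c("east", "west"), n, replace = TRUE)
  u <- rnorm(n)
  fit <- suppressWarnings(
    unusualness_regression(u, fam, area, pc60, sc60, chains = 2,
                           iterations = 1500, burnin = 700, seed = 3))
  expect_lt(fit$bayes_r2["mean"], 0.15)
})
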