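test_that("Gower distance follows the mutual-observation rule", {
  expect_equal(gower_distance(c(1, 0, 1, 1), c(1, 0, 1, 1)), 0)
  expect_equal(gower_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(gower_distance(rep(c(1, 0), 4), c(0, 1, rep(c(1, 0), 3))), 0.25)
  expect_equal(gower_distance(c(1, 0, NA), c(0, 0, 1)), 0.5)
  expect_true(is.na(gower_distance(c(NA, 1), c(0, NA))))
  ## matrix form agrees with the pairwise definition
  tm <- random_binary_matrix(10, 8, miss = 0.2, seed = 51)
  D <- gower_matrix(tm)
  v <- tm$values
  for (i in c(1, 4)) for (j in c(2, 9))
    expect_equal(D[i, j], gower_distance(v[i, ], v[j, ]))
})

test_that("kernel scores reproduce the worked contribution magnitudes", {
  ## a neighbour at 10% difference boosts the broad kernel by ~0.9 and
  ## the most local kernel by ~0.02
  expect_equal(round(exp(-1 * 0.1), 1), 0.9)
  expect_equal(round(exp(-1 * 0.2), 1), 0.8)
  expect_equal(round(exp(-1 * 0.5), 1), 0.6)
  expect_equal(signif(exp(-40 * 0.1), 1), 0.02)
  expect_equal(signif(exp(-40 * 0.2), 1), 0.0003)
  expect_equal(signif(exp(-40 * 0.5), 1), 2e-09)
  ## self contributes exp(0) = 1: a singleton dataset has P = 1, U = 0
  single <- trait_matrix(matrix(c(1L, 0L), 1, 2,
                                dimnames = list("solo", c("f1", "f2"))),
                         binarized = TRUE)
  expect_equal(unname(kernel_scores(single, 15)), 1)
  expect_equal(unname(surprisal(kernel_scores(single, 15))), 0)
  expect_error(kernel_scores(single, 0), "k must be > 0")
})

test_that("kernel surprisal decreases when a duplicate neighbour is added", {
  tm <- random_binary_matrix(20, 12, seed = 52)
  for (k in c(1, 15, 40)) {
    u0 <- surprisal(kernel_scores(tm, k))
    v2 <- rbind(tm$values, dup = tm$values[3, ])
    rownames(v2)[21] <- "dup"
    u1 <- surprisal(kernel_scores(trait_matrix(v2, binarized = TRUE), k))
    expect_lte(u1[3], u0[3])
    expect_true(all(u1[1:20] <= u0 + 1e-12))
  }
})

test_that("large-k kernel ranking approaches nearest-neighbour ranking", {
  tm <- random_binary_matrix(25, 14, seed = 53)
  u <- kernel_surprisal(tm, 400)
  D <- gower_matrix(tm); diag(D) <- NA
  nn <- apply(D, 1, min, na.rm = TRUE)
  ## every pair with distinct nearest-neighbour distances is ordered by
  ## them (within an nn tie the kernel refines by neighbour counts)
  for (i in 1:24) for (j in (i + 1):25) {
    if (nn[i] != nn[j])
      expect_equal(sign(u[i] - u[j]), sign(nn[i] - nn[j]),
                   info = sprintf("pair %d-%d", i, j))
  }
  ## the stable path agrees with the plain definition where both resolve
  u40 <- kernel_surprisal(tm, 40)
  expect_equal(u40, surprisal(kernel_scores(tm, 40)), tolerance = 1e-9)
})

test_that("feature bundling recovers planted blocks and collapses under noise", {
  set.seed(54)
  a <- rbinom(80, 1, 0.5); b <- rbinom(80, 1, 0.5)
  v <- cbind(a, a, a, b, b, b)  # two blocks of duplicated columns
  dimnames(v) <- list(sprintf("t%02d", 1:80), sprintf("f%d", 1:6))
  bl <- bundle_features(trait_matrix(v, binarized = TRUE), seed = 5)
  expect_equal(bl$k, 2)
  expect_equal(length(unique(bl$bundle[1:3])), 1)
  expect_equal(length(unique(bl$bundle[4:6])), 1)
  expect_false(bl$bundle[1] == bl$bundle[4])
  ## i.i.d. columns: one bundle in the majority of seeded runs
  ks <- vapply(1:5, function(s) {
    vv <- matrix(rbinom(80 * 8, 1, 0.5), 80, 8,
                 dimnames = list(sprintf("t%02d", 1:80), sprintf("f%d", 1:8)))
    bundle_features(trait_matrix(vv, binarized = TRUE), seed = s)$k
  }, numeric(1))
  expect_gte(mean(ks == 1), 0.6)
  ## determinism
  b2 <- bundle_features(trait_matrix(v, binarized = TRUE), seed = 5)
  expect_identical(b2$bundle, bl$bundle)
})

test_that("latent class probabilities normalize over the full grammar space", {
  ## brute-force oracle: sum of P over all 2^p grammars must be 1
  set.seed(55)
  for (p in c(4, 6)) {
    v <- matrix(rbinom(40 * p, 1, runif(1, 0.3, 0.7)), 40, p,
                dimnames = list(sprintf("t%02d", 1:40), sprintf("f%d", 1:p)))
    tm <- trait_matrix(v, binarized = TRUE)
    bundle <- setNames(rep(1:2, length.out = p), colnames(v))
    fit <- lca_probability(tm, bundle, max_classes = 3, seed = 6,
                           n_restarts = 3)
    grammars <- as.matrix(expand.grid(rep(list(0:1), p)))
    colnames(grammars) <- colnames(v)
    tot <- sum(lca_grammar_probability(grammars, fit$models))
    expect_equal(tot, 1, tolerance = 1e-8)
  }
})

test_that("a single latent class collapses to smoothed marginal products", {
  set.seed(56)
  v <- matrix(rbinom(60 * 3, 1, 0.4), 60, 3,
              dimnames = list(sprintf("t%02d", 1:60), c("fa", "fb", "fc")))
  tm <- trait_matrix(v, binarized = TRUE)
  bundle <- setNames(rep(1L, 3), colnames(v))
  fit <- lca_probability(tm, bundle, max_classes = 1, seed = 7)
  theta <- (colSums(v) + 1) / (60 + 2)   # add-one smoothing
  expected <- apply(v, 1, function(x) prod(theta^x * (1 - theta)^(1 - x)))
  expect_equal(unname(fit$prob), unname(expected), tolerance = 1e-6)
})

test_that("BIC finds two classes when a bundle is a clean mixture", {
  set.seed(57)
  n <- 120
  cl <- rep(0:1, each = n / 2)
  v <- sapply(1:5, function(j) rbinom(n, 1, ifelse(cl == 1, 0.9, 0.1)))
  dimnames(v) <- list(sprintf("t%03d", 1:n), sprintf("f%d", 1:5))
  fit <- lca_probability(trait_matrix(v, binarized = TRUE),
                         setNames(rep(1L, 5), colnames(v)),
                         max_classes = 4, seed = 8)
  expect_equal(unname(fit$classes["1"]), 2)
})

test_that("estimator selection minimizes absolute skewness", {
  set.seed(58)
  sym <- rnorm(200)
  skewed <- rexp(200)
  sel <- select_estimator(list(sym = sym, skewed = skewed))
  expect_equal(sel$chosen, "sym")
  expect_lt(abs(sel$skewness["sym"]), 0.3)
  ## exactly symmetric sample has zero skewness
  x <- c(-2, -1, 0, 1, 2)
  s0 <- select_estimator(list(a = x, b = x + rexp(5)))
  expect_equal(unname(s0$skewness["a"]), 0)
  ## mirrored distributions tie; lexicographically first tag wins
  expect_message(
    tie <- select_estimator(list(zeta = skewed, alpha = -skewed)),
    "tie")
  expect_equal(tie$chosen, "alpha")
  ## constant vectors are excluded with a warning
  expect_warning(select_estimator(list(c = rep(1, 5), d = rnorm(5))),
                 "constant")
})

test_that("the most-unusual set is the top share of the surprisal distribution", {
  u <- setNames(c(5, 1, 3, 2, 4, 0, 6, 2.5, 1.5, 0.5), paste0("t", 1:10))
  expect_equal(most_unusual(u), "t7")
  expect_equal(most_unusual(u, 0.3), c("t7", "t1", "t5"))
  expect_error(most_unusual(u, 1.2), "share")
})

test_that("Manhattan distances obey the skip rule", {
  v <- rbind(a = c(1L, 0L, NA), b = c(0L, 0L, 1L), c = c(1L, 0L, NA))
  colnames(v) <- c("f1", "f2", "f3")
  D <- manhattan_matrix(trait_matrix(v, binarized = TRUE))
  expect_equal(D["a", "b"], 1L)
  expect_equal(D["a", "c"], 0L)
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), rep(0L, 3))
  ## complementary complete rows count every feature
  n <- 113
  v2 <- rbind(x = rep(0L, n), y = rep(1L, n))
  colnames(v2) <- sprintf("f%03d", 1:n)
  expect_equal(manhattan_matrix(trait_matrix(v2, binarized = TRUE))["x", "y"],
               113L)
})
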