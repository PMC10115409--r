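test_that("structure dataset reading populates the matrix and metadata", {
  p <- write_cldf_fixture()
  ds <- read_structure_dataset(p$values, p$taxa, p$features)
  v <- as.matrix(ds$matrix)
  expect_equal(dim(v), c(3, 2))
  expect_equal(v["taxA", "F1"], "1")
  expect_equal(v["taxC", "F2"], "1")
  ## "?" becomes missing
  expect_true(is.na(v["taxB", "F1"]))
  expect_equal(ds$taxa$taxon_id, c("taxA", "taxB", "taxC"))
  expect_equal(ds$features$grammar_domain, c("nominal", "verbal"))
})

test_that("duplicate value rows and missing columns are rejected", {
  p <- write_cldf_fixture()
  vals <- read.csv(p$values)
  write.csv(rbind(vals, vals[1, ]), p$values, row.names = FALSE)
  expect_error(read_structure_dataset(p$values, p$taxa, p$features),
               "duplicate value rows.*taxA, F1")
  write.csv(vals[, c("Language_ID", "Value")], p$values, row.names = FALSE)
  expect_error(read_structure_dataset(p$values, p$taxa, p$features),
               "required columns.*Parameter_ID")
})

test_that("taxa absent from metadata are kept with a warning", {
  p <- write_cldf_fixture()
  langs <- read.csv(p$taxa)
  write.csv(langs[langs$ID != "taxC", ], p$taxa, row.names = FALSE)
  expect_warning(ds <- read_structure_dataset(p$values, p$taxa, p$features),
                 "taxC")
  expect_true("taxC" %in% taxon_ids(ds$matrix))
  expect_true(is.na(ds$taxa$lat[ds$taxa$taxon_id == "taxC"]))
})

test_that("trait matrix TSV round-trip is the identity", {
  tm <- random_binary_matrix(12, 7, miss = 0.2, seed = 7)
  f <- tempfile(fileext = ".tsv")
  write_trait_matrix(tm, f)
  back <- read_trait_matrix(f)
  expect_identical(back$values, tm$values)
  expect_identical(back$binarized, TRUE)
  ## raw codes round-trip too
  raw <- tiny_raw_matrix()
  f2 <- tempfile(fileext = ".tsv")
  write_trait_matrix(raw, f2)
  expect_identical(read_trait_matrix(f2)$values, raw$values)
})

test_that("dialect merge keeps the least-missing variety under the parent id", {
  v <- rbind(
    X_d1 = c("1", NA, NA, "0", NA),   # 3 missing
    X_d2 = c("1", NA, NA, NA, NA),    # 5 missing (worse)... actually 4
    Y    = c("0", "1", "1", "1", "0")
  )
  v["X_d2", ] <- c(NA, NA, NA, NA, NA)
  colnames(v) <- paste0("f", 1:5)
  meta <- tiny_meta(rownames(v))
  meta$level <- c("dialect", "dialect", "language")
  meta$parent_id <- c("X", "X", NA)
  out <- suppressMessages(merge_dialects(trait_matrix(v), meta))
  expect_equal(sort(taxon_ids(out$matrix)), c("X", "Y"))
  ## the retained row is the less-missing dialect X_d1, re-labelled X
  expect_equal(unname(as.matrix(out$matrix)["X", 1]), "1")
  expect_equal(sum(is.na(as.matrix(out$matrix)["X", ])), 3)
  expect_equal(out$meta$level, c("language", "language"))
})

test_that("dialect merge is a no-op without dialects and errors on orphans", {
  tm <- random_binary_matrix(5, 4, seed = 3)
  meta <- tiny_meta(taxon_ids(tm))
  out <- merge_dialects(tm, meta)
  expect_identical(out$matrix$values, tm$values)
  meta$level[2] <- "dialect"  # no parent_id
  expect_error(merge_dialects(tm, meta), "without parent_id.*tx002")
})

test_that("equal-missingness dialect ties break lexicographically", {
  v <- rbind(zz = c("1", NA), aa = c("0", NA))
  colnames(v) <- c("f1", "f2")
  meta <- tiny_meta(rownames(v), level = "dialect", parent = "X")
  out <- suppressMessages(merge_dialects(trait_matrix(v), meta))
  expect_equal(unname(as.matrix(out$matrix)["X", "f1"]), "0")  # aa kept
})

test_that("binarization maps the three word-order states and keeps shape", {
  b <- binarize(tiny_raw_matrix(), tiny_feature_meta())
  v <- as.matrix(b$matrix)
  expect_equal(colnames(v), c("F1", "F2", "WO1a", "WO1b"))
  expect_equal(unname(v["taxA", c("WO1a", "WO1b")]), c(1L, 0L))  # XY
  expect_equal(unname(v["taxB", c("WO1a", "WO1b")]), c(1L, 1L))  # both
  expect_equal(unname(v["taxC", c("WO1a", "WO1b")]), c(0L, 1L))  # YX
  expect_true(b$matrix$binarized)
  expect_false(any(b$features$multistate))
})

test_that("binarization propagates missing and rejects unknown states", {
  v <- tiny_raw_matrix()$values
  v["taxB", "WO1"] <- NA
  b <- binarize(trait_matrix(v), tiny_feature_meta())
  expect_true(all(is.na(as.matrix(b$matrix)["taxB", c("WO1a", "WO1b")])))
  v["taxB", "WO1"] <- "ZZ"
  expect_error(binarize(trait_matrix(v), tiny_feature_meta()),
               "unrecognized multistate value.*WO1.*taxB.*ZZ")
})

test_that("missingness crop drops features first, then taxa", {
  v <- matrix(1L, 4, 4, dimnames = list(paste0("t", 1:4), paste0("f", 1:4)))
  v[1:2, 1] <- NA          # feature f1 50% missing
  tm <- trait_matrix(v, binarized = TRUE)
  out <- suppressMessages(crop_missing(tm, 0.25))
  expect_equal(feature_ids(out), c("f2", "f3", "f4"))
  expect_equal(nrow(as.matrix(out)), 4)  # taxa survive once f1 is gone

  ## a taxon above threshold after the feature pass is dropped
  v2 <- v
  v2[1, ] <- NA
  out2 <- suppressMessages(crop_missing(trait_matrix(v2, binarized = TRUE), 0.25))
  expect_false("t1" %in% taxon_ids(out2))

  ## complete matrix unchanged; threshold 0 removes anything touched by NA
  cm <- random_binary_matrix(5, 5, seed = 2)
  expect_identical(suppressMessages(crop_missing(cm, 0.25))$values, cm$values)
  v3 <- cm$values; v3[2, 3] <- NA
  out3 <- suppressMessages(crop_missing(trait_matrix(v3, binarized = TRUE), 0)$values)
  expect_false(anyNA(out3))
  expect_equal(dim(out3), c(5, 4))
  expect_error(crop_missing(cm, 1.5), "threshold")
})

test_that("missing fraction is the plain cell proportion", {
  v <- matrix(c(1L, NA, 0L, 1L), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(missing_fraction(trait_matrix(v, binarized = TRUE)), 0.25)
  expect_equal(missing_fraction(random_binary_matrix(4, 4)), 0)
  allna <- matrix(NA_integer_, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(missing_fraction(trait_matrix(allna, binarized = TRUE)), 1)
  expect_error(missing_fraction(matrix(nrow = 0, ncol = 0)), "empty")
})
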