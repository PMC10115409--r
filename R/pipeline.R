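#' Run the analysis pipeline end to end
#'
#' Chains the stages over a dataset bundle (as produced by
#' \code{\link{generate_dataset}} or assembled from
#' \code{\link{read_structure_dataset}} plus a tree): preprocessing
#' (dialect merge, binarization, missingness crop), imputation, and the
#' requested analyses (variance partitioning, PCA + metrics, fixation
#' scores, unusualness, functional richness). Each stage writes its
#' table under \code{out_dir} and a manifest records inputs, seeds,
#' parameter knobs and timings; inputs on disk are never mutated.
#'
#' @param bundle list with \code{matrix}, \code{meta}, \code{tree},
#'   \code{feature_meta}, optionally \code{weights} and \code{sets}
#' @param out_dir output directory (created)
#' @param stages character subset of \code{c("signal", "pca", "fst",
#'   "unusualness", "richness")}
#' @param seed integer seed used for every stochastic stage
#' @param crop_threshold missingness crop threshold
#' @param n_trees imputation forest size
#' @param kernels kernel sweep for unusualness
#' @param prior \code{pc_prior} for the signal stage
#' @return (invisibly) list of stage results; files under \code{out_dir}
#' @export
run_pipeline <- function(bundle, out_dir,
                         stages = c("pca", "fst", "unusualness", "richness"),
                         seed = 1, crop_threshold = 0.25, n_trees = 100,
                         kernels = c(1, 5, 10, 15, 20, 25, 30, 40),
                         prior = pc_prior()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  manifest <- list(seed = seed,
                   stages = stages,
                   knobs = list(crop_threshold = crop_threshold,
                                n_trees = n_trees, kernels = kernels,
                                pc_prior = unclass(prior)[c("u", "alpha")]),
                   timings = list())
  tic <- function() Sys.time()
  toc <- function(nm, t0) manifest$timings[[nm]] <<-
    round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)

  t0 <- tic()
  merged <- merge_dialects(bundle$matrix, bundle$meta)
  bin <- if (merged$matrix$binarized) {
    list(matrix = merged$matrix, features = bundle$feature_meta)
  } else {
    binarize(merged$matrix, bundle$feature_meta)
  }
  cropped <- crop_missing(bin$matrix, threshold = crop_threshold)
  meta <- merged$meta[match(rownames(cropped$values), merged$meta$taxon_id), ]
  write_trait_matrix(cropped, file.path(out_dir, "cropped.tsv"))
  manifest$missing_fraction_full <- missing_fraction(bin$matrix)
  manifest$missing_fraction_cropped <- missing_fraction(cropped)
  toc("preprocess", t0)

  t0 <- tic()
  imp <- impute(cropped, seed = seed, n_trees = n_trees)
  write_trait_matrix(imp$completed, file.path(out_dir, "imputed.tsv"))
  manifest$oob_error <- imp$oob_error
  toc("impute", t0)

  results <- list(cropped = cropped, imputed = imp, meta = meta)

  common <- intersect(rownames(cropped$values), bundle$tree$tip.label)
  tree <- ape::keep.tip(bundle$tree, common)
  coords <- meta[match(common, meta$taxon_id), c("lat", "lon")]
  rownames(coords) <- common

  if ("signal" %in% stages) {
    t0 <- tic()
    pc <- brownian_vcv(tree, taxa_order = common)
    sc <- matern_cov(coords)
    sub <- cropped$values[common, , drop = FALSE]
    fits <- run_all_features(trait_matrix(sub, binarized = TRUE), pc, sc,
                             prior = prior)
    utils::write.csv(fits, file.path(out_dir, "signal.csv"), row.names = FALSE)
    results$signal <- fits
    toc("signal", t0)
  }

  if ("pca" %in% stages) {
    t0 <- tic()
    pca <- run_pca(imp$completed)
    k <- optimal_components(pca$sdev^2)
    scores <- consistency_scores(imp$completed, bundle$weights)
    if (!is.null(bundle$sets))
      scores$informativity <-
        informativity_scores(imp$completed, bundle$sets)$informativity
    utils::write.csv(data.frame(taxon_id = rownames(pca$scores),
                                pca$scores[, 1:min(5, ncol(pca$scores))]),
                     file.path(out_dir, "pc_scores.csv"), row.names = FALSE)
    utils::write.csv(scores, file.path(out_dir, "metric_scores.csv"),
                     row.names = FALSE)
    manifest$optimal_components <- k
    manifest$var_first3 <- sum(pca$variance_fractions[1:3])
    results$pca <- pca; results$metric_scores <- scores
    results$optimal_components <- k
    toc("pca", t0)
  }

  if ("fst" %in% stages) {
    t0 <- tic()
    grouping <- stats::setNames(meta$cultural_area, meta$taxon_id)
    fst <- pairwise_fst(cropped, grouping)
    utils::write.csv(fst$scores, file.path(out_dir, "fst.csv"))
    results$fst <- fst
    toc("fst", t0)
  }

  if ("unusualness" %in% stages) {
    t0 <- tic()
    us <- surprisal_scores(imp$completed, kernels = kernels, seed = seed)
    utils::write.csv(us$scores, file.path(out_dir, "unusualness.csv"),
                     row.names = FALSE)
    manifest$chosen_estimator <- us$selection$chosen
    results$unusualness <- us
    mh <- manhattan_matrix(cropped)
    manifest$max_manhattan <- max(mh)
    results$manhattan <- mh
    toc("unusualness", t0)
  }

  if ("richness" %in% stages) {
    t0 <- tic()
    rep <- richness_report(imp$completed, meta)
    utils::write.csv(rep$table, file.path(out_dir, "richness.csv"),
                     row.names = FALSE)
    results$richness <- rep
    toc("richness", t0)
  }

  manifest$total_seconds <-
    round(as.numeric(difftime(Sys.time(), t_start, units = "secs")), 2)
  manifest$file_checksums <- as.list(tools::md5sum(
    list.files(out_dir, full.names = TRUE, pattern = "\\.(csv|tsv)$")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}
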