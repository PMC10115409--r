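#' Configuration for the synthetic dataset generator
#'
#' Defaults mirror the statistical structure the analysis pipeline
#' assumes in real cross-linguistic data: binary features with
#' phylogenetic signal across the Pagel's-lambda grid {0.01, 0.3, 0.6,
#' 0.9} and prevalences {0.1, 0.25, 0.4}, a set of spatially
#' autocorrelated features (Matern field, kappa = 2, phi = 1.15),
#' independent noise features, 24\% missing data, dialect duplicates,
#' coordinate-derived regions and skewed endangerment labels.
#'
#' @param n_taxa number of languages (tree tips)
#' @param n_features total feature count (phylogenetic features =
#'   n_features - n_spatial_features - n_noise_features - n_multistate)
#' @param lambda_grid,prevalence_grid condition grids cycled over the
#'   phylogenetic features
#' @param n_spatial_features,n_noise_features,n_multistate feature
#'   counts by generating process
#' @param matern_smoothness,matern_range spatial field parameters
#' @param missing_rate MCAR missingness rate
#' @param missing_mode \code{"mcar"} or \code{"clustered"} (per-taxon
#'   blocks of features go missing together, mimicking undocumented
#'   grammar sections)
#' @param n_dialect_pairs languages replaced by two near-duplicate
#'   dialect rows
#' @param n_regions number of cultural areas (k-means on coordinates)
#' @param threatened_fraction average probability that a language is
#'   endangered (regional skew is applied around it)
#' @param seed integer seed
#' @return list of class \code{synth_config}
#' @export
synth_config <- function(n_taxa = 200, n_features = 60,
                         lambda_grid = c(0.01, 0.3, 0.6, 0.9),
                         prevalence_grid = c(0.1, 0.25, 0.4),
                         n_spatial_features = 12, n_noise_features = 12,
                         n_multistate = 0,
                         matern_smoothness = 2, matern_range = 1.15,
                         missing_rate = 0.24,
                         missing_mode = c("mcar", "clustered"),
                         n_dialect_pairs = 10, n_regions = 8,
                         threatened_fraction = 0.4, seed = 1) {
  missing_mode <- match.arg(missing_mode)
  n_phylo <- n_features - n_spatial_features - n_noise_features - n_multistate
  cfg <- list(n_taxa = n_taxa, n_features = n_features,
              lambda_grid = lambda_grid, prevalence_grid = prevalence_grid,
              n_phylo_features = n_phylo,
              n_spatial_features = n_spatial_features,
              n_noise_features = n_noise_features,
              n_multistate = n_multistate,
              matern_smoothness = matern_smoothness,
              matern_range = matern_range,
              missing_rate = missing_rate, missing_mode = missing_mode,
              n_dialect_pairs = n_dialect_pairs, n_regions = n_regions,
              threatened_fraction = threatened_fraction, seed = seed)
  if (n_taxa < 4) stop("n_taxa must be at least 4")
  if (n_phylo < 0) stop("feature counts exceed n_features")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0,1]")
  if (threatened_fraction < 0 || threatened_fraction > 1)
    stop("threatened_fraction must be in [0,1]")
  if (n_dialect_pairs > n_taxa / 2) stop("too many dialect pairs")
  structure(cfg, class = "synth_config")
}

#' Generate a complete synthetic dataset bundle
#'
#' Draws a birth--death tree, spatially autocorrelated coordinates
#' (Brownian diffusion along the tree), binary features with controlled
#' phylogenetic signal and prevalence, thresholded Matern-field spatial
#' features, i.i.d. noise features, missing-at-random cells, dialect
#' duplicates with parent links, k-means regions over the coordinates,
#' endangerment labels with per-region skew, and synthetic metric-weight
#' and function-set tables. Every generating parameter is stored in the
#' returned truth record.
#'
#' @param config a \code{synth_config}
#' @return list: \code{matrix} (trait_matrix; raw codes if multistate
#'   features are present, otherwise binarized), \code{meta},
#'   \code{tree}, \code{feature_meta}, \code{weights}, \code{sets},
#'   \code{truth}
#' @export
generate_dataset <- function(config = synth_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_taxa
  tree <- ape::rphylo(n, birth = 1, death = 0.5)
  tree$tip.label <- sprintf("lang%03d", seq_len(n))
  tree$edge.length <- tree$edge.length /
    max(ape::node.depth.edgelength(tree))

  ## coordinates: Brownian diffusion along the tree, clamped to the globe
  V <- ape::vcv.phylo(tree)
  lon <- MASS::mvrnorm(1, rep(0, n), 55^2 * V) + stats::runif(1, -120, 120)
  lat <- MASS::mvrnorm(1, rep(0, n), 30^2 * V)
  lon <- ((lon + 180) %% 360) - 180
  lat <- pmax(pmin(lat, 70), -55)
  names(lon) <- names(lat) <- tree$tip.label

  conds <- expand.grid(lambda = cfg$lambda_grid,
                       prevalence = cfg$prevalence_grid)
  truth <- list(config = cfg, features = list())
  cols <- list()
  femeta <- list()
  add_meta <- function(fid, kind, multistate = FALSE, domain = NA) {
    femeta[[fid]] <<- data.frame(feature_id = fid, description = kind,
                                 multistate = multistate,
                                 grammar_domain = domain,
                                 stringsAsFactors = FALSE)
  }
  domains <- c("clausal", "nominal", "pronominal", "verbal")
  ## phylogenetic features
  for (i in seq_len(cfg$n_phylo_features)) {
    cnd <- conds[(i - 1) %% nrow(conds) + 1, ]
    x <- simulate_binary_trait(tree, cnd$lambda, cnd$prevalence)
    fid <- sprintf("PH%03d", i)
    cols[[fid]] <- as.character(x)
    truth$features[[fid]] <- list(kind = "phylo", lambda = cnd$lambda,
                                  prevalence = cnd$prevalence,
                                  realized = mean(x))
    add_meta(fid, "phylogenetic trait", domain = domains[(i - 1) %% 4 + 1])
  }
  ## spatial features: thresholded Matern Gaussian field
  if (cfg$n_spatial_features > 0) {
    S <- matern_cov(data.frame(lat = lat, lon = lon),
                    smoothness = cfg$matern_smoothness,
                    range_par = cfg$matern_range)$vcv
    S <- S + diag(1e-6, n)
    for (i in seq_len(cfg$n_spatial_features)) {
      pv <- cfg$prevalence_grid[(i - 1) %% length(cfg$prevalence_grid) + 1]
      z <- MASS::mvrnorm(1, rep(0, n), S)
      x <- as.integer(z >= stats::quantile(z, 1 - pv))
      fid <- sprintf("SP%03d", i)
      cols[[fid]] <- as.character(x)
      truth$features[[fid]] <- list(kind = "spatial", prevalence = pv,
                                    realized = mean(x))
      add_meta(fid, "spatial trait", domain = domains[(i - 1) %% 4 + 1])
    }
  }
  ## i.i.d. noise features
  for (i in seq_len(cfg$n_noise_features)) {
    pv <- cfg$prevalence_grid[(i - 1) %% length(cfg$prevalence_grid) + 1]
    x <- stats::rbinom(n, 1, pv)
    fid <- sprintf("NS%03d", i)
    cols[[fid]] <- as.character(x)
    truth$features[[fid]] <- list(kind = "noise", prevalence = pv,
                                  realized = mean(x))
    add_meta(fid, "noise trait", domain = domains[(i - 1) %% 4 + 1])
  }
  ## multistate word-order features from two latent order traits
  for (i in seq_len(cfg$n_multistate)) {
    a <- simulate_binary_trait(tree, 0.6, 0.4)
    b <- simulate_binary_trait(tree, 0.6, 0.4)
    st <- ifelse(a == 1 & b == 1, "both",
                 ifelse(a == 1, "XY", ifelse(b == 1, "YX",
                        sample(c("XY", "YX"), n, replace = TRUE))))
    fid <- sprintf("WO%03d", i)
    cols[[fid]] <- st
    truth$features[[fid]] <- list(kind = "multistate")
    add_meta(fid, "word-order trait", multistate = TRUE, domain = "clausal")
  }
  v <- do.call(cbind, cols)
  rownames(v) <- tree$tip.label

  ## missingness
  if (cfg$missing_rate > 0) {
    if (cfg$missing_mode == "mcar") {
      drop <- matrix(stats::runif(length(v)) < cfg$missing_rate, nrow(v))
    } else {
      ## clustered: contiguous feature blocks go missing per taxon
      drop <- matrix(FALSE, nrow(v), ncol(v))
      blocks <- split(seq_len(ncol(v)),
                      ceiling(seq_len(ncol(v)) / max(1, ncol(v) %/% 6)))
      for (i in seq_len(nrow(v))) for (b in blocks)
        if (stats::runif(1) < cfg$missing_rate) drop[i, b] <- TRUE
    }
    v[drop] <- NA
  }

  ## regions from coordinates
  km <- stats::kmeans(cbind(lon, lat), centers = min(cfg$n_regions, n),
                      nstart = 5)
  region <- sprintf("area%02d", km$cluster)
  macro <- sprintf("macro%01d", stats::kmeans(cbind(lon, lat),
                                              centers = min(4, n),
                                              nstart = 5)$cluster)
  ## families: clades below a fixed depth threshold
  family <- synth_families(tree)

  ## endangerment with per-region skew
  tf <- cfg$threatened_fraction
  reg_prob <- stats::rbeta(cfg$n_regions, 4 * tf + 0.1, 4 * (1 - tf) + 0.1)
  names(reg_prob) <- sprintf("area%02d", seq_len(cfg$n_regions))
  threatened <- stats::runif(n) < reg_prob[region]
  endang <- ifelse(threatened,
                   sample(c("threatened", "shifting", "moribund",
                            "nearly extinct"), n, replace = TRUE),
                   "not endangered")
  endang[sample.int(n, max(1, round(0.01 * n)))] <- NA

  meta <- data.frame(taxon_id = tree$tip.label, level = "language",
                     parent_id = NA_character_, lat = lat, lon = lon,
                     family = family, macroarea = macro,
                     cultural_area = region, endangerment = endang,
                     stringsAsFactors = FALSE)

  ## dialect injection: replace some language rows by two dialect rows
  truth$dialects <- character(0)
  if (cfg$n_dialect_pairs > 0) {
    picks <- sample(tree$tip.label, cfg$n_dialect_pairs)
    truth$dialects <- picks
    for (pid in picks) {
      row <- v[pid, ]
      d1 <- row
      d2 <- row
      flip <- sample(which(!is.na(row)), min(2, sum(!is.na(row))))
      d2[flip] <- as.character(1 - as.numeric(d2[flip]))
      extra <- sample(which(!is.na(d2)), min(3, sum(!is.na(d2))))
      d2[extra] <- NA
      id1 <- paste0(pid, "_d1"); id2 <- paste0(pid, "_d2")
      v <- v[rownames(v) != pid, , drop = FALSE]
      v <- rbind(v, rbind(d1, d2))
      rownames(v)[(nrow(v) - 1):nrow(v)] <- c(id1, id2)
      base <- meta[meta$taxon_id == pid, ]
      meta <- meta[meta$taxon_id != pid, ]
      for (id in c(id1, id2)) {
        nr <- base; nr$taxon_id <- id; nr$level <- "dialect"
        nr$parent_id <- pid
        meta <- rbind(meta, nr)
      }
    }
    o <- order(rownames(v))
    v <- v[o, , drop = FALSE]
    meta <- meta[order(meta$taxon_id), ]
    rownames(meta) <- NULL
  }

  fmeta <- do.call(rbind, femeta); rownames(fmeta) <- NULL

  ## synthetic metric weights and function sets over the binary features
  bin_feats <- fmeta$feature_id[!fmeta$multistate]
  wfeats <- utils::head(bin_feats, min(12, length(bin_feats)))
  weights <- do.call(rbind, lapply(c("synthA", "synthB", "synthC"),
    function(m) data.frame(metric = m,
                           feature_id = sample(wfeats, min(6, length(wfeats))),
                           point_value = sample(c(0, 0.5, 1), min(6, length(wfeats)),
                                                replace = TRUE),
                           stringsAsFactors = FALSE)))
  rest <- setdiff(bin_feats, unique(weights$feature_id))
  setfeats <- utils::head(rest, 8)
  sets <- if (length(setfeats) >= 2) {
    data.frame(set_name = sprintf("fn%d", rep(1:4, length.out = length(setfeats))),
               feature_id = setfeats, stringsAsFactors = FALSE)
  } else NULL

  truth$region_prob_threatened <- reg_prob
  truth$seed <- cfg$seed
  binarized <- cfg$n_multistate == 0
  list(matrix = trait_matrix(v, binarized = binarized), meta = meta,
       tree = tree, feature_meta = fmeta, weights = weights, sets = sets,
       truth = truth)
}

## family labels: the most recent ancestor older than the depth cutoff
synth_families <- function(tree, cutoff = 0.45) {
  n <- ape::Ntip(tree)
  dep <- ape::node.depth.edgelength(tree)
  fam <- integer(n)
  for (tip in seq_len(n)) {
    node <- tip
    repeat {
      parent <- tree$edge[tree$edge[, 2] == node, 1]
      if (length(parent) == 0) { fam[tip] <- node; break }
      if (dep[parent] < cutoff) { fam[tip] <- parent; break }
      node <- parent
    }
  }
  sprintf("fam%02d", as.integer(factor(fam)))
}

#' Simulation battery across the signal-by-prevalence grid
#'
#' Simulates binary traits for every combination of the lambda grid
#' {0.01, 0.3, 0.6, 0.9} and the prevalence grid {0.1, 0.25, 0.4}, a
#' fixed number of replicates per condition (the default 15 gives 180
#' vectors).
#'
#' @param tree ultrametric \code{phylo}
#' @param seed integer seed
#' @param lambda_grid,prevalence_grid condition grids
#' @param n_reps replicates per condition
#' @param tol prevalence tolerance per trait
#' @return matrix (tips x traits) with a \code{conditions} attribute
#'   (data frame with lambda, prevalence, rep per column)
#' @export
replicate_simulation_grid <- function(tree, seed = 1,
                                      lambda_grid = c(0.01, 0.3, 0.6, 0.9),
                                      prevalence_grid = c(0.1, 0.25, 0.4),
                                      n_reps = 15, tol = 0.05) {
  set.seed(seed)
  conds <- expand.grid(lambda = lambda_grid, prevalence = prevalence_grid,
                       rep = seq_len(n_reps))
  out <- sapply(seq_len(nrow(conds)), function(i)
    simulate_binary_trait(tree, conds$lambda[i], conds$prevalence[i],
                          tol = tol))
  rownames(out) <- tree$tip.label
  colnames(out) <- sprintf("l%g_p%g_r%d", conds$lambda, conds$prevalence,
                           conds$rep)
  attr(out, "conditions") <- conds
  out
}
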