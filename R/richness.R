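#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric multidimensional scaling: the distance matrix is
#' squared, double-centred and eigendecomposed; coordinates are the
#' scaled eigenvectors of the positive eigenvalues. Negative eigenvalues
#' (non-Euclidean distances) are dropped and their total magnitude
#' logged. The variance fraction of each retained dimension is its
#' eigenvalue over the sum of positive eigenvalues.
#'
#' @param distance_matrix symmetric non-negative matrix with zero
#'   diagonal
#' @param dims number of dimensions to return
#' @return list: \code{coords} (taxa x dims), \code{eig},
#'   \code{variance_fractions} (for the retained dims)
#' @export
pcoa_embed <- function(distance_matrix, dims = 2) {
  D <- as.matrix(distance_matrix)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix not symmetric")
  if (any(D < -1e-12)) stop("distances must be non-negative")
  n <- nrow(D)
  mds <- stats::cmdscale(D, k = min(dims, n - 1), eig = TRUE)
  eig <- mds$eig
  neg <- sum(abs(eig[eig < -1e-10]))
  if (neg > 0)
    message(sprintf("pcoa_embed: dropped negative eigenvalue mass %.4g", neg))
  pos <- eig[eig > 1e-10]
  co <- mds$points
  if (ncol(co) < dims)
    co <- cbind(co, matrix(0, n, dims - ncol(co)))
  colnames(co) <- paste0("PCo", seq_len(ncol(co)))
  list(coords = co, eig = eig,
       variance_fractions = eig[seq_len(dims)] / sum(pos))
}

#' Convex-hull area of a taxon subset in a 2-D embedding
#'
#' The functional-richness measure: the area of the convex hull of the
#' subset's points in the (shared) ordination plane. Subsets with fewer
#' than 3 non-collinear points have zero area; an empty subset returns 0
#' with a warning.
#'
#' @param coords2d matrix with 2 columns and taxon row names
#' @param taxa_subset taxon ids (default: all rows)
#' @return hull area (>= 0)
#' @export
hull_richness <- function(coords2d, taxa_subset = rownames(coords2d)) {
  if (length(taxa_subset) == 0) {
    warning("empty taxon subset: area 0")
    return(0)
  }
  pts <- coords2d[intersect(taxa_subset, rownames(coords2d)), , drop = FALSE]
  pts <- unique(pts)
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  xy <- pts[h, , drop = FALSE]
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Split taxa by endangerment status
#'
#' Uses agglomerated endangerment categories: "not endangered" taxa are
#' nonthreatened; all categories associated with endangerment or recent
#' dormancy ("threatened", "shifting", "moribund", "nearly extinct",
#' "extinct") are threatened; taxa with missing status are excluded from
#' the analysis.
#'
#' @param meta taxon metadata frame with columns \code{taxon_id} and
#'   \code{endangerment}
#' @return list of taxon-id vectors: \code{nonthreatened},
#'   \code{threatened}, \code{excluded}
#' @export
endangerment_split <- function(meta) {
  if (!"endangerment" %in% names(meta))
    stop("metadata lacks an endangerment column")
  status <- tolower(trimws(meta$endangerment))
  nonthr <- "not endangered"
  thr <- c("threatened", "shifting", "moribund", "nearly extinct", "extinct")
  known <- c(nonthr, thr)
  bad <- !is.na(status) & !(status %in% known)
  if (any(bad))
    stop("unknown endangerment categories: ",
         paste(unique(meta$endangerment[bad]), collapse = ", "))
  list(nonthreatened = meta$taxon_id[!is.na(status) & status == nonthr],
       threatened = meta$taxon_id[!is.na(status) & status %in% thr],
       excluded = meta$taxon_id[is.na(status)])
}

#' Functional richness per region, with and without threatened taxa
#'
#' A single principal coordinates embedding is fitted on all taxa (so
#' regional hulls live in one shared plane) from the Gower distances of
#' the imputed matrix; per region, the convex-hull area is computed once
#' with all its taxa and once with threatened taxa removed, and the
#' ratio of the two is the fraction of structural diversity that would
#' remain under language loss.
#'
#' @param x complete binarized trait matrix
#' @param meta taxon metadata with \code{taxon_id}, \code{endangerment}
#'   and the region column
#' @param region_col metadata column holding the region label
#' @param dims embedding dimensions (hulls use the first two)
#' @param distance "gower" (default) or "euclidean"
#' @return list of class \code{richness_report}: \code{table} (per-region
#'   rows plus a global row), \code{coords}, \code{split}
#' @export
richness_report <- function(x, meta, region_col = "cultural_area", dims = 2,
                            distance = c("gower", "euclidean")) {
  distance <- match.arg(distance)
  v <- as_trait_values(x, binary = TRUE)
  if (any(is.na(v))) stop("richness_report requires a complete (imputed) matrix")
  meta <- meta[match(rownames(v), meta$taxon_id), , drop = FALSE]
  split <- endangerment_split(meta)
  D <- if (distance == "gower") gower_matrix(v) else as.matrix(stats::dist(v))
  emb <- pcoa_embed(D, dims = dims)
  co <- emb$coords[, 1:2, drop = FALSE]
  rownames(co) <- rownames(v)
  usable <- setdiff(rownames(v), split$excluded)
  regions <- sort(unique(stats::na.omit(meta[[region_col]])))
  one_row <- function(label, taxa) {
    taxa <- intersect(taxa, usable)
    nonthr <- intersect(taxa, split$nonthreatened)
    flagged <- length(taxa) < 3
    a_all <- if (length(taxa)) hull_richness(co, taxa) else 0
    a_non <- if (length(nonthr)) hull_richness(co, nonthr) else 0
    data.frame(region = label, n_taxa = length(taxa),
               n_nonthreatened = length(nonthr),
               area_all = a_all, area_nonthreatened = a_non,
               ratio = if (a_all > 0) a_non / a_all else 0,
               flagged_small = flagged, stringsAsFactors = FALSE)
  }
  rows <- lapply(regions, function(r)
    one_row(r, meta$taxon_id[!is.na(meta[[region_col]]) &
                             meta[[region_col]] == r]))
  tab <- rbind(do.call(rbind, rows), one_row("GLOBAL", rownames(v)))
  structure(list(table = tab, coords = co, split = split,
                 variance_fractions = emb$variance_fractions),
            class = "richness_report")
}

#' @export
print.richness_report <- function(x, ...) {
  g <- x$table[x$table$region == "GLOBAL", ]
  cat(sprintf("<richness_report> %d regions; global remaining richness %.2f\n",
              nrow(x$table) - 1, g$ratio))
  invisible(x)
}
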