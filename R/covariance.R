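#' Brownian-motion phylogenetic covariance
#'
#' Entry (i, j) is the shared root-to-MRCA path length of taxa i and j;
#' the diagonal holds root-to-tip depths.
#'
#' @param tree rooted \code{phylo} with branch lengths
#' @param taxa_order optional character vector giving the row/column
#'   order; all must be tips of the tree
#' @return a \code{covariance_model} (list with \code{vcv}, \code{kind},
#'   \code{hyperparams})
#' @export
brownian_vcv <- function(tree, taxa_order = NULL) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  V <- ape::vcv.phylo(tree)
  if (!is.null(taxa_order)) {
    absent <- setdiff(taxa_order, rownames(V))
    if (length(absent))
      stop("taxa absent from tree: ", paste(absent, collapse = ", "))
    V <- V[taxa_order, taxa_order, drop = FALSE]
  }
  structure(list(vcv = V, kind = "phylogenetic", hyperparams = list()),
            class = "covariance_model")
}

#' Matern correlation function
#'
#' \eqn{\rho(d) = 2^{1-\kappa}/\Gamma(\kappa) (d/\phi)^\kappa
#' K_\kappa(d/\phi)} with \eqn{\rho(0) = 1}.
#'
#' @param d non-negative distances
#' @param smoothness Matern smoothness \eqn{\kappa > 0}
#' @param range_par Matern range \eqn{\phi > 0}
#' @return correlations in [0, 1]
#' @export
matern_correlation <- function(d, smoothness = 2, range_par = 1.15) {
  if (smoothness <= 0 || range_par <= 0)
    stop("smoothness and range_par must be positive")
  x <- d / range_par
  r <- ifelse(d <= 0, 1,
              2^(1 - smoothness) / gamma(smoothness) *
                x^smoothness * besselK(x, smoothness))
  ## besselK underflows to 0 at very large x; that is the correct limit
  r[is.na(r) & d > 0] <- 0
  r
}

#' Spatial Matern covariance between taxa
#'
#' @param coords data frame or matrix with columns \code{lat}, \code{lon}
#'   (degrees), one row per taxon; row names or a \code{taxon_id} column
#'   give the taxon ids
#' @param smoothness,range_par Matern parameters (defaults
#'   \eqn{\kappa = 2}, \eqn{\phi = 1.15})
#' @param distance \code{"greatcircle100km"} (haversine distance in
#'   units of 100 km; default) or \code{"degrees"} (Euclidean distance
#'   on raw lat/lon degrees, matching common geostatistics toolchains)
#' @return a \code{covariance_model}
#' @export
matern_cov <- function(coords, smoothness = 2, range_par = 1.15,
                       distance = c("greatcircle100km", "degrees")) {
  distance <- match.arg(distance)
  cc <- as.data.frame(coords)
  if (!all(c("lat", "lon") %in% names(cc))) {
    if (ncol(cc) >= 2) names(cc)[1:2] <- c("lat", "lon")
    else stop("coords must have lat and lon columns")
  }
  ids <- if ("taxon_id" %in% names(cc)) cc$taxon_id else rownames(cc)
  bad <- is.na(cc$lat) | is.na(cc$lon)
  if (any(bad))
    stop("missing coordinates for taxa: ",
         paste(if (is.null(ids)) which(bad) else ids[bad], collapse = ", "))
  if (distance == "greatcircle100km") {
    d <- geosphere::distm(cbind(cc$lon, cc$lat),
                          fun = geosphere::distHaversine) / 1e5
  } else {
    d <- as.matrix(stats::dist(cbind(cc$lon, cc$lat)))
  }
  S <- matern_correlation(d, smoothness, range_par)
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  structure(list(vcv = S, kind = "spatial",
                 hyperparams = list(smoothness = smoothness,
                                    range_par = range_par,
                                    distance = distance)),
            class = "covariance_model")
}

#' Standardize a covariance matrix and invert it
#'
#' The matrix is divided by the "typical variance" of its diagonal (the
#' geometric mean by default) so that variances are approximately 1, and
#' then inverted to a precision matrix. Near-singular matrices are
#' regularized by a diagonal jitter, which is logged.
#'
#' @param vcv symmetric positive-definite matrix or a
#'   \code{covariance_model}
#' @param center \code{"geometric"} (default) or \code{"arithmetic"}
#'   mean of the diagonal used as the typical variance
#' @param jitter starting jitter used if the Cholesky fails
#' @return list with \code{scaled} (standardized covariance),
#'   \code{precision}, \code{jitter} (amount actually added)
#' @export
scale_and_invert <- function(vcv, center = c("geometric", "arithmetic"),
                             jitter = 1e-8) {
  center <- match.arg(center)
  V <- if (inherits(vcv, "covariance_model")) vcv$vcv else vcv
  if (!isSymmetric(unname(V), tol = 1e-8)) stop("matrix is not symmetric")
  if (any(diag(V) <= 0)) stop("diagonal must be strictly positive")
  tv <- if (center == "geometric") exp(mean(log(diag(V)))) else mean(diag(V))
  S <- V / tv
  used <- 0
  j <- jitter
  repeat {
    ch <- tryCatch(chol(S + diag(used, nrow(S))), error = function(e) NULL)
    if (!is.null(ch)) break
    used <- j
    j <- j * 10
    if (used > 1e-2) stop("matrix could not be inverted even with jitter")
  }
  if (used > 0)
    message(sprintf("scale_and_invert: added diagonal jitter %.1e", used))
  S <- S + diag(used, nrow(S))
  P <- chol2inv(ch)
  dimnames(P) <- dimnames(S)
  list(scaled = S, precision = P, jitter = used)
}

#' Rescale an ultrametric tree by Pagel's lambda
#'
#' Internal covariance structure is scaled by \eqn{\lambda} while tip
#' depths are preserved: the off-diagonal entries of the Brownian
#' covariance matrix of the returned tree equal \eqn{\lambda} times the
#' original ones, and the diagonal is unchanged. \eqn{\lambda = 1}
#' returns the tree unchanged; \eqn{\lambda = 0} gives a star phylogeny.
#'
#' @param tree ultrametric \code{phylo}
#' @param lambda signal parameter in [0, 1]
#' @return rescaled \code{phylo}
#' @export
pagel_rescale <- function(tree, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1)
    stop("`lambda` must be a single value in [0, 1]")
  if (!ape::is.ultrametric(tree, tol = 1e-6))
    stop("pagel_rescale requires an ultrametric tree")
  dep0 <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  out <- tree
  out$edge.length <- out$edge.length * lambda
  tip_edges <- which(out$edge[, 2] <= ape::Ntip(out))
  dep1 <- ape::node.depth.edgelength(out)
  tips <- out$edge[tip_edges, 2]
  out$edge.length[tip_edges] <- out$edge.length[tip_edges] +
    (dep0[tips] - dep1[tips])
  out
}
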