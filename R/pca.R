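#' Principal component analysis of an imputed trait matrix
#'
#' Columns are centred and scaled to unit variance before decomposition.
#' Component signs follow a deterministic convention: within each
#' component the loading of largest magnitude is made positive.
#'
#' @param x complete binarized trait matrix (no missing cells)
#' @return list of class \code{pca_result}: \code{loadings} (feature x
#'   component), \code{scores} (taxon x component),
#'   \code{variance_fractions}, \code{sdev}
#' @export
run_pca <- function(x) {
  v <- as_trait_values(x, binary = TRUE)
  if (any(is.na(v))) stop("run_pca requires a complete matrix (impute first)")
  if (nrow(v) < 2 || ncol(v) < 2) stop("need at least 2 taxa and 2 features")
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance features cannot be scaled: ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  p <- stats::prcomp(v, center = TRUE, scale. = TRUE)
  for (k in seq_len(ncol(p$rotation))) {
    j <- which.max(abs(p$rotation[, k]))
    if (p$rotation[j, k] < 0) {
      p$rotation[, k] <- -p$rotation[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  vf <- p$sdev^2 / sum(p$sdev^2)
  structure(list(loadings = p$rotation, scores = p$x,
                 variance_fractions = vf, sdev = p$sdev),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d taxa, %d components; first three explain %.1f%%\n",
              nrow(x$scores), ncol(x$scores),
              100 * sum(x$variance_fractions[1:min(3, length(x$variance_fractions))])))
  invisible(x)
}

#' Optimal number of components by the nongraphical scree test
#'
#' The "optimal coordinates" variant: component k is supported when its
#' eigenvalue exceeds the value predicted at position k by the straight
#' line through the (k+1)-th and the last eigenvalue; the returned count
#' is the largest supported k (at least 1). The "acceleration factor"
#' variant returns the component before the elbow with the largest
#' second difference of the spectrum.
#'
#' @param eigenvalues eigenvalues sorted in decreasing order (at least 3)
#' @param variant \code{"oc"} (optimal coordinates, default) or
#'   \code{"af"} (acceleration factor)
#' @return integer component count
#' @export
optimal_components <- function(eigenvalues, variant = c("oc", "af")) {
  variant <- match.arg(variant)
  ev <- as.numeric(eigenvalues)
  p <- length(ev)
  if (p < 3) stop("need at least 3 eigenvalues")
  if (is.unsorted(rev(ev))) stop("eigenvalues must be sorted decreasing")
  if (variant == "oc") {
    tol <- 1e-8 * (abs(ev[1]) + 1e-12)  # guards exact linear tails
    supported <- logical(p - 2)
    for (i in seq_len(p - 2)) {
      slope <- (ev[p] - ev[i + 1]) / (p - (i + 1))
      pred <- ev[i + 1] + slope * (i - (i + 1))
      supported[i] <- ev[i] > pred + tol
    }
    if (!any(supported)) return(1L)
    max(which(supported))
  } else {
    if (p < 4) return(1L)
    acc <- ev[3:p] - 2 * ev[2:(p - 1)] + ev[1:(p - 2)]  # at positions 2..p-1
    max(1L, which.max(acc))  # components before the sharpest elbow
  }
}

#' Phylogenetic generalized least squares correlation
#'
#' GLS regression of y on x under a Brownian correlation structure given
#' by a phylogenetic covariance matrix. Both variables are divided by
#' their standard deviations first so that the slope is a standardized
#' coefficient. Also reports a symmetric correlation analogue,
#' sign(slope) * sqrt(R2) with R2 the GLS coefficient of determination.
#'
#' @param x,y per-taxon numeric vectors
#' @param phylo_vcv covariance matrix (or \code{covariance_model}) over
#'   the same taxa, in the same order
#' @return list with \code{coef} (standardized slope), \code{se},
#'   \code{corr}, \code{intercept}
#' @export
pgls_corr <- function(x, y, phylo_vcv) {
  V <- if (inherits(phylo_vcv, "covariance_model")) phylo_vcv$vcv else phylo_vcv
  n <- length(x)
  if (length(y) != n || nrow(V) != n) stop("dimension mismatch")
  xs <- x / stats::sd(x); ys <- y / stats::sd(y)
  Vi <- tryCatch(solve(V), error = function(e) {
    tryCatch(solve(V + diag(1e-8 * mean(diag(V)), n)),
             error = function(e2) stop("singular phylogenetic covariance"))
  })
  X <- cbind(1, xs)
  XtVi <- crossprod(X, Vi)
  B <- solve(XtVi %*% X, XtVi %*% ys)
  resid <- ys - X %*% B
  s2 <- as.numeric(crossprod(resid, Vi %*% resid)) / (n - 2)
  covB <- s2 * solve(XtVi %*% X)
  ## GLS R^2 against the intercept-only GLS fit
  one <- matrix(1, n, 1)
  mu <- as.numeric(solve(crossprod(one, Vi %*% one),
                         crossprod(one, Vi %*% ys)))
  ss_tot <- as.numeric(crossprod(ys - mu, Vi %*% (ys - mu)))
  ss_res <- as.numeric(crossprod(resid, Vi %*% resid))
  r2 <- max(0, 1 - ss_res / ss_tot)
  list(coef = unname(B[2]), se = sqrt(covB[2, 2]),
       intercept = unname(B[1]),
       corr = unname(sign(B[2]) * sqrt(r2)))
}

#' Map the first three principal components to RGB
#'
#' Each of the first three component scores is min-max scaled to [0, 1]
#' and used as the red, green and blue channel. A constant component
#' maps to 0.5 on its channel.
#'
#' @param scores taxon x component score matrix (>= 3 components)
#' @return taxon x 3 matrix with columns R, G, B in [0, 1]
#' @export
pc_rgb <- function(scores) {
  if (ncol(scores) < 3) stop("need at least 3 components")
  out <- sapply(1:3, function(k) {
    s <- scores[, k]
    rng <- range(s)
    if (diff(rng) == 0) return(rep(0.5, length(s)))
    (s - rng[1]) / diff(rng)
  })
  dimnames(out) <- list(rownames(scores), c("R", "G", "B"))
  out
}
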