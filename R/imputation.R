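#' Chained random-forest imputation of a binary trait matrix
#'
#' Fills missing cells by iterated random-forest classification: each
#' feature with missing values is predicted from all other features,
#' cycling through features in order of increasing missingness until the
#' number of imputed cells that change between sweeps stops decreasing
#' (or \code{max_iter} is reached). The classifier sees only the trait
#' values themselves: it is entirely naive as to taxon genealogy or
#' geography. Observed cells are never altered.
#'
#' The reported out-of-bag (OOB) error is the mean over imputed features
#' of each forest's OOB misclassification rate at the final sweep; it is
#' an estimate of how often an imputed cell is wrong.
#'
#' @param x binarized trait matrix with missing cells (missing fraction
#'   below 50\%)
#' @param seed integer seed (required; the imputation is stochastic)
#' @param n_trees trees per forest
#' @param max_iter maximum number of sweeps over the features
#' @return list of class \code{imputation_result}: \code{completed}
#'   (trait matrix, no missing), \code{oob_error}, \code{oob_by_feature},
#'   \code{n_iterations}
#' @export
impute <- function(x, seed, n_trees = 100, max_iter = 10) {
  if (missing(seed)) stop("`seed` is required for reproducible imputation")
  tm <- if (inherits(x, "trait_matrix")) x else trait_matrix(x, binarized = TRUE)
  if (!tm$binarized) stop("impute() expects a binarized matrix")
  v <- tm$values
  miss <- is.na(v)
  if (!any(miss)) {
    return(structure(list(completed = tm, oob_error = 0,
                          oob_by_feature = numeric(0), n_iterations = 0L),
                     class = "imputation_result"))
  }
  if (mean(miss) >= 0.5)
    stop("missing fraction >= 50%: crop the matrix before imputing")
  allmiss <- colSums(!miss) == 0
  if (any(allmiss))
    stop("features with zero observed values cannot be imputed: ",
         paste(colnames(v)[allmiss], collapse = ", "))

  set.seed(seed)
  cur <- v
  ## initialize missing cells with the feature's majority class
  for (j in which(colSums(miss) > 0)) {
    obs <- v[!miss[, j], j]
    maj <- as.integer(names(sort(table(obs), decreasing = TRUE))[1])
    cur[miss[, j], j] <- maj
  }
  targets <- order(colSums(miss))
  targets <- targets[colSums(miss)[targets] > 0]
  oob <- rep(NA_real_, length(targets)); names(oob) <- colnames(v)[targets]
  prev_changed <- Inf
  it <- 0L
  prev <- cur
  repeat {
    it <- it + 1L
    for (idx in seq_along(targets)) {
      j <- targets[idx]
      yobs <- factor(v[!miss[, j], j], levels = c(0, 1))
      if (nlevels(droplevels(yobs)) < 2) {
        ## constant feature: nothing to learn, keep majority fill
        oob[idx] <- 0
        next
      }
      xdf <- as.data.frame(cur[, -j, drop = FALSE])
      xdf[] <- lapply(xdf, function(z) factor(z, levels = c(0, 1)))
      fit <- ranger::ranger(
        x = xdf[!miss[, j], , drop = FALSE], y = yobs,
        num.trees = n_trees, num.threads = 1,
        seed = seed + it * 1000L + idx,
        respect.unordered.factors = "order"
      )
      oob[idx] <- fit$prediction.error
      pred <- stats::predict(fit, data = xdf[miss[, j], , drop = FALSE],
                             num.threads = 1)$predictions
      cur[miss[, j], j] <- as.integer(as.character(pred))
    }
    changed <- sum(cur[miss] != prev[miss])
    if (changed >= prev_changed || it >= max_iter) {
      if (changed >= prev_changed && it > 1L) cur <- prev  # keep last improving sweep
      break
    }
    prev_changed <- changed
    prev <- cur
  }
  completed <- trait_matrix(cur, binarized = TRUE)
  structure(list(completed = completed,
                 oob_error = mean(oob, na.rm = TRUE),
                 oob_by_feature = oob,
                 n_iterations = it),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> %d sweeps, OOB error %.3f\n",
              x$n_iterations, x$oob_error))
  invisible(x)
}
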