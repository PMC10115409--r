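#' Cultural fixation score between two groups of taxa
#'
#' For each binary feature f with group frequencies p1, p2 (computed on
#' the group members observed for f), pooled frequency p-bar and group
#' sizes n1, n2, the per-feature score is the between-group share of the
#' total variance, F_f = [sum_g n_g (p_g - p-bar)^2 / sum_g n_g] /
#' [p-bar (1 - p-bar)]. Features whose pooled frequency is 0 or 1 carry
#' no usable variation and are skipped. The score is the mean of F_f
#' over usable features; when no feature is usable the groups are
#' indistinguishable on the data and the score is defined as 0 if both
#' groups are monomorphic and identical, otherwise an error is raised.
#'
#' @param x binarized trait matrix (missing allowed; frequencies use
#'   pairwise-complete observations per feature and group)
#' @param group_a,group_b disjoint character vectors of taxon ids
#' @param unbiased use the small-sample (n_g - 1) variance analogue
#' @return fixation score in [0, 1]
#' @export
cultural_fst <- function(x, group_a, group_b, unbiased = FALSE) {
  v <- as_trait_values(x, binary = TRUE)
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  if (!length(group_a) || !length(group_b)) stop("groups must be non-empty")
  missing_taxa <- setdiff(c(group_a, group_b), rownames(v))
  if (length(missing_taxa))
    stop("taxa not in matrix: ", paste(missing_taxa, collapse = ", "))
  A <- v[group_a, , drop = FALSE]
  B <- v[group_b, , drop = FALSE]
  f_scores <- vapply(seq_len(ncol(v)), function(j) {
    a <- A[, j]; b <- B[, j]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    n1 <- length(a); n2 <- length(b)
    if (n1 == 0 || n2 == 0) return(NA_real_)
    p1 <- mean(a); p2 <- mean(b)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    if (pbar <= 0 || pbar >= 1) return(NA_real_)
    if (unbiased) {
      num <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (n1 + n2 - 1)
    } else {
      num <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (n1 + n2)
    }
    num / (pbar * (1 - pbar))
  }, numeric(1))
  usable <- !is.na(f_scores)
  if (!any(usable)) {
    ## identical monomorphic groups: no usable variation, perfect affinity
    both <- rbind(A, B)
    if (all(apply(both, 2, function(c) length(unique(c[!is.na(c)])) <= 1)))
      return(0)
    stop("no usable feature for this group pair")
  }
  mean(f_scores[usable])
}

#' Pairwise cultural fixation scores over a grouping
#'
#' @param x binarized trait matrix
#' @param grouping named character vector mapping taxon id to group
#'   label (taxa with NA group are ignored)
#' @param min_size groups smaller than this are dropped with a warning
#' @param ... passed to \code{\link{cultural_fst}}
#' @return object of class \code{fst_table}: list with the symmetric
#'   \code{scores} matrix and \code{group_sizes}
#' @export
pairwise_fst <- function(x, grouping, min_size = 3, ...) {
  v <- as_trait_values(x, binary = TRUE)
  grouping <- grouping[!is.na(grouping)]
  grouping <- grouping[names(grouping) %in% rownames(v)]
  sizes <- table(grouping)
  small <- names(sizes)[sizes < min_size]
  if (length(small)) {
    warning("dropping groups below minimum size: ",
            paste(small, collapse = ", "))
    grouping <- grouping[!(grouping %in% small)]
    sizes <- table(grouping)
  }
  groups <- sort(unique(grouping))
  if (length(groups) < 2) stop("need at least two groups")
  Fm <- matrix(0, length(groups), length(groups),
               dimnames = list(groups, groups))
  for (i in seq_along(groups)) for (j in seq_len(i - 1)) {
    f <- cultural_fst(v, names(grouping)[grouping == groups[i]],
                      names(grouping)[grouping == groups[j]], ...)
    Fm[i, j] <- Fm[j, i] <- f
  }
  structure(list(scores = Fm, group_sizes = as.integer(sizes[groups])),
            class = "fst_table")
}

#' @export
print.fst_table <- function(x, ...) {
  cat(sprintf("<fst_table> %d groups, mean off-diagonal score %.3f\n",
              nrow(x$scores), mean(x$scores[lower.tri(x$scores)])))
  invisible(x)
}

#' Newman modularity of a partition of the fixation network
#'
#' Groups are nodes of a complete weighted graph whose edge weights are
#' a similarity transform of the fixation scores (by default
#' \code{max(F) - F}; alternatively \code{1 - F/max(F)}). The modularity
#' of the given binary (or k-way) partition is computed on that graph.
#'
#' @param fst an \code{fst_table} (or symmetric score matrix)
#' @param partition named vector assigning every group to a community
#' @param transform \code{"max_minus"} (default) or \code{"one_minus_rel"}
#' @return modularity score in [-1, 1]
#' @export
partition_modularity <- function(fst, partition,
                                 transform = c("max_minus", "one_minus_rel")) {
  transform <- match.arg(transform)
  Fm <- if (inherits(fst, "fst_table")) fst$scores else fst
  groups <- rownames(Fm)
  if (!all(groups %in% names(partition)))
    stop("partition must cover all groups: missing ",
         paste(setdiff(groups, names(partition)), collapse = ", "))
  mx <- max(Fm)
  W <- if (transform == "max_minus") mx - Fm else 1 - Fm / mx
  diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  memb <- as.integer(factor(partition[groups]))
  igraph::modularity(g, memb, weights = igraph::E(g)$weight)
}
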