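#' Typological consistency score of one taxon under a metric
#'
#' A metric assigns a point value in {0, 0.5, 1} to each relevant
#' feature. The per-feature consistency index is the taxon's value
#' multiplied by the point value for point values 0.5 and 1; for point
#' value 0 (a feature that contradicts the phenomenon) the taxon's value
#' is reversed (0 becomes 1 and 1 becomes 0) and the reversed value is
#' the index. The score is the mean index over the relevant features the
#' taxon has observed values for, or NA if none are observed.
#'
#' @param row named binary vector (one taxon's feature values, NA allowed)
#' @param weights data frame with \code{feature_id} and
#'   \code{point_value} in {0, 0.5, 1}
#' @return score in [0, 1], or NA when no relevant feature is observed
#' @export
consistency_score <- function(row, weights) {
  if (anyDuplicated(weights$feature_id))
    stop("a feature appears more than once in the weight table")
  if (!all(weights$point_value %in% c(0, 0.5, 1)))
    stop("point values must be 0, 0.5 or 1")
  rel <- intersect(weights$feature_id, names(row))
  w <- weights$point_value[match(rel, weights$feature_id)]
  v <- as.numeric(row[rel])
  keep <- !is.na(v)
  if (!any(keep)) return(NA_real_)
  v <- v[keep]; w <- w[keep]
  if (!all(v %in% c(0, 1))) stop("non-binary value among relevant features")
  idx <- ifelse(w == 0, 1 - v, w * v)
  mean(idx)
}

#' Consistency scores for all taxa and metrics
#'
#' @param x binarized trait matrix
#' @param weight_table data frame with columns \code{metric},
#'   \code{feature_id}, \code{point_value}
#' @return data frame of per-taxon scores, one column per metric
#' @export
consistency_scores <- function(x, weight_table) {
  v <- as_trait_values(x, binary = TRUE)
  metrics <- unique(weight_table$metric)
  out <- data.frame(taxon_id = rownames(v), stringsAsFactors = FALSE)
  for (m in metrics) {
    w <- weight_table[weight_table$metric == m, , drop = FALSE]
    out[[m]] <- apply(v, 1, consistency_score, weights = w)
  }
  out
}

#' Informativity score of one taxon
#'
#' Features are grouped into sets that express the same grammatical
#' function. A function counts as present if the taxon has a positive
#' value for any observed member of its set; a set is available if at
#' least one member is observed. The score is presences / available
#' sets.
#'
#' @param row named binary vector
#' @param sets named list of feature-id vectors, or a data frame with
#'   columns \code{set_name} and \code{feature_id}
#' @return score in [0, 1], or NA when no set is available
#' @export
informativity_score <- function(row, sets) {
  sets <- as_function_sets(sets)
  if (length(sets) == 0) stop("empty function-set table")
  present <- avail <- logical(length(sets))
  for (i in seq_along(sets)) {
    v <- row[intersect(sets[[i]], names(row))]
    v <- as.numeric(v)
    avail[i] <- any(!is.na(v))
    present[i] <- isTRUE(any(v == 1, na.rm = TRUE)) && avail[i]
  }
  if (!any(avail)) return(NA_real_)
  sum(present) / sum(avail)
}

#' @rdname informativity_score
#' @param x binarized trait matrix
#' @return \code{informativity_scores} returns a data frame of
#'   per-taxon scores
#' @export
informativity_scores <- function(x, sets) {
  v <- as_trait_values(x, binary = TRUE)
  data.frame(taxon_id = rownames(v),
             informativity = apply(v, 1, informativity_score, sets = sets),
             stringsAsFactors = FALSE)
}

as_function_sets <- function(sets) {
  if (is.data.frame(sets)) {
    if (!all(c("set_name", "feature_id") %in% names(sets)))
      stop("function-set table needs set_name and feature_id columns")
    sets <- split(sets$feature_id, sets$set_name)
  }
  if (anyDuplicated(unlist(sets)))
    stop("a feature may appear in at most one function set")
  if (any(lengths(sets) == 0)) stop("function sets must be non-empty")
  sets
}

#' Read a metric weight table / function set table from CSV
#'
#' @param path CSV with columns \code{metric}, \code{feature_id},
#'   \code{point_value} (weights) or \code{set_name}, \code{feature_id}
#'   (sets)
#' @return data frame
#' @export
read_metric_weights <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("metric", "feature_id", "point_value") %in% names(w)))
    stop("weight table needs metric, feature_id, point_value columns")
  if (!all(w$point_value %in% c(0, 0.5, 1)))
    stop("point values must be 0, 0.5 or 1")
  w
}

#' @rdname read_metric_weights
#' @export
read_function_sets <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_function_sets(s)
  s
}
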