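#' Merge dialects into their parent language
#'
#' Language varieties classified as dialects are collapsed so that at
#' most one row per language remains. Within each language the variety
#' with the least missing data is retained and re-identified by the id
#' of its parent language; ties are broken by the lexicographically
#' first taxon id so that the reduction is deterministic.
#'
#' @param x trait matrix
#' @param meta taxon metadata frame with columns \code{taxon_id},
#'   \code{level} ("language"/"dialect") and \code{parent_id}
#' @return list with the reduced \code{matrix} and \code{meta}
#' @export
merge_dialects <- function(x, meta) {
  tm <- if (inherits(x, "trait_matrix")) x else trait_matrix(x)
  v <- tm$values
  meta <- meta[match(rownames(v), meta$taxon_id), , drop = FALSE]
  if (any(is.na(meta$taxon_id)))
    stop("metadata missing for taxa: ",
         paste(setdiff(rownames(v), meta$taxon_id), collapse = ", "))
  is_dial <- meta$level == "dialect"
  orphan <- is_dial & (is.na(meta$parent_id) | meta$parent_id == "")
  if (any(orphan))
    stop("dialects without parent_id: ",
         paste(meta$taxon_id[orphan], collapse = ", "))
  lang <- ifelse(is_dial, meta$parent_id, meta$taxon_id)
  keep <- vapply(split(seq_len(nrow(v)), lang), function(rows) {
    nmiss <- rowSums(is.na(v[rows, , drop = FALSE]))
    cand <- rows[nmiss == min(nmiss)]
    cand[order(rownames(v)[cand])][1]
  }, integer(1))
  keep <- sort(keep)
  out <- v[keep, , drop = FALSE]
  meta_out <- meta[keep, , drop = FALSE]
  n_merged <- nrow(v) - nrow(out)
  ## retained dialect rows take their parent language id
  newid <- lang[keep]
  rownames(out) <- newid
  meta_out$taxon_id <- newid
  meta_out$level <- "language"
  meta_out$parent_id <- NA_character_
  o <- order(rownames(out))
  out <- out[o, , drop = FALSE]
  meta_out <- meta_out[o, , drop = FALSE]
  rownames(meta_out) <- NULL
  if (n_merged > 0)
    message(sprintf("merge_dialects: dropped %d dialect rows, %d taxa remain",
                    n_merged, nrow(out)))
  list(matrix = trait_matrix(out, binarized = tm$binarized), meta = meta_out)
}

#' Binarize multistate word-order features
#'
#' Each multistate feature with states \code{XY}, \code{YX}, \code{both}
#' ("what is the order of X and Y?") is split into two binary features
#' "is the order XY?" / "is the order YX?": \code{XY} maps to (1,0),
#' \code{YX} to (0,1), \code{both} to (1,1) and missing stays missing on
#' both. Binary features pass through unchanged, so a matrix with k
#' multistate features gains exactly k columns.
#'
#' @param x trait matrix with raw codes
#' @param feature_meta frame with \code{feature_id} and logical
#'   \code{multistate}
#' @return list with the binarized \code{matrix} (integer cells) and the
#'   updated \code{features} metadata
#' @export
binarize <- function(x, feature_meta) {
  tm <- if (inherits(x, "trait_matrix")) x else trait_matrix(x)
  v <- tm$values
  fm <- feature_meta[match(colnames(v), feature_meta$feature_id), , drop = FALSE]
  if (any(is.na(fm$feature_id)))
    stop("feature metadata missing for: ",
         paste(setdiff(colnames(v), feature_meta$feature_id), collapse = ", "))
  cols <- list(); metas <- list()
  for (j in seq_len(ncol(v))) {
    fid <- colnames(v)[j]
    col <- v[, j]
    if (isTRUE(fm$multistate[j])) {
      bad <- !is.na(col) & !(col %in% c("XY", "YX", "both"))
      if (any(bad)) {
        i <- which(bad)[1]
        stop("unrecognized multistate value: feature ", fid, ", taxon ",
             rownames(v)[i], ", value \"", col[i], "\"")
      }
      a <- ifelse(is.na(col), NA_integer_, as.integer(col %in% c("XY", "both")))
      b <- ifelse(is.na(col), NA_integer_, as.integer(col %in% c("YX", "both")))
      cols[[paste0(fid, "a")]] <- a
      cols[[paste0(fid, "b")]] <- b
      base <- fm[j, , drop = FALSE]
      for (suff in c("a", "b")) {
        mrow <- base
        mrow$feature_id <- paste0(fid, suff)
        mrow$multistate <- FALSE
        mrow$description <- paste0(base$description,
                                   if (suff == "a") " [order XY?]" else " [order YX?]")
        metas[[mrow$feature_id]] <- mrow
      }
    } else {
      bad <- !is.na(col) & !(col %in% c("0", "1"))
      if (any(bad)) {
        i <- which(bad)[1]
        stop("non-binary value in binary feature ", fid, ": taxon ",
             rownames(v)[i], ", value \"", col[i], "\"")
      }
      cols[[fid]] <- as.integer(col)
      mrow <- fm[j, , drop = FALSE]
      mrow$multistate <- FALSE
      metas[[fid]] <- mrow
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(v)
  fmeta <- do.call(rbind, metas)
  rownames(fmeta) <- NULL
  list(matrix = trait_matrix(out, binarized = TRUE), features = fmeta)
}

#' Crop features and taxa with excessive missing data
#'
#' Features whose missing fraction exceeds \code{threshold} are dropped
#' first; taxa whose missing fraction (computed on the feature-cropped
#' matrix) exceeds the threshold are then dropped. Both passes are
#' logged with counts.
#'
#' @param x binarized trait matrix
#' @param threshold maximum tolerated missing fraction, in [0, 1]
#' @return cropped \code{trait_matrix}
#' @export
crop_missing <- function(x, threshold = 0.25) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1)
    stop("`threshold` must be a single number in [0, 1]")
  tm <- if (inherits(x, "trait_matrix")) x else trait_matrix(x)
  v <- tm$values
  fmiss <- colMeans(is.na(v))
  keep_f <- fmiss <= threshold
  message(sprintf("crop_missing: dropped %d/%d features above %.0f%% missing",
                  sum(!keep_f), ncol(v), 100 * threshold))
  v <- v[, keep_f, drop = FALSE]
  tmiss <- rowMeans(is.na(v))
  if (ncol(v) == 0) tmiss <- rep(1, nrow(v))
  keep_t <- tmiss <= threshold
  message(sprintf("crop_missing: dropped %d/%d taxa above %.0f%% missing",
                  sum(!keep_t), nrow(v), 100 * threshold))
  v <- v[keep_t, , drop = FALSE]
  trait_matrix(v, binarized = tm$binarized)
}
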