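#' Construct a trait matrix
#'
#' A trait matrix holds the value of every structural feature for every
#' taxon (language variety). Before binarization cells may contain the
#' binary codes \code{"0"}/\code{"1"}, a declared multistate label
#' (e.g. the word-order states \code{"XY"}, \code{"YX"}, \code{"both"}),
#' or \code{NA} for missing. After binarization every cell is 0, 1 or
#' \code{NA} and the values are stored as integers.
#'
#' @param values matrix with unique row names (taxon ids) and unique
#'   column names (feature ids). Character storage before binarization,
#'   integer/numeric after.
#' @param binarized logical; \code{TRUE} once every cell is 0/1/missing.
#' @return an object of class \code{trait_matrix}.
#' @export
trait_matrix <- function(values, binarized = FALSE) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry taxon row names and feature column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicated taxon ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated feature ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (binarized) {
    num <- suppressWarnings(matrix(as.numeric(values), nrow(values),
                                   dimnames = dimnames(values)))
    bad <- !is.na(values) & (is.na(num) | !(num %in% c(0, 1)))
    if (any(bad)) {
      i <- which(bad, arr.ind = TRUE)[1, ]
      stop("non-binary cell after binarization: taxon ", rownames(values)[i[1]],
           ", feature ", colnames(values)[i[2]], ", value ", values[i[1], i[2]])
    }
    values <- matrix(as.integer(num), nrow(values), dimnames = dimnames(values))
  } else if (!is.character(values)) {
    values <- matrix(as.character(values), nrow(values), dimnames = dimnames(values))
    values[values %in% c("NA", "")] <- NA_character_
  }
  structure(list(values = values, binarized = binarized), class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("<trait_matrix> %d taxa x %d features (%s), %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              if (x$binarized) "binary" else "raw codes",
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$values)

#' @export
as.matrix.trait_matrix <- function(x, ...) x$values

#' Taxon and feature identifiers of a trait matrix
#' @param x a \code{trait_matrix}
#' @return character vector of ids
#' @export
taxon_ids <- function(x) rownames(as_trait_values(x))

#' @rdname taxon_ids
#' @export
feature_ids <- function(x) colnames(as_trait_values(x))

## Accept either a trait_matrix or a plain named matrix everywhere.
as_trait_values <- function(x, binary = FALSE) {
  v <- if (inherits(x, "trait_matrix")) x$values else x
  if (!is.matrix(v)) stop("expected a trait_matrix or a matrix")
  if (binary) {
    v <- suppressWarnings(matrix(as.numeric(v), nrow(v), dimnames = dimnames(v)))
    if (any(!is.na(v) & !(v %in% c(0, 1))))
      stop("matrix must be binary (0/1/missing)")
  }
  v
}

#' Fraction of missing cells
#'
#' @param x trait matrix (or plain matrix)
#' @return missing cells / total cells, in [0, 1]
#' @export
missing_fraction <- function(x) {
  v <- as_trait_values(x)
  if (length(v) == 0) stop("empty matrix: missing fraction undefined")
  mean(is.na(v))
}

#' Read a structure dataset from CLDF-style CSV tables
#'
#' Reads a long-format values table plus per-taxon and per-feature
#' metadata tables and assembles a \code{trait_matrix}, a taxon metadata
#' frame and a feature metadata frame. Taxa or features that appear in
#' the values table but not in the metadata are retained with empty
#' metadata (with a warning).
#'
#' @param values_path CSV with columns \code{Language_ID},
#'   \code{Parameter_ID}, \code{Value}.
#' @param taxa_path CSV with column \code{ID} plus optional
#'   \code{Level}, \code{Parent_ID}, \code{Latitude}, \code{Longitude},
#'   \code{Family}, \code{Macroarea}, \code{Cultural_Area}, \code{AES}.
#' @param features_path CSV with column \code{ID} plus optional
#'   \code{Name}, \code{Multistate}, \code{Domain}.
#' @param missing_codes cell values treated as missing.
#' @return list with elements \code{matrix}, \code{taxa}, \code{features}.
#' @export
read_structure_dataset <- function(values_path, taxa_path = NULL,
                                   features_path = NULL,
                                   missing_codes = c("", "?", "NA")) {
  vals <- utils::read.csv(values_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("Language_ID", "Parameter_ID", "Value")
  if (!all(need %in% names(vals)))
    stop("values table lacks required columns: ",
         paste(setdiff(need, names(vals)), collapse = ", "))
  key <- paste(vals$Language_ID, vals$Parameter_ID, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate value rows for (taxon, feature) pair: ",
         gsub("\r", ", ", d))
  }
  taxa <- sort(unique(vals$Language_ID))
  feats <- sort(unique(vals$Parameter_ID))
  m <- matrix(NA_character_, length(taxa), length(feats),
              dimnames = list(taxa, feats))
  m[cbind(match(vals$Language_ID, taxa), match(vals$Parameter_ID, feats))] <-
    vals$Value
  m[m %in% missing_codes] <- NA_character_

  tmeta <- empty_taxon_meta(taxa)
  if (!is.null(taxa_path)) {
    tt <- utils::read.csv(taxa_path, stringsAsFactors = FALSE)
    if (!"ID" %in% names(tt)) stop("taxa table lacks required column ID")
    absent <- setdiff(taxa, tt$ID)
    if (length(absent))
      warning("taxa without metadata retained with empty metadata: ",
              paste(absent, collapse = ", "))
    i <- match(taxa, tt$ID)
    pick <- function(col, default = NA) {
      if (col %in% names(tt)) tt[[col]][i] else rep(default, length(taxa))
    }
    tmeta <- data.frame(
      taxon_id = taxa,
      level = ifelse(is.na(pick("Level")), "language", pick("Level")),
      parent_id = as.character(pick("Parent_ID")),
      lat = as.numeric(pick("Latitude")),
      lon = as.numeric(pick("Longitude")),
      family = as.character(pick("Family")),
      macroarea = as.character(pick("Macroarea")),
      cultural_area = as.character(pick("Cultural_Area")),
      endangerment = as.character(pick("AES")),
      stringsAsFactors = FALSE
    )
    validate_taxon_meta(tmeta)
  }

  fmeta <- data.frame(feature_id = feats, description = NA_character_,
                      multistate = FALSE, grammar_domain = NA_character_,
                      stringsAsFactors = FALSE)
  if (!is.null(features_path)) {
    ff <- utils::read.csv(features_path, stringsAsFactors = FALSE)
    if (!"ID" %in% names(ff)) stop("features table lacks required column ID")
    absent <- setdiff(feats, ff$ID)
    if (length(absent))
      warning("features without metadata retained with empty metadata: ",
              paste(absent, collapse = ", "))
    i <- match(feats, ff$ID)
    fmeta$description <- if ("Name" %in% names(ff)) ff$Name[i] else NA_character_
    if ("Multistate" %in% names(ff))
      fmeta$multistate <- !is.na(ff$Multistate[i]) &
        tolower(as.character(ff$Multistate[i])) %in% c("true", "1", "yes")
    if ("Domain" %in% names(ff)) fmeta$grammar_domain <- ff$Domain[i]
  }

  list(matrix = trait_matrix(m), taxa = tmeta, features = fmeta)
}

empty_taxon_meta <- function(taxa) {
  data.frame(taxon_id = taxa, level = "language", parent_id = NA_character_,
             lat = NA_real_, lon = NA_real_, family = NA_character_,
             macroarea = NA_character_, cultural_area = NA_character_,
             endangerment = NA_character_, stringsAsFactors = FALSE)
}

validate_taxon_meta <- function(meta) {
  ok_lat <- is.na(meta$lat) | (meta$lat >= -90 & meta$lat <= 90)
  ok_lon <- is.na(meta$lon) | (meta$lon >= -180 & meta$lon <= 180)
  if (!all(ok_lat) || !all(ok_lon))
    stop("coordinates outside [-90,90] x [-180,180] for: ",
         paste(meta$taxon_id[!(ok_lat & ok_lon)], collapse = ", "))
  invisible(meta)
}

#' Write / read a trait matrix as wide TSV
#'
#' Taxa as rows, features as columns; the first column holds the taxon
#' id. Missing cells are written as empty fields. The round trip
#' \code{read_trait_matrix(write_trait_matrix(x, f))} is the identity.
#'
#' @param x trait matrix
#' @param path file path
#' @return \code{write_trait_matrix} returns \code{path} invisibly;
#'   \code{read_trait_matrix} returns a \code{trait_matrix}.
#' @export
write_trait_matrix <- function(x, path) {
  tm <- if (inherits(x, "trait_matrix")) x else trait_matrix(x)
  v <- tm$values
  df <- data.frame(taxon_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  cat(sprintf("# binarized=%s\n", tm$binarized),
      file = paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_trait_matrix
#' @export
read_trait_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = "")
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$taxon_id
  binar <- FALSE
  metaf <- paste0(path, ".meta")
  if (file.exists(metaf))
    binar <- grepl("binarized=TRUE", readLines(metaf)[1], fixed = TRUE)
  trait_matrix(v, binarized = binar)
}
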