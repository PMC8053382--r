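#' Construct a validated OTU count table
#'
#' The central data object of the package: an integer matrix of sequence
#' counts with samples as rows and OTUs as columns. All downstream functions
#' assume this orientation.
#'
#' @param counts matrix-like object of non-negative integer read counts.
#' @param sample_ids,otu_ids row/column identifiers; default to the dimnames.
#' @param drop_empty drop all-zero OTU columns with a warning (they routinely
#'   arise after rarefaction). Ignored when `strict = TRUE`.
#' @param strict error instead of dropping empty OTU columns.
#' @return an `otu_table`: an integer matrix with class `"otu_table"`.
#' @examples
#' x <- otu_table(matrix(c(0, 5, 3, 0), 2, 2,
#'                       dimnames = list(c("a", "b"), c("o1", "o2"))))
#' occupancy(x)
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts),
                      drop_empty = TRUE, strict = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(otu_ids)) otu_ids <- paste0("OTU_", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  if (length(sample_ids) != nrow(counts) || length(otu_ids) != ncol(counts))
    stop("identifier lengths do not match the count matrix", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU identifiers: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "),
         call. = FALSE)
  if (!is.numeric(counts))
    stop("counts must be numeric", call. = FALSE)
  if (anyNA(counts) || any(!is.finite(counts)))
    stop("counts contain missing or non-finite values", call. = FALSE)
  bad <- which(counts < 0 | abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("invalid count %s at sample '%s', OTU '%s' (must be a non-negative integer)",
                 format(counts[i, j]), sample_ids[i], otu_ids[j]),
         call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, otu_ids)
  empty <- colSums(counts) == 0L
  if (any(empty)) {
    if (strict)
      stop("all-zero OTU columns present: ",
           paste(otu_ids[empty], collapse = ", "), call. = FALSE)
    if (drop_empty) {
      warning(sprintf("dropping %d all-zero OTU column(s): %s",
                      sum(empty),
                      paste(utils::head(otu_ids[empty], 5L), collapse = ", ")),
              call. = FALSE)
      counts <- counts[, !empty, drop = FALSE]
    }
  }
  class(counts) <- c("otu_table", "matrix", "array")
  counts
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d OTUs, %s reads total\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Read an OTU table from a tab-separated file
#'
#' Expects a header row and a first column of row identifiers. Files stored
#' with OTUs as rows (a common deposition format) are transposed into the
#' canonical samples-as-rows orientation via `orientation = "otus"`.
#'
#' @param path file path.
#' @param orientation `"samples"` if rows are samples (default), `"otus"` if
#'   rows are OTUs.
#' @inheritParams otu_table
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path, orientation = c("samples", "otus"),
                           drop_empty = TRUE, strict = FALSE) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, row.names = 1, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  for (j in seq_along(raw)) {
    col <- raw[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      i <- which(is.na(num) & !is.na(col))[1]
      if (is.na(i)) i <- which(is.na(col))[1]
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s' of %s",
                   col[i], rownames(raw)[i], colnames(raw)[j], path),
           call. = FALSE)
    }
  }
  m <- as.matrix(raw)
  if (orientation == "otus") m <- t(m)
  otu_table(m, drop_empty = drop_empty, strict = strict)
}

#' Write an OTU table as TSV
#'
#' Inverse of [read_otu_table()]: `sample_id` header column followed by one
#' column per OTU.
#'
#' @param x an [otu_table()] (or presence table).
#' @param path output path.
#' @export
write_otu_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Binarize a count table into presence/absence
#'
#' @param x an [otu_table()], presence table or plain non-negative matrix.
#' @return a `presence_table`: integer matrix of 0/1 cells with the same axes.
#' @export
binarize <- function(x) {
  m <- unclass(x)
  out <- (m > 0) + 0L
  dimnames(out) <- dimnames(m)
  class(out) <- c("presence_table", "matrix", "array")
  out
}

#' Per-OTU occupancy
#'
#' Number of samples in which each OTU is present (count > 0).
#'
#' @param x an [otu_table()] or presence table.
#' @return named integer vector, one entry per OTU.
#' @export
occupancy <- function(x) {
  colSums(unclass(x) > 0)
}

#' Fraction of OTUs below an occupancy threshold
#'
#' Summarises the rare tail of the community, e.g. the fraction of OTUs
#' found in fewer than three samples.
#'
#' @param x an [otu_table()] or presence table.
#' @param threshold occupancy cutoff; OTUs with occupancy strictly below it
#'   are counted.
#' @return fraction in \[0, 1\].
#' @export
occupancy_fraction <- function(x, threshold = 3) {
  mean(occupancy(x) < threshold)
}

#' Read and validate per-sample metadata
#'
#' Tab-separated, one row per sample, with site assignment, coordinates
#' (decimal degrees), climate (MAT in degrees C, MAP in mm) and soil
#' covariates (pH, total N/P/K, organic matter).
#'
#' @param path file path.
#' @return data.frame with the required columns.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  validate_sample_metadata(md)
}

metadata_columns <- c("sample_id", "site", "latitude", "longitude",
                      "MAT", "MAP", "pH", "N", "P", "K", "OM")

#' Validate sample metadata (optionally against an OTU table)
#'
#' @param metadata data.frame of per-sample covariates.
#' @param table optional [otu_table()]; every sample in the table must have
#'   exactly one metadata row.
#' @return the validated data.frame, invisibly ordered as given.
#' @export
validate_sample_metadata <- function(metadata, table = NULL) {
  missing_cols <- setdiff(metadata_columns, colnames(metadata))
  if (length(missing_cols) > 0)
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$site <- as.character(metadata$site)
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  if (any(is.na(metadata$site) | metadata$site == ""))
    stop("every sample needs a site label", call. = FALSE)
  if (!is.null(table)) {
    absent <- setdiff(rownames(table), metadata$sample_id)
    if (length(absent) > 0)
      stop("samples missing from metadata: ",
           paste(absent, collapse = ", "), call. = FALSE)
  }
  metadata
}

#' Read an OTU taxonomy map
#'
#' @param path TSV with columns `otu_id`, `genus`, `lineage`.
#' @return data.frame; at most one record per OTU.
#' @export
read_taxonomy <- function(path) {
  tx <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  need <- c("otu_id", "genus", "lineage")
  missing_cols <- setdiff(need, colnames(tx))
  if (length(missing_cols) > 0)
    stop("taxonomy is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tx$otu_id))
    stop("taxonomy has more than one record for an otu_id", call. = FALSE)
  tx
}
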