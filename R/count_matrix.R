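#' Region-by-sample count matrix
#'
#' Lightweight container for the signal of one histone mark quantified over a
#' set of regions (genes, promoters, peaks) in a set of samples. Raw matrices
#' hold nonnegative integers (read counts per region); normalized matrices
#' (after [normalize_counts()]) hold nonnegative reals.
#'
#' @param counts numeric matrix with region ids as rownames and sample ids as
#'   colnames. No negative entries; raw matrices must be integer-valued.
#' @param mark character scalar tagging the histone mark (e.g. `"H3K27ac"`).
#' @param normalized logical; `FALSE` for raw counts.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `mark` and `normalized`.
#' @export
count_matrix <- function(counts, mark = NA_character_, normalized = FALSE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have region ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate region ids in count matrix")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in count matrix")
  if (anyNA(counts)) stop("count matrix contains missing values")
  if (any(counts < 0)) stop("count matrix contains negative entries")
  if (!normalized && any(counts != round(counts)))
    stop("raw count matrix contains non-integer entries")
  structure(
    list(counts = counts, mark = as.character(mark),
         normalized = isTRUE(normalized)),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d regions x %d samples; mark = %s; %s\n",
              nrow(x$counts), ncol(x$counts), x$mark,
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

## Accept either a count_matrix or a bare matrix everywhere downstream.
cm_counts <- function(x) {
  if (inherits(x, "count_matrix")) x$counts
  else if (is.matrix(x)) x
  else stop("expected a count_matrix or a matrix")
}

cm_mark <- function(x) if (inherits(x, "count_matrix")) x$mark else NA_character_

cm_is_normalized <- function(x) inherits(x, "count_matrix") && x$normalized

#' Read / write a region-by-sample count matrix as TSV
#'
#' The on-disk format is tab-separated with a header line; the first column is
#' `region_id`, the remaining columns are sample ids.
#'
#' @param path file path.
#' @param mark mark tag to attach to the matrix.
#' @param normalized logical; set `TRUE` when reading normalized (real-valued)
#'   matrices.
#' @return `read_count_matrix()` returns a [count_matrix()];
#'   `write_count_matrix()` returns `path` invisibly.
#' @export
read_count_matrix <- function(path, mark = NA_character_, normalized = FALSE) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count matrix file needs a region_id column plus >= 1 sample")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in count matrix file: ", path)
  rownames(m) <- as.character(df[[1L]])
  count_matrix(m, mark = mark, normalized = normalized)
}

#' @rdname read_count_matrix
#' @param x a [count_matrix()] or bare matrix.
#' @export
write_count_matrix <- function(x, path) {
  m <- cm_counts(x)
  df <- data.frame(region_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
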