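#' Construct a miRNA x sample count matrix
#'
#' The central container of the pipeline: an integer matrix of read counts
#' with unique row (miRNA) and column (sample) identifiers and a per-sample
#' library size. The library size is defined as the total number of assigned
#' miRNA reads in the sample, i.e. the column sum.
#'
#' @param counts integer matrix with rownames (miRNA ids) and colnames
#'   (sample ids).
#' @param lib_sizes optional named numeric vector of library sizes; defaults
#'   to the column sums and must equal them.
#' @return an object of class \code{count_matrix} with elements
#'   \code{counts} and \code{lib_sizes}.
#' @export
count_matrix <- function(counts, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have row and column names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate miRNA ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  lib_sizes <- lib_sizes[colnames(counts)]
  if (any(abs(lib_sizes - colSums(counts)) > 1e-6)) {
    stop("library sizes must equal column sums")
  }
  structure(list(counts = counts, lib_sizes = lib_sizes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d miRNAs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("library sizes: %s .. %s\n",
              format(min(x$lib_sizes)), format(max(x$lib_sizes))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# internal: subset rows/columns, recomputing library sizes
subset_count_matrix <- function(cm, rows = NULL, cols = NULL) {
  m <- cm$counts
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  if (!is.null(cols)) m <- m[, cols, drop = FALSE]
  count_matrix(m)
}
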