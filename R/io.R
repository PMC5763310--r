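# Delimited-text input/output. Matrices travel as TSV with an optional
# header row of sample IDs; numbers are written with 17 significant digits
# so that kernels round-trip bit-exactly through text.

#' Write a numeric matrix as tab-separated text
#'
#' @param x numeric matrix.
#' @param path output file.
#' @param ids optional character vector of sample IDs written as a header
#'   row.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, ids = NULL) {
  x <- as.matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(ids)) {
    if (length(ids) != ncol(x)) stop("'ids' must have one entry per column")
    writeLines(paste(ids, collapse = "\t"), con)
  }
  lines <- apply(x, 1, function(row) {
    paste(sprintf("%.17g", row), collapse = "\t")
  })
  writeLines(lines, con)
  invisible(path)
}

#' Read a numeric matrix from tab-separated text
#'
#' A first row that does not parse as numbers is treated as a header of
#' sample IDs (returned as column names).
#'
#' @param path input file.
#' @return A numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  x <- as.matrix(utils::read.table(path, sep = "\t", header = has_header,
                                   check.names = FALSE,
                                   colClasses = "numeric"))
  dimnames(x) <- if (has_header) list(NULL, colnames(x)) else NULL
  x
}

#' Write cluster labels as two-column TSV
#'
#' @param labels label vector.
#' @param path output file.
#' @param ids sample IDs; defaults to `sample_1 ... sample_n`.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(labels, path, ids = NULL) {
  if (is.null(ids)) ids <- paste0("sample_", seq_along(labels))
  utils::write.table(data.frame(id = ids, cluster = labels), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cluster labels from TSV
#'
#' Accepts the two-column format of [write_labels_tsv()] or a one-column
#' file of bare labels.
#'
#' @param path input file.
#' @return An integer-coded label vector (named by sample ID when present).
#' @export
read_labels_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  if (ncol(df) >= 2L) {
    stats::setNames(df[[2]], df[[1]])
  } else {
    utils::read.table(path, sep = "\t", header = FALSE)[[1]]
  }
}

#' Read and validate a set of view files
#'
#' Parses each file as a matrix, checks that all views cover the same
#' number of samples, that values are finite, and that square matrices
#' claimed to be kernels are symmetric within tolerance.
#'
#' @param paths character vector of TSV files (one per view).
#' @param expected_n optional sample count that every view must match.
#' @param kernels if `TRUE`, require square symmetric matrices.
#' @param tol symmetry tolerance for kernel files.
#' @return A [view_set()].
#' @export
validate_views <- function(paths, expected_n = NULL, kernels = FALSE,
                           tol = 1e-8) {
  views <- lapply(paths, read_matrix_tsv)
  names(views) <- if (!is.null(names(paths))) names(paths)
                  else tools::file_path_sans_ext(basename(paths))
  ns <- vapply(views, ncol, integer(1))
  if (length(unique(ns)) != 1L) {
    stop("views disagree in sample count: ",
         paste(basename(paths), ns, sep = "=", collapse = ", "))
  }
  if (!is.null(expected_n) && ns[1] != expected_n) {
    stop("expected ", expected_n, " samples, found ", ns[1])
  }
  for (i in seq_along(views)) {
    v <- views[[i]]
    if (!all(is.finite(v))) {
      stop("non-finite values in ", basename(paths[i]))
    }
    if (kernels) {
      if (nrow(v) != ncol(v)) {
        stop(basename(paths[i]), " is not square but was declared a kernel")
      }
      if (max(abs(v - t(v))) > tol * max(1, max(abs(v)))) {
        stop(basename(paths[i]), " is not symmetric within tolerance ", tol)
      }
    }
  }
  view_set(views)
}
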