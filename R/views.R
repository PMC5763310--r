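#' Assemble a set of views over common samples
#'
#' A view is either a data matrix (features x samples) or a precomputed
#' symmetric kernel (samples x samples). All views must describe the same
#' `n` samples in the same order; multi-view fitting needs at least two.
#' Data-matrix views are converted to Gaussian kernels by the fitting
#' functions.
#'
#' @param views list of numeric matrices, or a simulation object from
#'   [simulate_disagreement()] / [simulate_exchange()].
#' @param names optional view labels.
#' @return A list of class `"view_set"` with elements `views`, `n` and
#'   `view_names`.
#' @export
view_set <- function(views, names = NULL) {
  if (inherits(views, "multiview_sim")) views <- views$views
  if (inherits(views, "view_set")) return(views)
  if (!is.list(views) || length(views) < 1L) {
    stop("'views' must be a nonempty list of matrices")
  }
  views <- lapply(views, as.matrix)
  ns <- vapply(views, ncol, integer(1))
  if (length(unique(ns)) != 1L) {
    stop("all views must have the same number of samples (columns); got ",
         paste(ns, collapse = ", "))
  }
  for (i in seq_along(views)) {
    if (!all(is.finite(views[[i]]))) {
      stop("view ", i, " contains non-finite values")
    }
  }
  if (is.null(names)) {
    names <- if (!is.null(base::names(views))) base::names(views)
             else paste0("view", seq_along(views))
  }
  structure(list(views = views, n = ns[[1]], view_names = names),
            class = "view_set")
}

#' @export
print.view_set <- function(x, ...) {
  cat("view_set:", length(x$views), "views over", x$n, "samples\n")
  for (i in seq_along(x$views)) {
    v <- x$views[[i]]
    kind <- if (nrow(v) == ncol(v) &&
                max(abs(v - t(v))) <= 1e-8 * max(1, max(abs(v))))
      "kernel" else paste0(nrow(v), " features")
    cat("  ", x$view_names[i], ": ", kind, "\n", sep = "")
  }
  invisible(x)
}

# Resolve a view set to a list of kernel matrices: square symmetric views
# pass through, data matrices get a Gaussian kernel.
resolve_kernels <- function(views, bandwidth = "median") {
  vs <- view_set(views)
  lapply(vs$views, function(v) {
    if (nrow(v) == ncol(v) &&
        max(abs(v - t(v))) <= 1e-8 * max(1, max(abs(v)))) {
      (v + t(v)) / 2
    } else {
      gaussian_kernel(v, bandwidth = bandwidth)
    }
  })
}
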