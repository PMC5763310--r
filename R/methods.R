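#' @export
print.ecmc <- function(x, ...) {
  cat("Enhanced consensus multi-view clustering (ECMC) fit\n")
  cat(sprintf("  %d views, %d samples | alpha = %g, beta = %g\n",
              x$v, x$n, x$alpha, x$beta))
  cat(sprintf("  %s after %d outer iteration%s, objective %.6g\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, if (x$n_iter == 1) "" else "s",
              utils::tail(x$objective, 1)))
  cat("  consensus scores:",
      paste(sprintf("%s = %.3f", x$view_names, x$consensus), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.ecmc <- function(object, ...) {
  ranks <- function(lst) {
    vapply(lst, function(M) {
      ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
      sum(ev > 1e-8 * max(ev))
    }, numeric(1))
  }
  out <- list(
    alpha = object$alpha, beta = object$beta,
    n = object$n, v = object$v,
    converged = object$converged, n_iter = object$n_iter,
    objective = object$objective,
    consensus = object$consensus,
    consensus_flagged = object$consensus_flagged,
    rank_C = ranks(object$C), rank_D = ranks(object$D),
    view_names = object$view_names
  )
  class(out) <- "summary.ecmc"
  out
}

#' @export
print.summary.ecmc <- function(x, ...) {
  cat("ECMC fit summary\n")
  cat(sprintf("  views: %d | samples: %d | alpha = %g, beta = %g\n",
              x$v, x$n, x$alpha, x$beta))
  cat(sprintf("  outer iterations: %d (%s)\n", x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  objective: first %.6g -> last %.6g\n",
              x$objective[1], utils::tail(x$objective, 1)))
  df <- data.frame(view = x$view_names,
                   consensus_score = round(x$consensus, 4),
                   flagged = x$consensus_flagged,
                   rank_C = x$rank_C, rank_D = x$rank_D)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.cmc <- function(x, ...) {
  cat("Consensus multi-view clustering (CMC) fit\n")
  cat(sprintf("  %d views, %d samples | lambda = %g\n", x$v, x$n, x$lambda))
  cat(sprintf("  %s after %d outer iteration%s, objective %.6g\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, if (x$n_iter == 1) "" else "s",
              utils::tail(x$objective, 1)))
  invisible(x)
}

#' @export
summary.cmc <- function(object, ...) {
  out <- list(lambda = object$lambda, n = object$n, v = object$v,
              converged = object$converged, n_iter = object$n_iter,
              objective = object$objective, view_names = object$view_names)
  class(out) <- "summary.cmc"
  out
}

#' @export
print.summary.cmc <- function(x, ...) {
  cat("CMC fit summary\n")
  cat(sprintf("  views: %d | samples: %d | lambda = %g\n",
              x$v, x$n, x$lambda))
  cat(sprintf("  outer iterations: %d (%s)\n", x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  objective: first %.6g -> last %.6g\n",
              x$objective[1], utils::tail(x$objective, 1)))
  invisible(x)
}

#' Objective-trace plot of a model fit
#'
#' Plots the block-coordinate-ascent objective against the outer iteration;
#' a non-decreasing trace that flattens out is the visual convergence
#' check.
#'
#' @param x an [ecmc()] or [cmc()] fit.
#' @param ... passed to [plot.default()].
#' @return `x`, invisibly.
#' @export
plot.ecmc <- function(x, ...) {
  plot(seq_along(x$objective), x$objective, type = "b", pch = 16,
       xlab = "outer iteration", ylab = "objective",
       main = "ECMC block coordinate ascent", ...)
  invisible(x)
}

#' @rdname plot.ecmc
#' @export
plot.cmc <- function(x, ...) {
  plot(seq_along(x$objective), x$objective, type = "b", pch = 16,
       xlab = "outer iteration", ylab = "objective",
       main = "CMC block coordinate ascent", ...)
  invisible(x)
}

#' Reconstructed kernels of a fit
#'
#' For the enhanced model the fitted value of view i is the reconstructed
#' kernel `K_i = C_i + D_i`; for the consensus model it is `K_i` itself.
#'
#' @param object an [ecmc()] or [cmc()] fit.
#' @param ... unused.
#' @return A list of n x n matrices, one per view.
#' @export
fitted.ecmc <- function(object, ...) {
  stats::setNames(Map(`+`, object$C, object$D), object$view_names)
}

#' @rdname fitted.ecmc
#' @export
fitted.cmc <- function(object, ...) {
  stats::setNames(object$K, object$view_names)
}
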