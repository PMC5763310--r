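#' Subproblem matrix for one consensus-kernel update
#'
#' Updating the consensus part `C_i` of the enhanced model with all other
#' blocks held fixed is a trace maximization over the unit-trace PSD cone
#' (see [max_trace_psd()]) with matrix
#' `M_i = H (W_i + 2 alpha * sum_{j != i} C_j - beta * sum_j D_j) H`.
#' Note the disagreement sum runs over *all* views including the own view.
#'
#' @param W_i input kernel of view i (n x n).
#' @param C_others list of the current consensus kernels of the other views
#'   (may be empty).
#' @param D_all list of the current disagreement kernels of all views.
#' @param alpha,beta nonnegative coupling weights.
#' @return The symmetric n x n subproblem matrix.
#' @export
build_M <- function(W_i, C_others, D_all, alpha, beta) {
  n <- nrow(W_i)
  stopifnot(ncol(W_i) == n, alpha >= 0, beta >= 0)
  acc <- W_i
  for (C in C_others) {
    if (!all(dim(C) == n)) stop("dimension mismatch in 'C_others'")
    acc <- acc + 2 * alpha * C
  }
  for (D in D_all) {
    if (!all(dim(D) == n)) stop("dimension mismatch in 'D_all'")
    acc <- acc - beta * D
  }
  center_kernel(acc)
}

#' Subproblem matrix for one disagreement-kernel update
#'
#' Updating the disagreement part `D_i` with the consensus parts fixed is
#' the trace maximization with matrix `N_i = H (W_i - beta * sum_j C_j) H`,
#' the sum again running over all views.
#'
#' @param W_i input kernel of view i (n x n).
#' @param C_all list of the current consensus kernels of all views.
#' @param beta nonnegative weight of the consensus/disagreement repulsion.
#' @return The symmetric n x n subproblem matrix.
#' @export
build_N <- function(W_i, C_all, beta) {
  n <- nrow(W_i)
  stopifnot(ncol(W_i) == n, beta >= 0)
  acc <- W_i
  for (C in C_all) {
    if (!all(dim(C) == n)) stop("dimension mismatch in 'C_all'")
    acc <- acc - beta * C
  }
  center_kernel(acc)
}

# Objective of the enhanced model at the current blocks.
# sum_i tr(W_i H (C_i + D_i) H) + alpha sum_{i!=j} tr(C_i H C_j H)
#   - beta sum_{i,j} tr(C_i H D_j H)
ecmc_objective <- function(HWH, C, D, alpha, beta) {
  v <- length(C)
  HCH <- lapply(C, center_kernel)
  obj <- 0
  for (i in seq_len(v)) {
    obj <- obj + sum(HWH[[i]] * (C[[i]] + D[[i]]))
    for (j in seq_len(v)) {
      if (j != i) obj <- obj + alpha * sum(HCH[[i]] * C[[j]])
      obj <- obj - beta * sum(HCH[[i]] * D[[j]])
    }
  }
  obj
}

#' Fit the enhanced consensus multi-view clustering model
#'
#' Decomposes each view's kernel `W_i` into a consensus part `C_i` and a
#' disagreement part `D_i` (both positive semidefinite with unit trace) by
#' maximizing
#' \deqn{\sum_i tr(W_i H (C_i + D_i) H) + \alpha \sum_{i \ne j} tr(C_i H C_j H)
#'       - \beta \sum_{i,j} tr(C_i H D_j H)}
#' over all blocks, where `H` is the centering matrix. The first term makes
#' the reconstructed kernel `K_i = C_i + D_i` preserve each view's sample
#' similarities, the second rewards HSIC agreement between consensus parts
#' across views, and the third forces the consensus parts away from every
#' disagreement part. The linear sum of the fitted `C_i` is the input for
#' spectral clustering (see [consensus_kernel()] and [spectral_cluster()]).
#'
#' Optimization is block coordinate ascent: in each outer iteration all
#' `C_i` are updated one by one, then all `D_i`, each update being an exact
#' trace maximization over the unit-trace PSD cone ([max_trace_psd()]).
#' Blocks are initialized as `C_i = W_i - 2I` and `D_i = 2I`; these only
#' enter through the first round of subproblem matrices, after which all
#' iterates are feasible. Because every update is an exact block maximizer
#' and the objective is bounded above on the feasible set, the objective is
#' non-decreasing from the first full iteration on.
#'
#' @param views a [view_set()], a plain list of per-view matrices (data
#'   matrices are converted to Gaussian kernels), or a simulation object.
#' @param alpha nonnegative weight of the cross-view consensus agreement.
#' @param beta nonnegative weight of the consensus/disagreement repulsion.
#' @param bandwidth Gaussian bandwidth for data-matrix views (see
#'   [gaussian_kernel()]).
#' @param tol convergence tolerance: the fit stops when the largest
#'   Frobenius-norm change over all `C_i` and `D_i` in one outer iteration
#'   is at most `tol`.
#' @param obj_tol secondary stopping rule: stop when the relative objective
#'   increase stays below `obj_tol` for two consecutive outer iterations.
#'   At strong couplings the blocks can drift indefinitely inside a
#'   near-degenerate optimal manifold while the objective has flattened;
#'   the plateau rule ends such fits early (`status = "objective"`).
#'   Set to 0 to disable.
#' @param max_iter maximum number of outer iterations; reaching it without
#'   convergence gives a warning, not an error.
#' @param track_blocks if `TRUE`, record the objective after every single
#'   block update (for ascent audits), not just per outer iteration.
#' @param score_reference reference kernel in the consensus score
#'   (see [consensus_score()]): `"input"` compares against the original
#'   `W_i` (default), `"reconstructed"` against `K_i = C_i + D_i`. The
#'   reconstructed reading is degenerate whenever `C_i` and `D_i` are
#'   rank-one projectors (the generic optimum), where it always equals 1/2.
#' @return An object of class `"ecmc"`: a list with the fitted kernels
#'   `C` and `D` (lists of n x n matrices), the input kernels `W`, the
#'   per-outer-iteration `objective` trace, optional `block_objective`
#'   data frame, per-view `consensus` scores, `converged`, `status`
#'   (`"iterates"`, `"objective"` or `"max_iter"`), `final_delta` (last
#'   max Frobenius change), `n_iter`, `alpha`, `beta`, `n`, `v` and the
#'   matched call.
#' @seealso [cmc()] for the non-decomposed model, [ecmc_grid()] for
#'   hyperparameter search.
#' @examples
#' sim <- simulate_disagreement(t = 2, seed = 1)
#' fit <- ecmc(sim, alpha = 0.01, beta = 100)
#' fit
#' @export
ecmc <- function(views, alpha = 1, beta = 1, bandwidth = "median",
                 tol = 1e-6, obj_tol = 1e-7, max_iter = 100L,
                 track_blocks = FALSE,
                 score_reference = c("input", "reconstructed")) {
  score_reference <- match.arg(score_reference)
  stopifnot(alpha >= 0, beta >= 0, tol > 0, obj_tol >= 0, max_iter >= 1)
  W <- resolve_kernels(views, bandwidth)
  v <- length(W)
  if (v < 2L) stop("multi-view fitting needs at least 2 views")
  n <- nrow(W[[1]])

  HWH <- lapply(W, center_kernel)
  I2 <- 2 * diag(n)
  C <- lapply(W, function(w) w - I2)  # stated initials; infeasible, used
  D <- rep(list(I2), v)               # only to build the first subproblems

  objective <- numeric(0)
  blk <- if (track_blocks) {
    list(iter = integer(0), block = character(0), value = numeric(0))
  } else NULL
  note_block <- function(it, label) {
    if (track_blocks) {
      blk$iter  <<- c(blk$iter, it)
      blk$block <<- c(blk$block, label)
      blk$value <<- c(blk$value, ecmc_objective(HWH, C, D, alpha, beta))
    }
  }

  status <- "max_iter"
  n_iter <- 0L
  plateau <- 0L
  for (it in seq_len(max_iter)) {
    C_prev <- C
    D_prev <- D
    for (i in seq_len(v)) {
      C[[i]] <- max_trace_psd(build_M(W[[i]], C[-i], D, alpha, beta))$C_star
      note_block(it, paste0("C", i))
    }
    for (i in seq_len(v)) {
      D[[i]] <- max_trace_psd(build_N(W[[i]], C, beta))$C_star
      note_block(it, paste0("D", i))
    }
    objective <- c(objective, ecmc_objective(HWH, C, D, alpha, beta))
    n_iter <- it
    delta <- max(c(
      vapply(seq_len(v), function(i) sqrt(sum((C[[i]] - C_prev[[i]])^2)),
             numeric(1)),
      vapply(seq_len(v), function(i) sqrt(sum((D[[i]] - D_prev[[i]])^2)),
             numeric(1))))
    if (delta <= tol) {
      status <- "iterates"
      break
    }
    if (obj_tol > 0 && it >= 2) {
      rel <- abs(objective[it] - objective[it - 1]) /
             max(1, abs(objective[it]))
      plateau <- if (rel <= obj_tol) plateau + 1L else 0L
      if (plateau >= 2L) {
        status <- "objective"
        break
      }
    }
  }
  converged <- status != "max_iter"
  if (!converged) {
    warning("ECMC did not converge in ", max_iter,
            " outer iterations (last max Frobenius change ",
            format(delta), ")")
  }

  scores <- vapply(seq_len(v), function(i) {
    ref <- if (score_reference == "input") W[[i]] else NULL
    tryCatch(consensus_score(C[[i]], D[[i]], W = ref),
             error = function(e) NA_real_)
  }, numeric(1))
  flagged <- !is.na(scores) & (scores < 0 | scores > 1)
  if (any(flagged)) {
    warning("consensus score outside [0, 1] for view(s) ",
            paste(which(flagged), collapse = ", "),
            "; reported as-is (possible model pathology)")
  }

  structure(list(
    C = C, D = D, W = W,
    objective = objective,
    block_objective = if (track_blocks) as.data.frame(blk) else NULL,
    consensus = scores,
    consensus_flagged = flagged,
    score_reference = score_reference,
    converged = converged, status = status, final_delta = delta,
    n_iter = n_iter,
    alpha = alpha, beta = beta, n = n, v = v,
    view_names = view_set(views)$view_names,
    call = match.call()
  ), class = "ecmc")
}

#' Consensus score of one view's kernel decomposition
#'
#' The fraction of a reference kernel's (centered) signal that is explained
#' by the consensus part:
#' `tr(H K H C) / tr(H K H (C + D))`.
#' Two readings of the reference `K` exist. With `W` supplied (the view's
#' original input kernel) the score measures how much of the *observed*
#' similarity structure the consensus part carries, and discriminates
#' between views. With `W = NULL` the reconstructed kernel `K = C + D`
#' is used; note that whenever `C` and `D` are rank-one projectors
#' orthogonal to the constant vector -- the generic optimum of the model --
#' this reading collapses to exactly 1/2 regardless of the data, so it is
#' retained only for sensitivity analysis.
#'
#' A score within \[0, 1\] is expected but not guaranteed (traces of
#' indefinite products can be negative); out-of-range values are returned
#' as-is with a warning rather than clamped.
#'
#' @param C,D consensus and disagreement kernels (n x n).
#' @param W optional reference kernel; default `NULL` uses `C + D`.
#' @return A single number, close to 1 when the consensus part dominates
#'   the reference signal and close to 0 when the disagreement part does.
#' @export
consensus_score <- function(C, D, W = NULL) {
  if (!all(dim(C) == dim(D))) stop("'C' and 'D' must have equal dimension")
  K <- if (is.null(W)) C + D else W
  if (!all(dim(K) == dim(C))) stop("'W' must match the dimension of 'C'")
  HKH <- center_kernel(K)
  den <- sum(HKH * (C + D))
  if (abs(den) <= 1e-12) {
    stop("degenerate decomposition: tr(H K H (C + D)) is numerically zero")
  }
  val <- sum(HKH * C) / den
  if (val < 0 || val > 1) {
    warning("consensus score ", format(val), " outside [0, 1]")
  }
  val
}

#' Grid search over the ECMC coupling weights
#'
#' Fits the enhanced model for every (alpha, beta) combination, clusters the
#' summed consensus kernel with [spectral_cluster()], scores each fit, and
#' returns the best grid point together with the full score table. The
#' conventional search grid is powers of ten, `10^(-10:10)`; a fixed-alpha
#' protocol is expressed by passing a single alpha. When `stop_at` is set
#' the scan stops early once the score reaches it (useful with metrics that
#' have a known maximum, e.g. 1 for NMI).
#'
#' @param views views as in [ecmc()].
#' @param alphas,betas numeric vectors of nonnegative weights to try.
#' @param k number of clusters.
#' @param metric `"nmi"`, `"acc"` (both need `truth`) or `"silhouette"`.
#' @param truth ground-truth labels, required for `"nmi"` and `"acc"`.
#' @param n_replicates k-means replicates per grid point; the score of a
#'   grid point is the metric averaged over replicates (silhouette: of the
#'   consensus labeling).
#' @param seed seed for the k-means replicate stream.
#' @param bandwidth,tol,max_iter passed to [ecmc()].
#' @param normalizations character vector of [spectral_cluster()]
#'   normalization variants to evaluate per fit (the decomposition is
#'   fitted once per (alpha, beta) and clustered under each variant);
#'   the embedding is treated as one more searched protocol choice.
#' @param stop_at optional early-termination score.
#' @return A list of class `"ecmc_grid"`: `best_fit` (the refitted best
#'   model), `best_alpha`, `best_beta`, `best_score`, `best_clustering`,
#'   and `table` (a data frame with one row per evaluated grid point).
#' @export
ecmc_grid <- function(views, alphas = 10^(-10:10), betas = 10^(-10:10),
                      k = 2, metric = c("nmi", "acc", "silhouette"),
                      truth = NULL, n_replicates = 100, seed = NULL,
                      bandwidth = "median", tol = 1e-6, max_iter = 100L,
                      normalizations = "auto", stop_at = NULL) {
  metric <- match.arg(metric)
  if (metric %in% c("nmi", "acc") && is.null(truth)) {
    stop("metric '", metric, "' requires ground-truth labels")
  }
  if (length(alphas) == 0L || length(betas) == 0L) {
    stop("'alphas' and 'betas' must be nonempty")
  }
  if (inherits(views, "multiview_sim") && is.null(truth) &&
      metric != "silhouette") {
    truth <- views$truth
  }
  W <- resolve_kernels(views, bandwidth)

  tab <- data.frame(alpha = numeric(0), beta = numeric(0),
                    normalization = character(0), score = numeric(0),
                    converged = logical(0))
  best <- list(score = -Inf)
  done <- FALSE
  for (a in alphas) {
    for (b in betas) {
      # iterate non-convergence is recorded in the table instead of one
      # warning per grid point (large couplings commonly cycle between
      # tied block optima while the objective has plateaued)
      fit <- withCallingHandlers(
        ecmc(W, alpha = a, beta = b, tol = tol, max_iter = max_iter),
        warning = function(w) {
          if (grepl("did not converge", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
      CK <- consensus_kernel(fit)
      for (nrm in normalizations) {
        cl <- spectral_cluster(CK, k = k, n_replicates = n_replicates,
                               seed = seed, normalization = nrm)
        score <- switch(metric,
          nmi = mean(apply(cl$replicate_labels, 2, nmi, truth = truth)),
          acc = mean(apply(cl$replicate_labels, 2, clustering_accuracy,
                           truth = truth)),
          silhouette = silhouette_score(cl$embedding, cl$labels))
        tab <- rbind(tab, data.frame(alpha = a, beta = b,
                                     normalization = nrm, score = score,
                                     converged = fit$converged))
        if (score > best$score) {
          best <- list(score = score, alpha = a, beta = b,
                       normalization = nrm, fit = fit, clustering = cl)
        }
        if (!is.null(stop_at) && best$score >= stop_at) {
          done <- TRUE
          break
        }
      }
      if (done) break
    }
    if (done) break
  }
  structure(list(
    best_fit = best$fit, best_alpha = best$alpha, best_beta = best$beta,
    best_normalization = best$normalization,
    best_score = best$score, best_clustering = best$clustering,
    metric = metric, table = tab
  ), class = "ecmc_grid")
}

#' @export
print.ecmc_grid <- function(x, ...) {
  cat(sprintf("ECMC grid search: %d points evaluated, best %s = %.4f at alpha = %g, beta = %g (%s embedding)\n",
              nrow(x$table), x$metric, x$best_score, x$best_alpha,
              x$best_beta, x$best_normalization))
  invisible(x)
}
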