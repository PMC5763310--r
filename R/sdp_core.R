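#' Maximize tr(M C) over the unit-trace PSD cone
#'
#' Solves `max tr(M C)` subject to `C >= 0` (positive semidefinite) and
#' `tr(C) = 1` -- the shared subproblem to which every block update of the
#' CMC and ECMC models reduces. The feasible set (the "spectraplex") is the
#' convex hull of rank-one projectors, so the optimum equals the largest
#' eigenvalue of `M` and is attained at the projector onto the top
#' eigenvector.
#'
#' Two solution routes are provided:
#' \describe{
#'   \item{`"eigen"`}{the closed form: the top eigenprojector. When the
#'     largest eigenvalue is degenerate (eigenvalues within
#'     `degeneracy_tol`, relative, of the maximum), the projectors of all
#'     tied eigenvectors are averaged uniformly -- a deterministic,
#'     symmetric choice that is still optimal.}
#'   \item{`"sdp"`}{an interior-point solver following the log-det barrier
#'     central path: for each barrier weight mu the analytic center
#'     `C(mu) = mu * (nu I - M)^{-1}` is computed by a safeguarded Newton
#'     search for the multiplier nu, and mu is driven to zero. The duality
#'     gap at weight mu is exactly `n * mu`. This route is independent of
#'     any eigendecomposition and serves as a cross-check of the closed
#'     form.}
#' }
#'
#' Feasibility of the returned solution is certified on every call:
#' eigenvalues of `C_star` must be `>= -tol` and its trace within `tol`
#' of one.
#'
#' @param M symmetric numeric matrix. Asymmetry up to `tol` (relative, in
#'   max-norm) is symmetrized as `(M + t(M))/2`; larger asymmetry is an
#'   error.
#' @param tol numeric tolerance for symmetry checks, the feasibility
#'   certificate and (for `"sdp"`) the final duality gap.
#' @param method `"eigen"` (closed form, default) or `"sdp"`
#'   (interior-point cross-check).
#' @param degeneracy_tol relative tolerance under which top eigenvalues are
#'   treated as tied (eigen route only).
#' @return A list of class `"max_trace_psd"` with elements `C_star` (the
#'   optimizer), `objective` (`tr(M C_star)`) and `method`.
#' @examples
#' r <- max_trace_psd(diag(c(3, 1, 0)))
#' r$objective          # 3
#' r$C_star             # diag(1, 0, 0)
#' @export
max_trace_psd <- function(M, tol = 1e-8, method = c("eigen", "sdp"),
                          degeneracy_tol = 1e-8) {
  method <- match.arg(method)
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    stop("'M' must be a square matrix")
  }
  if (!all(is.finite(M))) {
    stop("'M' contains non-finite entries")
  }
  asym <- max(abs(M - t(M)))
  if (asym > tol * max(1, max(abs(M)))) {
    stop("'M' is not symmetric (max asymmetry ", format(asym), ")")
  }
  M <- (M + t(M)) / 2

  C <- switch(method,
    eigen = .spectraplex_eigen(M, degeneracy_tol),
    sdp   = .spectraplex_barrier(M, tol)
  )
  objective <- sum(M * C)

  # post-hoc feasibility certificate
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol || abs(sum(diag(C)) - 1) > tol) {
    stop("internal error: returned solution violates the PSD/unit-trace ",
         "certificate (min eigenvalue ", format(min(ev)), ", trace ",
         format(sum(diag(C))), ")")
  }
  structure(list(C_star = C, objective = objective, method = method),
            class = "max_trace_psd")
}

# closed form: (averaged) top eigenprojector; sign/rotation ambiguity of the
# eigenvectors cancels in the projector
.spectraplex_eigen <- function(M, degeneracy_tol) {
  e <- eigen(M, symmetric = TRUE)
  lmax <- e$values[1]
  tied <- which(e$values >= lmax - degeneracy_tol * max(1, abs(lmax)))
  V <- e$vectors[, tied, drop = FALSE]
  C <- tcrossprod(V) / length(tied)
  (C + t(C)) / 2
}

# log-det barrier central path. C(mu) = mu * (nu I - M)^{-1} with nu chosen
# so that tr(C) = 1; tr(M C(mu)) >= lambda_max - n * mu, so mu is reduced
# until n * mu is well below the requested tolerance.
.spectraplex_barrier <- function(M, tol) {
  n <- nrow(M)
  gersh <- max(diag(M) + (rowSums(abs(M)) - abs(diag(M))))  # >= lambda_max
  mu_final <- tol / (10 * n)
  mu <- 1
  nu <- gersh + mu * n  # here mu * tr((nu I - M)^-1) <= 1 and nu > lambda_max
  S <- NULL
  repeat {
    prev <- nu  # last multiplier with a successful factorization
    for (step in seq_len(200)) {
      R <- tryCatch(chol(nu * diag(n) - M), error = function(e) NULL)
      if (is.null(R)) {  # stepped past lambda_max: bisect back
        nu <- (nu + prev) / 2
        next
      }
      Rinv <- backsolve(R, diag(n))
      S <- tcrossprod(Rinv)              # (nu I - M)^{-1}
      f <- mu * sum(diag(S))
      if (abs(f - 1) < 1e-11) break
      gp <- -mu * sum(S * S)
      prev <- nu
      nu <- nu - (f - 1) / gp            # Newton on a convex decreasing map
    }
    if (mu <= mu_final) break
    mu <- mu / 10
    # warm start: the previous root stays right of lambda_max for smaller mu
  }
  C <- mu * S
  C <- (C + t(C)) / 2
  C / sum(diag(C))
}

#' Check the PSD / unit-trace feasibility certificate
#'
#' @param C square symmetric matrix.
#' @param tol tolerance on the minimum eigenvalue and on `|tr(C) - 1|`.
#' @return `TRUE` if `C` is symmetric PSD with unit trace within `tol`.
#' @export
is_unit_trace_psd <- function(C, tol = 1e-8) {
  if (!is.matrix(C) || nrow(C) != ncol(C)) return(FALSE)
  if (max(abs(C - t(C))) > tol * max(1, max(abs(C)))) return(FALSE)
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol && abs(sum(diag(C)) - 1) <= tol
}
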