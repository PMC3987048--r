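new_precision_result <- function(Gamma, method, cov, ...) {
  structure(c(list(Gamma = Gamma, method = method,
                   column_index = cov$column_index, q = cov$q), list(...)),
            class = "coev_precision")
}

#' @export
print.coev_precision <- function(x, ...) {
  cat(sprintf("<coev_precision> %s, side %d", x$method, nrow(x$Gamma)))
  if (!is.null(x$rho_final)) cat(sprintf(", rho = %g", x$rho_final))
  if (!is.null(x$density)) cat(sprintf(", density = %.4g", x$density))
  cat("\n")
  invisible(x)
}

#' Shrink a covariance matrix until it is positive definite
#'
#' Blends the covariance toward a scaled identity,
#' `C' = (1 - alpha) C + alpha * mean(diag(C)) * I`, increasing `alpha` from
#' 0 in steps of `step` until a Cholesky factorisation succeeds. `alpha = 1`
#' always succeeds when the mean diagonal is positive, so the procedure
#' terminates; a non-positive mean diagonal is a degenerate input.
#'
#' @param cov A `coev_covariance` (or plain symmetric matrix).
#' @param step Shrinkage increment in `(0, 1)`; default 0.05.
#' @return The input with `C` replaced by the shrunk matrix and an `alpha`
#'   element recording the blend used (0 when already positive definite).
#' @export
shrink_to_positive_definite <- function(cov, step = 0.05) {
  stopifnot(step > 0, step < 1)
  plain <- !inherits(cov, "coev_covariance")
  C <- if (plain) cov else cov$C
  mu <- mean(diag(C))
  if (mu <= 0) {
    stop_coev(sprintf("degenerate covariance: mean diagonal %.3g <= 0", mu),
              "coev_degenerate_input")
  }
  p <- nrow(C)
  for (alpha in unique(c(seq(0, 1, by = step), 1))) {
    Cp <- if (alpha == 0) C else (1 - alpha) * C + diag(alpha * mu, p)
    ok <- tryCatch({ chol(Cp); TRUE }, error = function(e) FALSE)
    if (ok) {
      if (plain) {
        attr(Cp, "alpha") <- alpha
        return(Cp)
      }
      cov$C <- Cp
      cov$alpha <- alpha
      return(cov)
    }
  }
  stop_coev("shrinkage failed to reach positive definiteness",
            "coev_degenerate_input")  # unreachable for mu > 0
}

#' Couplings by dense covariance inversion (mean-field DCA path)
#'
#' Inverts the (positive definite) site-state covariance matrix through a
#' Cholesky factorisation, `Gamma = C^-1`. The maximum elementwise residual
#' `|C Gamma - I|` is recorded.
#'
#' @param cov A `coev_covariance` (apply [shrink_to_positive_definite()]
#'   first if the raw matrix is singular) or plain symmetric matrix.
#' @return A `coev_precision` with `method = "inversion"`, the symmetric
#'   `Gamma`, and `residual`.
#' @export
invert_covariance <- function(cov) {
  plain <- !inherits(cov, "coev_covariance")
  C <- if (plain) cov else cov$C
  t0 <- proc.time()[["elapsed"]]
  R <- tryCatch(chol(C), error = function(e) {
    stop_coev(paste0(
      "covariance matrix is not positive definite; apply ",
      "shrink_to_positive_definite() or increase the pseudocount"),
      "coev_singular_matrix")
  })
  Gamma <- chol2inv(R)
  Gamma <- (Gamma + t(Gamma)) / 2
  residual <- max(abs(C %*% Gamma - diag(nrow(C))))
  covlike <- if (plain) list(column_index = seq_len(nrow(C)), q = NA_integer_) else cov
  new_precision_result(Gamma, "inversion", covlike, residual = residual,
                       elapsed = proc.time()[["elapsed"]] - t0)
}

#' Sparse inverse covariance estimation (graphical lasso)
#'
#' Estimates `Gamma` maximising
#' `log det(Gamma) - tr(C Gamma) - rho * ||Gamma||_1(off-diagonal)`
#' by block coordinate descent on the covariance (soft-thresholded lasso
#' updates per column, diagonal unpenalised). Convergence is declared when
#' the maximum change of the working covariance between sweeps drops below
#' `tol` times the mean absolute off-diagonal of `C`. The optional timeout
#' is cooperative: elapsed time is checked between column updates, so the
#' estimate is abandoned in a consistent state and a dedicated
#' `coev_icme_timeout` condition (CLI exit code 3) is raised.
#'
#' @param cov A `coev_covariance` or plain symmetric matrix.
#' @param rho L1 penalty on off-diagonal entries, `>= 0`.
#' @param max_iter Maximum outer sweeps.
#' @param tol Relative convergence tolerance.
#' @param timeout Wall-clock limit in seconds (`Inf` to disable).
#' @param warm Optional warm start: a previous `coev_precision` from this
#'   function on the same matrix (its working covariance and coefficients
#'   are reused).
#' @return A `coev_precision` with `method = "glasso"`, symmetric `Gamma`,
#'   `rho_final`, `density` (fraction of nonzero off-diagonal entries),
#'   `iterations`, `converged`, `elapsed`.
#' @export
glasso_estimate <- function(cov, rho, max_iter = 100L, tol = 1e-4,
                            timeout = Inf, warm = NULL) {
  plain <- !inherits(cov, "coev_covariance")
  C <- if (plain) cov else cov$C
  stopifnot(rho >= 0, isSymmetric(unname(C), tol = 1e-8))
  if (is.finite(timeout) && timeout <= 0) {
    stop_coev(
      "inverse covariance matrix estimation time limit already exhausted",
      "coev_icme_timeout", elapsed = 0)
  }
  W0 <- if (!is.null(warm)) warm$W else matrix(0, 0, 0)
  B0 <- if (!is.null(warm)) warm$B else matrix(0, 0, 0)
  res <- glasso_cpp(C, rho, as.integer(max_iter), tol,
                    if (is.finite(timeout)) timeout else -1, W0, B0)
  if (res$timed_out) {
    stop_coev(sprintf(
      "inverse covariance matrix estimation exceeded the %g s time limit",
      timeout), "coev_icme_timeout", elapsed = res$elapsed)
  }
  if (!res$converged) {
    warning(sprintf(
      "glasso did not converge in %d sweeps; returning best iterate",
      max_iter), call. = FALSE)
  }
  Gamma <- (res$Gamma + t(res$Gamma)) / 2
  p <- nrow(Gamma)
  off <- Gamma; diag(off) <- 0
  density <- if (p > 1L) sum(off != 0) / (p * (p - 1L)) else 0
  covlike <- if (plain) list(column_index = seq_len(p), q = NA_integer_) else cov
  new_precision_result(Gamma, "glasso", covlike, rho_final = rho,
                       density = density, iterations = res$iterations,
                       converged = res$converged, elapsed = res$elapsed,
                       W = res$W, B = res$B)
}

#' Graphical lasso with a target precision-matrix density
#'
#' Runs [glasso_estimate()] at `rho0` and then adjusts `rho` -- geometric
#' bracketing by factors of 2 followed by bisection in log space -- until
#' the achieved off-diagonal density is within +/- 20 percent (relative) of
#' `target_density`, or at most 12 adjustment rounds have elapsed, returning
#' the closest-achieving estimate. Density is non-increasing in `rho`, which
#' the bracketing relies on. Total elapsed time is monitored against
#' `timeout`: the remaining budget is passed to every inner call and a
#' `coev_icme_timeout` condition aborts the search.
#'
#' @inheritParams glasso_estimate
#' @param rho0 Initial penalty, `> 0`.
#' @param target_density Desired fraction of nonzero off-diagonal entries,
#'   in `(0, 1]`.
#' @param max_rounds Maximum adjustment rounds after the initial fit.
#' @param rel_tol Relative density tolerance (default 0.2).
#' @return As [glasso_estimate()], plus `rounds` (glasso calls made) and
#'   `target_density`.
#' @export
glasso_with_density_target <- function(cov, rho0, target_density,
                                       timeout = Inf, max_rounds = 12L,
                                       rel_tol = 0.2, max_iter = 100L,
                                       tol = 1e-4) {
  stopifnot(rho0 > 0, target_density > 0, target_density <= 1)
  t0 <- proc.time()[["elapsed"]]
  remaining <- function() {
    if (!is.finite(timeout)) Inf else timeout - (proc.time()[["elapsed"]] - t0)
  }
  fit_at <- function(rho, warm) {
    glasso_estimate(cov, rho, max_iter = max_iter, tol = tol,
                    timeout = remaining(), warm = warm)
  }
  score <- function(res) abs(res$density - target_density) / target_density

  res <- fit_at(rho0, NULL)
  best <- res; best_rho <- rho0; rounds <- 1L
  rho_lo <- NA_real_  # densest side: density > target
  rho_hi <- NA_real_  # sparsest side: density < target
  rho <- rho0
  while (score(best) > rel_tol && rounds <= max_rounds) {
    if (res$density > target_density) rho_lo <- rho else rho_hi <- rho
    rho <- if (is.na(rho_lo)) {
      rho / 2
    } else if (is.na(rho_hi)) {
      rho * 2
    } else {
      sqrt(rho_lo * rho_hi)
    }
    res <- fit_at(rho, res)
    rounds <- rounds + 1L
    if (score(res) < score(best)) { best <- res; best_rho <- rho }
  }
  best$rho_final <- best_rho
  best$rounds <- rounds
  best$target_density <- target_density
  best$elapsed <- proc.time()[["elapsed"]] - t0
  best
}
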