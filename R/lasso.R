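#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - gamma, 0)`, the inner step of the coordinate-descent
#' lasso solver.
#'
#' @param z numeric vector.
#' @param gamma non-negative threshold.
#' @return Thresholded values.
#' @export
soft_threshold <- function(z, gamma) {
  if (any(gamma < 0)) stop_validation("gamma must be non-negative")
  sign(z) * pmax(abs(z) - gamma, 0)
}

#' Smallest penalty with an all-zero lasso solution
#'
#' For the objective `||Xv - Y||^2 + beta * ||v||_1` (literal scaling, no
#' 1/(2n) factor), the zero vector is optimal iff `beta >= 2 * max_j |X_j' Y|`
#' by the subgradient condition; this function returns that boundary value.
#'
#' @param X numeric matrix (samples x features), typically column-normalized.
#' @param Y numeric response (the 0/1 carrier label).
#' @return Non-negative scalar.
#' @export
penalty_max <- function(X, Y) {
  X <- as.matrix(X)
  if (nrow(X) == 0 || ncol(X) == 0) stop_validation("penalty_max: empty matrix")
  if (nrow(X) != length(Y)) stop_validation("penalty_max: X and Y sizes disagree")
  2 * max(abs(crossprod(X, Y)))
}

#' Solve one lasso problem
#'
#' Minimizes `||Xv - Y||^2 + beta * ||v||_1` by cyclic coordinate descent
#' with a fixed feature order, so the result is deterministic. Note the
#' literal objective scaling: the common `1/(2n)` parameterization (as in
#' glmnet) corresponds to `lambda = beta / (2n)` with unstandardized columns
#' and no intercept.
#'
#' @param X numeric matrix (samples x features) with finite entries.
#' @param Y numeric response vector.
#' @param beta non-negative penalty.
#' @param tol convergence tolerance on the maximum coefficient change per
#'   sweep (default `1e-8`).
#' @param maxit sweep cap before a convergence error is raised.
#' @param warm_start optional coefficient vector to start from.
#' @return An object of class `lasso_fit` with elements `v` (named
#'   coefficients), `beta`, `support` (feature ids with non-zero
#'   coefficient), and `objective`.
#' @export
solve_lasso <- function(X, Y, beta, tol = 1e-8, maxit = 100000L,
                        warm_start = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(Y)) || !is.finite(beta))
    stop_validation("solve_lasso: inputs must be finite")
  if (beta < 0) stop_validation("solve_lasso: beta must be non-negative")
  if (tol <= 0) stop_validation("solve_lasso: tol must be positive")
  v0 <- if (is.null(warm_start)) numeric(0) else as.numeric(warm_start)
  V <- cd_lasso_path(X, Y, beta, tol, as.integer(maxit), v0)
  .lasso_fit(drop(V), X, Y, beta)
}

.ensure_colnames <- function(X) {
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  X
}

.lasso_fit <- function(v, X, Y, beta) {
  X <- .ensure_colnames(X)
  names(v) <- colnames(X)
  obj <- sum((X %*% v - Y)^2) + beta * sum(abs(v))
  structure(list(v = v, beta = beta,
                 support = colnames(X)[v != 0],
                 objective = obj),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("<lasso_fit: beta = %.4g, %d/%d non-zero, objective = %.6g>\n",
              x$beta, length(x$support), length(x$v), x$objective))
  invisible(x)
}

# KKT residual of the literal objective: for active features
# |2 X_j'(Xv - Y) + beta sign(v_j)|, for inactive max(|2 X_j'(Xv - Y)| - beta, 0).
kkt_residual <- function(X, Y, fit) {
  g <- 2 * drop(crossprod(X, X %*% fit$v - Y))
  active <- fit$v != 0
  r_active <- if (any(active)) max(abs(g[active] + fit$beta * sign(fit$v[active]))) else 0
  r_inactive <- if (any(!active)) max(pmax(abs(g[!active]) - fit$beta, 0)) else 0
  max(r_active, r_inactive)
}

#' Regularization path
#'
#' Solves the lasso on a log-spaced penalty grid running from [penalty_max()]
#' down to `penalty_max * beta_min_ratio`, warm-starting each solve from the
#' previous one. The first grid point yields the all-zero solution.
#'
#' @inheritParams solve_lasso
#' @param n_points number of grid points (at least 2).
#' @param beta_min_ratio ratio of the smallest to the largest penalty.
#' @return An object of class `lasso_path`: list with `betas` (decreasing)
#'   and `fits` (one `lasso_fit` per grid point).
#' @export
fit_path <- function(X, Y, n_points = 20L, beta_min_ratio = 1e-3,
                     tol = 1e-8, maxit = 100000L) {
  if (n_points < 2) stop_validation("fit_path: n_points must be >= 2")
  X <- .ensure_colnames(as.matrix(X))
  pmax_ <- penalty_max(X, Y)
  betas <- penalty_grid(pmax_, n_points, beta_min_ratio)
  V <- cd_lasso_path(X, Y, betas, tol, as.integer(maxit), numeric(0))
  fits <- lapply(seq_along(betas), function(g) .lasso_fit(V[, g], X, Y, betas[g]))
  structure(list(betas = betas, fits = fits), class = "lasso_path")
}

penalty_grid <- function(pmax_, n_points, beta_min_ratio = 1e-3) {
  if (pmax_ <= 0) return(rep(0, n_points))
  exp(seq(log(pmax_), log(pmax_ * beta_min_ratio), length.out = n_points))
}

#' Support-constrained lasso fit
#'
#' Implements the k-limited model variants: optionally prescreen to the
#' `prescreen` features with the largest absolute Pearson correlation with
#' the label (ties broken by feature order), then walk the regularization
#' path and return the densest fit whose support does not exceed `k`.
#' Coefficients outside the retained feature set are zero.
#'
#' @inheritParams fit_path
#' @param k maximum number of non-zero coefficients (0 allowed).
#' @param prescreen optional number of candidate features to retain before
#'   fitting.
#' @return A `lasso_fit` over the full feature set.
#' @export
support_constrained_fit <- function(X, Y, k, prescreen = NULL,
                                    n_points = 20L, beta_min_ratio = 1e-3,
                                    tol = 1e-8, maxit = 100000L) {
  X <- .ensure_colnames(as.matrix(X))
  if (k < 0) stop_validation("support_constrained_fit: k must be non-negative")
  k <- min(k, ncol(X))
  keep <- seq_len(ncol(X))
  if (!is.null(prescreen) && prescreen < ncol(X)) {
    r <- abs(suppressWarnings(apply(X, 2, function(col) {
      if (sd(col) == 0 || sd(Y) == 0) 0 else cor(col, Y)
    })))
    r[is.na(r)] <- 0
    keep <- sort(order(-r)[seq_len(prescreen)])  # order() is stable: ties keep feature order
  }
  Xk <- X[, keep, drop = FALSE]
  v_full <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (k == 0) return(.lasso_fit(v_full, X, Y, penalty_max(Xk, Y)))
  path <- fit_path(Xk, Y, n_points = n_points, beta_min_ratio = beta_min_ratio,
                   tol = tol, maxit = maxit)
  sizes <- vapply(path$fits, function(f) length(f$support), integer(1))
  ok <- which(sizes <= k)
  g <- ok[which.max(sizes[ok])]
  if (length(ok) > 1) g <- max(ok[sizes[ok] == max(sizes[ok])])  # densest, then smallest beta
  fit <- path$fits[[g]]
  v_full[names(fit$v)] <- fit$v
  .lasso_fit(v_full, X, Y, fit$beta)
}
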