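# Sparse loadings by regularized rank-one SVD with deflation (sPCA-rSVD).
#
# Each component solves
#   min_{t, p} ||X - t p'||_F^2 + penalty(p)   s.t. ||t|| = 1
# by alternating the closed-form conditional updates
#   t <- X p / ||X p||            (unit score vector)
#   p <- S(X' t, lambda / 2)      (lasso penalty lambda * ||p||_1)
#   p <- keep-r largest |X' t|    (cardinality constraint, exactly r nonzeros)
# The loadings update is separable in the variables, which is what makes the
# cardinality-constrained variant exact.  Subsequent components are fit on
# the residual X - t p'.

#' Sparsity penalty specification
#'
#' @param mode \code{"cardinality"} (exactly \code{cardinality} nonzeros per
#'   component) or \code{"lasso"} (l1 penalty \code{lam}).
#' @param lam Nonnegative lasso penalty (active in lasso mode, or mapped to a
#'   cardinality by bisection when \code{cardinality} is also given).
#' @param cardinality Integer number of nonzeros per component.
#' @param ridge Nonnegative ridge penalty (used by elastic-net SPCA only;
#'   \code{NULL} selects the high-dimension-aware default there).
#' @param rho Nonnegative cardinality penalty weight (pathSPCA bookkeeping).
#' @param search Bisection policy for mapping a target cardinality to a
#'   penalty: list with \code{max_steps}.
#' @return A list of class \code{"penalty_spec"}.
#' @export
penalty_spec <- function(mode = c("cardinality", "lasso"), lam = NULL,
                         cardinality = NULL, ridge = NULL, rho = 0,
                         search = list(max_steps = 60L)) {
  mode <- match.arg(mode)
  if (mode == "cardinality" && is.null(cardinality))
    stop("cardinality mode requires `cardinality`")
  if (mode == "lasso" && is.null(lam) && is.null(cardinality))
    stop("lasso mode requires `lam` or a target `cardinality`")
  if (!is.null(lam) && lam < 0) stop("`lam` must be nonnegative")
  if (!is.null(ridge) && ridge < 0) stop("`ridge` must be nonnegative")
  structure(list(mode = mode, lam = lam, cardinality = cardinality,
                 ridge = ridge, rho = rho, search = search),
            class = "penalty_spec")
}

# Conditional loadings update of the rank-one problem.
rsvd_p_update <- function(xt, penalty) {
  if (penalty$mode == "cardinality") {
    r <- penalty$cardinality
    keep <- order(abs(xt), decreasing = TRUE)[seq_len(r)]
    p <- numeric(length(xt))
    p[keep] <- xt[keep]
    p
  } else {
    soft_threshold(xt, penalty$lam / 2)
  }
}

rsvd_objective <- function(X, t, p, penalty) {
  obj <- fnorm2(X - tcrossprod(t, p))
  if (penalty$mode == "lasso") obj <- obj + penalty$lam * sum(abs(p))
  obj
}

#' Regularized rank-one SVD
#'
#' One sparse component: alternates the unit-score and thresholded-loading
#' updates until the relative objective change falls below \code{tol}.
#' Initialized at the leading singular pair of \code{X}.
#'
#' @param X Numeric matrix (typically a residual after deflation).
#' @param penalty A [penalty_spec()]; in cardinality mode \code{p} has exactly
#'   \code{r} nonzeros, in lasso mode \code{p = S(X't, lam/2)}.
#' @param tol Relative objective-change tolerance.
#' @param max_iter Maximum alternations (warning on non-convergence).
#' @return List with \code{t} (unit score vector), \code{p} (sparse loading
#'   vector carrying the scale), \code{objective}, \code{iterations},
#'   \code{converged}.
#' @export
rank1_sparse_svd <- function(X, penalty, tol = 1e-9, max_iter = 500L) {
  X <- as.matrix(X)
  if (all(X == 0)) stop("`X` is the zero matrix")
  J <- ncol(X)
  if (penalty$mode == "cardinality") {
    if (is.null(penalty$cardinality) || penalty$cardinality < 1L ||
        penalty$cardinality > J)
      stop("`cardinality` must be in [1, J]")
  }
  s <- truncated_svd(X, 1L)
  t <- s$u[, 1L]
  p <- rsvd_p_update(crossprod(X, t)[, 1L], penalty)
  if (all(p == 0)) stop("penalty zeroed the loading vector; decrease `lam`")
  obj <- rsvd_objective(X, t, p, penalty)
  trace <- obj
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    xp <- X %*% p
    nx <- sqrt(sum(xp^2))
    if (nx == 0) break
    t <- xp[, 1L] / nx
    p <- rsvd_p_update(crossprod(X, t)[, 1L], penalty)
    new_obj <- rsvd_objective(X, t, p, penalty)
    trace <- c(trace, new_obj)
    if (abs(obj - new_obj) <= tol * max(abs(obj), 1)) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  if (!converged)
    warning("rank1_sparse_svd: no convergence in ", max_iter, " iterations")
  list(t = t, p = p, objective = obj, objective_trace = trace,
       iterations = iter, converged = converged)
}

#' Sparse PCA via regularized SVD (sPCA-rSVD)
#'
#' Extracts \code{K} sparse-loading components sequentially, each by
#' [rank1_sparse_svd()] on the residual left by the previous components.
#' Score columns are unit norm; loadings carry the scale.  When a lasso
#' penalty is requested together with a target cardinality, \code{lam} is
#' mapped to the cardinality by bisection (nonzero count is non-increasing in
#' \code{lam}).
#'
#' @param X Numeric data matrix (centered/scaled for the standard pipeline).
#' @param K Number of components.
#' @param penalty A [penalty_spec()].
#' @param tol,max_iter Passed to [rank1_sparse_svd()].
#' @return An object of class \code{"spca_model"} (no weights: this is a
#'   sparse-loadings method).
#' @export
spca_rsvd <- function(X, K, penalty, tol = 1e-9, max_iter = 500L) {
  X <- as.matrix(X)
  res <- X
  I <- nrow(X); J <- ncol(X)
  scores <- matrix(0, I, K)
  loadings <- matrix(0, J, K)
  for (k in seq_len(K)) {
    pen_k <- penalty
    if (penalty$mode == "lasso" && !is.null(penalty$cardinality)) {
      pen_k$lam <- bisect_penalty(
        function(lam) {
          p <- rank1_sparse_svd(res, penalty_spec("lasso", lam = lam),
                                tol = tol, max_iter = max_iter)$p
          sum(p != 0)
        },
        target = penalty$cardinality,
        upper = 2 * max(abs(crossprod(res, truncated_svd(res, 1L)$u[, 1L]))),
        max_steps = penalty$search$max_steps)
      pen_k$cardinality <- NULL
    }
    fit <- rank1_sparse_svd(res, pen_k, tol = tol, max_iter = max_iter)
    scores[, k] <- fit$t
    loadings[, k] <- fit$p
    res <- deflate(res, fit$t, fit$p)
  }
  component_model(scores, loadings, weights = NULL, method = "spca-rsvd",
                  extra = list(penalty = penalty, residual_ss = fnorm2(res)))
}

# Bisection on a penalty for which `count(lam)` (number of nonzeros) is
# non-increasing in lam; returns a lam whose count is as close as possible to
# `target` (warning when the exact target is unattainable on the grid).
bisect_penalty <- function(count, target, upper, lower = 0,
                           max_steps = 60L) {
  lo <- lower; hi <- upper
  best_lam <- lower; best_gap <- abs(count(lower) - target)
  if (best_gap == 0L) return(lower)
  for (step in seq_len(max_steps)) {
    mid <- (lo + hi) / 2
    n <- count(mid)
    gap <- abs(n - target)
    if (gap < best_gap || (gap == best_gap && mid > best_lam)) {
      best_gap <- gap
      best_lam <- mid
    }
    if (n > target) lo <- mid else if (n < target) hi <- mid else break
  }
  if (best_gap > 0L)
    warning("bisection could not reach cardinality ", target,
            "; nearest achieved differs by ", best_gap)
  best_lam
}
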