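# Sparse component weights: elastic-net SPCA, greedy cardinality-penalized
# pathSPCA, and the generalized power method (GPower) with a lasso penalty.
#
# All three return T = X W computed on the original data and report loadings
# obtained by least squares given the scores, P = X'T (T'T)^{-1}, so that the
# explained variance of the reconstruction T P' is well defined.

# Least-squares loadings given scores; guards a rank-deficient score matrix.
ls_loadings <- function(X, scores) {
  G <- crossprod(scores)
  if (rcond(G) < 1e-12)
    stop("score matrix is rank deficient; cannot compute loadings")
  crossprod(X, scores) %*% solve(G)
}

#' Elastic net regression by cyclic coordinate descent
#'
#' Minimizes \eqn{\|y - X w\|^2 + \lambda_2 \|w\|^2 + \lambda_1 \|w\|_1} by
#' cyclic coordinate descent with closed-form soft-thresholded updates.
#' Intended for the moderate problem sizes of the sparse PCA updates; the
#' solution satisfies the KKT conditions of the stated objective to within
#' \code{tol}.
#'
#' @param X Numeric I x J design matrix (no intercept; columns used as is).
#' @param y Numeric response of length I.
#' @param lam1 Nonnegative l1 penalty.
#' @param lam2 Nonnegative l2 penalty.
#' @param tol KKT tolerance.
#' @param max_sweeps Maximum coordinate sweeps.
#' @return Numeric coefficient vector of length J.
#' @export
elastic_net_cd <- function(X, y, lam1, lam2, tol = 1e-10,
                           max_sweeps = 10000L) {
  X <- as.matrix(X)
  if (lam1 < 0 || lam2 < 0) stop("penalties must be nonnegative")
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite input")
  J <- ncol(X)
  xx <- colSums(X^2)
  w <- numeric(J)
  r <- as.numeric(y)  # residual y - X w
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(J)) {
      zj <- sum(X[, j] * r) + xx[j] * w[j]
      wj <- soft_threshold(zj, lam1 / 2) / (xx[j] + lam2)
      if (wj != w[j]) {
        r <- r - X[, j] * (wj - w[j])
        delta <- max(delta, abs(wj - w[j]))
      }
      w[j] <- wj
    }
    if (delta < tol) break
  }
  # KKT residuals of  ||y - Xw||^2 + lam2 ||w||^2 + lam1 ||w||_1
  g <- -2 * crossprod(X, r) + 2 * lam2 * w
  active <- w != 0
  bad <- max(c(abs(g[active] + lam1 * sign(w[active])), 0),
             c(pmax(abs(g[!active]) - lam1, 0), 0))
  if (bad > max(tol * 100, 1e-6))
    warning("elastic_net_cd: KKT residual ", format(bad),
            " above tolerance after ", max_sweeps, " sweeps")
  as.numeric(w)
}

# Elastic-net weight update with an exact cardinality target, via the lasso
# on ridge-augmented data (glmnet path; local bisection refinement when no
# path point has exactly r nonzeros).
en_weights_cardinality <- function(X, y, lam2, r) {
  I <- nrow(X); J <- ncol(X)
  Xa <- rbind(X, diag(sqrt(lam2), J))
  ya <- c(y, numeric(J))
  n <- nrow(Xa)
  fit <- glmnet::glmnet(Xa, ya, alpha = 1, standardize = FALSE,
                        intercept = FALSE, nlambda = 100L,
                        lambda.min.ratio = 1e-4, dfmax = min(J, r + 25L))
  df <- fit$df
  hit <- which(df == r)
  if (length(hit)) {
    lam <- fit$lambda[hit[length(hit)]]
    return(as.numeric(fit$beta[, hit[length(hit)]]))
  }
  # bracket the target df between adjacent path lambdas and bisect
  above <- which(df > r); below <- which(df < r)
  hi <- if (length(below)) fit$lambda[max(below)] else max(fit$lambda)
  lo <- if (length(above)) fit$lambda[min(above)] else 0
  beta_at <- function(lam) {
    f <- glmnet::glmnet(Xa, ya, alpha = 1, standardize = FALSE,
                        intercept = FALSE, lambda = lam)
    as.numeric(f$beta[, 1L])
  }
  best <- beta_at(hi); best_gap <- abs(sum(best != 0) - r)
  for (step in seq_len(30L)) {
    if (best_gap == 0L) break
    mid <- (lo + hi) / 2
    b <- beta_at(mid)
    nz <- sum(b != 0)
    gap <- abs(nz - r)
    if (gap < best_gap) { best <- b; best_gap <- gap }
    if (nz > r) lo <- mid else hi <- mid
  }
  if (sum(best != 0) > r) {
    # zero the smallest surplus coefficients so the cardinality is exact
    keep <- order(abs(best), decreasing = TRUE)[seq_len(r)]
    trimmed <- numeric(length(best))
    trimmed[keep] <- best[keep]
    best <- trimmed
  } else if (sum(best != 0) < r) {
    warning("SPCA weight update: achievable cardinality ", sum(best != 0),
            " below target ", r)
  }
  best
}

#' Sparse PCA via elastic-net regularization (SPCA)
#'
#' Alternating minimization of
#' \eqn{\|X - X W P^\top\|_F^2 + \lambda_2 \sum_k \|w_k\|^2 +
#'      \sum_k \lambda_{1,k} \|w_k\|_1} subject to \eqn{P^\top P = I}:
#' for fixed \code{P} each weight column solves the elastic-net regression of
#' \code{X p_k} on \code{X} (cyclic coordinate descent); for fixed \code{W}
#' the loadings update is the orthogonal Procrustes polar factor of
#' \code{X'X W}.  With a cardinality target, the per-component lasso penalty
#' is tuned at each update so the weight column has the requested number of
#' nonzeros.
#'
#' @param X Numeric data matrix.
#' @param K Number of components.
#' @param penalty A [penalty_spec()].  \code{ridge} defaults to \code{1e-6}
#'   when \code{I > J} and \code{1} when \code{J >= I} (the regression is
#'   high-dimensional there and needs the ridge term).
#' @param tol Relative change of the penalized objective at which the
#'   alternation stops.
#' @param max_alt Maximum alternations.
#' @return An object of class \code{"spca_model"} with unit-norm weight
#'   columns, \code{T = X W}, and least-squares loadings.
#' @export
spca_zou <- function(X, K, penalty, tol = 1e-7, max_alt = 100L) {
  X <- as.matrix(X)
  I <- nrow(X); J <- ncol(X)
  lam2 <- penalty$ridge
  if (is.null(lam2)) lam2 <- if (I > J) 1e-6 else 1
  cardinality_mode <- penalty$mode == "cardinality"
  lam1 <- if (cardinality_mode) NA_real_ else penalty$lam
  P <- truncated_svd(X, K)$v
  W <- P
  XtX <- crossprod(X)
  obj <- Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_alt)) {
    W_old <- W
    for (k in seq_len(K)) {
      y <- X %*% P[, k]
      W[, k] <- if (cardinality_mode) {
        en_weights_cardinality(X, y, lam2, penalty$cardinality)
      } else {
        elastic_net_cd(X, y, lam1 = lam1, lam2 = lam2)
      }
    }
    if (all(W == 0)) stop("all weight columns zero; decrease the penalty")
    P <- procrustes_rotation(XtX %*% W)
    new_obj <- fnorm2(X - X %*% tcrossprod(W, P)) + lam2 * fnorm2(W) +
      if (cardinality_mode) 0 else lam1 * sum(abs(W))
    trace <- c(trace, new_obj)
    # in cardinality mode the lasso penalty is re-tuned every alternation, so
    # the stationary point is detected on the iterate rather than the objective
    w_change <- sqrt(fnorm2(W - W_old) / max(fnorm2(W_old), 1e-12))
    if ((is.finite(obj) && abs(obj - new_obj) <= tol * max(abs(obj), 1)) ||
        w_change <= sqrt(tol)) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  if (!converged) warning("spca_zou: no convergence in ", max_alt,
                          " alternations")
  if (any(colSums(W != 0) == 0L))
    stop("a weight column is entirely zero; decrease the penalty")
  W <- unit_columns(W)
  scores <- X %*% W
  component_model(scores, ls_loadings(X, scores), weights = W,
                  method = "spca",
                  extra = list(penalty = penalty, ridge = lam2,
                               objective = obj, objective_trace = trace,
                               converged = converged))
}

#' Sparse PCA via a cardinality penalty (pathSPCA)
#'
#' Greedy forward selection for the variance-maximization problem with an l0
#' penalty: starting from the single variable of maximal variance, each step
#' adds the variable that maximizes the leading eigenvalue of the covariance
#' submatrix on the augmented support, until \code{r} variables are selected.
#' The weight vector is the leading unit eigenvector on the support (zeros
#' elsewhere); subsequent components repeat the search on the least-squares
#' deflated residual.
#'
#' @param X Numeric data matrix.
#' @param K Number of components.
#' @param r Nonzeros per component, \code{1 <= r <= J}.
#' @return An object of class \code{"spca_model"} with sparse unit-norm
#'   weights; \code{supports} lists the selected index set per component.
#' @export
pathspca <- function(X, K, r) {
  X <- as.matrix(X)
  J <- ncol(X)
  if (r < 1L || r > J) stop("`r` must be in [1, J]")
  res <- X
  W <- matrix(0, J, K)
  supports <- vector("list", K)
  for (k in seq_len(K)) {
    S <- crossprod(res)
    sel <- which.max(diag(S))
    while (length(sel) < r) {
      cand <- setdiff(seq_len(J), sel)
      vals <- vapply(cand, function(j) {
        idx <- c(sel, j)
        eigen(S[idx, idx], symmetric = TRUE, only.values = TRUE)$values[1L]
      }, numeric(1))
      sel <- c(sel, cand[which.max(vals)])
    }
    sel <- sort(sel)
    ev <- eigen(S[sel, sel, drop = FALSE], symmetric = TRUE)
    w <- numeric(J)
    w[sel] <- ev$vectors[, 1L]
    jmax <- which.max(abs(w))
    if (w[jmax] < 0) w <- -w
    W[, k] <- w
    supports[[k]] <- sel
    t <- res %*% w
    p <- crossprod(res, t) / sum(t^2)
    res <- deflate(res, t, p)
  }
  scores <- X %*% W
  component_model(scores, ls_loadings(X, scores), weights = W,
                  method = "pathspca",
                  extra = list(r = r, supports = supports))
}

#' Generalized power method, rank one (GPower)
#'
#' Solves \eqn{\max_{\|z\| \le 1} \|S(X^\top z, \lambda)\|^2} by the power-type
#' iteration \eqn{z \gets X S(X^\top z, \lambda) / \|X S(X^\top z, \lambda)\|},
#' initialized at the largest-norm column of \code{X}; the objective is
#' non-decreasing over iterations.  The sparse weight vector is the
#' normalized thresholded image \eqn{w = S(X^\top z, \lambda) /
#' \|S(X^\top z, \lambda)\|}, whose nonzeros give the sparsity pattern.
#'
#' @param X Numeric data matrix.
#' @param lam Lasso penalty, \code{0 <= lam < max_j ||x_j||} (at or above the
#'   largest column norm the threshold kills every variable).
#' @param tol Relative objective-gain tolerance.
#' @param max_iter Maximum iterations.
#' @return List with \code{w} (sparse unit vector), \code{support} (nonzero
#'   indices), \code{z}, \code{objective}, \code{iterations},
#'   \code{converged}.
#' @export
gpower_rank1 <- function(X, lam, tol = 1e-9, max_iter = 1000L) {
  X <- as.matrix(X)
  if (lam < 0) stop("`lam` must be nonnegative")
  colnorm <- sqrt(colSums(X^2))
  if (lam >= max(colnorm))
    stop("penalty eliminates all variables: `lam` must be below max_j ||x_j||")
  jstar <- which.max(colnorm)
  z <- X[, jstar] / colnorm[jstar]
  obj <- sum(soft_threshold(crossprod(X, z), lam)^2)
  trace <- obj
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- soft_threshold(crossprod(X, z)[, 1L], lam)
    xg <- X %*% g
    nx <- sqrt(sum(xg^2))
    if (nx == 0) break
    z <- xg[, 1L] / nx
    new_obj <- sum(soft_threshold(crossprod(X, z), lam)^2)
    trace <- c(trace, new_obj)
    if (new_obj - obj <= tol * max(obj, 1)) {
      obj <- max(new_obj, obj)
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  if (!converged) warning("gpower_rank1: no convergence in ", max_iter,
                          " iterations")
  w <- soft_threshold(crossprod(X, z)[, 1L], lam)
  if (all(w == 0)) stop("penalty zeroed the weight vector")
  w <- w / sqrt(sum(w^2))
  jmax <- which.max(abs(w))
  if (w[jmax] < 0) w <- -w
  list(w = w, support = which(w != 0), z = z, objective = obj,
       objective_trace = trace, iterations = iter, converged = converged)
}

#' Sparse PCA via the generalized power method (GPower)
#'
#' For each component the sparsity pattern is found by [gpower_rank1()] on
#' the current residual (with \code{lam} mapped from a cardinality target by
#' bisection when requested); the within-support weights are then the
#' ordinary leading principal component of the retained columns, with zeros
#' elsewhere.  Components after the first are extracted from the
#' least-squares deflated residual, and \code{T = X W} is computed on the
#' original data.
#'
#' @param X Numeric data matrix.
#' @param K Number of components.
#' @param penalty A [penalty_spec()]: either \code{lam} or a per-component
#'   \code{cardinality} target.
#' @param tol,max_iter Passed to [gpower_rank1()].
#' @return An object of class \code{"spca_model"} with sparse unit-norm
#'   weights and least-squares loadings.
#' @export
gpower <- function(X, K, penalty, tol = 1e-9, max_iter = 1000L) {
  X <- as.matrix(X)
  J <- ncol(X)
  res <- X
  W <- matrix(0, J, K)
  supports <- vector("list", K)
  for (k in seq_len(K)) {
    maxnorm <- max(sqrt(colSums(res^2)))
    lam <- if (penalty$mode == "cardinality") {
      bisect_penalty(
        function(l) {
          length(gpower_rank1(res, l, tol = tol, max_iter = max_iter)$support)
        },
        target = penalty$cardinality,
        upper = maxnorm * (1 - 1e-10),
        max_steps = penalty$search$max_steps)
    } else {
      penalty$lam
    }
    g1 <- gpower_rank1(res, lam, tol = tol, max_iter = max_iter)
    support <- g1$support
    if (penalty$mode == "cardinality" &&
        length(support) != penalty$cardinality) {
      # lambda-to-support-size plateaus can make the exact target unreachable
      # by bisection; enforce it from the magnitude order of X'z, which the
      # thresholded pattern is a prefix of
      mag <- abs(crossprod(res, g1$z))
      support <- sort(order(mag, decreasing = TRUE)[seq_len(penalty$cardinality)])
    }
    sv <- truncated_svd(res[, support, drop = FALSE], 1L)
    w <- numeric(J)
    w[support] <- sv$v[, 1L]
    W[, k] <- w
    supports[[k]] <- support
    t <- res %*% w
    p <- crossprod(res, t) / sum(t^2)
    res <- deflate(res, t, p)
  }
  scores <- X %*% W
  component_model(scores, ls_loadings(X, scores), weights = W,
                  method = "gpower",
                  extra = list(penalty = penalty, supports = supports))
}
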