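#' Center and scale a data matrix
#'
#' Centers each column to mean zero and scales it to unit sample standard
#' deviation (denominator \code{I - 1}).  This is the standardization assumed
#' by all estimators in the package: after it, \code{crossprod(X) / (I - 1)}
#' is the sample correlation matrix.
#'
#' @param raw Numeric matrix (observations in rows, variables in columns)
#'   with at least two rows and no missing values.
#' @return A numeric matrix of the same dimension with attributes
#'   \code{"scaled:center"} and \code{"scaled:scale"} holding the column
#'   means and standard deviations, so the original values are recoverable.
#' @examples
#' X <- center_scale(matrix(rnorm(40), 10, 4))
#' colMeans(X)            # ~ 0
#' apply(X, 2, sd)        # ~ 1
#' @export
center_scale <- function(raw) {
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) stop("`raw` must be a numeric matrix")
  if (nrow(raw) < 2L) stop("`raw` must have at least 2 rows")
  if (anyNA(raw)) stop("`raw` contains missing values")
  sds <- apply(raw, 2L, stats::sd)
  const <- which(sds == 0 | !is.finite(sds))
  if (length(const)) {
    nm <- colnames(raw)[const]
    if (is.null(nm)) nm <- as.character(const)
    stop("constant column(s) cannot be scaled: ", paste(nm, collapse = ", "))
  }
  scale(raw, center = TRUE, scale = sds)
}

#' Truncated singular value decomposition with a fixed sign convention
#'
#' Computes the rank-\code{K} truncated SVD \eqn{X \approx U D V^\top} and
#' applies a deterministic sign convention: each column of \code{V} is
#' flipped so that its largest-magnitude entry is positive (ties broken by
#' the first index), with the corresponding column of \code{U} flipped
#' accordingly.
#'
#' @param X Numeric matrix.
#' @param K Number of singular triplets to retain, \code{1 <= K <= min(dim(X))}.
#' @return A list with components \code{u} (I x K), \code{d} (length K,
#'   non-increasing), \code{v} (J x K).
#' @export
truncated_svd <- function(X, K) {
  X <- as.matrix(X)
  if (length(K) != 1L || K < 1L || K > min(dim(X)))
    stop("`K` must be an integer in [1, min(I, J)]")
  K <- as.integer(K)
  s <- svd(X, nu = K, nv = K)
  s$d <- s$d[seq_len(K)]
  fix_svd_signs(list(u = s$u, d = s$d, v = s$v))
}

# Flip each column of v so its largest-|entry| is positive; first index on ties.
fix_svd_signs <- function(s) {
  for (k in seq_len(ncol(s$v))) {
    j <- which.max(abs(s$v[, k]))
    if (s$v[j, k] < 0) {
      s$v[, k] <- -s$v[, k]
      s$u[, k] <- -s$u[, k]
    }
  }
  s
}

#' Construct a component model
#'
#' Container for an estimated sparse (or ordinary) PCA solution: component
#' scores \code{T} (I x K), component loadings \code{P} (J x K), and, when
#' the method defines them, component weights \code{W} (J x K) with
#' \code{T = X W}.
#'
#' @param scores I x K matrix of component scores.
#' @param loadings J x K matrix of component loadings.
#' @param weights J x K matrix of component weights, or \code{NULL}.
#' @param method Character label of the estimator.
#' @param formulation Optional PCA formulation label.
#' @param extra Optional named list of method-specific fields.
#' @return An object of class \code{"spca_model"}.
#' @export
component_model <- function(scores, loadings, weights = NULL,
                            method = "pca", formulation = NA_character_,
                            extra = list()) {
  stopifnot(is.matrix(scores), is.matrix(loadings),
            ncol(scores) == ncol(loadings))
  out <- c(list(scores = scores, loadings = loadings, weights = weights,
                n_components = ncol(scores), method = method,
                formulation = formulation), extra)
  class(out) <- "spca_model"
  out
}

#' @export
print.spca_model <- function(x, ...) {
  cat(sprintf("Sparse PCA model: method = %s, K = %d, I = %d, J = %d\n",
              x$method, x$n_components, nrow(x$scores), nrow(x$loadings)))
  nzp <- sum(x$loadings != 0)
  cat(sprintf("  loadings: %d/%d nonzero\n", nzp, length(x$loadings)))
  if (!is.null(x$weights))
    cat(sprintf("  weights : %d/%d nonzero\n", sum(x$weights != 0),
                length(x$weights)))
  invisible(x)
}

#' Ordinary principal component analysis under three equivalent formulations
#'
#' Fits ordinary PCA by truncated SVD \eqn{X = U D V^\top} and returns the
#' solution in one of three equivalent parameterizations:
#' \describe{
#'   \item{\code{"ls-orthP"}}{least squares with orthonormal loadings:
#'     \eqn{T = U D}, \eqn{P = V}, \eqn{W = V}.}
#'   \item{\code{"ls-orthT"}}{least squares with score constraint
#'     \eqn{T^\top T = (I-1) I}: \eqn{T = (I-1)^{1/2} U},
#'     \eqn{P = (I-1)^{-1/2} V D}, \eqn{W = (I-1)^{1/2} V D^{-1}}.}
#'   \item{\code{"maxvar"}}{variance maximization: \eqn{W = V},
#'     \eqn{T = X W}, \eqn{P = V}.}
#' }
#' All three produce the identical reconstruction \eqn{T P^\top}.
#'
#' @param X Numeric data matrix, normally centered and scaled
#'   (see [center_scale()]).
#' @param K Number of components.
#' @param formulation One of \code{"ls-orthP"}, \code{"ls-orthT"},
#'   \code{"maxvar"}.
#' @return An object of class \code{"spca_model"}.
#' @export
pca_fit <- function(X, K, formulation = c("ls-orthP", "ls-orthT", "maxvar")) {
  formulation <- match.arg(formulation)
  X <- as.matrix(X)
  s <- truncated_svd(X, K)
  I <- nrow(X)
  if (formulation == "ls-orthP") {
    scores <- s$u %*% diag(s$d, K)
    loadings <- s$v
    weights <- s$v
  } else if (formulation == "ls-orthT") {
    if (any(s$d <= .Machine$double.eps * max(dim(X)) * max(s$d, 1)))
      stop("zero singular value among the first K: ls-orthT weights undefined")
    scores <- sqrt(I - 1) * s$u
    loadings <- s$v %*% diag(s$d / sqrt(I - 1), K)
    weights <- sqrt(I - 1) * s$v %*% diag(1 / s$d, K)
  } else {
    weights <- s$v
    scores <- X %*% weights
    loadings <- s$v
  }
  component_model(scores, loadings, weights, method = "pca",
                  formulation = formulation, extra = list(d = s$d))
}

#' Soft-thresholding operator
#'
#' Elementwise \eqn{S(x, \lambda) = \mathrm{sign}(x) \max(|x| - \lambda, 0)},
#' the proximal operator of the l1 penalty.
#'
#' @param x Numeric vector or matrix.
#' @param lam Nonnegative threshold.
#' @return Object of the same shape as \code{x}.
#' @export
soft_threshold <- function(x, lam) {
  if (length(lam) != 1L || lam < 0) stop("`lam` must be a nonnegative scalar")
  sign(x) * pmax(abs(x) - lam, 0)
}

#' Orthogonal Procrustes polar factor
#'
#' Given \code{M}, returns the (semi-)orthogonal matrix \code{Q} of the same
#' shape maximizing \eqn{\mathrm{Tr}(Q^\top M)}: the polar factor
#' \eqn{Q = A B^\top} from the SVD \eqn{M = A \Sigma B^\top}.  This is the
#' closed-form solution of the orthogonal Procrustes problem used, e.g., in
#' the loadings update of elastic-net sparse PCA.
#'
#' @param M Numeric matrix with finite entries.
#' @return Matrix \code{Q} with \code{crossprod(Q)} equal to the identity.
#' @export
procrustes_rotation <- function(M) {
  M <- as.matrix(M)
  if (!all(is.finite(M))) stop("`M` must be finite")
  s <- svd(M)
  s$u %*% t(s$v)
}

#' Rank-one deflation
#'
#' Removes a fitted rank-one term from the data: \code{X - tcrossprod(t, p)}.
#'
#' @param X Numeric I x J matrix.
#' @param t Score vector of length I.
#' @param p Loading vector of length J.
#' @return The residual matrix.
#' @export
deflate <- function(X, t, p) {
  X <- as.matrix(X)
  if (length(t) != nrow(X) || length(p) != ncol(X))
    stop("dimension mismatch in deflate(): need length(t) == nrow(X), length(p) == ncol(X)")
  X - tcrossprod(as.numeric(t), as.numeric(p))
}
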