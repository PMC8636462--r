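# Performance measures for comparing an estimated component model with the
# planted truth, plus exhaustive component alignment over column
# permutations and sign flips.

#' Squared relative error
#'
#' \eqn{\|\hat A - A\|_F^2 / \|A\|_F^2}.  Zero means perfect recovery;
#' values near or above one mean the estimate is no better than zero.
#'
#' @param A_hat,A Numeric matrices of the same shape.
#' @return Nonnegative scalar.
#' @export
sre <- function(A_hat, A) {
  A_hat <- as.matrix(A_hat); A <- as.matrix(A)
  if (!identical(dim(A_hat), dim(A))) stop("shape mismatch")
  den <- fnorm2(A)
  if (den == 0) stop("reference matrix is all zero")
  fnorm2(A_hat - A) / den
}

#' Misidentification rate
#'
#' Fraction of true zero coefficients not estimated as zero.  Not defined
#' (returns \code{NA}) when the truth has no zeros.
#'
#' @param zero_mask_true,zero_mask_est Logical matrices of the same shape
#'   (\code{TRUE} marks a zero entry).
#' @return Scalar in \code{[0, 1]}, or \code{NA} when there are no true
#'   zeros.
#' @export
mr <- function(zero_mask_true, zero_mask_est) {
  if (!identical(dim(zero_mask_true), dim(zero_mask_est)))
    stop("shape mismatch")
  n_true <- sum(zero_mask_true)
  if (n_true == 0L) return(NA_real_)
  sum(zero_mask_true & !zero_mask_est) / n_true
}

#' Proportion of explained variance
#'
#' \eqn{1 - \|\hat T \hat P^\top - X\|_F^2 / \|X\|_F^2}, clipped to
#' \code{[0, 1]} with a warning when the reconstruction error exceeds the
#' data norm.
#'
#' @param X Data matrix.
#' @param T_hat,P_hat Estimated scores and loadings.
#' @return Scalar in \code{[0, 1]}.
#' @export
pev <- function(X, T_hat, P_hat) {
  X <- as.matrix(X)
  val <- 1 - fnorm2(tcrossprod(as.matrix(T_hat), as.matrix(P_hat)) - X) /
    fnorm2(X)
  if (val < 0) {
    warning("reconstruction error exceeds the data norm; PEV clipped to 0")
    val <- 0
  }
  min(val, 1)
}

#' Tucker congruence (mean columnwise cosine similarity)
#'
#' \eqn{K^{-1} \sum_k a_k^\top b_k / (\|a_k\| \|b_k\|)}.
#'
#' @param A,B Numeric matrices with the same number of columns and no zero
#'   column.
#' @return Scalar in \code{[-1, 1]}.
#' @export
cossim <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("column count mismatch")
  na <- sqrt(colSums(A^2)); nb <- sqrt(colSums(B^2))
  if (any(na == 0) || any(nb == 0)) stop("zero column")
  mean(colSums(A * B) / (na * nb))
}

all_permutations <- function(K) {
  if (K == 1L) return(list(1L))
  out <- list()
  for (k in seq_len(K)) {
    sub <- all_permutations(K - 1L)
    rest <- setdiff(seq_len(K), k)
    out <- c(out, lapply(sub, function(p) c(k, rest[p])))
  }
  out
}

#' Align estimated components to the truth over permutations and signs
#'
#' Exhaustively searches all \eqn{K! \cdot 2^K} column permutations and sign
#' flips of \code{A_hat} for the combination minimizing the squared relative
#' error against \code{A} (\code{objective = "min-sre"}) or maximizing the
#' mean columnwise cosine (\code{"max-cossim"}).  The returned alignment is
#' meant to be applied consistently to the scores, loadings, and weights of
#' the same model (see [apply_alignment()]).
#'
#' @param A_hat,A Numeric matrices with the same column count, \code{K <= 6}.
#' @param objective Alignment criterion.
#' @return List with \code{permutation} (integer vector), \code{signs}
#'   (vector of +-1), and \code{value} (the optimized criterion).
#' @export
align_components <- function(A_hat, A, objective = c("min-sre", "max-cossim")) {
  objective <- match.arg(objective)
  A_hat <- as.matrix(A_hat); A <- as.matrix(A)
  K <- ncol(A)
  if (ncol(A_hat) != K) stop("column count mismatch")
  if (K > 6L)
    stop("exhaustive alignment supports K <= 6; use an assignment ",
         "approximation for larger K (not implemented)")
  signs_grid <- as.matrix(expand.grid(rep(list(c(1, -1)), K)))
  best <- NULL
  for (perm in all_permutations(K)) {
    Ap <- A_hat[, perm, drop = FALSE]
    for (i in seq_len(nrow(signs_grid))) {
      sg <- signs_grid[i, ]
      As <- sweep(Ap, 2L, sg, "*")
      val <- if (objective == "min-sre") sre(As, A) else cossim(As, A)
      better <- if (objective == "min-sre") {
        is.null(best) || val < best$value
      } else {
        is.null(best) || val > best$value
      }
      if (better) best <- list(permutation = perm, signs = sg, value = val)
    }
  }
  best
}

#' Apply a component alignment to a model
#'
#' Permutes and sign-flips the columns of the scores, loadings, and (when
#' present) weights of an \code{"spca_model"} by an alignment found with
#' [align_components()].  The reconstruction \eqn{T P^\top} is unchanged.
#'
#' @param model An \code{"spca_model"}.
#' @param alignment List with \code{permutation} and \code{signs}.
#' @return The aligned model.
#' @export
apply_alignment <- function(model, alignment) {
  flip <- function(M) {
    if (is.null(M)) return(NULL)
    sweep(M[, alignment$permutation, drop = FALSE], 2L, alignment$signs, "*")
  }
  model$scores <- flip(model$scores)
  model$loadings <- flip(model$loadings)
  model$weights <- flip(model$weights)
  model
}

#' Index of sparseness
#'
#' \eqn{IS = PEV_{sparse} \times PEV_{pca} \times PS}; larger is better, and
#' the sparsity level of an empirical analysis is chosen by maximizing it.
#'
#' @param pev_sparse PEV of the sparse solution.
#' @param pev_pca PEV of ordinary PCA with the same number of components.
#' @param ps Proportion of sparsity of the sparse solution.
#' @return The product.
#' @export
index_of_sparseness <- function(pev_sparse, pev_pca, ps) {
  pev_sparse * pev_pca * ps
}

#' Asymptotic consistency limit for the leading eigenvector
#'
#' The almost-sure limit of the squared cosine between the estimated and
#' population leading eigenvectors as the sample grows with \eqn{J/I \to c}:
#' \eqn{R^2_\infty(\omega, c) = (\omega^2 - c)_+ / (\omega^2 + c\,\omega)},
#' where \eqn{\omega} is the limiting signal-to-noise ratio.  Equals 1 (a
#' consistent estimate) if and only if \eqn{c = 0}.
#'
#' @param omega Positive limiting signal-to-noise ratio.
#' @param c Nonnegative limit of \code{J / I}.
#' @return Scalar in \code{[0, 1]}.
#' @export
r_inf_squared <- function(omega, c) {
  if (omega <= 0) stop("`omega` must be positive")
  if (c < 0) stop("`c` must be nonnegative")
  max(omega^2 - c, 0) / (omega^2 + c * omega)
}
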