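# Sparse loadings via simple-structure rotation followed by thresholding.
#
# The rotational freedom of the least-squares PCA model,
#   X = T P' + E = [T (Q^{-1})'] [(P Q)'] + E,
# leaves the reconstruction invariant for any non-singular Q.  Varimax
# searches orthogonal Q, Simplimax oblique Q; neither produces exact zeros,
# so the smallest rotated loadings are thresholded to zero afterwards (the
# field's long-standing, admittedly ad hoc, practice -- reproduced here
# deliberately: scores are not re-estimated after thresholding).

#' Varimax criterion
#'
#' Sum over components of the (population) variance of the squared loadings.
#'
#' @param P Numeric J x K loadings matrix.
#' @return Scalar criterion value.
#' @export
varimax_criterion <- function(P) {
  J <- nrow(P)
  sq <- P^2
  sum(colMeans(sq^2) - colMeans(sq)^2) * J
}

#' Varimax rotation
#'
#' Orthogonal rotation maximizing the variance of the squared loadings, by
#' cyclic pairwise (Jacobi-style) planar rotations with Kaiser's closed-form
#' optimal angle per pair.  The criterion is non-decreasing over sweeps.
#'
#' @param P Numeric J x K loadings matrix, K >= 2 (K = 1 returns the identity
#'   rotation with a warning).
#' @param scores Optional I x K score matrix to rotate along (by Q, since the
#'   inverse transpose of an orthogonal Q is Q itself).
#' @param normalize Kaiser row normalization: rows of P are scaled to unit
#'   length before rotation and unscaled after.  Off by default.
#' @param tol Convergence: stop when the criterion gain of a full sweep falls
#'   below \code{tol}.
#' @param max_iter Maximum number of sweeps.
#' @return A list of class \code{"spca_rotation"} with elements \code{Q}
#'   (K x K orthogonal), \code{rotated_loadings} (\code{P \%*\% Q}),
#'   \code{rotated_scores} (or \code{NULL}), \code{criterion_value},
#'   \code{n_starts_used}, \code{iterations}.
#' @export
rotate_varimax <- function(P, scores = NULL, normalize = FALSE,
                           tol = 1e-8, max_iter = 200L) {
  P <- as.matrix(P)
  K <- ncol(P)
  if (K < 2L) {
    warning("K = 1: varimax rotation is the identity")
    return(structure(list(Q = diag(1), rotated_loadings = P,
                          rotated_scores = scores,
                          criterion_value = varimax_criterion(P),
                          n_starts_used = 1L, iterations = 0L),
                     class = "spca_rotation"))
  }
  scl <- NULL
  L <- P
  if (normalize) {
    scl <- sqrt(rowSums(P^2))
    scl[scl == 0] <- 1
    L <- P / scl
  }
  J <- nrow(L)
  Q <- diag(K)
  crit <- varimax_criterion(L)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (k in seq_len(K - 1L)) {
      for (l in seq.int(k + 1L, K)) {
        x <- L[, k]; y <- L[, l]
        u <- x^2 - y^2
        v <- 2 * x * y
        A <- sum(u); B <- sum(v)
        num <- 2 * sum(u * v) - 2 * A * B / J
        den <- sum(u^2 - v^2) - (A^2 - B^2) / J
        theta <- atan2(num, den) / 4
        if (abs(theta) > .Machine$double.eps) {
          # apply whichever sign of the closed-form angle improves the pair
          # criterion; skip the pair if neither does (already at an optimum)
          base <- varimax_criterion(L[, c(k, l)])
          for (th in c(theta, -theta)) {
            cs <- cos(th); sn <- sin(th)
            R <- matrix(c(cs, -sn, sn, cs), 2L, 2L, byrow = TRUE)
            cand <- L[, c(k, l)] %*% R
            if (varimax_criterion(cand) > base) {
              L[, c(k, l)] <- cand
              Q[, c(k, l)] <- Q[, c(k, l)] %*% R
              break
            }
          }
        }
      }
    }
    new_crit <- varimax_criterion(L)
    gain <- new_crit - crit
    crit <- new_crit
    if (gain < tol || iter >= max_iter) break
  }
  rl <- if (normalize) L * scl else L
  structure(list(Q = Q, rotated_loadings = rl,
                 rotated_scores = if (is.null(scores)) NULL else scores %*% Q,
                 criterion_value = varimax_criterion(rl),
                 n_starts_used = 1L, iterations = iter),
            class = "spca_rotation")
}

# Zero the m smallest-magnitude entries of L (global, ties broken by
# column-major first index); returns the target matrix B.
simplimax_target <- function(L, m) {
  B <- L
  if (m > 0L) {
    ord <- order(abs(L), seq_along(L))[seq_len(m)]
    B[ord] <- 0
  }
  B
}

#' Simplimax rotation
#'
#' Oblique rotation toward a partially specified target: finds a non-singular
#' K x K transformation \code{Q} minimizing \eqn{\|P Q - B\|_F^2}, where the
#' target \code{B} equals \code{P Q} with its \code{m} smallest-magnitude
#' entries set to zero.  Solved by alternating least squares (target update,
#' then column-wise least-squares transform update with \code{Q} rescaled so
#' that \code{diag(solve(crossprod(Q)))} is one, keeping rotated scores on a
#' fixed scale).  The algorithm is prone to local optima, so the best of
#' several starts (random non-singular starts plus a Varimax start) is kept.
#'
#' @param P Numeric J x K loadings matrix of full column rank.
#' @param m Number of target zeros, \code{0 <= m <= J*K - K} (at least one
#'   nonzero must remain per column).
#' @param scores Optional score matrix, rotated by the inverse transpose of
#'   \code{Q}.
#' @param n_starts Number of random starts in addition to the Varimax start.
#' @param tol Stop an ALS run when the loss decrease falls below \code{tol}.
#' @param max_iter Maximum ALS alternations per start.
#' @param seed Optional seed for the random starts.
#' @return A list of class \code{"spca_rotation"}; \code{criterion_value} is
#'   the final least-squares loss.
#' @export
rotate_simplimax <- function(P, m, scores = NULL, n_starts = 10L,
                             tol = 1e-8, max_iter = 500L, seed = NULL) {
  P <- as.matrix(P)
  J <- nrow(P); K <- ncol(P)
  m <- as.integer(m)
  if (m < 0L || m > J * K - K)
    stop("`m` must be in [0, J*K - K] so every column keeps a nonzero")
  if (!is.null(seed)) set.seed(seed)
  if (m == 0L) {
    return(structure(list(Q = diag(K), rotated_loadings = P,
                          rotated_scores = scores, criterion_value = 0,
                          n_starts_used = 0L, iterations = 0L),
                     class = "spca_rotation"))
  }
  PtP <- crossprod(P)
  rescale_q <- function(Q) {
    G <- solve(crossprod(Q))
    Q %*% diag(sqrt(diag(G)), K)
  }
  run_start <- function(Q) {
    Q <- rescale_q(Q)
    loss <- Inf
    it <- 0L
    repeat {
      it <- it + 1L
      L <- P %*% Q
      B <- simplimax_target(L, m)
      new_loss <- fnorm2(L - B)
      if (loss - new_loss < tol || it >= max_iter) {
        loss <- min(loss, new_loss)
        break
      }
      loss <- new_loss
      Qn <- solve(PtP, crossprod(P, B))
      if (rcond(Qn) < 1e-12) break  # degenerate target; keep current iterate
      Q <- rescale_q(Qn)
    }
    list(Q = Q, loss = loss, iterations = it)
  }
  starts <- c(list(rotate_varimax(P)$Q),
              replicate(n_starts, matrix(stats::rnorm(K * K), K, K),
                        simplify = FALSE))
  best <- NULL
  for (Q0 in starts) {
    res <- tryCatch(run_start(Q0), error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$loss < best$loss)) best <- res
  }
  if (is.null(best)) stop("simplimax failed from every start")
  Q <- best$Q
  structure(list(Q = Q, rotated_loadings = P %*% Q,
                 rotated_scores = if (is.null(scores)) NULL
                                  else scores %*% t(solve(Q)),
                 criterion_value = best$loss,
                 n_starts_used = length(starts),
                 iterations = best$iterations),
            class = "spca_rotation")
}

#' Threshold loadings to a target sparsity proportion
#'
#' Sets the \code{floor(ps * J * K)} smallest-magnitude entries to exact zero
#' (globally over the matrix by default, per column with
#' \code{per_column = TRUE}); ties are broken by column-major first index.
#' Nonzero entries are left untouched and scores are not re-estimated.
#'
#' @param P Numeric J x K loadings matrix.
#' @param ps Target proportion of zeros, in \code{[0, 1)}.
#' @param per_column Apply the proportion within each column instead of
#'   globally.
#' @return A list with \code{loadings} (thresholded), \code{zero_mask}
#'   (logical J x K), \code{proportion_sparsity} (realized proportion).
#' @export
threshold_to_sparsity <- function(P, ps, per_column = FALSE) {
  P <- as.matrix(P)
  if (ps < 0 || ps >= 1) stop("`ps` must be in [0, 1)")
  J <- nrow(P); K <- ncol(P)
  L <- P
  if (per_column) {
    nz <- as.integer(floor(ps * J))
    for (k in seq_len(K)) {
      if (nz > 0L) L[order(abs(P[, k]), seq_len(J))[seq_len(nz)], k] <- 0
    }
  } else {
    nz <- as.integer(floor(ps * J * K))
    if (nz > 0L) L[order(abs(P), seq_along(P))[seq_len(nz)]] <- 0
  }
  if (any(colSums(L != 0) == 0L))
    stop("thresholding emptied a column; lower `ps`")
  mask <- L == 0
  list(loadings = L, zero_mask = mask,
       proportion_sparsity = sum(mask) / (J * K))
}
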