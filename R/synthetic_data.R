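# Synthetic data with planted sparse component structure.
#
# Three generating regimes, all starting from the truncated SVD (U, D, V) of
# an iid standard normal, column-centered base matrix X0:
#   alg1-sparseP: sparsify P = V D, orthonormal scores T = U.
#   alg2-sparseW: sparsify W = V (unit-norm columns), T = X0 W, loadings by
#                 least squares of X0 on T.
#   alg3-double : sparsify V with disjoint column supports and unit norms;
#                 loadings and weights share the zero pattern and differ only
#                 by the singular-value scaling.
# Noise is iid normal, column-centered and projected orthogonal to the
# signal, then rescaled so the realized proportion of variance attributable
# to the signal equals the requested VAF exactly.

#' Impose a sparsity pattern on a factor matrix
#'
#' Zeroes a fraction \code{ps} of the entries of \code{M}.  Zero positions
#' are chosen uniformly at random within each column, stratified so all
#' columns have the same nonzero count up to one.  In \code{disjoint} mode
#' the nonzero row slots are dealt round-robin from a random row permutation,
#' so column supports never overlap (requires \code{(1-ps)*J*K <= J}).
#'
#' @param M Numeric J x K matrix.
#' @param ps Proportion of zeros over the whole matrix, in \code{[0, 1)}.
#' @param disjoint Force disjoint column supports.
#' @param unit_norm Renormalize columns to unit Euclidean norm after zeroing.
#' @param by_magnitude Zero the smallest-magnitude entries per column (the
#'   default, which keeps the planted nonzeros well separated from zero and
#'   the support identifiable); \code{FALSE} zeroes uniformly random
#'   positions instead.
#' @return List with \code{matrix} (sparsified) and \code{zero_mask}
#'   (logical J x K).
#' @export
sparsify <- function(M, ps, disjoint = FALSE, unit_norm = FALSE,
                     by_magnitude = TRUE) {
  M <- as.matrix(M)
  J <- nrow(M); K <- ncol(M)
  if (ps < 0 || ps >= 1) stop("`ps` must be in [0, 1)")
  n_zero_total <- as.integer(round(ps * J * K))
  zero_per_col <- rep(n_zero_total %/% K, K)
  extra <- n_zero_total %% K
  if (extra > 0L) zero_per_col[seq_len(extra)] <- zero_per_col[seq_len(extra)] + 1L
  nonzero_per_col <- J - zero_per_col
  if (any(nonzero_per_col < 1L))
    stop("`ps` leaves no nonzero entry in some column")
  mask <- matrix(FALSE, J, K)
  if (disjoint) {
    if (sum(nonzero_per_col) > J)
      stop("disjoint supports infeasible: total nonzeros exceed J")
    mask[] <- TRUE
    quota <- nonzero_per_col
    taken <- logical(J)
    perm <- if (by_magnitude) NULL else sample.int(J)
    pos <- 1L
    k <- 1L
    while (any(quota > 0L)) {        # round-robin deal of row slots
      if (quota[k] > 0L) {
        row <- if (by_magnitude) {
          # column takes its largest-magnitude row still available
          avail <- which(!taken)
          avail[which.max(abs(M[avail, k]))]
        } else {
          while (taken[perm[pos]]) pos <- pos + 1L
          perm[pos]
        }
        taken[row] <- TRUE
        mask[row, k] <- FALSE
        quota[k] <- quota[k] - 1L
      }
      k <- if (k == K) 1L else k + 1L
    }
  } else {
    for (k in seq_len(K)) {
      if (zero_per_col[k] == 0L) next
      idx <- if (by_magnitude) {
        order(abs(M[, k]), seq_len(J))[seq_len(zero_per_col[k])]
      } else {
        sample.int(J, zero_per_col[k])
      }
      mask[idx, k] <- TRUE
    }
  }
  out <- M
  out[mask] <- 0
  if (unit_norm) out <- unit_columns(out)
  list(matrix = out, zero_mask = mask)
}

#' Scale a noise draw to a target proportion of explained variance
#'
#' Draws an iid standard normal matrix of the shape of \code{signal},
#' column-centers it, projects it orthogonal to the signal (in the Frobenius
#' inner product), and rescales so that
#' \eqn{\|signal\|_F^2 / (\|signal\|_F^2 + \|E\|_F^2)} equals \code{vaf}
#' exactly.  With the cross term removed the realized VAF of
#' \code{signal + E} is exact, not just exact in expectation.
#'
#' @param signal Numeric I x J signal matrix (nonzero unless \code{vaf = 1}).
#' @param vaf Target proportion in \code{(0, 1]}; \code{vaf = 1} returns a
#'   zero matrix.
#' @return Noise matrix \code{E} of the shape of \code{signal}.
#' @export
scale_noise_to_vaf <- function(signal, vaf) {
  signal <- as.matrix(signal)
  if (vaf <= 0 || vaf > 1) stop("`vaf` must be in (0, 1]")
  if (vaf == 1) return(matrix(0, nrow(signal), ncol(signal)))
  s2 <- fnorm2(signal)
  if (s2 == 0) stop("zero signal cannot be scaled to vaf < 1")
  E0 <- matrix(stats::rnorm(length(signal)), nrow(signal), ncol(signal))
  E0 <- sweep(E0, 2L, colMeans(E0))
  E0 <- E0 - signal * (sum(E0 * signal) / s2)
  E0 * sqrt(s2 * (1 - vaf) / vaf / fnorm2(E0))
}

#' Generate a dataset with planted sparse component structure
#'
#' @param regime One of \code{"alg1-sparseP"}, \code{"alg2-sparseW"},
#'   \code{"alg3-double"}.
#' @param I,J,K Dimensions: observations, variables, components
#'   (\code{K <= min(I, J)}).
#' @param vaf Target proportion of variance attributable to the signal,
#'   in \code{(0, 1]}.
#' @param ps Proportion of zeros planted in the sparse factor matrix.
#' @param seed Integer seed; the same arguments always reproduce the same
#'   dataset bitwise.
#' @param scenario For \code{"alg3-double"} only: \code{"sparse-W"} reports
#'   the truth in the weight scaling (\code{W = P = V_s}), \code{"sparse-P"}
#'   in the loading scaling (\code{P = V_s D}, \code{W = V_s D^{-1}}).  The
#'   generated data are identical; only the reported truth matrices differ.
#' @param by_magnitude Zero smallest-magnitude entries (default) or random
#'   positions (see [sparsify()]).
#' @return A list of class \code{"spca_dataset"}: \code{X}, \code{T_true},
#'   \code{P_true}, \code{W_true} (\code{NULL} for alg1), \code{E},
#'   \code{signal}, \code{vaf}, \code{ps}, \code{regime}, \code{scenario},
#'   \code{zero_mask_P}, \code{zero_mask_W}, \code{seed}.
#' @export
generate_dataset <- function(regime = c("alg1-sparseP", "alg2-sparseW",
                                        "alg3-double"),
                             I, J, K, vaf, ps, seed,
                             scenario = c("sparse-W", "sparse-P"),
                             by_magnitude = TRUE) {
  regime <- match.arg(regime)
  scenario <- match.arg(scenario)
  if (K > min(I, J)) stop("`K` must be at most min(I, J)")
  set.seed(as.integer(seed))
  X0 <- matrix(stats::rnorm(I * J), I, J)
  X0 <- scale(X0, center = TRUE, scale = FALSE)
  attr(X0, "scaled:center") <- NULL
  s <- truncated_svd(X0, K)
  zero_mask_P <- zero_mask_W <- NULL
  W <- NULL
  if (regime == "alg1-sparseP") {
    sp <- sparsify(s$v %*% diag(s$d, K), ps, by_magnitude = by_magnitude)
    P <- sp$matrix
    zero_mask_P <- sp$zero_mask
    Tm <- s$u
    signal <- tcrossprod(Tm, P)
  } else if (regime == "alg2-sparseW") {
    sp <- sparsify(s$v, ps, unit_norm = TRUE, by_magnitude = by_magnitude)
    W <- sp$matrix
    zero_mask_W <- sp$zero_mask
    Tm <- X0 %*% W
    # loadings that make the weight model self-consistent: with
    # P = W (W'W)^{-1}, the noiseless data satisfy signal %*% W = T exactly,
    # and the loadings share the planted sparsity pattern (up to the support
    # union induced by the K x K mixing), so the principal axes of the
    # generated data are themselves sparse and the planted weights are
    # estimable by variance-maximization methods.
    P <- W %*% solve(crossprod(W))
    signal <- tcrossprod(Tm, P)
  } else {
    sp <- sparsify(s$v, ps, disjoint = TRUE, unit_norm = TRUE,
                   by_magnitude = by_magnitude)
    Vs <- sp$matrix
    zero_mask_P <- zero_mask_W <- sp$zero_mask
    if (scenario == "sparse-W") {
      W <- Vs
      P <- Vs
    } else {
      W <- Vs %*% diag(1 / s$d, K)
      P <- Vs %*% diag(s$d, K)
    }
    Tm <- X0 %*% W
    signal <- tcrossprod(Tm, P)   # = X0 Vs Vs' in either scaling
  }
  E <- scale_noise_to_vaf(signal, vaf)
  X <- signal + E
  structure(list(X = X, T_true = Tm, P_true = P, W_true = W, E = E,
                 signal = signal, vaf = vaf, ps = ps, regime = regime,
                 scenario = if (regime == "alg3-double") scenario else NA,
                 zero_mask_P = zero_mask_P, zero_mask_W = zero_mask_W,
                 seed = as.integer(seed)),
            class = "spca_dataset")
}

#' @export
print.spca_dataset <- function(x, ...) {
  cat(sprintf("Synthetic sparse PCA dataset: %s, I = %d, J = %d, K = %d\n",
              x$regime, nrow(x$X), ncol(x$X), ncol(x$T_true)))
  cat(sprintf("  target VAF = %.3f, sparsity proportion = %.2f, seed = %d\n",
              x$vaf, x$ps, x$seed))
  invisible(x)
}
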