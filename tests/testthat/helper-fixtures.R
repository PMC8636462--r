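# Shared fixtures: everything is generated in code at test time.

# Standardized random matrix.
std_matrix <- function(I, J, seed) {
  set.seed(seed)
  center_scale(matrix(rnorm(I * J), I, J))
}

# A loadings matrix with perfect simple structure: each row has one nonzero.
simple_structure <- function(J, K, seed = 1) {
  set.seed(seed)
  P <- matrix(0, J, K)
  cols <- rep(seq_len(K), length.out = J)
  P[cbind(seq_len(J), cols)] <- runif(J, 0.5, 1.5)
  P
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

# Exhaustive elastic net solution for tiny J by enumerating the KKT sign
# patterns of  ||y - Xw||^2 + lam2 ||w||^2 + lam1 ||w||_1.
enet_bruteforce <- function(X, y, lam1, lam2) {
  J <- ncol(X)
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), J)))
  best <- NULL
  best_obj <- Inf
  for (i in seq_len(nrow(patterns))) {
    s <- patterns[i, ]
    A <- which(s != 0)
    w <- numeric(J)
    if (length(A)) {
      XA <- X[, A, drop = FALSE]
      rhs <- 2 * crossprod(XA, y) - lam1 * s[A]
      wA <- tryCatch(solve(2 * crossprod(XA) + 2 * lam2 * diag(length(A)),
                           rhs),
                     error = function(e) NULL)
      if (is.null(wA)) next
      if (any(sign(wA) != s[A])) next
      w[A] <- wA
    }
    # KKT for the zero coordinates: |2 x_j'(y - Xw)| <= lam1
    g <- 2 * crossprod(X, y - X %*% w)
    if (length(A) < J && any(abs(g[setdiff(seq_len(J), A)]) > lam1 + 1e-8))
      next
    obj <- sum((y - X %*% w)^2) + lam2 * sum(w^2) + lam1 * sum(abs(w))
    if (obj < best_obj) {
      best_obj <- obj
      best <- w
    }
  }
  best
}
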