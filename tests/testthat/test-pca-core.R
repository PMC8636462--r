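test_that("center_scale standardizes, is idempotent, and flags bad input", {
  expect_equal(as.numeric(center_scale(matrix(c(1, 3), 2, 1))),
               c(-1, 1) / sqrt(2))
  X <- std_matrix(20, 5, seed = 1)
  expect_lt(max(abs(center_scale(X) - X)), 1e-10)
  expect_lt(max(abs(colMeans(X))), 1e-10)
  expect_lt(max(abs(apply(X, 2, sd) - 1)), 1e-8)
  expect_error(center_scale(matrix(c(2, 2), 2, 1)), "constant")
  expect_error(center_scale(matrix(c(1, NA, 3, 4), 2, 2)), "missing")
})

test_that("truncated_svd satisfies Eckart-Young and the sign convention", {
  s <- truncated_svd(diag(c(3, 1)), 1)
  expect_equal(s$d, 3)
  expect_equal(as.numeric(s$v), c(1, 0))

  # exact reconstruction at the true rank
  set.seed(2)
  L <- matrix(rnorm(18), 6, 3)
  R <- matrix(rnorm(12), 4, 3)
  X <- L %*% t(R)
  s <- truncated_svd(X, 3)
  expect_lt(sum((X - s$u %*% diag(s$d) %*% t(s$v))^2), 1e-16)

  # residual equals the discarded singular values (full-decomposition oracle)
  set.seed(3)
  X <- matrix(rnorm(40), 8, 5)
  full_d <- svd(X)$d
  s <- truncated_svd(X, 3)
  resid <- sum((X - s$u %*% diag(s$d) %*% t(s$v))^2)
  expect_equal(resid, sum(full_d[4:5]^2), tolerance = 1e-8)

  # sign convention: largest-magnitude entry of each v column is positive
  for (k in 1:3) expect_gt(s$v[which.max(abs(s$v[, k])), k], 0)
  expect_error(truncated_svd(X, 6), "K")
})

test_that("the three PCA formulations are equivalent and deterministic", {
  X <- std_matrix(20, 10, seed = 4)
  I <- nrow(X)
  m <- lapply(c("ls-orthP", "ls-orthT", "maxvar"),
              function(f) pca_fit(X, 3, f))
  recon <- lapply(m, function(x) tcrossprod(x$scores, x$loadings))
  expect_lt(max(abs(recon[[1]] - recon[[2]])), 1e-8)
  expect_lt(max(abs(recon[[1]] - recon[[3]])), 1e-8)
  # constraint structure per formulation
  expect_lt(max(abs(crossprod(m[[1]]$loadings) - diag(3))), 1e-8)
  expect_lt(max(abs(crossprod(m[[2]]$scores) - (I - 1) * diag(3))), 1e-6)
  # stored scores equal X %*% W whenever weights are present
  for (x in m) expect_lt(max(abs(x$scores - X %*% x$weights)), 1e-8)
  # equal loadings/weights for formulations with orthonormal loadings
  expect_lt(max(abs(m[[1]]$weights - m[[3]]$weights)), 1e-12)
  # determinism
  m2 <- pca_fit(X, 3, "ls-orthP")
  expect_identical(m[[1]]$loadings, m2$loadings)
})

test_that("maxvar weights on two perfectly correlated columns are (1,1)/sqrt(2)", {
  set.seed(5)
  x <- rnorm(30)
  X <- center_scale(cbind(x, 2 * x + 1))
  m <- pca_fit(X, 1, "maxvar")
  expect_equal(as.numeric(abs(m$weights)), rep(1 / sqrt(2), 2),
               tolerance = 1e-10)
})

test_that("pca_fit PEV equals the singular-value ratio", {
  X <- std_matrix(25, 8, seed = 6)
  d_full <- svd(X)$d
  m <- pca_fit(X, 3)
  expect_equal(pev(X, m$scores, m$loadings),
               sum(d_full[1:3]^2) / sum(d_full^2), tolerance = 1e-10)
})

test_that("soft_threshold matches its definition", {
  expect_equal(soft_threshold(2, 0.5), 1.5)
  expect_equal(soft_threshold(-0.3, 0.5), 0)
  x <- rnorm(10)
  expect_equal(soft_threshold(x, 0), x)
  expect_error(soft_threshold(1, -1), "nonnegative")
})

test_that("procrustes_rotation returns the polar factor", {
  expect_equal(procrustes_rotation(diag(3)), diag(3))
  set.seed(7)
  Q0 <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(procrustes_rotation(Q0), Q0, tolerance = 1e-12)
  # 2x2 oracle: grid over rotations and reflections at 1e-3 resolution
  M <- matrix(rnorm(4), 2, 2)
  Q <- procrustes_rotation(M)
  expect_lt(max(abs(crossprod(Q) - diag(2))), 1e-10)
  thetas <- seq(0, 2 * pi, by = 1e-3)
  best <- -Inf
  for (th in thetas) {
    R <- rot2(th)
    best <- max(best, sum(diag(t(R) %*% M)),
                sum(diag(t(R %*% diag(c(1, -1))) %*% M)))
  }
  expect_equal(sum(diag(t(Q) %*% M)), best, tolerance = 1e-5)
  expect_error(procrustes_rotation(matrix(c(1, Inf, 0, 1), 2, 2)), "finite")
})

test_that("deflate removes rank-one structure", {
  set.seed(8)
  t <- rnorm(6); p <- rnorm(4)
  expect_equal(deflate(tcrossprod(t, p), t, p), matrix(0, 6, 4))
  X <- matrix(rnorm(24), 6, 4)
  expect_equal(deflate(X, rep(0, 6), p), X)
  expect_error(deflate(X, rnorm(5), p), "dimension")
  # K successive exact deflations of a noiseless rank-K dataset reach zero
  ds <- generate_dataset("alg1-sparseP", 30, 8, 3, vaf = 1, ps = 0, seed = 9)
  res <- ds$X
  for (k in 1:3) {
    s <- truncated_svd(res, 1)
    res <- deflate(res, s$u[, 1] * s$d[1], s$v[, 1])
  }
  expect_lt(sqrt(sum(res^2)), 1e-8)
})
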