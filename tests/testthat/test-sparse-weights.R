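test_that("elastic_net_cd satisfies closed-form special cases", {
  X <- std_matrix(20, 5, seed = 1)
  set.seed(2)
  y <- rnorm(20)
  # l1 penalty above 2 max|X'y| forces the zero solution
  lam_big <- 2 * max(abs(crossprod(X, y))) + 1
  expect_equal(elastic_net_cd(X, y, lam_big, 0), rep(0, 5))
  # orthonormal design, no penalty: ordinary least squares X'y
  Q <- qr.Q(qr(matrix(rnorm(60), 20, 3)))
  expect_equal(elastic_net_cd(Q, y, 0, 0), as.numeric(crossprod(Q, y)),
               tolerance = 1e-8)
})

test_that("elastic_net_cd matches KKT sign-pattern enumeration at J = 3", {
  for (seed in 1:4) {
    set.seed(seed)
    X <- matrix(rnorm(30), 10, 3)
    y <- rnorm(10)
    for (lams in list(c(1, 0.5), c(4, 0), c(0.2, 2))) {
      w_cd <- elastic_net_cd(X, y, lams[1], lams[2])
      w_bf <- enet_bruteforce(X, y, lams[1], lams[2])
      expect_equal(w_cd, w_bf, tolerance = 1e-6)
    }
  }
})

test_that("elastic_net_cd agrees with glmnet on the shared objective", {
  set.seed(5)
  X <- matrix(rnorm(200), 40, 5)
  y <- rnorm(40)
  lam1 <- 3; lam2 <- 1.5
  w_cd <- elastic_net_cd(X, y, lam1, lam2)
  n <- nrow(X)
  a <- lam1 / (2 * n); b <- lam2 / n
  fit <- glmnet::glmnet(X, y, alpha = a / (a + b), lambda = a + b,
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-14)
  w_gl <- as.numeric(fit$beta)
  expect_equal(w_cd, w_gl, tolerance = 1e-2)
  obj <- function(w) sum((y - X %*% w)^2) + lam2 * sum(w^2) +
    lam1 * sum(abs(w))
  expect_lte(obj(w_cd), obj(w_gl) + 1e-8)  # CD is at least as optimal
})

test_that("elastic net support is non-increasing in the l1 penalty", {
  set.seed(6)
  X <- matrix(rnorm(200), 20, 10)
  y <- rnorm(20)
  nnz <- vapply(c(0, 1, 2, 4, 8, 16),
                function(l) sum(elastic_net_cd(X, y, l, 0.5) != 0),
                numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("penalty-free SPCA spans the leading principal subspace", {
  X <- std_matrix(40, 6, seed = 7)
  fit <- spca_zou(X, 2, penalty_spec("lasso", lam = 0, ridge = 1e-6))
  V <- truncated_svd(X, 2)$v
  # principal angles between span(W) and span(V)
  sv <- svd(crossprod(qr.Q(qr(fit$weights)), qr.Q(qr(V))))$d
  expect_lt(max(acos(pmin(sv, 1))), 1e-4)
  expect_equal(pev(X, fit$scores, fit$loadings),
               pev(X, pca_fit(X, 2)$scores, pca_fit(X, 2)$loadings),
               tolerance = 1e-6)
})

test_that("SPCA objective is non-increasing at fixed penalties and recovers planted weights", {
  X <- std_matrix(25, 8, seed = 8)
  fit <- spca_zou(X, 2, penalty_spec("lasso", lam = 1, ridge = 0.5))
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
  # planted one-sparse weights, noiseless: with one nonzero per component
  # the support is identifiable even though the data are exactly rank K
  ds <- generate_dataset("alg2-sparseW", 50, 12, 2, vaf = 1, ps = 11 / 12,
                         seed = 9)
  f <- suppressWarnings(fit_sparse_pca(ds$X, 2, "spca", ps = 11 / 12))
  ev <- evaluate_model(f, ds, "I")
  expect_equal(ev$mr, 0)
  expect_lt(ev$sre_sparse, 1e-3)
})

test_that("pathspca endpoints match their closed forms", {
  # distinct column norms (standardized data would tie every variance)
  set.seed(10)
  X <- matrix(rnorm(180), 30, 6) %*% diag(c(0.5, 2, 1, 1.5, 0.8, 1.2))
  X <- sweep(X, 2, colMeans(X))
  # r = 1: the single largest-norm column
  f1 <- pathspca(X, 1, r = 1)
  jstar <- which.max(colSums(X^2))
  expect_identical(which(f1$weights[, 1] != 0), jstar)
  # r = J: ordinary leading eigenvector
  fJ <- pathspca(X, 1, r = 6)
  v1 <- truncated_svd(X, 1)$v[, 1]
  expect_lt(min(sum((fJ$weights[, 1] - v1)^2),
                sum((fJ$weights[, 1] + v1)^2)), 1e-10)
  expect_error(pathspca(X, 1, r = 7), "r")
})

test_that("pathspca greedy eigenvalue is bounded by the exhaustive optimum and monotone in r", {
  X <- std_matrix(20, 6, seed = 11)
  S <- crossprod(X)
  lead_ev <- function(idx) eigen(S[idx, idx, drop = FALSE],
                                 symmetric = TRUE, only.values = TRUE)$values[1]
  vals <- numeric(6)
  for (r in 1:6) {
    f <- pathspca(X, 1, r = r)
    sup <- which(f$weights[, 1] != 0)
    vals[r] <- lead_ev(sup)
    exhaustive <- max(apply(combn(6, r), 2, lead_ev))
    expect_lte(vals[r], exhaustive + 1e-10)
    if (r %in% c(1, 6)) expect_equal(vals[r], exhaustive, tolerance = 1e-10)
  }
  expect_true(all(diff(vals) >= -1e-10))
})

test_that("gpower_rank1 matches the leading singular vector without penalty", {
  X <- std_matrix(30, 8, seed = 12)
  g <- gpower_rank1(X, 0)
  v1 <- truncated_svd(X, 1)$v[, 1]
  expect_lt(min(sum((g$w - v1)^2), sum((g$w + v1)^2)), 1e-6)
  expect_true(all(diff(g$objective_trace) >= -1e-10))
})

test_that("gpower_rank1 isolates a dominant column and rejects an excessive penalty", {
  set.seed(13)
  X <- matrix(rnorm(100), 20, 5)
  X[, 1] <- X[, 1] * 50
  lam <- 0.95 * sqrt(sum(X[, 1]^2))
  g <- gpower_rank1(X, lam)
  expect_identical(g$support, 1L)
  expect_equal(abs(g$w[1]), 1)
  expect_error(gpower_rank1(X, max(sqrt(colSums(X^2)))), "eliminates")
})

test_that("gpower support size is non-increasing in the penalty", {
  X <- std_matrix(25, 10, seed = 14)
  maxn <- max(sqrt(colSums(X^2)))
  sizes <- vapply(seq(0, 0.9, by = 0.15) * maxn,
                  function(l) length(gpower_rank1(X, l)$support), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("gpower at zero penalty reproduces the leading PCA component", {
  X <- std_matrix(30, 7, seed = 15)
  f <- gpower(X, 1, penalty_spec("lasso", lam = 0))
  m <- pca_fit(X, 1)
  sg <- sign(sum(f$weights * m$weights))
  expect_lt(max(abs(sg * f$weights - m$weights)), 1e-6)
  expect_lt(max(abs(sg * f$scores - m$scores)), 1e-5)
})

test_that("gpower cardinality targeting yields the exact nonzero count", {
  ds <- generate_dataset("alg2-sparseW", 60, 12, 2, vaf = 0.95, ps = 0.75,
                         seed = 16)
  f <- gpower(ds$X, 2, penalty_spec("cardinality", cardinality = 3))
  expect_equal(sum(f$weights != 0), 6L)
})

test_that("weight-based methods return unit-norm weights with T = X W", {
  ds <- generate_dataset("alg2-sparseW", 40, 10, 2, vaf = 0.95, ps = 0.5,
                         seed = 17)
  for (method in c("spca", "pathspca", "gpower")) {
    f <- suppressWarnings(fit_sparse_pca(ds$X, 2, method, ps = 0.5))
    expect_lt(max(abs(colSums(f$weights^2) - 1)), 1e-10)
    expect_equal(f$scores, ds$X %*% f$weights)
  }
})
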