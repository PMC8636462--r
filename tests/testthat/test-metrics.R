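test_that("sre matches its definition", {
  set.seed(1)
  A <- matrix(rnorm(12), 4, 3)
  expect_equal(sre(A, A), 0)
  expect_equal(sre(matrix(0, 4, 3), A), 1)
  expect_equal(sre(2 * A, A), 1)
  expect_error(sre(A, matrix(0, 4, 3)), "zero")
  expect_error(sre(A, matrix(0, 3, 4)), "shape")
})

test_that("mr counts unrecovered zeros and is undefined without true zeros", {
  truth <- matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), 3, 2)
  est <- matrix(c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE), 3, 2)
  expect_equal(mr(truth, est), 0.25)
  expect_true(is.na(mr(matrix(FALSE, 3, 2), est)))
  # matched cardinality, 80% true zeros: the minimum-overlap estimate
  # misses exactly the complement's worth, 1 - .6/.8
  truth10 <- c(rep(TRUE, 8), rep(FALSE, 2))
  est10 <- c(rep(FALSE, 2), rep(TRUE, 8))   # 8 estimated zeros, overlap 6
  expect_equal(mr(truth10, est10), 1 - 0.6 / 0.8)
})

test_that("pev matches the singular-value oracle and clips", {
  X <- std_matrix(20, 6, seed = 2)
  m <- pca_fit(X, 2)
  d <- svd(X)$d
  expect_equal(pev(X, m$scores, m$loadings), sum(d[1:2]^2) / sum(d^2),
               tolerance = 1e-10)
  expect_equal(pev(X, m$scores, m$loadings),
               pev(X, matrix(1, 20, 1), matrix(0, 6, 1)) +
                 sum(d[1:2]^2) / sum(d^2))  # T P' = 0 gives PEV 0
  expect_warning(val <- pev(X, 10 * m$scores, m$loadings), "clipped")
  expect_equal(val, 0)
})

test_that("cossim is the mean columnwise cosine", {
  set.seed(3)
  A <- matrix(rnorm(12), 4, 3)
  expect_equal(cossim(A, A), 1)
  expect_equal(cossim(A, -A), -1)
  B <- cbind(c(1, 0), c(0, 1))
  C <- cbind(c(0, 1), c(1, 0))
  expect_equal(cossim(B, C), 0)
  expect_error(cossim(A, cbind(A, A[, 1])), "column count")
  expect_error(cossim(A, cbind(A[, 1:2], 0)), "zero column")
})

test_that("align_components undoes permutations and sign flips", {
  set.seed(4)
  A <- matrix(rnorm(24), 8, 3)
  A_hat <- A[, c(2, 1, 3)]
  A_hat[, 1] <- -A_hat[, 1]
  al <- align_components(A_hat, A)
  expect_equal(al$value, 0, tolerance = 1e-14)
  aligned <- sweep(A_hat[, al$permutation], 2, al$signs, "*")
  expect_equal(aligned, A)
  # objective switch changes nothing when the estimate equals the truth
  expect_equal(align_components(A, A, "min-sre")$permutation,
               align_components(A, A, "max-cossim")$permutation)
  expect_error(align_components(matrix(1, 2, 7), matrix(1, 2, 7)), "K <= 6")
})

test_that("align_components matches an independent brute force at K = 2", {
  set.seed(5)
  A <- matrix(rnorm(10), 5, 2)
  B <- matrix(rnorm(10), 5, 2)
  al <- align_components(A, B, "min-sre")
  # independent enumeration of all 8 combinations
  best <- Inf
  for (perm in list(1:2, 2:1)) {
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
      cand <- cbind(s1 * A[, perm[1]], s2 * A[, perm[2]])
      best <- min(best, sum((cand - B)^2) / sum(B^2))
    }
  }
  expect_equal(al$value, best, tolerance = 1e-12)
})

test_that("metrics are invariant to scrambling once aligned; pev exactly", {
  ds <- generate_dataset("alg2-sparseW", 40, 10, 2, vaf = 0.9, ps = 0.5,
                         seed = 6)
  f <- fit_sparse_pca(ds$X, 2, "gpower", ps = 0.5)
  base <- evaluate_model(f, ds, "I")
  scr <- f
  scr$scores <- scr$scores[, 2:1] %*% diag(c(-1, 1))
  scr$loadings <- scr$loadings[, 2:1] %*% diag(c(-1, 1))
  scr$weights <- scr$weights[, 2:1] %*% diag(c(-1, 1))
  scrambled <- evaluate_model(scr, ds, "I")
  expect_equal(scrambled$sre_sparse, base$sre_sparse, tolerance = 1e-12)
  expect_equal(scrambled$sre_scores, base$sre_scores, tolerance = 1e-12)
  expect_equal(scrambled$mr, base$mr)
  expect_equal(scrambled$pev, base$pev, tolerance = 1e-14)
})

test_that("index of sparseness is the three-way product", {
  expect_equal(index_of_sparseness(0, 0.5, 0.5), 0)
  expect_equal(index_of_sparseness(0.18, 0.24, 0.73), 0.031536)
  expect_gt(index_of_sparseness(0.2, 0.24, 0.73),
            index_of_sparseness(0.18, 0.24, 0.73))
})

test_that("the high-dimensional consistency limit behaves as stated", {
  expect_equal(r_inf_squared(1.3, 0), 1)
  expect_equal(r_inf_squared(1, 1.5), 0)
  expect_equal(r_inf_squared(2, 1), 0.5)
  expect_error(r_inf_squared(0, 1), "positive")
})
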