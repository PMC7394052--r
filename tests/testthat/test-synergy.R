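test_that("reconstruction quality matches hand Frobenius arithmetic", {
  # X = I2: WA = [[1,0],[0,0]] leaves ||X - WA||^2 = 1 of ||X||^2 = 2
  X <- diag(2)
  W <- matrix(c(1, 0), 2, 1)
  A <- matrix(c(1, 0), 1, 2)
  expect_equal(reconstruction_quality(X, W, A), 50)
  expect_equal(reconstruction_quality(X, diag(2), diag(2)), 100)
  expect_equal(reconstruction_quality(X, matrix(0, 2, 1), matrix(0, 1, 2)), 0)
  expect_error(reconstruction_quality(matrix(0, 2, 2), W, A), "zero")
})

test_that("synergy contributions add up on orthogonal supports", {
  # 4x2 toy with disjoint supports: w1 a1 covers rows 1-2, w2 a2 rows 3-4
  w1 <- c(1, 0)
  w2 <- c(0, 1)
  a1 <- c(2, 1, 0, 0)
  a2 <- c(0, 0, 3, 1)
  X <- t(outer(w1, a1) + outer(w2, a2)) # 4 x 2
  l1 <- synergy_contribution(X, w1, a1)
  l2 <- synergy_contribution(X, w2, a2)
  lam2 <- reconstruction_quality(X, cbind(w1, w2), rbind(a1, a2))
  expect_equal(lam2, 100)
  expect_equal(l1 + l2, lam2, tolerance = 0.1)
  expect_equal(synergy_contribution(X, c(0, 0), a1), 0)
  expect_equal(synergy_contribution(X, w1, a1 * 0 + X[, 1] * 0), 0)
})

test_that("nmf recovers an exact rank-1 factorization", {
  set.seed(2)
  w <- runif(26)
  a <- runif(400)
  X <- outer(a, w)
  fit <- nmf_synergies(X, 1, n_restarts = 2, seed = 1)
  expect_gt(fit$lambda_total, 99.9)
  expect_equal(max(fit$W), 1) # unit-max normalization
  expect_error(nmf_synergies(X * 0, 1), "zeros")
  expect_error(nmf_synergies(-X, 1), "non-negative")
  # objective never increases across iterations
  expect_true(all(diff(fit$err_trace) <= 1e-12))
})

test_that("planted rank-5 weights are recovered after optimal matching", {
  sm <- synth_envelope_matrix(n_sc = 4, noise_sd = 0.05, seed = 3)
  fit <- nmf_synergies(sm$X, 5, n_restarts = 3, seed = 3)
  mc <- match_columns(fit$W, sm$W_true)
  expect_true(all(mc$cosines > 0.9))
  expect_true(all(sort(mc$perm) == 1:5))
})

test_that("select_rank applies the dual-cutoff rule and is monotone", {
  set.seed(6)
  X1 <- outer(runif(300), runif(26)) # exact rank 1
  sel1 <- select_rank(X1, max_rank = 3, n_restarts = 2, seed = 1)
  expect_equal(sel1$m, 1)
  sel <- select_rank(synth_envelope_matrix(n_sc = 3, seed = 7)$X,
                     max_rank = 7, n_restarts = 2, seed = 7)
  expect_equal(sel$m, 5)
  # lambda profile non-decreasing (warm-started best-of-restarts)
  expect_true(all(diff(sel$lambda_profile) >= -1e-6))
  # no satisfying rank -> max_rank with warning
  expect_warning(
    sel_hi <- select_rank(X1 + matrix(runif(300 * 26), 300, 26) * 2,
                          lambda_cutoff = 99.999, delta_cutoff = 30,
                          max_rank = 2, n_restarts = 1, seed = 1),
    "no rank")
  expect_equal(sel_hi$m, 2)
  expect_false(sel_hi$satisfied)
})

test_that("order_synergies sorts by main-peak timing with weight tie-break", {
  N <- 100
  mk_model <- function(peaks) {
    A <- t(sapply(peaks, function(p) {
      v <- numeric(N)
      v[p] <- 1
      rep(v, 2) # two identical strides
    }))
    W <- diag(3)[, seq_along(peaks), drop = FALSE]
    structure(list(W = W, A = A, m = length(peaks)),
              class = "synergy_model")
  }
  m1 <- order_synergies(mk_model(c(10, 60)), N)
  expect_equal(m1$ordering, 1:2)
  m2 <- order_synergies(mk_model(c(60, 10)), N)
  expect_equal(m2$ordering, 2:1)
  # equal peaks: tie-break by index of the largest muscle weight
  m3 <- mk_model(c(30, 30))
  m3$W <- cbind(c(0, 0, 1), c(0, 1, 0))
  res <- order_synergies(m3, N)
  expect_equal(res$ordering, 2:1)
})
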