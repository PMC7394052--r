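test_that("synergy_layers builds weighted one-mode projections", {
  N <- 100
  # one-hot weight column -> empty layer (self-loops removed)
  A <- matrix(rep(c(numeric(40), rep(1, 20), numeric(40)), 2), 1)
  model <- structure(list(W = matrix(c(1, 0, 0), 3, 1), A = A, m = 1L),
                     class = "synergy_model")
  net <- synergy_layers(model, N)
  expect_true(all(net$layers[[1]] == 0))
  # w = (1,1,0): single edge weighted by the waveform integral
  model2 <- structure(list(W = matrix(c(1, 1, 0), 3, 1), A = A, m = 1L),
                      class = "synergy_model")
  net2 <- synergy_layers(model2, N)
  # two identical strides, each integrated over the 0-100% cycle
  expect_equal(net2$layers[[1]][1, 2],
               2 * trapz_ref(seq(0, 100, length.out = N), A[1, 1:N]))
  # zero waveform -> zero layer
  model3 <- model2
  model3$A <- A * 0
  expect_true(all(synergy_layers(model3, N)$layers[[1]] == 0))
  expect_symmetric_zero_diag(net2$layers[[1]])
})

test_that("coherence_layers places pair weights and averages subjects", {
  pairs <- muscle_pairs()
  n_pairs <- nrow(pairs)
  sc <- data.frame(subject = c("1", "2", "1", "2"),
                   condition = c("2:1", "2:1", "1:1", "1:1"))
  m <- 2
  A_coh <- matrix(runif(m * nrow(sc) * n_pairs), m)
  comps <- structure(list(m = m, A_coh = A_coh), class = "coherence_components")
  net <- coherence_layers(comps, sc)
  expect_length(net$layers, m * 2) # 2 components x 2 conditions
  for (L in net$layers) expect_symmetric_zero_diag(L)
  # single subject -> averaging is the identity
  sc1 <- data.frame(subject = "1", condition = "2:1")
  comps1 <- structure(list(m = 1, A_coh = matrix(runif(n_pairs), 1)),
                      class = "coherence_components")
  net1 <- coherence_layers(comps1, sc1)
  expect_equal(net1$layers[[1]][cbind(pairs[, 1], pairs[, 2])],
               as.numeric(comps1$A_coh))
  expect_error(coherence_layers(comps1, data.frame(subject = "1",
                                                   condition = "2:1")[0, ]),
               "missing")
})

test_that("minimally_connect matches brute force and preserves weak nodes", {
  set.seed(8)
  for (rep in 1:15) {
    layers <- list(random_layer(6), random_layer(6))
    # ensure no fully isolated node
    for (i in 1:6) {
      if (all(layers[[1]][i, ] == 0) && all(layers[[2]][i, ] == 0))
        layers[[1]][i, (i %% 6) + 1] <- layers[[1]][(i %% 6) + 1, i] <- 0.01
    }
    net <- multiplex_network(layers)
    mc <- minimally_connect(net)
    # brute-force oracle over all candidate thresholds (edge values)
    ut <- upper.tri(layers[[1]])
    cand <- sort(unique(c(layers[[1]][ut], layers[[2]][ut])))
    cand <- cand[cand > 0]
    feasible <- vapply(cand, function(tau) {
      keep <- lapply(layers, function(L) L * (L >= tau))
      all(vapply(1:6, function(i) {
        any(vapply(keep, function(L) any(L[i, ] > 0), logical(1)))
      }, logical(1)))
    }, logical(1))
    expect_equal(mc$tau, max(cand[feasible]))
    # every node with any nonzero edge stays connected in some layer
    for (i in 1:6) {
      expect_true(any(vapply(mc$net$layers, function(L) any(L[i, ] > 0),
                             logical(1))))
    }
    # equal edge counts across layers (up to layers short of edges)
    counts <- vapply(mc$net$layers, function(L) sum(L[ut] > 0), numeric(1))
    avail <- vapply(layers, function(L) sum(L[ut] > 0), numeric(1))
    expect_equal(counts, pmin(mc$k, avail))
  }
  # all edges equal weight: tau equals that weight, nothing removed
  eq <- sym_from_ut(rep(0.4, 15), 6)
  mc_eq <- minimally_connect(multiplex_network(list(eq)))
  expect_equal(mc_eq$tau, 0.4)
  expect_equal(mc_eq$removed$n, 0)
})

test_that("communities recover planted structure and scale invariance", {
  # two disconnected 13-node cliques duplicated across layers
  L <- matrix(0, 26, 26)
  L[1:13, 1:13] <- 1
  L[14:26, 14:26] <- 1
  diag(L) <- 0
  net <- multiplex_network(list(L, L))
  p <- communities_multiplex(net, seed = 1)
  expect_equal(compare_partitions(p$membership, rep(1:2, each = 13),
                                  n_perm = 0)$adjusted_rand, 1)
  # single clique -> one community
  K <- matrix(1, 10, 10)
  diag(K) <- 0
  p1 <- communities_multiplex(multiplex_network(list(K)), seed = 1)
  expect_equal(length(unique(p1$membership)), 1)
  # invariant to uniform weight scaling
  p_scaled <- communities_multiplex(multiplex_network(list(L * 7, L * 7)),
                                    seed = 1)
  expect_equal(p$membership, p_scaled$membership)
  expect_error(communities_multiplex(multiplex_network(list(L * 0))),
               "empty")
})

test_that("planted 4-module weighted networks are recovered exactly", {
  truth <- rep(1:4, c(7, 7, 6, 6))
  for (s in 1:10) {
    set.seed(s)
    L <- matrix(0.05 * runif(26 * 26), 26, 26)
    for (g in 1:4) {
      idx <- which(truth == g)
      L[idx, idx] <- 1
    }
    L[lower.tri(L)] <- t(L)[lower.tri(L)]
    diag(L) <- 0
    p <- communities_multiplex(multiplex_network(list(L)), seed = s)
    expect_equal(compare_partitions(p$membership, truth,
                                    n_perm = 0)$adjusted_rand, 1)
  }
})

test_that("layer_metrics matches closed forms", {
  n <- 7
  comp <- matrix(1, n, n)
  diag(comp) <- 0
  m <- layer_metrics(comp)
  expect_equal(m$global_efficiency, 1)
  expect_equal(m$transitivity, 1)
  expect_equal(m$average_strength, n - 1)
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- 1
  star <- star + t(star)
  expect_equal(layer_metrics(star)$transitivity, 0)
  # unit-weight 5-path: hand-computed mean inverse path length
  path5 <- matrix(0, 5, 5)
  for (i in 1:4) path5[i, i + 1] <- 1
  path5 <- path5 + t(path5)
  expect_equal(layer_metrics(path5)$global_efficiency,
               (4 * 1 + 3 / 2 + 2 / 3 + 1 / 4) / 10)
  expect_warning(m0 <- layer_metrics(matrix(0, 4, 4)), "all-zero")
  expect_equal(m0$global_efficiency, 0)
})

test_that("compare_partitions counts pairs correctly", {
  p <- c(1, 1, 2, 2, 3)
  self <- compare_partitions(p, p, n_perm = 99, seed = 1)
  expect_equal(self$rand, 1)
  expect_equal(self$adjusted_rand, 1)
  # brute-force pair enumeration: one community vs all singletons on n = 4
  # agrees on no pair (all "same" vs all "different"), so Rand = 0
  expect_equal(compare_partitions(rep(1, 4), 1:4, n_perm = 0)$rand, 0)
  # random partitions: ARI ~ 0 on average
  set.seed(2)
  aris <- replicate(40, {
    compare_partitions(sample(1:3, 30, TRUE), sample(1:3, 30, TRUE),
                       n_perm = 0)$adjusted_rand
  })
  expect_lt(abs(mean(aris)), 0.05)
  expect_error(compare_partitions(1, 1), "length|>= 2")
})
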