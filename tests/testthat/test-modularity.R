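test_that("null expectation reproduces forced single-edge values", {
  a <- matrix(0, 2, 2); a[1, 2] <- a[2, 1] <- 2
  net1 <- multilayer_network(list(a))
  st <- layerwise_strengths(net1)
  # single intra edge of weight 2: P_uv = 2*2 / (2*2) = 1
  expect_equal(null_expectation(st, 1, 1, 2, 1), 1)

  x <- matrix(0, 2, 2); x[1, 2] <- 0.5
  net2 <- multilayer_network(list(matrix(0, 2, 2), matrix(0, 2, 2)),
                             list("1:2" = x))
  st2 <- layerwise_strengths(net2)
  # single inter edge of weight 0.5: P = 0.5*0.5 / 0.5 = 0.5
  expect_equal(null_expectation(st2, 1, 1, 2, 2), 0.5)
  # empty block has zero expectation
  expect_equal(null_expectation(st2, 1, 1, 1, 2), 0)
})

test_that("null model preserves layer-wise strengths in expectation", {
  for (s in 1:5) {
    net <- random_multilayer_network(3, 8, seed = 20 + s)
    st <- layerwise_strengths(net)
    P <- null_model_matrix(net)
    rows <- layer_rows(net)
    for (h in 1:3) for (k in 1:3) {
      marg <- rowSums(P[rows[[h]], rows[[k]], drop = FALSE])
      expect_lt(max(abs(marg - st$s[rows[[h]], k])), 1e-12)
    }
    expect_equal(P, t(P))
  }
})

test_that("all-in-one partition scores exactly zero at unit resolution", {
  for (s in 1:5) {
    net <- random_multilayer_network(4, 8, seed = 30 + s)
    one <- rep(1L, n_layer_nodes(net))
    for (om in c(0, 0.3, 1, 2.5)) {
      expect_lt(abs(multilayer_modularity(net, one, gamma_r = 1,
                                          omega = om)), 1e-9)
    }
  }
})

test_that("modularity decomposes over layers at omega zero", {
  withr::with_seed(7, {
    for (s in 1:5) {
      net <- random_multilayer_network(3, 7, seed = 40 + s)
      part <- sample(1:3, n_layer_nodes(net), replace = TRUE)
      q <- multilayer_modularity(net, part, gamma_r = 1.02, omega = 0)
      rows <- layer_rows(net)
      q_layers <- sum(vapply(1:3, function(h)
        singlelayer_modularity(net$intra[[h]], part[rows[[h]]],
                               gamma_r = 1.02), 0))
      expect_lt(abs(q - q_layers), 1e-9)
    }
  })
})

test_that("modularity is invariant under label and node permutations", {
  withr::with_seed(11, {
    net <- random_multilayer_network(2, 6, seed = 50)
    part <- sample(1:3, 12, replace = TRUE)
    q <- multilayer_modularity(net, part, 1.01, 0.7)
    relab <- c(3L, 1L, 2L)[part]
    expect_equal(multilayer_modularity(net, relab, 1.01, 0.7), q)

    # permute node order consistently in both layers
    p <- sample(6)
    intra_p <- lapply(net$intra, function(A) A[p, p])
    inter_p <- list("1:2" = net$inter[["1:2"]][p, p])
    net_p <- multilayer_network(intra_p, inter_p)
    part_p <- part[c(p, 6 + p)]
    expect_equal(multilayer_modularity(net_p, part_p, 1.01, 0.7), q)
  })
})

test_that("increasing the resolution parameter strictly decreases quality", {
  net <- random_multilayer_network(2, 6, seed = 60)
  part <- rep(c(1L, 2L), each = 6)   # has within-community pairs, P > 0
  qs <- vapply(c(0.9, 1, 1.1, 1.3), function(g)
    multilayer_modularity(net, part, g, 0.5), 0)
  expect_true(all(diff(qs) < 0))
})

test_that("single-layer modularity matches the hand-computed two-clique value", {
  A <- matrix(0, 6, 6)
  A[1, 2] <- A[1, 3] <- A[2, 3] <- A[4, 5] <- A[4, 6] <- A[5, 6] <- 1
  A <- A + t(A)
  # two disjoint triangles, partition = triangles, gamma 1: per triangle
  # sum(A) = 6 and sum(s_i s_j)/2m = 36/12 = 3, so Q = 2 * (6 - 3) = 6
  expect_equal(singlelayer_modularity(A, rep(1:2, each = 3)), 6)
  expect_equal(singlelayer_modularity(A, rep(1, 6)), 0)
  expect_equal(singlelayer_modularity(matrix(0, 4, 4), rep(1, 4)), 0)
})

test_that("single-layer modularity equals multilayer on a one-layer network", {
  withr::with_seed(3, {
    A <- matrix(0, 7, 7)
    A[upper.tri(A)] <- runif(21)
    A <- A + t(A)
    net <- multilayer_network(list(A))
    part <- sample(1:3, 7, replace = TRUE)
    for (om in c(0, 1, 5)) {
      expect_equal(multilayer_modularity(net, part, 1.05, om),
                   singlelayer_modularity(A, part, 1.05))
    }
  })
})

test_that("planted partition maximizes quality on a toy network", {
  parts6 <- all_partitions(6)
  res <- make_planted_network(planted_network_spec(
    2, 3, 2, mu_in = 1, mu_out = 0.2, noise_sd = 0.05, seed = 77))
  B <- modularity_matrix(res$network, 1, 1)
  q_planted <- sum(B * outer(res$partition, res$partition, "=="))
  expect_equal(q_planted, brute_force_best_q(B, parts6))
  # and beats 50 random partitions
  withr::with_seed(1, {
    for (i in 1:50) {
      g <- sample(1:3, 6, replace = TRUE)
      expect_gte(q_planted, sum(B * outer(g, g, "==")))
    }
  })
})

test_that("partitions are rejected when they do not cover the network", {
  net <- random_multilayer_network(2, 3, seed = 1)
  expect_error(multilayer_modularity(net, rep(1, 5)), "every layer-node")
  expect_error(multilayer_modularity(net, c(rep(1, 5), NA)), "missing")
})

test_that("canonicalization relabels by first appearance", {
  expect_identical(canonicalize_partition(c(7, 7, 2, 9, 2)),
                   c(1L, 1L, 2L, 3L, 2L))
})
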