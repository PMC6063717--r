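test_that("modularity matches closed forms and the literal double sum", {
  # two disconnected unit-weight edges, split by component -> Q = 0.5
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 1
  net <- dynamical_network(w)
  expect_equal(modularity_q(net, c(1, 1, 2, 2)), 0.5, tolerance = 1e-14)
  # everything in one module -> 0
  expect_equal(modularity_q(net, rep(1, 4)), 0, tolerance = 1e-14)
  # random nets, random partitions vs brute-force double sum
  withr::with_seed(19, {
    for (rep in 1:10) {
      rn <- rand_weighted_net(8, density = 0.6)
      labels <- sample(1:3, 8, replace = TRUE)
      expect_equal(
        modularity_q(rn, labels),
        brute_modularity(rn$weights, labels),
        tolerance = 1e-12
      )
    }
  })
  expect_error(
    modularity_q(dynamical_network(matrix(0, 3, 3)), c(1, 1, 2)),
    "zero total weight"
  )
})

test_that("modularity agrees with igraph's implementation", {
  withr::with_seed(20, {
    for (rep in 1:5) {
      net <- rand_weighted_net(10, density = 0.5)
      labels <- sample(1:3, 10, replace = TRUE)
      g <- igraph::graph_from_adjacency_matrix(
        net$weights,
        mode = "undirected", weighted = TRUE, diag = FALSE
      )
      expect_equal(
        modularity_q(net, labels),
        igraph::modularity(g, labels, weights = igraph::E(g)$weight),
        tolerance = 1e-12
      )
    }
  })
})

test_that("partition label inputs are flexible", {
  net <- triangle_net()
  df <- data.frame(neuron_id = c("c", "a", "b"), module = c(2, 1, 1))
  q_df <- modularity_q(net, df)
  q_vec <- modularity_q(net, c(1, 1, 2))
  named <- c(b = 1, c = 2, a = 1)
  expect_equal(q_df, q_vec, tolerance = 1e-14)
  expect_equal(modularity_q(net, named), q_vec, tolerance = 1e-14)
  expect_error(modularity_q(net, c(1, 2)), "every neuron")
})

test_that("unambiguous structure is found identically on every run", {
  net <- two_cliques_net(4)
  p <- detect_modules(net, n_runs = 10, seed = 2)
  expect_equal(attr(p, "n_modules"), 2L)
  expect_equal(attr(p, "iterations"), 1L) # consensus of agreement
  expect_equal(p$module[1:4], rep(p$module[1], 4))
  expect_equal(p$module[5:8], rep(p$module[5], 4))
  expect_equal(
    attr(p, "q"), modularity_q(net, p$module),
    tolerance = 1e-14
  )
})

test_that("detection is deterministic per seed and label-permutation invariant", {
  withr::with_seed(33, net <- rand_weighted_net(15, density = 0.4))
  p1 <- detect_modules(net, n_runs = 20, seed = 5)
  p2 <- detect_modules(net, n_runs = 20, seed = 5)
  expect_identical(p1$module, p2$module)

  # permuting neurons permutes the partition (ARI 1) on unambiguous nets
  net2 <- two_cliques_net(4)
  perm <- c(3, 7, 1, 5, 8, 2, 6, 4)
  permuted <- dynamical_network(
    net2$weights[perm, perm], net2$neuron_ids[perm]
  )
  pa <- detect_modules(net2, n_runs = 10, seed = 6)
  pb <- detect_modules(permuted, n_runs = 10, seed = 6)
  expect_equal(
    adjusted_rand_index(pa$module[perm], pb$module), 1
  )
})

test_that("zero-strength neurons become singleton modules", {
  w <- matrix(0, 5, 5)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 1
  net <- dynamical_network(w)
  p <- detect_modules(net, n_runs = 5, seed = 3)
  expect_equal(attr(p, "n_modules"), 3L)
  expect_equal(sum(p$module == p$module[5]), 1L)
  expect_error(
    detect_modules(dynamical_network(matrix(0, 3, 3))), "link"
  )
})

test_that("planted ensembles are recovered from spike trains", {
  hits <- vapply(1:3, function(s) {
    out <- small_planted_session(seed = 40 + s)
    net <- build_networks(out$session, sigma = 0.05)[[1]]
    p <- detect_modules(net, n_runs = 30, seed = s)
    truth <- out$truth$ensemble[match(p$neuron_id, out$truth$neuron_id)]
    adjusted_rand_index(p$module, truth)
  }, numeric(1))
  expect_true(all(hits >= 0.9))
})

test_that("adjusted Rand index behaves canonically", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)
  expect_equal(adjusted_rand_index(rep(1, 6), rep(1, 6)), 1)
  withr::with_seed(50, {
    a <- sample(1:3, 300, replace = TRUE)
    b <- sample(1:3, 300, replace = TRUE)
  })
  expect_lt(abs(adjusted_rand_index(a, b)), 0.1) # independent -> ~0
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("raster order groups by module then descending strength", {
  net <- two_cliques_net(3)
  w <- net$weights
  w[1, 2] <- w[2, 1] <- 0.5 # weaken node 1 within its clique
  net <- dynamical_network(w, net$neuron_ids)
  p <- detect_modules(net, n_runs = 5, seed = 1)
  ord <- raster_order(p, net)
  labels <- p$module[match(ord, p$neuron_id)]
  expect_true(!is.unsorted(labels)) # contiguous modules
  strengths <- degree_strength(net)$strength
  first_block <- ord[labels == labels[1]]
  s_block <- strengths[match(first_block, net$neuron_ids)]
  expect_true(all(diff(s_block) <= 0))
})
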