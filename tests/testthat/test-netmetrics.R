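test_that("degree, strength and link weights match direct counts", {
  tri <- triangle_net(0.5, 0.5, 0.5)
  ds <- degree_strength(tri)
  expect_equal(ds$degree, c(2L, 2L, 2L))
  expect_equal(ds$strength, c(1, 1, 1))
  expect_equal(sort(link_weights(tri)), c(0.5, 0.5, 0.5))

  empty <- dynamical_network(matrix(0, 4, 4))
  ds0 <- degree_strength(empty)
  expect_true(all(ds0$degree == 0) && all(ds0$strength == 0))
  expect_length(link_weights(empty), 0L)

  # random net vs brute-force recount from the edge list
  withr::with_seed(31, net <- rand_weighted_net(6))
  edges <- tidy(net)
  for (i in seq_len(6)) {
    id <- net$neuron_ids[i]
    touching <- edges[edges$node_a == id | edges$node_b == id, ]
    ds <- degree_strength(net)
    expect_equal(ds$degree[i], nrow(touching))
    expect_equal(ds$strength[i], sum(touching$weight))
  }
})

test_that("weighted clustering matches hand values on small fixtures", {
  expect_equal(unname(weighted_clustering(triangle_net())), c(1, 1, 1))
  expect_equal(unname(weighted_clustering(path_net_3()))[2], 0)
  # weighted triangle, scaled weights (1, 0.5, 0.5): ordered triangles/triples
  tri <- triangle_net(1, 0.5, 0.5)
  cc <- unname(weighted_clustering(tri))
  expect_equal(cc[1], 2 * (1 * 0.5 * 0.5) / ((1.5)^2 - 1.25), tolerance = 1e-14)
  # degree < 2 -> 0; all in [0,1]
  expect_true(all(cc >= 0 & cc <= 1))
})

test_that("weighted clustering reduces to binary clustering on binary nets", {
  withr::with_seed(17, {
    for (rep in 1:20) {
      n <- sample(4:12, 1)
      net <- rand_binary_net(n, density = runif(1, 0.2, 0.8))
      expect_equal(
        unname(weighted_clustering(net)),
        brute_binary_clustering(net$weights),
        tolerance = 1e-12
      )
    }
  })
})

test_that("clustering is invariant to weight scaling; efficiency to relabeling", {
  withr::with_seed(23, net <- rand_weighted_net(9))
  scaled <- dynamical_network(net$weights * 7.3, net$neuron_ids)
  expect_equal(
    weighted_clustering(scaled), weighted_clustering(net),
    tolerance = 1e-12
  )
  perm <- sample(9)
  permuted <- dynamical_network(
    net$weights[perm, perm], net$neuron_ids[perm]
  )
  expect_equal(global_efficiency(permuted), global_efficiency(net),
    tolerance = 1e-12
  )
  expect_equal(
    sort(unname(weighted_clustering(permuted))),
    sort(unname(weighted_clustering(net))),
    tolerance = 1e-12
  )
})

test_that("global efficiency matches closed forms", {
  # two disconnected unit edges: 4 of 12 ordered pairs at distance 1
  expect_equal(global_efficiency(two_cliques_net(2)), 1 / 3, tolerance = 1e-12)
  complete4 <- dynamical_network(matrix(1, 4, 4) - diag(4))
  expect_equal(global_efficiency(complete4), 1, tolerance = 1e-12)
  expect_equal(global_efficiency(dynamical_network(matrix(0, 2, 2))), 0)
  expect_equal(global_efficiency(path_net_3()), (1 + 1 + 0.5) / 3,
    tolerance = 1e-12
  )
})

test_that("efficiency fingerprint matches hand-computed star deltas", {
  star <- star_net(3)
  expect_equal(global_efficiency(star), 0.75, tolerance = 1e-12)
  fp <- efficiency_fingerprint(star)
  expect_equal(fp$delta_eff[1], 0.75, tolerance = 1e-12) # hub removal
  expect_equal(fp$delta_eff[2], 0.75 - 5 / 6, tolerance = 1e-12) # leaf removal
  complete5 <- dynamical_network(matrix(1, 5, 5) - diag(5))
  expect_equal(
    efficiency_fingerprint(complete5)$delta_eff, rep(0, 5),
    tolerance = 1e-12
  )
  expect_error(efficiency_fingerprint(dynamical_network(matrix(0, 2, 2))), "3")
})

test_that("summarise_network agrees with its constituent metrics", {
  withr::with_seed(41, net <- rand_weighted_net(8))
  m <- summarise_network(net)
  nodes <- tidy(m)
  expect_equal(nodes$degree, degree_strength(net)$degree)
  expect_equal(nodes$clustering, unname(weighted_clustering(net)))
  expect_equal(nodes$delta_eff, efficiency_fingerprint(net)$delta_eff)
  g <- glance(m)
  expect_equal(g$global_efficiency, global_efficiency(net))
  expect_equal(g$mean_clustering, mean(nodes$clustering))
  expect_equal(g$total_weight, sum(link_weights(net)))

  m0 <- summarise_network(dynamical_network(matrix(0, 3, 3)))
  expect_equal(glance(m0)$total_weight, 0)
  expect_equal(glance(m0)$global_efficiency, 0)
})

test_that("autoplot methods return ggplot objects", {
  withr::with_seed(4, net <- rand_weighted_net(6))
  expect_s3_class(autoplot(net), "ggplot")
  expect_s3_class(autoplot(summarise_network(net)), "ggplot")
})
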