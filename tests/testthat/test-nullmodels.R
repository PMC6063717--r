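test_that("weight_shuffle conserves topology, weights and degrees exactly", {
  withr::with_seed(5, net <- rand_weighted_net(12))
  ns <- sample_null(net, "weight_shuffle", n_samples = 10, seed = 3)
  src_pos <- net$weights > 0
  for (s in ns$nets) {
    expect_identical(s$weights > 0, src_pos) # identical topology
    expect_equal(sum(s$weights), sum(net$weights), tolerance = 1e-12)
    expect_equal(
      sort(upper_vals(s$weights)), sort(upper_vals(net$weights))
    ) # identical weight multiset
    expect_identical(s$weights, t(s$weights))
    expect_equal(diag(s$weights), rep(0, 12))
  }
})

test_that("weight_shuffle of an equal-weight net returns the net itself", {
  net <- two_cliques_net(3)
  ns <- sample_null(net, "weight_shuffle", n_samples = 3, seed = 1)
  for (s in ns$nets) expect_identical(s$weights, net$weights)
})

test_that("degree_rewire_binary conserves the degree sequence", {
  withr::with_seed(6, net <- rand_binary_net(6, density = 0.5))
  ns <- sample_null(net, "degree_rewire_binary", n_samples = 5, seed = 2)
  for (s in ns$nets) {
    expect_equal(rowSums(s$weights > 0), rowSums(net$weights > 0))
    expect_true(all(diag(s$weights) == 0))
  }
})

test_that("erdos_renyi_binary conserves the link count", {
  withr::with_seed(8, net <- rand_weighted_net(10))
  m <- length(link_weights(net))
  ns <- sample_null(net, "erdos_renyi_binary", n_samples = 5, seed = 4)
  for (s in ns$nets) {
    expect_equal(length(link_weights(s)), m)
    expect_true(all(s$weights %in% c(0, 1)))
  }
})

test_that("strength_rank tracks source strengths more closely than a shuffle", {
  withr::with_seed(9, net <- rand_weighted_net(50, density = 0.3))
  s_src <- degree_strength(net)$strength
  mean_strength_cor <- function(model) {
    ns <- sample_null(net, model, n_samples = 20, seed = 7)
    mean(vapply(ns$nets, function(x) {
      cor(s_src, degree_strength(x)$strength)
    }, numeric(1)))
  }
  c_shuffle <- mean_strength_cor("weight_shuffle")
  c_rank <- mean_strength_cor("strength_rank")
  expect_gt(c_shuffle, 0) # strengths conserved in expectation
  expect_gte(c_rank, c_shuffle)
  # strength_rank still conserves topology and the weight multiset
  ns <- sample_null(net, "strength_rank", n_samples = 3, seed = 8)
  for (s in ns$nets) {
    expect_identical(s$weights > 0, net$weights > 0)
    expect_equal(
      sort(upper_vals(s$weights)), sort(upper_vals(net$weights)),
      tolerance = 1e-12
    )
  }
})

test_that("null sampling is reproducible per seed and varies across seeds", {
  withr::with_seed(10, net <- rand_weighted_net(10))
  a <- sample_null(net, "weight_shuffle", n_samples = 4, seed = 11)
  b <- sample_null(net, "weight_shuffle", n_samples = 4, seed = 11)
  d <- sample_null(net, "weight_shuffle", n_samples = 4, seed = 12)
  for (i in 1:4) expect_identical(a$nets[[i]]$weights, b$nets[[i]]$weights)
  expect_false(all(vapply(
    1:4, function(i) identical(a$nets[[i]]$weights, d$nets[[i]]$weights),
    logical(1)
  )))
})

test_that("null model errors are informative", {
  tiny <- dynamical_network(matrix(c(0, 1, 1, 0), 2, 2))
  expect_error(
    sample_null(tiny, "degree_rewire_binary", 2, seed = 1), "2 links"
  )
  expect_error(sample_null(tiny, "weight_shuffle", 0, seed = 1), "n_samples")
})

test_that("null metric distributions summarise correctly", {
  withr::with_seed(13, net <- rand_weighted_net(10))
  ns <- sample_null(net, "weight_shuffle", n_samples = 5, seed = 2)
  nd_const <- null_metric_distribution(ns, function(x) length(x$neuron_ids))
  expect_equal(nd_const$sd, 0)
  ns1 <- sample_null(net, "weight_shuffle", n_samples = 1, seed = 2)
  nd1 <- null_metric_distribution(ns1, global_efficiency)
  expect_equal(nd1$mean, global_efficiency(ns1$nets[[1]]))
  expect_equal(nrow(tidy(nd_const)), 5L)
})

test_that("planted-ensemble clustering exceeds the weight_shuffle null", {
  out <- small_planted_session(seed = 3)
  net <- build_networks(out$session, sigma = 0.05)[[1]]
  nd <- null_metric_distribution(
    sample_null(net, "weight_shuffle", 20, seed = 5),
    function(x) mean(weighted_clustering(x))
  )
  c_data <- mean(weighted_clustering(net))
  expect_gt(c_data, nd$mean)
  expect_gt(excess_ratio(c_data, nd$mean), 100)
})

test_that("excess_ratio handles equality, arithmetic and zero nulls", {
  expect_identical(excess_ratio(0.37, 0.37), 100)
  expect_equal(excess_ratio(0.3, 0.2), 150)
  expect_warning(out <- excess_ratio(0.3, 0), "zero")
  expect_true(is.na(out))
})
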