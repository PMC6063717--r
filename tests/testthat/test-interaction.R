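make_trains <- function(times_by_neuron, window, trial = NULL) {
  df <- tibble::tibble(
    neuron_id = rep(names(times_by_neuron), lengths(times_by_neuron)),
    time = unlist(times_by_neuron, use.names = FALSE) %||% numeric()
  )
  spike_trains(df,
    neuron_ids = names(times_by_neuron), window = window,
    trial_id = trial
  )
}

test_that("Gaussian convolution reproduces the unit-area kernel", {
  st <- make_trains(list(a = 1, b = numeric()), window = c(0, 2))
  ca <- convolve_trains(st, sigma = 0.25, dt = 0.01)
  # empty train -> all-zero series
  expect_true(all(ca$values[2, ] == 0))
  # peak of a single spike ~ density at zero offset, 1/(sigma*sqrt(2*pi))
  expect_equal(max(ca$values[1, ]), dnorm(0, sd = 0.25), tolerance = 1e-3)
  expect_equal(ncol(ca$values), floor(2 / 0.01))
  expect_true(all(ca$values >= 0))

  # two coincident spikes double the series exactly
  st2 <- make_trains(list(a = c(1, 1)), window = c(0, 2))
  ca2 <- convolve_trains(st2, sigma = 0.25, dt = 0.01)
  expect_equal(ca2$values[1, ], 2 * ca$values[1, ])
})

test_that("convolution is linear in the spike train", {
  withr::with_seed(7, {
    t_a <- sort(runif(15, 0, 10))
    t_b <- sort(runif(9, 0, 10))
  })
  win <- c(0, 10)
  v_a <- convolve_trains(
    make_trains(list(x = t_a), win), 0.2, 0.02
  )$values
  v_b <- convolve_trains(
    make_trains(list(x = t_b), win), 0.2, 0.02
  )$values
  v_ab <- convolve_trains(
    make_trains(list(x = sort(c(t_a, t_b))), win), 0.2, 0.02
  )$values
  expect_equal(v_ab, v_a + v_b, tolerance = 1e-12)
})

test_that("convolution guards its preconditions", {
  st <- make_trains(list(a = 0.5), window = c(0, 1))
  expect_error(convolve_trains(st, sigma = -1), "sigma")
  expect_warning(convolve_trains(st, 0.01, dt = 0.5), "undersampled")
  st0 <- make_trains(list(a = numeric()), window = c(0, 0))
  expect_error(convolve_trains(st0, 0.1), "empty")
})

fake_activity <- function(values, ids = NULL) {
  structure(
    list(
      values = values, times = seq_len(ncol(values)), dt = 1, sigma = 1,
      window = c(0, ncol(values)),
      neuron_ids = ids %||% paste0("n", seq_len(nrow(values)))
    ),
    class = "convolved_activity"
  )
}

test_that("rectified Pearson weights match hand computations", {
  # identical nonconstant series -> weight 1
  v <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(pairwise_weights(fake_activity(v))$weights[1, 2], 1)
  # anticorrelated series -> rectified to 0
  v <- rbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(pairwise_weights(fake_activity(v))$weights[1, 2], 0)
  # orthogonal-in-covariance series -> exactly 0
  v <- rbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_equal(pairwise_weights(fake_activity(v))$weights[1, 2], 0)
  # constant series -> zero weights, never NaN, node kept
  v <- rbind(c(1, 1, 1), c(0, 1, 2), c(2, 1, 0))
  net <- pairwise_weights(fake_activity(v))
  expect_false(anyNA(net$weights))
  expect_equal(net$weights[1, ], c(0, 0, 0))
  expect_error(
    pairwise_weights(fake_activity(matrix(1, 2, 1))), "samples"
  )
  expect_error(
    pairwise_weights(fake_activity(matrix(1, 1, 5))), "neurons"
  )
})

test_that("cosine weights are nonnegative and unit on identical series", {
  v <- rbind(c(1, 0, 2), c(2, 0, 4), c(0, 3, 0))
  net <- pairwise_weights(fake_activity(v), "cosine")
  expect_equal(net$weights[1, 2], 1)
  expect_equal(net$weights[1, 3], 0)
  expect_true(all(net$weights >= 0 & net$weights <= 1))
})

test_that("weight matrices are exactly symmetric with zero diagonal", {
  withr::with_seed(11, v <- matrix(rexp(8 * 50), nrow = 8))
  net <- pairwise_weights(fake_activity(v))
  expect_identical(net$weights, t(net$weights))
  expect_identical(diag(net$weights), rep(0, 8))
})

test_that("pairwise weights are permutation-equivariant and affine-invariant", {
  withr::with_seed(3, v <- matrix(rexp(6 * 40), nrow = 6))
  w <- pairwise_weights(fake_activity(v))$weights
  perm <- c(4, 1, 6, 2, 5, 3)
  w_perm <- pairwise_weights(fake_activity(v[perm, ]))$weights
  expect_equal(w_perm, w[perm, perm], tolerance = 1e-12)
  # positive-gain affine rescaling leaves rectified Pearson untouched
  gains <- c(0.5, 2, 7, 1, 3, 10)
  offs <- c(1, 0, 4, 2, 5, 3)
  w_aff <- pairwise_weights(fake_activity(v * gains + offs))$weights
  expect_equal(w_aff, w, tolerance = 1e-10)
})

test_that("build_networks is deterministic and keeps trials aligned", {
  out <- small_planted_session(seed = 21, n_neurons = 12, n_trials = 3,
    duration_s = 10)
  ser <- build_networks(out$session, sigma = 0.1)
  expect_s3_class(ser, "trial_series")
  expect_length(ser, 3L)
  for (net in ser) expect_equal(net$neuron_ids, neuron_ids(out$session))

  # a duplicated trial gives an identical matrix
  dup <- recording_session(list(out$session[[1]], out$session[[1]]))
  ser2 <- build_networks(dup, sigma = 0.1)
  expect_identical(ser2[[1]]$weights, ser2[[2]]$weights)
})

test_that("planted ensembles show higher within- than between-ensemble weight", {
  out <- small_planted_session(seed = 9)
  net <- build_networks(out$session, sigma = 0.05)[[1]]
  labs <- out$truth$ensemble[match(net$neuron_ids, out$truth$neuron_id)]
  same <- outer(labs, labs, "==") & upper.tri(net$weights)
  diff <- outer(labs, labs, "!=") & upper.tri(net$weights)
  expect_gt(mean(net$weights[same]), mean(net$weights[diff]))
})

test_that("median ISI pools intervals across neurons", {
  st <- make_trains(list(a = c(0, 1, 2, 3)), window = c(0, 3))
  expect_equal(median_isi_sigma(st), 1)
  st2 <- make_trains(
    list(a = c(0, 0.1, 0.3), b = c(0, 0.9)),
    window = c(0, 1)
  )
  expect_equal(median_isi_sigma(st2), 0.2) # pooled ISIs {0.1, 0.2, 0.9}
  st3 <- make_trains(list(a = 0.5), window = c(0, 1))
  expect_error(median_isi_sigma(st3), "interspike")
})

test_that("median ISI of a Poisson train approaches ln(2)/rate", {
  lambda <- 5
  withr::with_seed(100, {
    ts <- cumsum(rexp(20000, rate = lambda))
  })
  st <- make_trains(list(a = ts), window = c(0, max(ts)))
  expect_equal(median_isi_sigma(st), log(2) / lambda, tolerance = 0.05)
})
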