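# Null models for weighted networks. The workhorse is weight_shuffle, which
# keeps the topology and the multiset of weights but permutes which link gets
# which weight; strength_rank additionally rank-matches large weights to node
# pairs with large strength products (a closer approximation to a
# strength-conserving null, which a pure permutation cannot achieve exactly).

null_models <- c(
  "weight_shuffle", "strength_rank",
  "erdos_renyi_binary", "degree_rewire_binary"
)

sample_one_null <- function(w, model) {
  n <- nrow(w)
  ut <- upper.tri(w)
  pos <- which(ut & w > 0)
  m <- length(pos)
  out <- matrix(0, n, n)
  if (model == "weight_shuffle") {
    out[pos] <- sample(w[pos])
  } else if (model == "strength_rank") {
    # Rubinov & Sporns style rank matching: visit link slots in random
    # order; each visited slot receives the remaining weight whose rank
    # (descending) equals the slot's rank by source strength product.
    s <- rowSums(w)
    idx <- arrayInd(pos, dim(w))
    expected <- s[idx[, 1]] * s[idx[, 2]]
    weights_left <- sort(w[pos], decreasing = TRUE)
    assign_order <- sample.int(m)
    vals <- numeric(m)
    remaining <- rep(TRUE, m)
    for (f in assign_order) {
      r <- sum(expected[remaining] > expected[f]) + 1L
      vals[f] <- weights_left[r]
      weights_left <- weights_left[-r]
      remaining[f] <- FALSE
    }
    out[pos] <- vals
  } else if (model == "erdos_renyi_binary") {
    slots <- which(ut)
    out[sample(slots, m)] <- 1
  } else if (model == "degree_rewire_binary") {
    b <- (w > 0) * 1
    edges <- which(upper.tri(b) & b > 0, arr.ind = TRUE)
    m_e <- nrow(edges)
    if (m_e < 2) {
      stop_dynet("degree_rewire_binary needs at least 2 links.")
    }
    adj <- b
    n_swaps <- 10L * m_e
    attempts <- 0L
    done <- 0L
    while (done < n_swaps && attempts < 100L * n_swaps) {
      attempts <- attempts + 1L
      pick <- sample.int(m_e, 2)
      e1 <- edges[pick[1], ]
      e2 <- edges[pick[2], ]
      # swap (a-b),(c-d) -> (a-d),(c-b)
      i1 <- e1[1]; j1 <- e2[2]; i2 <- e2[1]; j2 <- e1[2]
      if (length(unique(c(e1[1], e1[2], e2[1], e2[2]))) < 4) next
      if (adj[i1, j1] > 0 || adj[i2, j2] > 0) next
      adj[e1[1], e1[2]] <- 0; adj[e1[2], e1[1]] <- 0
      adj[e2[1], e2[2]] <- 0; adj[e2[2], e2[1]] <- 0
      adj[i1, j1] <- 1; adj[j1, i1] <- 1
      adj[i2, j2] <- 1; adj[j2, i2] <- 1
      edges[pick[1], ] <- sort(c(i1, j1))
      edges[pick[2], ] <- sort(c(i2, j2))
      done <- done + 1L
    }
    return(adj)
  }
  out + t(out)
}

#' Sample randomized networks from a null model
#'
#' Draws `n_samples` random networks against which features of a data-derived
#' dynamical network can be tested:
#' \describe{
#'   \item{`weight_shuffle`}{permutes the multiset of existing link weights
#'     uniformly over the existing link positions, conserving topology, the
#'     degree sequence, the weight multiset and total weight exactly, and
#'     node strength in expectation.}
#'   \item{`strength_rank`}{same positions and weight multiset, but larger
#'     weights are preferentially reassigned to node pairs with larger
#'     strength products (randomised rank matching), approximating a
#'     strength-conserving null more closely than a uniform shuffle.}
#'   \item{`erdos_renyi_binary`}{binary network with the same link count,
#'     links placed uniformly at random.}
#'   \item{`degree_rewire_binary`}{binarizes the network and applies
#'     `10 x links` double-edge swaps, conserving the degree sequence.}
#' }
#' Identical seeds reproduce identical samples; each sample draws from its
#' own substream derived from `seed`, so samples are reproducible
#' independently of evaluation order.
#'
#' @param net A [dynamical_network()].
#' @param model Null model name (see above).
#' @param n_samples Number of samples (default 20).
#' @param seed Master seed (integer below 2^31); drawn at random if `NULL`.
#' @return A `null_sample` object: list with `nets` (list of
#'   [dynamical_network()]), `model`, `n_samples`, `seed`.
#' @export
sample_null <- function(net, model = null_models, n_samples = 20,
                        seed = NULL) {
  stopifnot(inherits(net, "dynamical_network"))
  model <- match.arg(model)
  if (!is_scalar_number(n_samples) || n_samples < 1) {
    stop_dynet("`n_samples` must be >= 1.")
  }
  n_samples <- as.integer(n_samples)
  seed <- as.integer(seed %||% random_seed())
  w <- net$weights
  m <- sum(upper_tri_values(w) > 0)
  if (model %in% c("degree_rewire_binary") && m < 2) {
    stop_dynet("degree_rewire_binary needs at least 2 links.")
  }
  nets <- lapply(seq_len(n_samples), function(i) {
    wi <- with_seed(
      derive_seed(seed, paste0(model, ":", i)),
      sample_one_null(w, model)
    )
    dynamical_network(
      wi, net$neuron_ids,
      measure = paste0("null:", model),
      sigma = net$meta$sigma, dt = net$meta$dt, trial_id = net$meta$trial_id
    )
  })
  structure(
    list(nets = nets, model = model, n_samples = n_samples, seed = seed),
    class = "null_sample"
  )
}

#' @export
print.null_sample <- function(x, ...) {
  cat(sprintf(
    "<null_sample: %d samples from %s (seed %d)>\n",
    x$n_samples, x$model, x$seed
  ))
  invisible(x)
}

#' Distribution of a network metric over a null sample
#'
#' Evaluates a scalar network metric on every sampled network and summarises
#' the null distribution.
#'
#' @param ns A `null_sample` from [sample_null()].
#' @param metric A function taking a [dynamical_network()] and returning one
#'   number, e.g. `function(net) mean(weighted_clustering(net))` or
#'   [global_efficiency()].
#' @return A `null_distribution` object: list with `values` (per-sample),
#'   `mean`, `sd`, `model`. `tidy()` gives a (`sample`, `value`) tibble;
#'   `glance()` the summary row.
#' @export
null_metric_distribution <- function(ns, metric) {
  stopifnot(inherits(ns, "null_sample"), is.function(metric))
  values <- vapply(ns$nets, function(net) as.numeric(metric(net)), numeric(1))
  structure(
    list(
      values = values,
      mean = mean(values),
      sd = if (length(values) > 1) stats::sd(values) else 0,
      model = ns$model
    ),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution (%s): n = %d, mean = %.5g, sd = %.3g>\n",
    x$model, length(x$values), x$mean, x$sd
  ))
  invisible(x)
}

#' @describeIn null_metric_distribution Per-sample values as a tibble.
#' @param x,... Tidier arguments.
#' @method tidy null_distribution
#' @export
tidy.null_distribution <- function(x, ...) {
  tibble(sample = seq_along(x$values), value = x$values)
}

#' @describeIn null_metric_distribution Summary row (n, mean, sd, model).
#' @method glance null_distribution
#' @export
glance.null_distribution <- function(x, ...) {
  tibble(
    n = length(x$values), mean = x$mean, sd = x$sd, model = x$model
  )
}

#' Excess of a data metric over its null expectation
#'
#' Expresses a data value as a percentage of the null-model mean,
#' `100 * data / null`: 100 means the data equal the null expectation, 150
#' means a 50% excess. Vectorised; a zero null mean gives `NA` with a
#' warning, since the ratio is undefined.
#'
#' @param data_value Observed metric value(s).
#' @param null_mean Null-model mean(s), typically from
#'   [null_metric_distribution()].
#' @return Percentage value(s).
#' @export
excess_ratio <- function(data_value, null_mean) {
  out <- 100 * data_value / null_mean
  bad <- !is.na(null_mean) & null_mean == 0
  if (any(bad)) {
    warn("`null_mean` is zero; excess ratio undefined, returning NA.")
    out[bad] <- NA_real_
  }
  out
}
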