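# Neural ensembles as modules of the dynamical network: weighted modularity,
# a Louvain-style base optimizer with node-swap refinement, and consensus
# clustering over repeated randomized runs.

labels_from_input <- function(labels, ids) {
  if (inherits(labels, "ensemble_partition") || is.data.frame(labels)) {
    df <- as_tibble(labels)
    if (!all(c("neuron_id", "module") %in% names(df))) {
      stop_dynet("Partition data frames need columns `neuron_id`, `module`.")
    }
    idx <- match(ids, as.character(df$neuron_id))
    if (anyNA(idx)) {
      stop_dynet("Partition is missing some roster neurons.")
    }
    return(as.integer(factor(df$module[idx])))
  }
  if (!is.null(names(labels)) && all(ids %in% names(labels))) {
    labels <- labels[ids]
  }
  if (length(labels) != length(ids)) {
    stop_dynet("`labels` must cover every neuron exactly once.")
  }
  as.integer(factor(labels))
}

# Relabel to consecutive integers 1..k by first occurrence.
canonical_labels <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

#' Weighted modularity of a partition
#'
#' Newman-Girvan modularity generalised to weighted networks: the fraction
#' of link weight falling within modules minus the fraction expected under a
#' strength-preserving random model,
#' `Q = (1/2m) * sum_ij (w_ij - s_i s_j / 2m) * delta(c_i, c_j)`,
#' with `m` the total link weight and `s` the node strengths. Q is 0 for the
#' trivial one-module partition and approaches 1 for strongly modular
#' networks.
#'
#' @param net A [dynamical_network()] with positive total weight.
#' @param labels Module labels: a vector in roster order (or named by
#'   neuron), or a partition data frame (`neuron_id`, `module`).
#' @return Modularity Q, a number in \[-1, 1\].
#' @export
modularity_q <- function(net, labels) {
  stopifnot(inherits(net, "dynamical_network"))
  w <- net$weights
  two_m <- sum(w)
  if (two_m <= 0) {
    stop_dynet("Modularity is undefined for a network with zero total weight.")
  }
  labels <- labels_from_input(labels, net$neuron_ids)
  s <- rowSums(w)
  q <- 0
  for (c in unique(labels)) {
    members <- labels == c
    q <- q + sum(w[members, members]) / two_m - (sum(s[members]) / two_m)^2
  }
  q
}

# Modularity from a raw weight matrix (internal fast path).
q_of <- function(w, labels) {
  two_m <- sum(w)
  s <- rowSums(w)
  q <- 0
  for (c in unique(labels)) {
    members <- labels == c
    q <- q + sum(w[members, members]) / two_m - (sum(s[members]) / two_m)^2
  }
  q
}

# Node-swap refinement: greedily move single nodes to the neighbouring
# community with the largest positive modularity gain until no move helps.
refine_partition <- function(w, labels, max_passes = 50) {
  n <- nrow(w)
  if (n < 2 || sum(w) == 0) {
    return(canonical_labels(labels))
  }
  two_m <- sum(w)
  s <- rowSums(w)
  labels <- canonical_labels(labels)
  comm_strength <- tapply(s, labels, sum)
  for (pass in seq_len(max_passes)) {
    moved <- FALSE
    for (i in sample.int(n)) {
      a <- labels[i]
      k_i <- tapply(w[i, ], labels, sum) # weight from i into each community
      cands <- as.integer(names(k_i)[k_i > 0])
      cands <- setdiff(cands, a)
      if (length(cands) == 0) next
      k_ia <- if (as.character(a) %in% names(k_i)) k_i[[as.character(a)]] else 0
      s_a <- comm_strength[[as.character(a)]]
      gains <- vapply(cands, function(b) {
        s_b <- comm_strength[[as.character(b)]]
        (k_i[[as.character(b)]] - k_ia) / (two_m / 2) -
          s[i] * (s_b - s_a + s[i]) / (2 * (two_m / 2)^2)
      }, numeric(1))
      best <- which.max(gains)
      if (gains[best] > 1e-12) {
        b <- cands[best]
        comm_strength[[as.character(a)]] <- s_a - s[i]
        comm_strength[[as.character(b)]] <-
          comm_strength[[as.character(b)]] + s[i]
        labels[i] <- b
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  canonical_labels(labels)
}

# One randomized base run: greedy agglomerative (Louvain) moves on the
# weighted graph, then node-swap refinement. Randomness comes from the
# caller's RNG state (igraph draws vertex orderings from R's stream).
base_partition <- function(w) {
  g <- igraph::graph_from_adjacency_matrix(
    w,
    mode = "undirected", weighted = TRUE, diag = FALSE
  )
  ew <- igraph::E(g)$weight
  labels <- if (length(ew) == 0) {
    seq_len(nrow(w))
  } else {
    as.integer(igraph::membership(igraph::cluster_louvain(g, weights = ew)))
  }
  refine_partition(w, labels)
}

# Mean pairwise co-assignment expected if each run's labels were permuted
# across nodes (preserving module sizes): sum_c n_c (n_c - 1) / (n (n - 1)).
permutation_null_coassignment <- function(label_matrix) {
  n <- ncol(label_matrix)
  if (n < 2) {
    return(0)
  }
  per_run <- apply(label_matrix, 1, function(lab) {
    sizes <- table(lab)
    sum(sizes * (sizes - 1)) / (n * (n - 1))
  })
  mean(per_run)
}

coassignment_matrix <- function(label_matrix) {
  n <- ncol(label_matrix)
  p <- matrix(0, n, n)
  for (r in seq_len(nrow(label_matrix))) {
    same <- outer(label_matrix[r, ], label_matrix[r, ], "==")
    p <- p + same
  }
  p / nrow(label_matrix)
}

new_ensemble_partition <- function(neuron_id, module, q,
                                   seed = NA_integer_, n_runs = NA_integer_,
                                   iterations = NA_integer_) {
  structure(
    tibble(neuron_id = as.character(neuron_id), module = as.integer(module)),
    q = q,
    n_modules = length(unique(module)),
    seed = seed,
    n_runs = n_runs,
    iterations = iterations,
    class = c("ensemble_partition", class(tibble()))
  )
}

#' @export
print.ensemble_partition <- function(x, ...) {
  cat(sprintf(
    "<ensemble_partition: %d neurons in %d modules, Q = %s>\n",
    nrow(x), attr(x, "n_modules"),
    if (is.na(attr(x, "q"))) "NA" else sprintf("%.4f", attr(x, "q"))
  ))
  NextMethod()
}

#' @describeIn detect_modules `tidy()` returns the (`neuron_id`, `module`)
#'   tibble.
#' @param x,... Tidier arguments.
#' @method tidy ensemble_partition
#' @export
tidy.ensemble_partition <- function(x, ...) {
  tibble(neuron_id = x$neuron_id, module = x$module)
}

#' @describeIn detect_modules `glance()` returns one row with `q`,
#'   `n_modules`, `n_neurons` and the consensus iteration count.
#' @method glance ensemble_partition
#' @export
glance.ensemble_partition <- function(x, ...) {
  tibble(
    q = attr(x, "q"),
    n_modules = attr(x, "n_modules"),
    n_neurons = nrow(x),
    iterations = attr(x, "iterations")
  )
}

#' Detect neural ensembles by consensus modularity maximization
#'
#' Finds modules of the dynamical network — the operational definition of
#' neural ensembles: groups of neurons more coactive with each other than
#' with the rest of the population. A randomized modularity-maximizing base
#' algorithm (greedy agglomerative moves plus node-swap refinement) is run
#' `n_runs` times; if runs disagree, their co-assignment (consensus) matrix
#' is thresholded at the co-assignment expected from a label-permutation
#' null that preserves module sizes, reclustered, and iterated until every
#' run agrees. Zero-strength neurons are set aside as their own singleton
#' modules before consensus and reattached afterwards.
#'
#' @param net A [dynamical_network()] with at least one link.
#' @param n_runs Base runs per consensus iteration (default 100).
#' @param seed Master seed; drawn at random if `NULL`. All runs use
#'   substreams derived from it, so results are reproducible.
#' @param max_iter Maximum consensus iterations (default 50); exceeding it
#'   raises an error carrying the last consensus matrix in its `consensus`
#'   field.
#' @return An `ensemble_partition`: a tibble (`neuron_id`, `module`) with
#'   attributes `q` (modularity on the original network), `n_modules`,
#'   `seed`, `n_runs` and `iterations`.
#' @examples
#' w <- matrix(0, 4, 4)
#' w[1, 2] <- w[2, 1] <- 1
#' w[3, 4] <- w[4, 3] <- 1
#' p <- detect_modules(dynamical_network(w), n_runs = 10, seed = 1)
#' glance(p)
#' @export
detect_modules <- function(net, n_runs = 100, seed = NULL, max_iter = 50) {
  stopifnot(inherits(net, "dynamical_network"))
  w <- net$weights
  n <- nrow(w)
  if (sum(w) <= 0) {
    stop_dynet("Module detection needs at least one link.")
  }
  n_runs <- as.integer(n_runs)
  if (n_runs < 1) {
    stop_dynet("`n_runs` must be >= 1.")
  }
  seed <- as.integer(seed %||% random_seed())
  strengths <- rowSums(w)
  active <- which(strengths > 0)
  w_act <- w[active, active, drop = FALSE]
  n_act <- length(active)

  target <- w_act # matrix being clustered (data, then consensus)
  labels_act <- rep(1L, n_act)
  iterations <- 0L
  converged <- FALSE
  p <- NULL
  best_run <- NULL # highest-Q single base run seen on the data matrix
  best_run_q <- -Inf
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    runs <- matrix(0L, nrow = n_runs, ncol = n_act)
    for (r in seq_len(n_runs)) {
      runs[r, ] <- with_seed(
        derive_seed(seed, paste0("iter:", iterations, ":run:", r)),
        base_partition(target)
      )
    }
    if (iterations == 1L) {
      run_qs <- apply(runs, 1, function(lab) q_of(w_act, lab))
      best_run <- runs[which.max(run_qs), ]
      best_run_q <- max(run_qs)
    }
    p <- coassignment_matrix(runs)
    off <- upper_tri_values(p)
    if (all(off == 0 | off == 1)) {
      # all runs agree (up to relabeling): read the partition off p
      g <- igraph::graph_from_adjacency_matrix(
        (p == 1) * 1,
        mode = "undirected", diag = FALSE
      )
      labels_act <- as.integer(igraph::components(g)$membership)
      converged <- TRUE
      break
    }
    theta <- permutation_null_coassignment(runs)
    p_thr <- p
    p_thr[p_thr <= theta] <- 0
    diag(p_thr) <- 0
    if (sum(p_thr) == 0) {
      # no co-assignment above chance anywhere: fall back to the best run
      labels_act <- canonical_labels(best_run)
      converged <- TRUE
      break
    }
    target <- p_thr
  }
  if (!converged) {
    abort(
      sprintf(
        "Consensus did not converge within %d iterations.", max_iter
      ),
      class = c("dynet_consensus_error", "dynet_error"),
      consensus = p
    )
  }
  # final node-swap pass against the *data* matrix: consensus reclustering
  # optimizes Q of the co-assignment matrix, which on weakly structured
  # networks can sit a few moves short of a local optimum of the data Q
  labels_act <- with_seed(
    derive_seed(seed, "final-refine"),
    refine_partition(w_act, labels_act)
  )
  # a modularity maximizer must not return less Q than its best single run;
  # on structured networks the consensus partition ties or wins and is kept
  if (!is.null(best_run) && best_run_q > q_of(w_act, labels_act) + 1e-12) {
    labels_act <- canonical_labels(best_run)
  }

  labels <- integer(n)
  labels[active] <- labels_act
  if (any(strengths == 0)) {
    labels[strengths == 0] <-
      max(labels_act, 0L) + seq_len(sum(strengths == 0))
  }
  labels <- canonical_labels(labels)
  new_ensemble_partition(
    neuron_id = net$neuron_ids, module = labels,
    q = q_of(w, labels),
    seed = seed, n_runs = n_runs, iterations = iterations
  )
}

#' Raster display order for a partition
#'
#' Orders neurons by module label, then by descending node strength within
#' each module — the order used to draw spike rasters grouped by ensemble.
#'
#' @param partition An `ensemble_partition` (or partition data frame).
#' @param net The [dynamical_network()] supplying node strengths.
#' @return Character vector of neuron ids in display order.
#' @export
raster_order <- function(partition, net) {
  stopifnot(inherits(net, "dynamical_network"))
  labels <- labels_from_input(partition, net$neuron_ids)
  strength <- rowSums(net$weights)
  net$neuron_ids[order(labels, -strength)]
}
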