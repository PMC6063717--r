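# Fixture builders and independent brute-force oracles used across tests.
# The oracles deliberately use naive enumeration so they share no code with
# the package implementations they check.

# Random symmetric nonnegative weighted net with zero diagonal.
rand_weighted_net <- function(n, density = 0.5, ids = NULL) {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on <- runif(length(ut)) < density
  w[ut[on]] <- runif(sum(on), 0.05, 1)
  w <- w + t(w)
  dynamical_network(w, ids %||% paste0("n", seq_len(n)))
}

rand_binary_net <- function(n, density = 0.5) {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  w[ut[runif(length(ut)) < density]] <- 1
  dynamical_network(w + t(w))
}

# Small named fixtures
triangle_net <- function(w_ab = 1, w_bc = 1, w_ac = 1) {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- w_ab
  w[2, 3] <- w[3, 2] <- w_bc
  w[1, 3] <- w[3, 1] <- w_ac
  dynamical_network(w, c("a", "b", "c"))
}

path_net_3 <- function() triangle_net(1, 1, 0)

star_net <- function(n_leaves = 3) {
  n <- n_leaves + 1
  w <- matrix(0, n, n)
  w[1, 2:n] <- 1
  w[2:n, 1] <- 1
  dynamical_network(w)
}

two_cliques_net <- function(k = 4) {
  n <- 2 * k
  w <- matrix(0, n, n)
  w[1:k, 1:k] <- 1
  w[(k + 1):n, (k + 1):n] <- 1
  diag(w) <- 0
  dynamical_network(w)
}

# --- oracles ---------------------------------------------------------------

# Triangles/triples weighted clustering by triple loops over max-scaled
# weights (ordered sums in numerator and denominator).
brute_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) {
    return(numeric(n))
  }
  u <- w / mx
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0
    den <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        num <- num + u[i, j] * u[j, k] * u[k, i]
        den <- den + u[i, j] * u[i, k]
      }
    }
    out[i] <- if (den > 0) num / den else 0
  }
  out
}

# Binary clustering coefficient: triangles / (k(k-1)/2) pairs of neighbours.
brute_binary_clustering <- function(adj) {
  n <- nrow(adj)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (j in nb) {
      for (l in nb) {
        if (l > j && adj[j, l] > 0) tri <- tri + 1
      }
    }
    out[i] <- tri / (k * (k - 1) / 2)
  }
  out
}

# Global efficiency via Floyd-Warshall on lengths 1/w.
brute_efficiency <- function(w) {
  n <- nrow(w)
  if (n < 2) {
    return(0)
  }
  d <- matrix(Inf, n, n)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

# Modularity as the literal double sum over node pairs.
brute_modularity <- function(w, labels) {
  two_m <- sum(w)
  s <- rowSums(w)
  q <- 0
  n <- nrow(w)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (labels[i] == labels[j]) {
        q <- q + (w[i, j] - s[i] * s[j] / two_m) / two_m
      }
    }
  }
  q
}

# All set partitions of n items as restricted-growth label vectors.
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, k) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (c in seq_len(k + 1L)) {
      rec(c(labels, c), max(k, c))
    }
  }
  rec(integer(0), 0L)
  out
}

# Best modularity over every partition (Bell-number enumeration).
brute_max_modularity <- function(w) {
  n <- nrow(w)
  two_m <- sum(w)
  s <- rowSums(w)
  b <- w / two_m - outer(s, s) / two_m^2
  best <- -Inf
  for (lab in all_partitions(n)) {
    q <- sum(b[outer(lab, lab, "==")])
    if (q > best) best <- q
  }
  best
}

`%||%` <- function(x, y) if (is.null(x)) y else x

upper_vals <- function(m) m[upper.tri(m)]

# Quick planted-ensemble session used in several tests.
small_planted_session <- function(seed, n_neurons = 30, n_trials = 1,
                                  duration_s = 30, p = 0.8, jitter = 0.02,
                                  drift = 0, n_ensembles = 3) {
  generate_synthetic_session(synthetic_config(
    n_neurons = n_neurons, n_ensembles = n_ensembles,
    duration_s = duration_s, n_trials = n_trials,
    background_rate_hz = 1, event_rate_hz = 1,
    participation_p = p, jitter_s = jitter, drift = drift, seed = seed
  ))
}
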