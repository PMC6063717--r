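#' Node degree, strength and link weights
#'
#' Degree counts a node's strictly positive links (rectified-Pearson zeros
#' are structural absences; no epsilon threshold); strength sums its link
#' weights. `link_weights()` returns each undirected link's weight once.
#'
#' @param net A [dynamical_network()].
#' @return `degree_strength()`: a tibble (`neuron_id`, `degree`, `strength`);
#'   `link_weights()`: a numeric vector of the nonzero upper-triangle weights.
#' @export
degree_strength <- function(net) {
  stopifnot(inherits(net, "dynamical_network"))
  w <- net$weights
  tibble(
    neuron_id = net$neuron_ids,
    degree = as.integer(rowSums(w > 0)),
    strength = rowSums(w)
  )
}

#' @rdname degree_strength
#' @export
link_weights <- function(net) {
  stopifnot(inherits(net, "dynamical_network"))
  w <- upper_tri_values(net$weights)
  w[w > 0]
}

#' Weighted clustering coefficient per neuron
#'
#' The ratio of weighted triangles to weighted triples in which each neuron
#' participates, after scaling all weights to \[0, 1\] by the maximum weight.
#' For node i with scaled weights `u`,
#' `C_i = sum_{j != k} u_ij u_jk u_ki / ((sum_j u_ij)^2 - sum_j u_ij^2)`,
#' and `C_i = 0` when the denominator vanishes (degree < 2). On a binary
#' network this reduces to the classic triangles/triples clustering
#' coefficient. The `"onnela"` variant (geometric-mean triangle intensity
#' over `k(k-1)` pairs) is provided for comparison with other toolboxes.
#'
#' @param net A [dynamical_network()].
#' @param variant `"triangles_triples"` (default) or `"onnela"`.
#' @return Named numeric vector of per-neuron clustering values in \[0, 1\].
#' @export
weighted_clustering <- function(net,
                                variant = c("triangles_triples", "onnela")) {
  stopifnot(inherits(net, "dynamical_network"))
  variant <- match.arg(variant)
  w <- net$weights
  n <- nrow(w)
  mx <- max(w)
  out <- numeric(n)
  if (n >= 1 && mx > 0) {
    u <- w / mx
    if (variant == "triangles_triples") {
      num <- diag(u %*% u %*% u)
      s <- rowSums(u)
      den <- s^2 - rowSums(u^2)
      out <- ifelse(den > 0, num / den, 0)
    } else {
      u3 <- u^(1 / 3)
      num <- diag(u3 %*% u3 %*% u3)
      k <- rowSums(w > 0)
      den <- k * (k - 1)
      out <- ifelse(den > 0, num / den, 0)
    }
  }
  out <- pmin(pmax(out, 0), 1)
  names(out) <- net$neuron_ids
  out
}

net_distances <- function(w) {
  g <- igraph::graph_from_adjacency_matrix(w,
    mode = "undirected",
    weighted = TRUE, diag = FALSE
  )
  ew <- igraph::E(g)$weight
  igraph::distances(g, weights = if (length(ew)) 1 / ew else numeric())
}

#' Global efficiency of a weighted network
#'
#' How easily the network is traversed: link length is 1/weight, `d_ij` the
#' weighted shortest-path length, and efficiency the mean over ordered pairs
#' `i != j` of `1/d_ij`, taking `1/Inf = 0` for disconnected pairs. Lies in
#' \[0, 1\] for weights in \[0, 1\]; higher values mean more cohesive
#' population interactions.
#'
#' @param net A [dynamical_network()], or a plain weight matrix.
#' @return A single number in \[0, 1\].
#' @export
global_efficiency <- function(net) {
  w <- if (inherits(net, "dynamical_network")) net$weights else as.matrix(net)
  n <- nrow(w)
  if (n < 2) {
    return(0)
  }
  d <- net_distances(w)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Efficiency fingerprint: per-neuron impact on global efficiency
#'
#' Deletes each neuron (and its links) in turn and records the change
#' `Eff(G) - Eff(G minus node)`, with the reduced graph's efficiency averaged
#' over its own `(n-1)(n-2)` ordered pairs. Large positive deltas flag
#' hub-like neurons that mediate many interactions; deltas can be negative,
#' since removing a weakly connected neuron can raise the average.
#'
#' @param net A [dynamical_network()] with at least 3 neurons.
#' @return A tibble (`neuron_id`, `delta_eff`).
#' @export
efficiency_fingerprint <- function(net) {
  stopifnot(inherits(net, "dynamical_network"))
  w <- net$weights
  n <- nrow(w)
  if (n < 3) {
    stop_dynet("Efficiency fingerprint needs at least 3 neurons.")
  }
  eff_full <- global_efficiency(net)
  delta <- vapply(seq_len(n), function(i) {
    eff_full - global_efficiency(w[-i, -i, drop = FALSE])
  }, numeric(1))
  tibble(neuron_id = net$neuron_ids, delta_eff = delta)
}

#' Summarise a dynamical network
#'
#' Bundles the descriptive statistics of a dynamical network: per-neuron
#' degree, strength, weighted clustering and (for n >= 3) the efficiency
#' fingerprint, plus the global efficiency and mean clustering.
#'
#' @param net A [dynamical_network()].
#' @param fingerprint Compute the (O(n) shortest-path solves) per-neuron
#'   efficiency fingerprint? Default `TRUE` when `n >= 3`.
#' @return A `network_metrics` object. `tidy()` gives the per-neuron table;
#'   `glance()` the network-level scalars; `autoplot()` the distribution
#'   panels (degree, strength, link weight, clustering).
#' @export
summarise_network <- function(net, fingerprint = NULL) {
  stopifnot(inherits(net, "dynamical_network"))
  n <- nrow(net$weights)
  fingerprint <- fingerprint %||% (n >= 3)
  nodes <- degree_strength(net)
  nodes$clustering <- unname(weighted_clustering(net))
  nodes$delta_eff <- if (fingerprint && n >= 3) {
    efficiency_fingerprint(net)$delta_eff
  } else {
    NA_real_
  }
  structure(
    list(
      nodes = nodes,
      link_weights = link_weights(net),
      global_efficiency = global_efficiency(net),
      mean_clustering = if (n > 0) mean(nodes$clustering) else NA_real_,
      meta = net$meta,
      n_neurons = n
    ),
    class = "network_metrics"
  )
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(
    "<network_metrics: %d neurons, Eff = %.4f, C = %.4f>\n",
    x$n_neurons, x$global_efficiency, x$mean_clustering
  ))
  invisible(x)
}

#' @describeIn summarise_network Per-neuron metric table.
#' @param x,... Tidier arguments.
#' @method tidy network_metrics
#' @export
tidy.network_metrics <- function(x, ...) {
  x$nodes
}

#' @describeIn summarise_network One-row network-level summary.
#' @method glance network_metrics
#' @export
glance.network_metrics <- function(x, ...) {
  tibble(
    n_neurons = x$n_neurons,
    n_links = length(x$link_weights),
    total_weight = sum(x$link_weights),
    global_efficiency = x$global_efficiency,
    mean_clustering = x$mean_clustering
  )
}

#' @describeIn summarise_network Histogram panels of the degree, strength,
#'   link-weight and clustering distributions (the network's "fingerprints").
#' @param object A `network_metrics` object.
#' @method autoplot network_metrics
#' @export
autoplot.network_metrics <- function(object, ...) {
  nodes <- object$nodes
  df <- dplyr::bind_rows(
    tibble(metric = "degree", value = as.numeric(nodes$degree)),
    tibble(metric = "strength", value = nodes$strength),
    tibble(metric = "link weight", value = object$link_weights),
    tibble(metric = "clustering", value = nodes$clustering)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey30") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(
      x = NULL, y = "count",
      title = "Network fingerprints",
      subtitle = sprintf(
        "Eff = %.3f, mean C = %.3f",
        object$global_efficiency, object$mean_clustering
      )
    ) +
    ggplot2::theme_minimal()
}
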