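#' Dynamical network objects
#'
#' A dynamical network is a weighted graph whose nodes are recorded neurons
#' and whose links are pairwise activity interactions (distinct from the
#' anatomical, synaptic network). The weight matrix is symmetric and
#' nonnegative with a zero diagonal; for the rectified-Pearson measure all
#' weights lie in \[0, 1\].
#'
#' @param weights Square numeric matrix, symmetric, nonnegative, zero
#'   diagonal. Values within `tol` of symmetry/zero are snapped.
#' @param neuron_ids Character roster, one id per row; defaults to
#'   `"n1".."nN"`.
#' @param measure,sigma,dt,trial_id Provenance metadata: the interaction
#'   measure name, the Gaussian width and sample interval (seconds) used to
#'   build it, and the trial it came from.
#' @param tol Numeric tolerance for symmetry checks.
#' @return A `dynamical_network` object (list with elements `weights`,
#'   `neuron_ids`, `meta`).
#' @examples
#' w <- matrix(c(0, .5, 0, .5, 0, .2, 0, .2, 0), 3, 3)
#' net <- dynamical_network(w, c("a", "b", "c"))
#' tidy(net)
#' @export
dynamical_network <- function(weights, neuron_ids = NULL, measure = NA_character_,
                              sigma = NA_real_, dt = NA_real_, trial_id = NULL,
                              tol = 1e-8) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) {
    stop_dynet("`weights` must be a square matrix.")
  }
  if (anyNA(weights)) {
    stop_dynet("`weights` must not contain missing values.")
  }
  if (any(weights < -tol)) {
    stop_dynet("`weights` must be nonnegative (rectified).")
  }
  if (max(abs(weights - t(weights)), 0) > tol) {
    stop_dynet("`weights` must be symmetric.")
  }
  if (any(abs(diag(weights)) > tol)) {
    stop_dynet("`weights` must have a zero diagonal.")
  }
  weights <- (weights + t(weights)) / 2
  weights[weights < 0] <- 0
  diag(weights) <- 0
  if (is.null(neuron_ids)) {
    neuron_ids <- paste0("n", seq_len(n))
  }
  neuron_ids <- as.character(neuron_ids)
  if (length(neuron_ids) != n || anyDuplicated(neuron_ids)) {
    stop_dynet("`neuron_ids` must be unique and match the matrix size.")
  }
  dimnames(weights) <- NULL
  structure(
    list(
      weights = weights,
      neuron_ids = neuron_ids,
      meta = list(
        measure = measure, sigma = sigma, dt = dt, trial_id = trial_id
      )
    ),
    class = "dynamical_network"
  )
}

#' Coerce matrices or edge lists to a dynamical network
#'
#' @param x A square matrix, a `dynamical_network`, or a data frame edge list
#'   with columns `node_a`/`node_b`/`weight` (or `from`/`to`/`weight`).
#' @param neuron_ids Optional roster; for edge lists, defaults to the sorted
#'   union of endpoint ids.
#' @param ... Passed to [dynamical_network()].
#' @return A [dynamical_network()].
#' @export
as_dynamical_network <- function(x, neuron_ids = NULL, ...) {
  if (inherits(x, "dynamical_network")) {
    return(x)
  }
  if (is.matrix(x)) {
    return(dynamical_network(x, neuron_ids = neuron_ids, ...))
  }
  if (is.data.frame(x)) {
    nm <- names(x)
    a <- if ("node_a" %in% nm) x$node_a else x$from
    b <- if ("node_b" %in% nm) x$node_b else x$to
    if (is.null(a) || is.null(b) || is.null(x$weight)) {
      stop_dynet("Edge list needs columns node_a/node_b/weight (or from/to).")
    }
    a <- as.character(a)
    b <- as.character(b)
    ids <- neuron_ids %||% sort(unique(c(a, b)))
    w <- matrix(0, length(ids), length(ids))
    ia <- match(a, ids)
    ib <- match(b, ids)
    w[cbind(ia, ib)] <- x$weight
    w[cbind(ib, ia)] <- x$weight
    return(dynamical_network(w, ids, ...))
  }
  stop_dynet("Cannot coerce this object to a dynamical_network.")
}

#' @export
neuron_ids.dynamical_network <- function(x) x$neuron_ids

#' @export
print.dynamical_network <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<dynamical_network: %d neurons, %d links, total weight %.4g%s>\n",
    g$n_neurons, g$n_links, g$total_weight,
    if (!is.na(g$sigma)) sprintf(", sigma = %g s (%s)", g$sigma, g$measure) else ""
  ))
  invisible(x)
}

#' @describeIn dynamical_network `tidy()` returns the nonzero upper-triangle
#'   links as a tibble (`node_a`, `node_b`, `weight`).
#' @param x,... Tidier arguments (object, unused).
#' @method tidy dynamical_network
#' @export
tidy.dynamical_network <- function(x, ...) {
  w <- x$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  tibble(
    node_a = x$neuron_ids[idx[, 1]],
    node_b = x$neuron_ids[idx[, 2]],
    weight = w[idx]
  )
}

#' @describeIn dynamical_network `glance()` returns one-row network-level
#'   summary (size, link count, total weight, density, provenance).
#' @method glance dynamical_network
#' @export
glance.dynamical_network <- function(x, ...) {
  w <- x$weights
  n <- nrow(w)
  ut <- upper_tri_values(w)
  tibble(
    n_neurons = n,
    n_links = sum(ut > 0),
    total_weight = sum(ut),
    density = if (n > 1) sum(ut > 0) / (n * (n - 1) / 2) else NA_real_,
    measure = x$meta$measure,
    sigma = x$meta$sigma,
    dt = x$meta$dt
  )
}

#' @describeIn dynamical_network `autoplot()` draws the weight matrix as a
#'   heat map, optionally re-ordering neurons by descending strength.
#' @param object A `dynamical_network`.
#' @param order_by `"roster"` or `"strength"` (descending node strength, the
#'   usual presentation for weight matrices).
#' @method autoplot dynamical_network
#' @export
autoplot.dynamical_network <- function(object, order_by = c("strength", "roster"),
                                       ...) {
  order_by <- match.arg(order_by)
  w <- object$weights
  ids <- object$neuron_ids
  ord <- if (order_by == "strength") order(-rowSums(w)) else seq_along(ids)
  w <- w[ord, ord, drop = FALSE]
  ids <- ids[ord]
  df <- tidyr::expand_grid(
    row = seq_along(ids), col = seq_along(ids)
  )
  df$weight <- w[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "black") +
    ggplot2::labs(
      x = "neuron (by strength)", y = "neuron (by strength)",
      fill = "weight", title = "Dynamical network weight matrix"
    ) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Trial series of dynamical networks
#'
#' An ordered sequence of dynamical networks (one per trial) sharing a neuron
#' roster, as produced by [build_networks()].
#'
#' @param nets List of [dynamical_network()] objects with identical rosters.
#' @param trial_labels Optional labels, defaulting to the nets' own trial ids
#'   or their position.
#' @return A `trial_series` object (list of networks with labels).
#' @export
trial_series <- function(nets, trial_labels = NULL) {
  if (!is.list(nets) ||
    !all(vapply(nets, inherits, logical(1), "dynamical_network"))) {
    stop_dynet("`nets` must be a list of dynamical_network objects.")
  }
  if (length(nets) > 0) {
    roster <- nets[[1]]$neuron_ids
    ok <- vapply(nets, function(x) identical(x$neuron_ids, roster), logical(1))
    if (!all(ok)) {
      stop_dynet("All networks in a series must share one neuron roster.")
    }
  }
  if (is.null(trial_labels)) {
    trial_labels <- vapply(seq_along(nets), function(i) {
      as.character(nets[[i]]$meta$trial_id %||% i)
    }, character(1))
  }
  if (length(trial_labels) != length(nets)) {
    stop_dynet("`trial_labels` must match the number of networks.")
  }
  structure(
    nets,
    trial_labels = as.character(trial_labels),
    class = "trial_series"
  )
}

#' @export
print.trial_series <- function(x, ...) {
  cat(sprintf(
    "<trial_series: %d trials, %d neurons>\n",
    length(x), if (length(x) > 0) length(x[[1]]$neuron_ids) else 0L
  ))
  invisible(x)
}

#' @rdname accessors
#' @export
trial_labels <- function(x) attr(x, "trial_labels")
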