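net_upper <- function(net) upper_tri_values(net$weights)

stability_cor <- function(va, vb) {
  if (identical(va, vb)) {
    return(1) # Pearson of identical vectors is exactly 1
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    return(NA_real_) # Pearson undefined for constant matrices
  }
  stats::cor(va, vb)
}

#' Trial-to-trial stability of the dynamical network
#'
#' For each consecutive pair of trials, the Pearson correlation between the
#' vectorised strict upper triangles of the weight matrices W(t-1) and W(t).
#' The diagonal and the duplicate symmetric entries are excluded, since
#' including them inflates the correlation. A pair involving a constant
#' matrix yields `NA` (Pearson is undefined there).
#'
#' @param series A [trial_series()] with at least 2 trials.
#' @return A tibble (`trial_from`, `trial_to`, `stability`) with one row per
#'   consecutive pair.
#' @export
network_stability <- function(series) {
  stopifnot(inherits(series, "trial_series"))
  if (length(series) < 2) {
    stop_dynet("Stability needs at least 2 trials.")
  }
  labels <- trial_labels(series)
  uppers <- lapply(series, net_upper)
  vals <- vapply(seq_len(length(series) - 1), function(t) {
    stability_cor(uppers[[t]], uppers[[t + 1]])
  }, numeric(1))
  tibble(
    trial_from = labels[-length(labels)],
    trial_to = labels[-1],
    stability = vals
  )
}

#' Per-trial total weight and link count
#'
#' @param series A [trial_series()].
#' @return A tibble (`trial`, `total_weight`, `n_links`), summing and
#'   counting the strict upper triangle.
#' @export
network_totals <- function(series) {
  stopifnot(inherits(series, "trial_series"))
  tibble(
    trial = trial_labels(series),
    total_weight = vapply(
      series, function(net) sum(net_upper(net)), numeric(1)
    ),
    n_links = vapply(
      series, function(net) sum(net_upper(net) > 0), numeric(1)
    )
  )
}

#' Track a dynamical network across trials
#'
#' Assembles the trial-by-trial report: network stability (correlation of
#' consecutive weight matrices), total weight and link counts, the mean
#' weighted clustering of each trial's network ("data"), the mean clustering
#' over `n_samples` null-model networks per trial, and the excess clustering
#' percentage `100 * C_data / C_null`. Null samples are drawn independently
#' per trial from substreams of `seed` keyed by each trial's weight matrix,
#' so the report is deterministic given the seed and identical trials are
#' compared against identical null ensembles.
#'
#' @param series A [trial_series()].
#' @param null_model Null model for the clustering comparison
#'   (see [sample_null()]).
#' @param n_samples Null networks per trial (default 20).
#' @param seed Master seed; drawn at random if `NULL`.
#' @return A `tracking_report`: a tibble with one row per trial
#'   (`trial`, `total_weight`, `n_links`, `clustering_data`,
#'   `clustering_null_mean`, `excess_clustering_pct`, `stability`), the
#'   `stability` column offset by one (first trial `NA`).
#' @export
track <- function(series, null_model = "weight_shuffle", n_samples = 20,
                  seed = NULL) {
  stopifnot(inherits(series, "trial_series"))
  if (length(series) < 1) {
    stop_dynet("`series` must contain at least one trial.")
  }
  seed <- as.integer(seed %||% random_seed())
  totals <- network_totals(series)
  c_data <- vapply(
    series, function(net) mean(weighted_clustering(net)), numeric(1)
  )
  c_null <- vapply(seq_along(series), function(t) {
    # substream keyed by the trial's weight content: identical trials face
    # identical null ensembles (so their excess ratios agree exactly),
    # different trials draw independently
    w <- series[[t]]$weights
    key <- paste(
      format(c(sum(w), sum(w * w)), digits = 17),
      collapse = ","
    )
    ns <- sample_null(
      series[[t]], null_model, n_samples,
      seed = derive_seed(seed, paste0("trial:", key))
    )
    null_metric_distribution(
      ns, function(net) mean(weighted_clustering(net))
    )$mean
  }, numeric(1))
  stab <- if (length(series) >= 2) {
    c(NA_real_, network_stability(series)$stability)
  } else {
    NA_real_
  }
  out <- totals
  out$clustering_data <- c_data
  out$clustering_null_mean <- c_null
  out$excess_clustering_pct <- suppressWarnings(excess_ratio(c_data, c_null))
  out$stability <- stab
  structure(
    out,
    null_model = null_model, n_samples = as.integer(n_samples), seed = seed,
    class = c("tracking_report", class(tibble()))
  )
}

#' @export
print.tracking_report <- function(x, ...) {
  cat(sprintf(
    "<tracking_report: %d trials, null = %s (%d samples, seed %d)>\n",
    nrow(x), attr(x, "null_model"), attr(x, "n_samples"), attr(x, "seed")
  ))
  NextMethod()
}

#' @describeIn track Plot the tracking report: stability, totals, and
#'   data-vs-null clustering panels across trials.
#' @param object A `tracking_report`.
#' @param ... Unused.
#' @method autoplot tracking_report
#' @export
autoplot.tracking_report <- function(object, ...) {
  df <- as_tibble(object)
  df$trial_index <- seq_len(nrow(df))
  long <- dplyr::bind_rows(
    tibble(
      trial_index = df$trial_index, panel = "stability",
      series = "W(t) vs W(t-1)", value = df$stability
    ),
    tibble(
      trial_index = df$trial_index, panel = "totals",
      series = "total weight", value = df$total_weight
    ),
    tibble(
      trial_index = df$trial_index, panel = "totals",
      series = "n links", value = df$n_links
    ),
    tibble(
      trial_index = df$trial_index, panel = "clustering",
      series = "data", value = df$clustering_data
    ),
    tibble(
      trial_index = df$trial_index, panel = "clustering",
      series = "null model", value = df$clustering_null_mean
    ),
    tibble(
      trial_index = df$trial_index, panel = "excess clustering (%)",
      series = "100 C_data/C_null", value = df$excess_clustering_pct
    )
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$trial_index, .data$value, colour = .data$series)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(
      x = "trial", y = NULL, colour = NULL,
      title = "Tracking the dynamical network across trials"
    ) +
    ggplot2::theme_minimal()
}
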