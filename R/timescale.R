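#' Default timescale grid for a recording
#'
#' Ten log-spaced Gaussian widths spanning a quarter of the pooled median
#' interspike interval to ten times it — the median-ISI heuristic for
#' bracketing the timescales at which a population's coactivity could be
#' structured.
#'
#' @param spikes A [spike_trains()] or [recording_session()].
#' @param n Number of grid points (default 10).
#' @return Ascending numeric vector of sigma values in seconds.
#' @export
default_sigma_grid <- function(spikes, n = 10) {
  isi <- median_isi_sigma(spikes)
  exp(seq(log(isi / 4), log(10 * isi), length.out = n))
}

#' Scan ensemble structure across timescales
#'
#' Rebuilds the dynamical network over a grid of Gaussian widths sigma,
#' detects consensus modules at each, and assembles the cross-timescale
#' confusion matrix: entry (i, j) is the proportion of timescales at which
#' neurons i and j were placed in the same module. Small sigma captures
#' precise spike-timing relationships; large sigma captures firing-rate
#' covariation.
#'
#' @param spikes A [spike_trains()] object (one recording).
#' @param sigmas Ascending grid of Gaussian widths in seconds; defaults to
#'   [default_sigma_grid()].
#' @param dt Sample interval, or `NULL` for the per-sigma default
#'   `sigma / 10` (floored at 1 ms).
#' @param measure Interaction measure, see [pairwise_weights()].
#' @param n_runs Base runs per consensus detection (default 100).
#' @param seed Master seed; per-sigma substreams are derived from it.
#' @return A `timescale_scan` object: list with `results` (tibble `sigma`,
#'   `q`, `n_modules`), `partitions` (list of `ensemble_partition`),
#'   `confusion` (symmetric matrix, unit diagonal), `neuron_ids`.
#' @export
timescale_scan <- function(spikes, sigmas = NULL, dt = NULL,
                           measure = c("rectified_pearson", "cosine"),
                           n_runs = 100, seed = NULL) {
  stopifnot(inherits(spikes, "spike_trains"))
  measure <- match.arg(measure)
  sigmas <- sigmas %||% default_sigma_grid(spikes)
  if (length(sigmas) == 0) {
    stop_dynet("`sigmas` must be a nonempty ascending grid.")
  }
  if (is.unsorted(sigmas, strictly = TRUE)) {
    stop_dynet("`sigmas` must be strictly ascending.")
  }
  seed <- as.integer(seed %||% random_seed())
  ids <- neuron_ids(spikes)
  partitions <- vector("list", length(sigmas))
  for (k in seq_along(sigmas)) {
    net <- pairwise_weights(convolve_trains(spikes, sigmas[k], dt), measure)
    partitions[[k]] <- detect_modules(
      net,
      n_runs = n_runs,
      seed = derive_seed(seed, paste0("sigma:", k))
    )
  }
  label_matrix <- do.call(rbind, lapply(partitions, function(p) p$module))
  confusion <- coassignment_matrix(label_matrix)
  dimnames(confusion) <- list(ids, ids)
  results <- tibble(
    sigma = as.numeric(sigmas),
    q = vapply(partitions, function(p) attr(p, "q"), numeric(1)),
    n_modules = vapply(
      partitions, function(p) attr(p, "n_modules"), integer(1)
    )
  )
  structure(
    list(
      results = results, partitions = partitions,
      confusion = confusion, neuron_ids = ids, seed = seed
    ),
    class = "timescale_scan"
  )
}

#' @export
print.timescale_scan <- function(x, ...) {
  cat(sprintf(
    "<timescale_scan: %d timescales (%.4g-%.4g s), peak Q = %.4f at sigma = %.4g s>\n",
    nrow(x$results), min(x$results$sigma), max(x$results$sigma),
    max(x$results$q), peak_timescale(x)
  ))
  invisible(x)
}

#' Timescale at which population structure peaks
#'
#' Returns the sigma maximizing modularity Q over the scan — the timescale at
#' which the population dynamics are most structured. Ties go to the
#' smallest sigma. A flat Q curve is a valid outcome (some populations show
#' no consistent preferred timescale); inspect the full curve via
#' `tidy(scan)` before reading much into the peak.
#'
#' @param scan A `timescale_scan`.
#' @return The peak sigma in seconds.
#' @export
peak_timescale <- function(scan) {
  stopifnot(inherits(scan, "timescale_scan"))
  res <- scan$results
  if (nrow(res) == 0) {
    stop_dynet("Empty timescale scan.")
  }
  res$sigma[which.max(res$q)] # which.max takes the first (smallest sigma)
}

#' @describeIn timescale_scan `tidy()` returns the per-sigma table
#'   (`sigma`, `q`, `n_modules`).
#' @param x,... Tidier arguments.
#' @method tidy timescale_scan
#' @export
tidy.timescale_scan <- function(x, ...) {
  x$results
}

#' @describeIn timescale_scan `glance()` returns one row: grid size, peak
#'   sigma, peak Q, and the mean cross-timescale co-assignment.
#' @method glance timescale_scan
#' @export
glance.timescale_scan <- function(x, ...) {
  tibble(
    n_sigmas = nrow(x$results),
    peak_sigma = peak_timescale(x),
    peak_q = max(x$results$q),
    mean_coassignment = mean(upper_tri_values(x$confusion))
  )
}

#' @describeIn timescale_scan `autoplot()` draws the Q(sigma) curve with the
#'   module count as point labels.
#' @param object A `timescale_scan`.
#' @method autoplot timescale_scan
#' @export
autoplot.timescale_scan <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(.data$sigma, .data$q)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$n_modules),
      vjust = -0.8, size = 3
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = expression(sigma ~ "(s)"), y = "modularity Q",
      title = "Ensemble structure across timescales",
      subtitle = "point labels: number of modules"
    ) +
    ggplot2::theme_minimal()
}
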