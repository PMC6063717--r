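#' Convolve spike trains with a Gaussian kernel
#'
#' Each neuron's spike train is turned into a smoothed firing-rate series by
#' summing a unit-area Gaussian density of width `sigma` centred on every
#' spike, evaluated at the midpoints of a regular sample grid. The kernel is
#' truncated at +/- 5 sigma; mass falling outside the recording window is
#' discarded (no reflection or renormalisation), so rates near the window
#' edges are biased slightly downward.
#'
#' @param spikes A [spike_trains()] object.
#' @param sigma Gaussian width in seconds (> 0). Small sigma emphasises
#'   spike-time precision; large sigma emphasises firing-rate covariation.
#' @param dt Sample interval in seconds; defaults to `sigma / 10`, floored at
#'   1 ms. A `dt > sigma` undersamples the kernel and triggers a warning.
#' @return A `convolved_activity` object: list with `values`
#'   (neurons x samples matrix of smoothed rate, 1/s), `times` (sample
#'   midpoints), `dt`, `sigma`, `window`, `neuron_ids`.
#' @examples
#' st <- spike_trains(
#'   data.frame(neuron_id = "a", time = 1),
#'   window = c(0, 2)
#' )
#' ca <- convolve_trains(st, sigma = 0.25)
#' max(ca$values) # ~ 1 / (0.25 * sqrt(2 * pi))
#' @export
convolve_trains <- function(spikes, sigma, dt = NULL) {
  stopifnot(inherits(spikes, "spike_trains"))
  if (!is_scalar_number(sigma) || sigma <= 0) {
    stop_dynet("`sigma` must be a positive number of seconds.")
  }
  dt <- dt %||% max(sigma / 10, 1e-3)
  if (!is_scalar_number(dt) || dt <= 0) {
    stop_dynet("`dt` must be a positive number of seconds.")
  }
  if (dt > sigma) {
    warn("`dt` exceeds `sigma`; the kernel is undersampled.")
  }
  win <- spike_window(spikes)
  n_samples <- floor((win[2] - win[1]) / dt)
  if (n_samples < 1) {
    stop_dynet("Recording window is empty at this `dt`.")
  }
  mid <- win[1] + (seq_len(n_samples) - 0.5) * dt
  ids <- neuron_ids(spikes)
  trains <- spike_list(spikes)
  values <- matrix(0, nrow = length(ids), ncol = n_samples)
  half <- 5 * sigma
  for (i in seq_along(ids)) {
    ts <- trains[[i]]
    if (length(ts) == 0) next
    row <- numeric(n_samples)
    for (s in ts) {
      lo <- max(1L, ceiling((s - half - win[1]) / dt + 0.5))
      hi <- min(n_samples, floor((s + half - win[1]) / dt + 0.5))
      if (lo > hi) next
      row[lo:hi] <- row[lo:hi] + dnorm(mid[lo:hi], mean = s, sd = sigma)
    }
    values[i, ] <- row
  }
  structure(
    list(
      values = values, times = mid, dt = dt, sigma = sigma,
      window = win, neuron_ids = ids
    ),
    class = "convolved_activity"
  )
}

#' @export
print.convolved_activity <- function(x, ...) {
  cat(sprintf(
    "<convolved_activity: %d neurons x %d samples, sigma = %g s, dt = %g s>\n",
    nrow(x$values), ncol(x$values), x$sigma, x$dt
  ))
  invisible(x)
}

#' Pairwise interaction weights between smoothed spike trains
#'
#' Builds the dynamical network from convolved activity. The default measure
#' is rectified Pearson correlation: the Pearson R between each pair of
#' smoothed series with negative values set to zero, so weights lie in
#' \[0, 1\]. The alternative is cosine similarity (automatically nonnegative
#' for nonnegative series). A constant (for example all-zero) series yields
#' weight 0 with every partner, never `NaN`, so silent neurons remain in the
#' network as isolated nodes.
#'
#' @param activity A `convolved_activity` from [convolve_trains()].
#' @param measure `"rectified_pearson"` (default) or `"cosine"`.
#' @return A [dynamical_network()].
#' @export
pairwise_weights <- function(activity,
                             measure = c("rectified_pearson", "cosine")) {
  stopifnot(inherits(activity, "convolved_activity"))
  measure <- match.arg(measure)
  v <- activity$values
  n <- nrow(v)
  if (n < 2) {
    stop_dynet("Need at least 2 neurons to build a network.")
  }
  if (ncol(v) < 2) {
    stop_dynet("Need at least 2 samples to compute interactions.")
  }
  if (measure == "rectified_pearson") {
    sds <- apply(v, 1, stats::sd)
    w <- suppressWarnings(stats::cor(t(v)))
    w[!is.finite(w)] <- 0
    w[sds == 0, ] <- 0
    w[, sds == 0] <- 0
    w <- pmax(w, 0)
  } else {
    nrm <- sqrt(rowSums(v^2))
    w <- tcrossprod(v)
    denom <- outer(nrm, nrm)
    w <- ifelse(denom > 0, w / denom, 0)
    w <- pmin(pmax(w, 0), 1)
  }
  w <- (w + t(w)) / 2
  diag(w) <- 0
  dynamical_network(
    w, activity$neuron_ids,
    measure = measure, sigma = activity$sigma, dt = activity$dt
  )
}

#' Build one dynamical network per trial
#'
#' Convolves every trial of a session at the same timescale and computes the
#' pairwise weight matrix, returning networks with identical neuron ordering
#' so they can be compared link-by-link across trials.
#'
#' @param session A [recording_session()].
#' @param sigma Gaussian width in seconds.
#' @param dt Sample interval; defaults to `sigma / 10` (floored at 1 ms).
#' @param measure Interaction measure, see [pairwise_weights()].
#' @return A [trial_series()].
#' @export
build_networks <- function(session, sigma, dt = NULL,
                           measure = c("rectified_pearson", "cosine")) {
  stopifnot(inherits(session, "recording_session"))
  measure <- match.arg(measure)
  nets <- lapply(session, function(tr) {
    net <- pairwise_weights(convolve_trains(tr, sigma, dt), measure)
    net$meta$trial_id <- trial_id(tr)
    net
  })
  trial_series(nets)
}

#' Median interspike interval of a recording
#'
#' Pools the interspike intervals (ISIs) of every neuron and returns their
#' median, the usual first guess at the timescale `sigma` of coactivity for
#' a recording.
#'
#' @param spikes A [spike_trains()] object, or a [recording_session()] whose
#'   trials are pooled.
#' @return Median ISI in seconds.
#' @export
median_isi_sigma <- function(spikes) {
  trains <- if (inherits(spikes, "recording_session")) {
    unlist(lapply(spikes, spike_list), recursive = FALSE)
  } else if (inherits(spikes, "spike_trains")) {
    spike_list(spikes)
  } else {
    stop_dynet("`spikes` must be spike_trains or a recording_session.")
  }
  isis <- unlist(lapply(trains, function(ts) {
    if (length(ts) >= 2) diff(ts) else numeric()
  }))
  if (length(isis) == 0) {
    stop_dynet("No interspike intervals available (need >= 2 spikes somewhere).")
  }
  stats::median(isis)
}
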