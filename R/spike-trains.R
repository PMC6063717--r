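#' Spike-train containers
#'
#' A `spike_trains` object holds the spike times of a simultaneously recorded
#' neural population during one recording window (typically one trial). It is
#' a tibble with columns `neuron_id` (character) and `time` (seconds), carrying
#' the neuron roster, the recording window and an optional trial label as
#' attributes, so that neurons that fired no spikes remain representable.
#'
#' @param spikes A data frame with columns `neuron_id` and `time` (seconds).
#'   May have zero rows.
#' @param neuron_ids Character vector giving the roster and its order. Defaults
#'   to the sorted unique ids present in `spikes`. Must contain every id in
#'   `spikes`.
#' @param window Numeric length-2 `(t_start, t_end)` in seconds. Defaults to
#'   the range of the spike times (0..0 if there are none).
#' @param trial_id Optional trial label.
#' @return A `spike_trains` tibble.
#' @examples
#' st <- spike_trains(
#'   data.frame(neuron_id = c("a", "a", "b"), time = c(0.1, 0.5, 0.2)),
#'   window = c(0, 1)
#' )
#' neuron_ids(st)
#' @export
spike_trains <- function(spikes, neuron_ids = NULL, window = NULL,
                         trial_id = NULL) {
  spikes <- as_tibble(spikes)
  if (!all(c("neuron_id", "time") %in% names(spikes))) {
    stop_dynet("`spikes` must have columns `neuron_id` and `time`.")
  }
  spikes$neuron_id <- as.character(spikes$neuron_id)
  spikes$time <- as.numeric(spikes$time)
  if (anyNA(spikes$time) || anyNA(spikes$neuron_id)) {
    stop_dynet("Spike times and neuron ids must not be missing.")
  }
  if (any(spikes$time < 0)) {
    stop_dynet("Negative spike times are not valid.",
      class = "dynet_validation_error"
    )
  }
  if (is.null(neuron_ids)) {
    neuron_ids <- sort(unique(spikes$neuron_id))
  } else {
    neuron_ids <- as.character(neuron_ids)
    if (anyDuplicated(neuron_ids)) {
      stop_dynet("`neuron_ids` must be unique.")
    }
    missing_ids <- setdiff(spikes$neuron_id, neuron_ids)
    if (length(missing_ids) > 0) {
      stop_dynet(paste0(
        "Spikes reference neurons absent from the roster: ",
        paste(head(missing_ids, 5), collapse = ", ")
      ))
    }
  }
  if (is.null(window)) {
    window <- if (nrow(spikes) > 0) range(spikes$time) else c(0, 0)
  }
  window <- as.numeric(window)
  if (length(window) != 2 || anyNA(window) || window[2] < window[1]) {
    stop_dynet("`window` must be (t_start, t_end) with t_end >= t_start.")
  }
  if (nrow(spikes) > 0 &&
    (min(spikes$time) < window[1] || max(spikes$time) > window[2])) {
    stop_dynet("All spike times must lie within the recording window.",
      class = "dynet_validation_error"
    )
  }
  spikes <- dplyr::arrange(
    spikes,
    match(.data$neuron_id, neuron_ids), .data$time
  )
  structure(
    spikes,
    neuron_ids = neuron_ids,
    window = window,
    trial_id = trial_id,
    class = c("spike_trains", class(tibble()))
  )
}

#' @export
print.spike_trains <- function(x, ...) {
  w <- spike_window(x)
  cat(sprintf(
    "<spike_trains: %d neurons, %d spikes, window [%g, %g] s%s>\n",
    length(neuron_ids(x)), nrow(x), w[1], w[2],
    if (!is.null(trial_id(x))) paste0(", trial ", trial_id(x)) else ""
  ))
  NextMethod()
}

#' Accessors for spike-train and network containers
#'
#' @param x A `spike_trains`, `recording_session`, `dynamical_network` or
#'   related object.
#' @return `neuron_ids()` the roster (character); `spike_window()` the
#'   `(t_start, t_end)` window in seconds; `trial_id()` the trial label or
#'   `NULL`; `n_trials()` the number of trials.
#' @name accessors
#' @export
neuron_ids <- function(x) UseMethod("neuron_ids")

#' @export
neuron_ids.spike_trains <- function(x) attr(x, "neuron_ids")

#' @export
neuron_ids.recording_session <- function(x) attr(x, "neuron_ids")

#' @rdname accessors
#' @export
spike_window <- function(x) attr(x, "window")

#' @rdname accessors
#' @export
trial_id <- function(x) attr(x, "trial_id")

#' @rdname accessors
#' @export
n_trials <- function(x) length(x)

#' Split spike times into a per-neuron list
#'
#' @param x A `spike_trains` object.
#' @return A named list (one sorted numeric vector per roster neuron; empty
#'   vectors for silent neurons).
#' @export
spike_list <- function(x) {
  stopifnot(inherits(x, "spike_trains"))
  ids <- neuron_ids(x)
  out <- split(x$time, factor(x$neuron_id, levels = ids))
  lapply(out, as.numeric)
}

#' Multi-trial recording sessions
#'
#' A `recording_session` is an ordered list of [spike_trains()] objects that
#' share one neuron roster (in one order), so that networks built from the
#' trials align neuron-by-neuron. Trial windows may differ in duration.
#'
#' @param trials A list of `spike_trains` objects. Rosters must agree; a trial
#'   missing some roster neurons is an error (add them to its roster with
#'   empty trains instead).
#' @return A `recording_session` object.
#' @export
recording_session <- function(trials) {
  if (!is.list(trials) ||
    !all(vapply(trials, inherits, logical(1), "spike_trains"))) {
    stop_dynet("`trials` must be a list of spike_trains objects.")
  }
  if (length(trials) > 0) {
    roster <- neuron_ids(trials[[1]])
    same <- vapply(
      trials,
      function(t) identical(neuron_ids(t), roster), logical(1)
    )
    if (!all(same)) {
      stop_dynet("All trials must share an identical neuron roster and order.")
    }
  } else {
    roster <- character()
  }
  labels <- lapply(trials, trial_id)
  if (any(vapply(labels, is.null, logical(1)))) {
    labels <- as.list(seq_along(trials))
    trials <- purrr::map2(trials, labels, function(t, l) {
      attr(t, "trial_id") <- l
      t
    })
  }
  structure(
    trials,
    neuron_ids = roster,
    class = "recording_session"
  )
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf(
    "<recording_session: %d trials, %d neurons>\n",
    length(x), length(neuron_ids(x))
  ))
  invisible(x)
}

#' @method as_tibble recording_session
#' @export
as_tibble.recording_session <- function(x, ...) {
  if (length(x) == 0) {
    return(tibble(
      trial_id = character(), neuron_id = character(),
      spike_time_s = numeric()
    ))
  }
  purrr::map_dfr(x, function(t) {
    tibble(
      trial_id = as.character(trial_id(t)),
      neuron_id = t$neuron_id,
      spike_time_s = t$time
    )
  })
}
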