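#' Configuration for synthetic multi-trial population recordings
#'
#' Describes a population of neurons partitioned into planted ensembles.
#' Each ensemble emits shared "events" as a homogeneous Poisson process;
#' each member neuron spikes at each event with probability
#' `participation_p`, at the event time plus Gaussian jitter, on top of an
#' independent background Poisson train. Between trials each neuron switches
#' to a uniformly chosen ensemble with probability `drift`, emulating the
#' reorganization of interactions seen across learning.
#'
#' Defaults emulate a cortical population recording: 52 neurons (a typical
#' simultaneously recorded medial prefrontal population), 70 s trials,
#' 1 Hz background firing, 1 Hz ensemble events, participation 0.8, and
#' 50 ms jitter (spike-timing-scale coactivity).
#'
#' @param n_neurons Number of neurons.
#' @param n_ensembles Number of planted ensembles; membership is equal-size
#'   (remainders go to the first ensembles).
#' @param duration_s Trial duration in seconds.
#' @param n_trials Number of trials.
#' @param background_rate_hz Per-neuron background Poisson rate.
#' @param event_rate_hz Per-ensemble rate of shared events.
#' @param participation_p Probability a member spikes at each event.
#' @param jitter_s SD of a member's spike time around the event (clipped to
#'   the trial window, not wrapped).
#' @param drift Per-trial probability a neuron is reassigned to a uniformly
#'   random ensemble.
#' @param seed Master seed; drawn at random if `NULL`.
#' @return A `synthetic_config` object (validated list).
#' @export
synthetic_config <- function(n_neurons = 52, n_ensembles = 3,
                             duration_s = 70, n_trials = 1,
                             background_rate_hz = 1, event_rate_hz = 1,
                             participation_p = 0.8, jitter_s = 0.05,
                             drift = 0, seed = NULL) {
  cfg <- list(
    n_neurons = as.integer(n_neurons),
    n_ensembles = as.integer(n_ensembles),
    duration_s = as.numeric(duration_s),
    n_trials = as.integer(n_trials),
    background_rate_hz = as.numeric(background_rate_hz),
    event_rate_hz = as.numeric(event_rate_hz),
    participation_p = as.numeric(participation_p),
    jitter_s = as.numeric(jitter_s),
    drift = as.numeric(drift),
    seed = as.integer(seed %||% random_seed())
  )
  if (cfg$n_neurons < 1 || cfg$n_ensembles < 1 ||
    cfg$n_ensembles > cfg$n_neurons) {
    stop_dynet("Need 1 <= n_ensembles <= n_neurons.")
  }
  if (cfg$duration_s < 0 || cfg$n_trials < 1) {
    stop_dynet("`duration_s` must be >= 0 and `n_trials` >= 1.")
  }
  if (cfg$background_rate_hz < 0 || cfg$event_rate_hz < 0) {
    stop_dynet("Rates must be nonnegative.")
  }
  if (cfg$participation_p < 0 || cfg$participation_p > 1) {
    stop_dynet("`participation_p` must lie in [0, 1].")
  }
  if (cfg$jitter_s < 0 || cfg$drift < 0 || cfg$drift > 1) {
    stop_dynet("`jitter_s` must be >= 0 and `drift` in [0, 1].")
  }
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<synthetic_config: %d neurons in %d ensembles, %d x %g s trials,\n",
      "  background %g Hz, events %g Hz, p = %g, jitter %g s, drift %g, ",
      "seed %d>\n"
    ),
    x$n_neurons, x$n_ensembles, x$n_trials, x$duration_s,
    x$background_rate_hz, x$event_rate_hz, x$participation_p,
    x$jitter_s, x$drift, x$seed
  ))
  invisible(x)
}

synthetic_neuron_ids <- function(n) {
  sprintf(paste0("n%0", nchar(as.character(n)), "d"), seq_len(n))
}

equal_membership <- function(n_neurons, n_ensembles) {
  rep(seq_len(n_ensembles), length.out = n_neurons)[
    order(rep(seq_len(n_ensembles), length.out = n_neurons))
  ]
}

poisson_train <- function(rate, duration) {
  if (rate <= 0 || duration <= 0) {
    return(numeric())
  }
  n <- rpois(1, rate * duration)
  sort(runif(n, 0, duration))
}

#' Generate a synthetic recording session with planted ensembles
#'
#' Draws the session described by a [synthetic_config()]: per trial, each
#' ensemble draws a Poisson event train; each member emits one spike per
#' event with probability `participation_p` at the event time plus Gaussian
#' jitter (clipped to the trial window); an independent background Poisson
#' train is superimposed. Identical seeds give identical output.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `session` (a [recording_session()]) and `truth`
#'   (tibble `trial`, `neuron_id`, `ensemble`: the planted membership per
#'   trial).
#' @examples
#' out <- generate_synthetic_session(synthetic_config(
#'   n_neurons = 12, n_ensembles = 2, duration_s = 10, seed = 1
#' ))
#' out$session
#' @export
generate_synthetic_session <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ids <- synthetic_neuron_ids(cfg$n_neurons)
  with_seed(cfg$seed, {
    membership <- equal_membership(cfg$n_neurons, cfg$n_ensembles)
    trials <- vector("list", cfg$n_trials)
    truth <- vector("list", cfg$n_trials)
    for (tr in seq_len(cfg$n_trials)) {
      if (tr > 1 && cfg$drift > 0) {
        switch_mask <- runif(cfg$n_neurons) < cfg$drift
        membership[switch_mask] <- sample.int(
          cfg$n_ensembles, sum(switch_mask),
          replace = TRUE
        )
      }
      truth[[tr]] <- tibble(
        trial = as.character(tr), neuron_id = ids, ensemble = membership
      )
      spikes_by_neuron <- lapply(seq_len(cfg$n_neurons), function(i) {
        poisson_train(cfg$background_rate_hz, cfg$duration_s)
      })
      for (e in seq_len(cfg$n_ensembles)) {
        events <- poisson_train(cfg$event_rate_hz, cfg$duration_s)
        members <- which(membership == e)
        if (length(events) == 0 || length(members) == 0) next
        for (i in members) {
          fires <- runif(length(events)) < cfg$participation_p
          if (!any(fires)) next
          times <- events[fires] +
            rnorm(sum(fires), mean = 0, sd = cfg$jitter_s)
          times <- pmin(pmax(times, 0), cfg$duration_s)
          spikes_by_neuron[[i]] <- sort(c(spikes_by_neuron[[i]], times))
        }
      }
      df <- tibble(
        neuron_id = rep(ids, lengths(spikes_by_neuron)),
        time = unlist(spikes_by_neuron)
      )
      trials[[tr]] <- spike_trains(
        df,
        neuron_ids = ids, window = c(0, cfg$duration_s),
        trial_id = as.character(tr)
      )
    }
    list(
      session = recording_session(trials),
      truth = dplyr::bind_rows(truth)
    )
  })
}

#' Qualitative expectations for a synthetic configuration
#'
#' Returns the planted membership of the first trial and whether
#' within-ensemble interactions are expected to exceed between-ensemble ones
#' (which requires both shared events and nonzero participation).
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `membership` (tibble `neuron_id`, `ensemble`),
#'   `structured` (logical), and `stable_across_trials` (logical;
#'   `drift == 0`).
#' @export
expected_structure <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  list(
    membership = tibble(
      neuron_id = synthetic_neuron_ids(cfg$n_neurons),
      ensemble = equal_membership(cfg$n_neurons, cfg$n_ensembles)
    ),
    structured = cfg$participation_p > 0 && cfg$event_rate_hz > 0 &&
      cfg$n_ensembles > 1,
    stable_across_trials = cfg$drift == 0
  )
}
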