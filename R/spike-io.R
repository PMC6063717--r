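#' Read a long-table spike file into a recording session
#'
#' Reads delimited text with columns `trial_id`, `neuron_id`, `spike_time_s`
#' (one spike per row). The neuron roster is the lexicographically sorted
#' union of ids across all trials and is frozen in that order, so weight
#' matrices built from different trials align; a neuron absent from a trial's
#' rows is retained with an empty train. Trial windows default to the per-trial
#' spike-time range unless `windows` supplies explicit bounds.
#'
#' @param path Path to a TSV/CSV file.
#' @param format Only `"long_table"` is supported.
#' @param delim Field delimiter; guessed from the extension (`.csv` gives
#'   `","`, anything else tab) when `NULL`.
#' @param header Does the file carry a header row naming the three columns?
#'   If `FALSE` the columns are taken positionally as
#'   (trial_id, neuron_id, spike_time_s).
#' @param windows Optional data frame (`trial_id`, `t_start`, `t_end`) giving
#'   recording windows in seconds.
#' @return A [recording_session()].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "trial_id\tneuron_id\tspike_time_s",
#'   "1\ta\t0.10", "1\tb\t0.20", "1\ta\t0.35"
#' ), f)
#' read_spike_file(f)
#' @export
read_spike_file <- function(path, format = "long_table", delim = NULL,
                            header = TRUE, windows = NULL) {
  format <- match.arg(format, "long_table")
  if (!file.exists(path)) {
    stop_dynet(paste0("Spike file not found: ", path))
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  cols <- readr::cols(
    trial_id = readr::col_character(),
    neuron_id = readr::col_character(),
    spike_time_s = readr::col_double()
  )
  df <- suppressWarnings(if (header) {
    readr::read_delim(path,
      delim = delim, col_types = cols,
      progress = FALSE, show_col_types = FALSE
    )
  } else {
    readr::read_delim(path,
      delim = delim,
      col_names = c("trial_id", "neuron_id", "spike_time_s"),
      col_types = cols, progress = FALSE, show_col_types = FALSE
    )
  }) # parse issues surface below as a structured error with the line number
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop_dynet(
      sprintf(
        "Malformed spike file %s: first problem at line %d (%s).",
        path, probs$row[1] + as.integer(header), probs$expected[1]
      ),
      class = "dynet_parse_error"
    )
  }
  if (nrow(df) == 0) {
    warn(paste0("Spike file is empty: ", path))
    return(recording_session(list()))
  }
  if (!all(c("trial_id", "neuron_id", "spike_time_s") %in% names(df))) {
    stop_dynet(
      "Expected columns trial_id, neuron_id, spike_time_s.",
      class = "dynet_parse_error"
    )
  }
  if (any(df$spike_time_s < 0)) {
    bad <- which(df$spike_time_s < 0)[1]
    stop_dynet(
      sprintf(
        "Negative spike time at data row %d.", bad
      ),
      class = "dynet_validation_error"
    )
  }
  roster <- sort(unique(df$neuron_id))
  trial_levels <- unique(df$trial_id) # file order
  win_tbl <- NULL
  if (!is.null(windows)) {
    windows <- as_tibble(windows)
    if (!all(c("trial_id", "t_start", "t_end") %in% names(windows))) {
      stop_dynet("`windows` must have columns trial_id, t_start, t_end.")
    }
    windows$trial_id <- as.character(windows$trial_id)
    win_tbl <- windows
  }
  trials <- lapply(trial_levels, function(tr) {
    rows <- df[df$trial_id == tr, c("neuron_id", "spike_time_s")]
    names(rows) <- c("neuron_id", "time")
    win <- NULL
    if (!is.null(win_tbl) && tr %in% win_tbl$trial_id) {
      w <- win_tbl[win_tbl$trial_id == tr, ]
      win <- c(w$t_start[1], w$t_end[1])
    }
    spike_trains(rows, neuron_ids = roster, window = win, trial_id = tr)
  })
  recording_session(trials)
}

#' Write a recording session as a long-table spike file
#'
#' Inverse of [read_spike_file()]: one row per spike with columns `trial_id`,
#' `neuron_id`, `spike_time_s`. Windows are not stored in the long table; use
#' the `windows` argument of [read_spike_file()] to restore non-default ones.
#'
#' @param session A [recording_session()].
#' @param path Output path (`.csv` writes comma-delimited, otherwise TSV).
#' @return `path`, invisibly.
#' @export
write_spike_file <- function(session, path) {
  stopifnot(inherits(session, "recording_session"))
  df <- as_tibble(session)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(df, path, progress = FALSE)
  } else {
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}

net_format_from_path <- function(path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    "graphml"
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    "dense_csv"
  } else {
    "edge_list_tsv"
  }
}

#' Write and read dynamical networks
#'
#' `edge_list_tsv` stores the nonzero upper-triangle links as
#' (`node_a`, `node_b`, `weight`) after a `# neurons: ...` comment line that
#' preserves the full roster (so isolated neurons survive the round trip);
#' `dense_csv` stores the full weight matrix with the roster as header
#' row/column; `graphml` stores weights as a `weight` edge attribute.
#' Text formats round-trip weights losslessly (shortest round-trip doubles).
#'
#' @param net A [dynamical_network()].
#' @param path Output path.
#' @param format One of `"edge_list_tsv"`, `"dense_csv"`, `"graphml"`;
#'   guessed from the extension when `NULL`.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a [dynamical_network()].
#' @export
write_network <- function(net, path, format = NULL) {
  stopifnot(inherits(net, "dynamical_network"))
  format <- match.arg(
    format %||% net_format_from_path(path),
    c("edge_list_tsv", "dense_csv", "graphml")
  )
  w <- net$weights
  ids <- net$neuron_ids
  if (format == "edge_list_tsv") {
    idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    edges <- tibble(
      node_a = ids[idx[, 1]],
      node_b = ids[idx[, 2]],
      weight = w[idx]
    )
    writeLines(paste0("# neurons: ", paste(ids, collapse = ",")), path)
    readr::write_tsv(edges, path, append = TRUE, col_names = TRUE)
  } else if (format == "dense_csv") {
    df <- as_tibble(as.data.frame(w))
    names(df) <- ids
    df <- dplyr::bind_cols(tibble(neuron_id = ids), df)
    readr::write_csv(df, path, progress = FALSE)
  } else {
    g <- igraph::graph_from_adjacency_matrix(w,
      mode = "undirected",
      weighted = TRUE, diag = FALSE
    )
    igraph::V(g)$name <- ids
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = NULL) {
  if (!file.exists(path)) {
    stop_dynet(paste0("Network file not found: ", path))
  }
  format <- match.arg(
    format %||% net_format_from_path(path),
    c("edge_list_tsv", "dense_csv", "graphml")
  )
  if (format == "edge_list_tsv") {
    first <- readLines(path, n = 1)
    if (!grepl("^# neurons:", first)) {
      stop_dynet("Edge-list file lacks the '# neurons:' roster line.",
        class = "dynet_parse_error"
      )
    }
    ids <- strsplit(sub("^# neurons:\\s*", "", first), ",")[[1]]
    # base parser: correctly rounded doubles, so the round trip is lossless
    edges <- utils::read.delim(path,
      skip = 1,
      colClasses = c("character", "character", "numeric")
    )
    n <- length(ids)
    w <- matrix(0, n, n)
    if (nrow(edges) > 0) {
      ia <- match(edges$node_a, ids)
      ib <- match(edges$node_b, ids)
      if (anyNA(ia) || anyNA(ib)) {
        stop_dynet("Edge references a neuron absent from the roster line.",
          class = "dynet_parse_error"
        )
      }
      w[cbind(ia, ib)] <- edges$weight
      w[cbind(ib, ia)] <- edges$weight
    }
    dynamical_network(w, ids)
  } else if (format == "dense_csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    ids <- as.character(df$neuron_id)
    w <- as.matrix(df[, -1, drop = FALSE])
    dimnames(w) <- NULL
    dynamical_network(w, ids)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    w <- igraph::as_adjacency_matrix(g,
      attr = if ("weight" %in% igraph::edge_attr_names(g)) "weight" else NULL,
      sparse = FALSE
    )
    ids <- igraph::V(g)$name %||% as.character(seq_len(nrow(w)))
    dimnames(w) <- NULL
    dynamical_network(w, ids)
  }
}

#' Write and read ensemble partitions
#'
#' Partitions are stored as a two-column TSV (`neuron_id`, `module_label`);
#' the round trip is exact. An empty partition writes a header-only file.
#'
#' @param p An [ensemble_partition()] or a data frame with columns
#'   `neuron_id` and `module`.
#' @param path Output path.
#' @return `write_partition()` returns `path` invisibly; `read_partition()`
#'   returns a tibble (`neuron_id`, `module`) with attributes `q` and
#'   `n_modules` when present in the file, as an [ensemble_partition()].
#' @export
write_partition <- function(p, path) {
  df <- as_tibble(p)
  if (!all(c("neuron_id", "module") %in% names(df))) {
    stop_dynet("Partition must have columns `neuron_id` and `module`.")
  }
  out <- tibble(
    neuron_id = as.character(df$neuron_id),
    module_label = as.integer(df$module)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      neuron_id = readr::col_character(),
      module_label = readr::col_integer()
    )
  )
  new_ensemble_partition(
    neuron_id = df$neuron_id, module = df$module_label,
    q = NA_real_
  )
}
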