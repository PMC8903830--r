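#' Event-train set
#'
#' The pipeline's central currency: per-neuron sparse calcium-event times
#' (seconds) within one recording session.
#'
#' @param trains list of numeric vectors, one per neuron, event times in
#'   seconds (will be sorted).
#' @param duration_s session duration in seconds.
#' @param fs_hz trace sampling rate the events were extracted at (Hz).
#' @param neuron_ids optional character/integer ids; defaults to `seq_along`.
#' @return An object of class `event_train_set`: a list with elements
#'   `trains` (named list of sorted numeric vectors), `duration_s`, `fs_hz`,
#'   `n_neurons`.
#' @export
event_train_set <- function(trains, duration_s, fs_hz = 10, neuron_ids = NULL) {
  stopifnot_scalar_num(duration_s, "duration_s", lower = 1e-12)
  stopifnot_scalar_num(fs_hz, "fs_hz", lower = 1e-12)
  if (!is.list(trains)) stop("`trains` must be a list of numeric vectors")
  if (is.null(neuron_ids)) neuron_ids <- seq_along(trains)
  if (length(neuron_ids) != length(trains)) stop("neuron_ids length mismatch")
  trains <- lapply(trains, function(t) {
    t <- as.numeric(t)
    if (any(!is.finite(t)) || any(t < 0) || any(t > duration_s)) {
      stop("event times must lie in [0, duration_s]")
    }
    sort(t)
  })
  names(trains) <- as.character(neuron_ids)
  structure(
    list(trains = trains, duration_s = duration_s, fs_hz = fs_hz,
         n_neurons = length(trains)),
    class = "event_train_set"
  )
}

#' @export
print.event_train_set <- function(x, ...) {
  cnt <- lengths(x$trains)
  cat(sprintf("<event_train_set> %d neurons, %.0f s at %g Hz; %d events (%.2f/neuron)\n",
              x$n_neurons, x$duration_s, x$fs_hz, sum(cnt), mean(cnt)))
  invisible(x)
}

#' Subset an event-train set by neuron id
#'
#' @param x `event_train_set`.
#' @param ids neuron ids to keep (matched against `names(x$trains)`).
#' @return A new `event_train_set` restricted to `ids`, in the given order.
#' @export
subset_trains <- function(x, ids) {
  stopifnot(inherits(x, "event_train_set"))
  ids <- as.character(ids)
  missing <- setdiff(ids, names(x$trains))
  if (length(missing)) stop("unknown neuron ids: ", paste(missing, collapse = ", "))
  event_train_set(x$trains[ids], x$duration_s, x$fs_hz, neuron_ids = ids)
}

#' Redraw every neuron's event times uniformly in-session
#'
#' Temporal shuffle used by all permutation nulls: each neuron keeps its event
#' count but event times are redrawn uniformly over the session, destroying
#' all timing structure.
#'
#' @param x `event_train_set`.
#' @param seed integer seed (optional).
#' @param scheme `"redraw"` (uniform redraw, default) or `"circular"`
#'   (per-neuron circular shift by a uniform offset, preserving inter-event
#'   structure).
#' @return A shuffled `event_train_set`.
#' @export
shuffle_trains <- function(x, seed = NULL, scheme = c("redraw", "circular")) {
  stopifnot(inherits(x, "event_train_set"))
  scheme <- match.arg(scheme)
  with_seed(seed, {
    tr <- lapply(x$trains, function(t) {
      if (!length(t)) return(t)
      if (scheme == "redraw") {
        sort(runif(length(t), 0, x$duration_s))
      } else {
        sort((t + runif(1, 0, x$duration_s)) %% x$duration_s)
      }
    })
    event_train_set(tr, x$duration_s, x$fs_hz, neuron_ids = names(x$trains))
  })
}

#' Count events per neuron in a time window
#'
#' @param x `event_train_set`.
#' @param from,to window bounds in seconds, half-open `[from, to)`.
#' @return Named integer vector of counts.
#' @export
count_events <- function(x, from = 0, to = x$duration_s) {
  vapply(x$trains, function(t) sum(t >= from & t < to), integer(1))
}

#' Read / write event tables
#'
#' Event tables are plain CSV with columns `neuron_id,time_s`, one row per
#' calcium event; session metadata travels in a JSON sidecar.
#'
#' @param path CSV file path.
#' @param duration_s,fs_hz session metadata (required on read).
#' @return `read_events`: an `event_train_set`. `write_events`: the path,
#'   invisibly.
#' @export
read_events <- function(path, duration_s, fs_hz = 10) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("neuron_id", "time_s") %in% names(df)))
  ids <- unique(df$neuron_id)
  trains <- lapply(ids, function(id) df$time_s[df$neuron_id == id])
  event_train_set(trains, duration_s, fs_hz, neuron_ids = ids)
}

#' @rdname read_events
#' @param x `event_train_set` to write.
#' @export
write_events <- function(x, path) {
  stopifnot(inherits(x, "event_train_set"))
  df <- data.frame(
    neuron_id = rep(names(x$trains), lengths(x$trains)),
    time_s = unlist(x$trains, use.names = FALSE)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
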