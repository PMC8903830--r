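#' Binned z-score of a neuron's event counts against its pre-shock baseline
#'
#' The session is tiled with `bin_s` bins; each bin's event count is z-scored
#' against the mean and SD of the bins inside the baseline window. The
#' baseline SD is floored (default: the equivalent of 0.5 events per bin) so
#' silent-baseline neurons get large but finite z; such neurons are flagged.
#'
#' @param times event times (s) of one neuron.
#' @param duration_s session length (s).
#' @param bin_s bin width (default 5).
#' @param baseline_window `c(start, end)` in seconds (default `c(0, 180)`).
#' @param sd_floor minimum baseline SD in events/bin (default 0.5).
#' @return A list: `z` (per-bin z), `counts`, `bin_start_s`, `baseline_mean`,
#'   `baseline_sd` (pre-floor), `floored` (logical).
#' @export
zscore_binned <- function(times, duration_s, bin_s = 5,
                          baseline_window = c(0, 180), sd_floor = 0.5) {
  stopifnot_scalar_num(bin_s, "bin_s", lower = 1e-9)
  edges <- seq(0, duration_s + 1e-9, by = bin_s)
  if (utils::tail(edges, 1) < duration_s - 1e-9) edges <- c(edges, duration_s)
  starts <- utils::head(edges, -1)
  counts <- vapply(seq_along(starts), function(b) {
    sum(times >= edges[b] & times < edges[b + 1])
  }, numeric(1))
  base_bins <- starts >= baseline_window[1] - 1e-9 &
    starts < baseline_window[2] - 1e-9
  if (sum(base_bins) < 6) stop("baseline window must contain at least 6 bins")
  mu <- mean(counts[base_bins])
  s <- sd(counts[base_bins])
  floored <- !is.finite(s) || s < sd_floor
  list(z = (counts - mu) / max(s, sd_floor, na.rm = TRUE),
       counts = counts, bin_start_s = starts,
       baseline_mean = mu, baseline_sd = s, floored = floored)
}

#' Classify foot-shock-responsive (FSR) neurons
#'
#' A neuron is FSR when its 5-s-binned, baseline-z-scored activity rises
#' above 2 SD during or after any foot-shock. The default statistic is the
#' mean binned z over a shock's response window
#' `[shock, shock + response_window_s]` (the shock-delivery bin included),
#' the same window average used for the preFS/postFS quantification; with
#' `criterion = "any_bin"` a single bin above 2 SD in any window suffices
#' instead (note that with Poisson count statistics the per-bin maximum over
#' 18 bins has a heavy null tail, so that variant mislabels a large share of
#' non-responders).
#'
#' @param trains an [event_train_set()].
#' @param shock_times_s shock onset times (s); session metadata, default
#'   `c(180, 240, 300)`.
#' @param bin_s bin width (default 5).
#' @param baseline_window baseline window (default `c(0, 180)` = up to the
#'   first shock).
#' @param response_window_s response window length after each shock (default
#'   30). `Inf` extends every window to the session end.
#' @param z_crit FSR criterion in SD units (default 2, strict `>`).
#' @param criterion `"window_mean"` (default) or `"any_bin"`.
#' @param sd_floor see [zscore_binned()].
#' @return A list of class `fsr_labeling`: `label` (factor FSR/nFSR per
#'   neuron), `pct_fsr`, `max_window_z` (the per-neuron maximum of the
#'   criterion statistic over shock windows), `flag_floored`, and the
#'   parameters.
#' @export
classify_fsr <- function(trains, shock_times_s = c(180, 240, 300), bin_s = 5,
                         baseline_window = c(0, 180), response_window_s = 30,
                         z_crit = 2, criterion = c("window_mean", "any_bin"),
                         sd_floor = 0.5) {
  stopifnot(inherits(trains, "event_train_set"))
  criterion <- match.arg(criterion)
  ids <- names(trains$trains)
  max_z <- rep(-Inf, length(ids))
  floored <- logical(length(ids))
  zs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    zb <- zscore_binned(trains$trains[[i]], trains$duration_s, bin_s,
                        baseline_window, sd_floor)
    zs[[i]] <- zb
    floored[i] <- zb$floored
    for (t0 in shock_times_s) {
      # bins overlapping [shock, shock + window]
      inwin <- zb$bin_start_s + bin_s > t0 &
        zb$bin_start_s < t0 + response_window_s
      if (any(inwin)) {
        stat <- if (criterion == "window_mean") mean(zb$z[inwin]) else max(zb$z[inwin])
        max_z[i] <- max(max_z[i], stat)
      }
    }
  }
  label <- factor(ifelse(max_z > z_crit, "FSR", "nFSR"), levels = c("FSR", "nFSR"))
  names(label) <- ids
  structure(list(label = label,
                 pct_fsr = 100 * mean(label == "FSR"),
                 max_window_z = stats::setNames(max_z, ids),
                 flag_floored = stats::setNames(floored, ids),
                 z = zs, shock_times_s = shock_times_s, bin_s = bin_s,
                 baseline_window = baseline_window,
                 response_window_s = response_window_s),
            class = "fsr_labeling")
}

#' @export
print.fsr_labeling <- function(x, ...) {
  cat(sprintf("<fsr_labeling> %d neurons, %.1f%% FSR (%d shocks)\n",
              length(x$label), x$pct_fsr, length(x$shock_times_s)))
  invisible(x)
}

#' Pre/post foot-shock response per neuron
#'
#' For each shock, the mean baseline-z-scored activity over the 30 s before
#' (`preFS`) and after (`postFS`) the shock; averaged over shocks. Because it
#' averages whole windows, the mean postFS response of an FSR neuron can fall
#' below the 2-SD classification criterion.
#'
#' @param trains an [event_train_set()].
#' @param labeling a [classify_fsr()] result (supplies bins, baseline and
#'   shock times).
#' @param window_s pre/post window length (default 30).
#' @return Data frame: `neuron_id`, `label`, `preFS`, `postFS` (mean z, SD
#'   units).
#' @export
pre_post_response <- function(trains, labeling, window_s = 30) {
  stopifnot(inherits(labeling, "fsr_labeling"))
  shocks <- labeling$shock_times_s
  if (length(shocks) > 1 && any(diff(sort(shocks)) < 2 * window_s)) {
    warning("pre/post windows of consecutive shocks overlap")
  }
  ids <- names(labeling$label)
  pre <- post <- numeric(length(ids))
  for (i in seq_along(ids)) {
    zb <- labeling$z[[i]]
    pre_i <- post_i <- numeric(0)
    for (t0 in shocks) {
      pre_bins <- zb$bin_start_s >= t0 - window_s - 1e-9 & zb$bin_start_s < t0 - 1e-9
      post_bins <- zb$bin_start_s >= t0 - 1e-9 & zb$bin_start_s < t0 + window_s - 1e-9
      pre_i <- c(pre_i, mean(zb$z[pre_bins]))
      post_i <- c(post_i, mean(zb$z[post_bins]))
    }
    pre[i] <- mean(pre_i); post[i] <- mean(post_i)
  }
  data.frame(neuron_id = ids, label = as.character(labeling$label),
             preFS = pre, postFS = post, stringsAsFactors = FALSE)
}

#' Sham FSR classification on a no-shock baseline session
#'
#' Runs the FSR classification at virtual shock times on a recording that
#' contained no foot-shock, as a false-positive control. The computation is
#' identical to [classify_fsr()]; only the time labels differ.
#'
#' @param trains baseline-session [event_train_set()].
#' @param virtual_shock_times_s virtual shock times (default
#'   `c(180, 240, 300)`, the real protocol's times).
#' @param ... passed to [classify_fsr()].
#' @return An `fsr_labeling` (the "shamFSR" labels).
#' @export
sham_fsr <- function(trains, virtual_shock_times_s = c(180, 240, 300), ...) {
  classify_fsr(trains, shock_times_s = virtual_shock_times_s, ...)
}

#' Reactivation of FSR neurons among later correlated neurons
#'
#' The percentage of day-1 correlated neurons that are cross-day-registered
#' day-0 FSR cells: a cell counts when (1) it is matched across the two days,
#' (2) it was FSR on day 0, (3) it is correlated with at least one other cell
#' on day 1.
#'
#' @param fsr_ids_day0 day-0 neuron ids labeled FSR.
#' @param correlated_ids_day1 day-1 ids of neurons in at least one correlated
#'   pair.
#' @param map a [register_fixed_threshold()] registration map.
#' @param session_day0,session_day1 session indices within the map.
#' @return Percent of day-1 correlated neurons satisfying all three criteria;
#'   `NA` with a warning when the correlated set is empty.
#' @export
fsr_correlated_reactivation <- function(fsr_ids_day0, correlated_ids_day1, map,
                                        session_day0 = 1, session_day1 = 2) {
  if (!length(correlated_ids_day1)) {
    warning("empty correlated set; reactivation % undefined")
    return(NA_real_)
  }
  fsr_ids_day0 <- as.character(fsr_ids_day0)
  correlated_ids_day1 <- as.character(correlated_ids_day1)
  hits <- vapply(correlated_ids_day1, function(id) {
    g <- map_lookup(map, session_day1, id)
    if (is.na(g)) return(FALSE)
    partner <- map_reverse(map, session_day0, g)
    !is.na(partner) && partner %in% fsr_ids_day0
  }, logical(1))
  100 * mean(hits)
}
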