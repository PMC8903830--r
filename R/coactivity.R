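#' Build an event-padded binary raster
#'
#' Each event is represented as a contiguous run of 1s covering the event
#' frame +/- `pad_ms` (rounded to frames; 200 ms at 10 Hz is +/- 2 frames),
#' clipped to the session bounds. Overlapping pads merge (binary OR).
#'
#' @param trains an [event_train_set()].
#' @param fs_hz raster sampling rate (defaults to the set's `fs_hz`).
#' @param pad_ms pad half-width in milliseconds (default 200).
#' @param duration_s raster duration (defaults to the set's).
#' @return Binary integer matrix, neurons x frames, with `pad_frames` and
#'   `fs_hz` attributes.
#' @export
events_to_padded_raster <- function(trains, fs_hz = trains$fs_hz, pad_ms = 200,
                                    duration_s = trains$duration_s) {
  stopifnot(inherits(trains, "event_train_set"))
  n_frames <- max(1L, round(duration_s * fs_hz))
  pad <- round(pad_ms * fs_hz / 1000)
  r <- matrix(0L, trains$n_neurons, n_frames,
              dimnames = list(names(trains$trains), NULL))
  for (i in seq_len(trains$n_neurons)) {
    for (t0 in trains$trains[[i]]) {
      if (t0 < 0 || t0 > duration_s) {
        stop(sprintf("event at %.3f s outside session for neuron %s",
                     t0, names(trains$trains)[i]))
      }
      f <- min(n_frames, floor(t0 * fs_hz) + 1L)
      r[i, max(1L, f - pad):min(n_frames, f + pad)] <- 1L
    }
  }
  attr(r, "pad_frames") <- pad
  attr(r, "fs_hz") <- fs_hz
  r
}

#' Zero-lag pairwise correlation of a padded raster
#'
#' Pearson correlation between all row pairs of the binary raster. Rows with
#' zero variance (all-0 or all-1) get correlation 0 against every other row
#' and are flagged. Optionally the maximum absolute correlation over lags up
#' to `max_lag_frames` is taken instead (default 0: the +/- 200 ms pad
#' already absorbs small lags).
#'
#' @param r raster from [events_to_padded_raster()].
#' @param max_lag_frames maximum lag to scan (default 0, zero-lag).
#' @return Symmetric correlation matrix with `NA` diagonal and a
#'   `zero_variance` attribute (logical per row).
#' @export
pairwise_correlation <- function(r, max_lag_frames = 0) {
  stopifnot(is.matrix(r), nrow(r) >= 2, ncol(r) >= 1)
  v <- apply(r, 1, stats::var)
  zv <- v == 0 | !is.finite(v)
  cmat <- suppressWarnings(stats::cor(t(r)))
  if (max_lag_frames > 0) {
    for (lag in seq_len(max_lag_frames)) {
      a <- r[, seq_len(ncol(r) - lag), drop = FALSE]
      b <- r[, (lag + 1):ncol(r), drop = FALSE]
      cl <- suppressWarnings(stats::cor(t(a), t(b)))
      cand <- pmax(abs(cl), abs(t(cl)))
      upd <- cand > abs(cmat) & is.finite(cand)
      cmat[upd] <- cand[upd]
    }
  }
  cmat[zv, ] <- 0
  cmat[, zv] <- 0
  diag(cmat) <- NA_real_
  attr(cmat, "zero_variance") <- zv
  cmat
}

#' Temporal-shuffle null for pairwise correlations
#'
#' For each shuffle, every neuron's event times are redrawn uniformly over
#' the session (event counts preserved), the padded raster is rebuilt, and
#' all pairwise correlations are pooled into one null distribution. The
#' correlated-pair threshold is the pooled mean + 2 pooled SD. Correlations
#' involving zero-variance rows are excluded from the pool.
#'
#' @param trains an [event_train_set()].
#' @param n_shuffles number of shuffles (default 1000).
#' @param seed integer seed.
#' @param pad_ms,fs_hz raster parameters, as in
#'   [events_to_padded_raster()].
#' @param scheme shuffle scheme, see [shuffle_trains()].
#' @param sd_mult threshold multiplier (default 2).
#' @return A list with `null_mean`, `null_sd`, `threshold`, `n_shuffles`,
#'   `seed`.
#' @export
shuffle_null <- function(trains, n_shuffles = 1000, seed = 1L, pad_ms = 200,
                         fs_hz = trains$fs_hz, scheme = "redraw", sd_mult = 2) {
  stopifnot(inherits(trains, "event_train_set"), n_shuffles >= 1)
  if (all(lengths(trains$trains) == 0)) {
    return(list(null_mean = NA_real_, null_sd = NA_real_, threshold = NA_real_,
                n_shuffles = n_shuffles, seed = seed, flag = "all trains empty"))
  }
  seeds <- derive_seeds(seed, n_shuffles)
  # accumulate moments rather than the full pool (n_pairs x n_shuffles values)
  s1 <- 0; s2 <- 0; m <- 0
  for (k in seq_len(n_shuffles)) {
    sh <- shuffle_trains(trains, seed = seeds[k], scheme = scheme)
    cm <- pairwise_correlation(events_to_padded_raster(sh, fs_hz, pad_ms))
    zv <- attr(cm, "zero_variance")
    cm <- cm[!zv, !zv, drop = FALSE]
    vals <- cm[upper.tri(cm)]
    vals <- vals[is.finite(vals)]
    s1 <- s1 + sum(vals); s2 <- s2 + sum(vals^2); m <- m + length(vals)
  }
  if (m < 2) {
    return(list(null_mean = NA_real_, null_sd = NA_real_, threshold = NA_real_,
                n_shuffles = n_shuffles, seed = seed, flag = "null pool empty"))
  }
  mu <- s1 / m
  sdv <- sqrt(max(0, (s2 - m * mu^2) / (m - 1)))
  list(null_mean = mu, null_sd = sdv, threshold = mu + sd_mult * sdv,
       n_shuffles = n_shuffles, seed = seed)
}

#' Percentage of correlated pairs
#'
#' The share (in %) of neuron pairs whose zero-lag correlation exceeds the
#' shuffle threshold, over all possible pairs within the (sub)set.
#'
#' @param cmat correlation matrix from [pairwise_correlation()].
#' @param threshold correlated-pair threshold (from [shuffle_null()]).
#' @param subset optional neuron ids (row/col names) to restrict to.
#' @return Percent in `[0, 100]`; `NA` (flagged by warning) when fewer than
#'   two neurons are in the subset.
#' @export
count_correlated_pairs <- function(cmat, threshold, subset = NULL) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (!is.null(subset)) {
    subset <- as.character(subset)
    if (!all(subset %in% rownames(cmat))) stop("subset ids not in matrix")
    cmat <- cmat[subset, subset, drop = FALSE]
  }
  n <- nrow(cmat)
  if (n < 2) {
    warning("fewer than 2 neurons in subset; correlated-pair % undefined")
    return(NA_real_)
  }
  vals <- cmat[upper.tri(cmat)]
  100 * sum(vals > threshold, na.rm = TRUE) / (n * (n - 1) / 2)
}

#' One-call co-activity summary for a session
#'
#' Builds the padded raster, the pairwise correlation matrix, the
#' temporal-shuffle null and the correlated-pair percentage.
#'
#' @inheritParams shuffle_null
#' @param subset optional neuron ids for the pair count.
#' @return A list of class `correlation_summary`: `cor_matrix`, `null_mean`,
#'   `null_sd`, `threshold`, `pct_pairs`, `n_neurons`, `n_shuffles`, `seed`.
#' @export
coactivity_summary <- function(trains, n_shuffles = 1000, seed = 1L,
                               pad_ms = 200, subset = NULL) {
  cm <- pairwise_correlation(events_to_padded_raster(trains, pad_ms = pad_ms))
  nul <- shuffle_null(trains, n_shuffles, seed, pad_ms)
  pct <- if (is.finite(nul$threshold)) {
    count_correlated_pairs(cm, nul$threshold, subset)
  } else NA_real_
  structure(list(cor_matrix = cm, null_mean = nul$null_mean,
                 null_sd = nul$null_sd, threshold = nul$threshold,
                 pct_pairs = pct, n_neurons = trains$n_neurons,
                 n_shuffles = n_shuffles, seed = seed),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf("<correlation_summary> %d neurons; threshold %.4f (null %.4f +/- %.4f, %d shuffles); %.2f%% correlated pairs\n",
              x$n_neurons, x$threshold, x$null_mean, x$null_sd, x$n_shuffles,
              x$pct_pairs))
  invisible(x)
}

#' Normalize a correlated-pair percentage to the same-day baseline
#'
#' @param ctx_pct correlated-pair % in the context session.
#' @param baseline_pct correlated-pair % in the same-day baseline session.
#' @return The ratio (1 = at baseline); `NA` with a warning when the baseline
#'   is zero.
#' @export
normalize_to_baseline <- function(ctx_pct, baseline_pct) {
  if (!is.finite(baseline_pct) || baseline_pct == 0) {
    warning("baseline correlated-pair % is zero or undefined; ratio flagged NA")
    return(NA_real_)
  }
  ctx_pct / baseline_pct
}

#' Cross-group correlated-pair percentage
#'
#' The share of above-threshold pairs among all `|A| x |B|` pairs spanning
#' two disjoint neuron groups (e.g. FSR vs non-FSR).
#'
#' @param cmat correlation matrix.
#' @param group_a,group_b disjoint neuron id vectors.
#' @param threshold correlated-pair threshold.
#' @return Percent in `[0, 100]`.
#' @export
cross_group_coactivity <- function(cmat, group_a, group_b, threshold) {
  group_a <- as.character(group_a); group_b <- as.character(group_b)
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  if (!all(c(group_a, group_b) %in% rownames(cmat))) stop("ids not in matrix")
  sub <- cmat[group_a, group_b, drop = FALSE]
  100 * sum(sub > threshold, na.rm = TRUE) / (length(group_a) * length(group_b))
}
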